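# PLINK 1.9 binary I/O. SNP-major .bed with the 2-bit codes
#   00 -> two copies of allele 1 (code 2), 10 -> heterozygote (code 1),
#   11 -> no copy of allele 1 (code 0), 01 -> missing.
# The counted allele (code 2) is .bim allele 1, and the within-byte order
# puts the first sample in the two lowest-order bits.

.bedMagic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> the four genotype codes it packs
.bedDecodeTable <- local({
  two_bit_to_code <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  tab <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    v <- b
    for (s in 1:4) {
      tab[b + 1, s] <- two_bit_to_code[(v %% 4) + 1]
      v <- v %/% 4
    }
  }
  tab
})

.codeToTwoBit <- function(codes) {
  out <- integer(length(codes))
  out[is.na(codes)] <- 1L
  out[!is.na(codes) & codes == 2L] <- 0L
  out[!is.na(codes) & codes == 1L] <- 2L
  out[!is.na(codes) & codes == 0L] <- 3L
  out
}

#' Construct a GenotypeData object
#'
#' @param codes integer matrix of 0/1/2/NA genotype codes, individuals in
#'   rows, SNPs in columns.
#' @param map data.frame with \code{snp_id}, \code{chrom}, \code{pos_bp}
#'   (and optionally \code{a1}, \code{a2}); SNPs are reordered to
#'   (chrom, pos_bp) order.
#' @param iid character individual ids.
#' @param pop population label per individual (at most two).
#' @return a \linkS4class{GenotypeData}; counted-allele frequencies are
#'   computed from the non-missing codes of the pooled sample.
#' @export
genotypeData <- function(codes, map, iid, pop) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!"a1" %in% names(map)) map$a1 <- "A"
  if (!"a2" %in% names(map)) map$a2 <- "B"
  o <- order(map$chrom, map$pos_bp)
  map <- map[o, , drop = FALSE]
  codes <- codes[, o, drop = FALSE]
  rownames(map) <- NULL
  rownames(codes) <- iid
  colnames(codes) <- map$snp_id
  freq <- colMeans(codes, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- NA_real_
  new("GenotypeData", codes = codes, map = map, iid = as.character(iid),
      pop = factor(pop), freq = unname(freq))
}

#' Read a PLINK 1.9 binary fileset
#'
#' Decodes \code{prefix.bed/.bim/.fam} into a \linkS4class{GenotypeData}.
#' The counted allele (genotype code 2) is the first allele column of the
#' \code{.bim} file; the population label is taken from the family id
#' (first) column of the \code{.fam} file.
#'
#' @param prefix path prefix of the .bed/.bim/.fam triplet.
#' @return a \linkS4class{GenotypeData}.
#' @seealso [writePlink()]
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("input missing: ", f, call. = FALSE)
  if (length(readLines(fam, n = 1)) == 0)
    stop("empty .fam file: ", fam, call. = FALSE)
  famDf <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
  bimDf <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("chrom", "snp_id", "cm", "pos_bp",
                                    "a1", "a2"))
  n <- nrow(famDf); m <- nrow(bimDf)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .bedMagic))
    stop("malformed .bed magic bytes (expected 6c 1b 01, SNP-major)",
         call. = FALSE)
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stop(sprintf(".bed size inconsistent with .fam/.bim (%d bytes, expected %d)",
                 length(raw) - 3L, bps * m), call. = FALSE)
  body <- as.integer(raw[-(1:3)])
  # decode all bytes at once, then reshape: columns of `dec` are SNPs
  dec <- matrix(t(.bedDecodeTable[body + 1L, , drop = FALSE]), nrow = 4L * bps)
  codes <- dec[seq_len(n), , drop = FALSE]
  map <- data.frame(snp_id = bimDf$snp_id, chrom = bimDf$chrom,
                    pos_bp = bimDf$pos_bp, a1 = bimDf$a1, a2 = bimDf$a2,
                    stringsAsFactors = FALSE)
  genotypeData(codes, map, iid = famDf[[2]], pop = famDf[[1]])
}

#' Write a PLINK 1.9 binary fileset
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
writePlink <- function(g, prefix) {
  codes <- g@codes
  n <- nrow(codes); m <- ncol(codes)
  pad <- (4 - n %% 4) %% 4
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bedMagic, con)
  tb <- .codeToTwoBit(as.vector(codes))  # column-major: SNP after SNP
  tb <- matrix(tb, nrow = n)
  if (pad > 0) tb <- rbind(tb, matrix(0L, pad, m))
  mult <- c(1L, 4L, 16L, 64L)
  bytes <- tb[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] * mult[1] +
    tb[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] * mult[2] +
    tb[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] * mult[3] +
    tb[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE] * mult[4]
  writeBin(as.raw(bytes), con)
  bim <- data.frame(g@map$chrom, g@map$snp_id, 0L, g@map$pos_bp,
                    g@map$a1, g@map$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(as.character(g@pop), g@iid, 0L, 0L, 0L, -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read or write the phenotype TSV interface
#'
#' The phenotype table is a TSV with header \code{iid}, \code{pop} and one
#' or more trait columns; missing values are written as \code{NA}.
#' Responses are pre-corrected phenotypes or de-regressed proofs; both are
#' treated identically as response values.
#'
#' @param path file path.
#' @return \code{readPhenotypes}: a data.frame with columns \code{iid},
#'   \code{pop} and the trait columns.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("input missing: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("iid", "pop") %in% names(df)))
    stop("phenotype file must have 'iid' and 'pop' columns", call. = FALSE)
  df$iid <- as.character(df$iid)
  if (anyDuplicated(df$iid))
    stop("duplicated individual in phenotype table", call. = FALSE)
  df
}

#' @rdname readPhenotypes
#' @param pheno a phenotype data.frame as returned by [readPhenotypes()].
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a block definition TSV
#'
#' Blocks are stored as \code{chrom  start_bp  end_bp  block_id} with
#' 1-based inclusive ends. Reading requires the SNP map to convert base-pair
#' spans back to SNP index ranges.
#'
#' @param path file path.
#' @param g a \linkS4class{GenotypeData} supplying the SNP map.
#' @return \code{readBlocks}: a \linkS4class{GenomePartition}.
#' @export
readBlocks <- function(path, g) {
  if (!file.exists(path)) stop("input missing: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start_bp", "end_bp", "block_id")
  if (!all(need %in% names(df)))
    stop("block file must have chrom, start_bp, end_bp, block_id",
         call. = FALSE)
  map <- g@map
  rows <- lapply(seq_len(nrow(df)), function(i) {
    sel <- which(map$chrom == df$chrom[i] & map$pos_bp >= df$start_bp[i] &
                 map$pos_bp <= df$end_bp[i])
    if (!length(sel)) return(NULL)
    data.frame(block_id = df$block_id[i], chrom = df$chrom[i],
               start_index = min(sel), end_index = max(sel),
               start_bp = map$pos_bp[min(sel)], end_bp = map$pos_bp[max(sel)],
               n_snps = length(sel), stringsAsFactors = FALSE)
  })
  b <- do.call(rbind, rows)
  b <- b[order(b$start_index), , drop = FALSE]
  rownames(b) <- NULL
  new("GenomePartition", blocks = b)
}

#' @rdname readBlocks
#' @param partition a \linkS4class{GenomePartition}.
#' @export
writeBlocks <- function(partition, path) {
  b <- partition@blocks
  out <- data.frame(chrom = b$chrom, start_bp = b$start_bp,
                    end_bp = b$end_bp, block_id = b$block_id)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
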