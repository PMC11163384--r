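#' Squared LD correlation between two SNPs
#'
#' Squared Pearson correlation of two centered genotype columns.
#'
#' @param w a \linkS4class{CenteredGenotypes}.
#' @param i,j column indices into \code{w}.
#' @return r-squared in [0, 1].
#' @export
pairwiseR2 <- function(w, i, j) {
  x <- w@W[, i]; y <- w@W[, j]
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant genotype column", call. = FALSE)
  cor(x, y)^2
}

# Cross-break LD score: sum of r2 over pairs with i in the `window` SNPs
# left of the break and j in the `window` SNPs right of it. C2 is the
# squared correlation matrix of the chromosome's columns (local indices).
.breakScore <- function(C2, start, end, b, window) {
  li <- max(start, b - window + 1):b
  ri <- (b + 1):min(end, b + window)
  sum(C2[li, ri])
}

# Split blocks recursively until none exceeds maxBlockSnps. Blocks and
# breakpoints use local (within-chromosome) indices.
.splitBlocks <- function(C2, nLoc, maxBlockSnps, minSnps, window) {
  blocks <- list(c(1L, nLoc))
  repeat {
    sizes <- vapply(blocks, function(b) b[2] - b[1] + 1L, integer(1))
    if (max(sizes) <= maxBlockSnps) break
    k <- which.max(sizes)  # largest block; ties -> leftmost
    st <- blocks[[k]][1]; en <- blocks[[k]][2]
    cand <- seq(st + minSnps - 1L, en - minSnps)
    scores <- vapply(cand, function(b) .breakScore(C2, st, en, b, window),
                     numeric(1))
    b <- cand[which.min(scores)]  # leftmost minimal score
    blocks <- append(blocks[-k], list(c(st, b), c(b + 1L, en)), after = k - 1L)
  }
  blocks
}

#' Partition one chromosome into LD blocks
#'
#' Recursive breakpoint search: while any block exceeds
#' \code{maxBlockSnps}, the block with the most SNPs is split at the
#' admissible breakpoint (both resulting blocks at least \code{minSnps}
#' SNPs) minimizing the local cross-break LD score, i.e. the sum of
#' \eqn{r^2} over SNP pairs within \code{window} SNPs on either side of the
#' break. Ties go to the leftmost minimal breakpoint.
#'
#' @param w a \linkS4class{CenteredGenotypes} covering (at least) the
#'   chromosome.
#' @param g the parent \linkS4class{GenotypeData} (for the map).
#' @param chrom chromosome label.
#' @param maxBlockSnps largest tolerated block size in SNPs.
#' @param minSnps smallest allowed block size in SNPs.
#' @param window number of flanking SNPs scored on each side of a
#'   candidate break.
#' @return a \linkS4class{GenomePartition} for the chromosome (block ids
#'   numbered from 1).
#' @export
partitionChromosome <- function(w, g, chrom, maxBlockSnps,
                                minSnps = 25, window = 50) {
  if (maxBlockSnps < 2 * minSnps)
    stop("maxBlockSnps must be at least 2*minSnps", call. = FALSE)
  glob <- which(g@map$chrom == chrom)
  if (!length(glob)) stop("unknown chromosome: ", chrom, call. = FALSE)
  loc <- match(glob, w@snpIndex)
  if (anyNA(loc))
    stop("centered genotypes do not cover chromosome ", chrom, call. = FALSE)
  nLoc <- length(loc)
  if (nLoc <= maxBlockSnps) {
    blocks <- list(c(1L, nLoc))
  } else {
    Wc <- w@W[, loc, drop = FALSE]
    # constant columns carry no LD information; score them as zero r2
    C <- suppressWarnings(cor(Wc))
    C[!is.finite(C)] <- 0
    C2 <- C^2
    diag(C2) <- 1
    blocks <- .splitBlocks(C2, nLoc, maxBlockSnps, minSnps, window)
  }
  b <- do.call(rbind, lapply(seq_along(blocks), function(k) {
    st <- glob[blocks[[k]][1]]; en <- glob[blocks[[k]][2]]
    data.frame(block_id = k, chrom = chrom, start_index = st,
               end_index = en, start_bp = g@map$pos_bp[st],
               end_bp = g@map$pos_bp[en], n_snps = en - st + 1L,
               stringsAsFactors = FALSE)
  }))
  new("GenomePartition", blocks = b)
}

#' Partition the genome into LD blocks
#'
#' Applies [partitionChromosome()] to every chromosome in map order; block
#' ids are numbered genome-wide. A chromosome with fewer than
#' \code{minSnps} SNPs is emitted as a single block with a warning.
#'
#' @inheritParams partitionChromosome
#' @return a \linkS4class{GenomePartition}.
#' @export
partitionGenome <- function(w, g, maxBlockSnps, minSnps = 25, window = 50) {
  chroms <- unique(g@map$chrom)
  parts <- lapply(chroms, function(ch) {
    nCh <- sum(g@map$chrom == ch)
    if (nCh < minSnps) {
      warning("chromosome ", ch, " has fewer than minSnps SNPs; ",
              "emitted as a single block", call. = FALSE)
      glob <- which(g@map$chrom == ch)
      return(data.frame(block_id = 1L, chrom = ch, start_index = min(glob),
                        end_index = max(glob),
                        start_bp = g@map$pos_bp[min(glob)],
                        end_bp = g@map$pos_bp[max(glob)], n_snps = nCh,
                        stringsAsFactors = FALSE))
    }
    partitionChromosome(w, g, ch, maxBlockSnps, minSnps, window)@blocks
  })
  b <- do.call(rbind, parts)
  b$block_id <- seq_len(nrow(b))
  rownames(b) <- NULL
  new("GenomePartition", blocks = b)
}

#' SNP index sets of the blocks of a partition
#'
#' @param partition a \linkS4class{GenomePartition}.
#' @return named list (by block_id) of global SNP index vectors.
#' @export
blockSnpSets <- function(partition) {
  b <- partition@blocks
  out <- lapply(seq_len(nrow(b)),
                function(k) seq(b$start_index[k], b$end_index[k]))
  names(out) <- as.character(b$block_id)
  out
}
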