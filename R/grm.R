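#' Center genotypes for GRM construction
#'
#' Computes the VanRaden-centered matrix \eqn{w_{ij} = m_{ij} - 2 p_j} over
#' a SNP subset together with the denominator
#' \eqn{\sum_j 2 p_j (1 - p_j)}. Frequencies are the counted-allele
#' frequencies of the pooled two-population sample; missing codes are
#' mean-imputed (to \eqn{2 p_j}, i.e. a centered value of 0) so that
#' centering is exact.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param snpSubset integer column indices (default: all SNPs).
#' @return a \linkS4class{CenteredGenotypes}.
#' @export
centerGenotypes <- function(g, snpSubset = seq_len(nSnps(g))) {
  snpSubset <- as.integer(snpSubset)
  if (!length(snpSubset)) stop("empty SNP subset", call. = FALSE)
  p <- g@freq[snpSubset]
  denom <- sum(2 * p * (1 - p), na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0)
    stop("denominator is 0: subset contains only monomorphic/missing SNPs",
         call. = FALSE)
  W <- sweep(g@codes[, snpSubset, drop = FALSE], 2, 2 * p)
  W[is.na(W)] <- 0
  new("CenteredGenotypes", W = W, snpIndex = snpSubset, denom = denom,
      iid = g@iid, pop = g@pop)
}

#' Build a VanRaden genomic relationship matrix
#'
#' \eqn{G = W W' / \sum_j 2 p_j (1 - p_j)} from centered genotypes.
#'
#' @param w a \linkS4class{CenteredGenotypes}.
#' @param snpSet label recorded on the GRM (e.g. "ALL", "SIG").
#' @return a \linkS4class{GRM}.
#' @examples
#' g <- simulateGenotypes(scenarioConfig("null", nPerPop = 15))
#' G <- makeGRM(centerGenotypes(g))
#' mean(diag(grmValues(G)))
#' @export
makeGRM <- function(w, snpSet = "ALL") {
  if (nrow(w@W) == 0) stop("no individuals", call. = FALSE)
  V <- tcrossprod(w@W) / w@denom
  V <- (V + t(V)) / 2
  dimnames(V) <- list(w@iid, w@iid)
  new("GRM", values = V, iid = w@iid, pop = w@pop, snpSet = snpSet,
      nSnps = ncol(w@W), denom = w@denom)
}

#' Region-restricted GRMs for a SNP classification
#'
#' Builds one GRM per region class, each scaled by its own denominator
#' restricted to the class's SNP set (so each kernel is a standalone
#' VanRaden GRM for its genome part). Classes with no SNPs are omitted with
#' a warning, degrading the downstream model to fewer kernels.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param classes either a \linkS4class{RegionClasses} or a named list of
#'   SNP index vectors; sets must be disjoint.
#' @return named list of \linkS4class{GRM} objects.
#' @export
grmForPartition <- function(g, classes) {
  if (is(classes, "RegionClasses")) classes <- classes@snpSets
  idx <- unlist(classes)
  if (anyDuplicated(idx)) stop("class SNP sets overlap", call. = FALSE)
  out <- list()
  for (cl in names(classes)) {
    snps <- classes[[cl]]
    if (!length(snps)) {
      warning("class '", cl, "' has no SNPs; kernel omitted", call. = FALSE)
      next
    }
    out[[cl]] <- makeGRM(centerGenotypes(g, snps), snpSet = cl)
  }
  out
}

#' GCTA binary GRM export/import
#'
#' Writes/reads \code{prefix.grm.bin} (float32 lower triangle, row-major by
#' individual), \code{prefix.grm.id} (two-column id file) and
#' \code{prefix.grm.N.bin} (float32 SNP counts per pair), the format used by
#' GCTA.
#'
#' @param grm a \linkS4class{GRM}.
#' @param prefix path prefix.
#' @return \code{readGRMBin}: a \linkS4class{GRM} (population labels come
#'   from the first id column).
#' @export
writeGRMBin <- function(grm, prefix) {
  n <- nrow(grm@values)
  lt <- grm@values[upper.tri(grm@values, diag = TRUE)]
  # upper.tri by column == lower triangle row-major
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm@nSnps), length(lt)), con, size = 4)
  close(con)
  write.table(data.frame(as.character(grm@pop), grm@iid),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname writeGRMBin
#' @export
readGRMBin <- function(prefix) {
  id <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  n <- nrow(id)
  nv <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), what = "numeric", n = nv,
                  size = 4)
  Ns <- readBin(paste0(prefix, ".grm.N.bin"), what = "numeric", n = nv,
                size = 4)
  V <- matrix(0, n, n)
  V[upper.tri(V, diag = TRUE)] <- vals
  V <- V + t(V) - diag(diag(V))
  dimnames(V) <- list(id[[2]], id[[2]])
  new("GRM", values = V, iid = id[[2]], pop = factor(id[[1]]),
      snpSet = "ALL", nSnps = as.integer(round(Ns[1])), denom = NA_real_)
}

#' TSV GRM export
#'
#' @param grm a \linkS4class{GRM}.
#' @param path output file.
#' @export
writeGRMTsv <- function(grm, path) {
  df <- as.data.frame(grm@values)
  names(df) <- grm@iid
  df <- cbind(iid = grm@iid, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
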