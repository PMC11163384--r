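#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square test comparing observed genotype counts
#' to the expectation under Hardy-Weinberg proportions at the sample allele
#' frequency. Monomorphic SNPs return p = 1 by convention.
#'
#' @param n0,n1,n2 counts of genotype codes 0, 1 and 2.
#' @return the p-value.
#' @examples
#' hweChisq(25, 50, 25)  # exact HWE proportions: p = 1
#' hweChisq(50, 0, 50)   # no heterozygotes: strong departure
#' @export
hweChisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n <= 0) stop("no genotype observations", call. = FALSE)
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' SNP quality control
#'
#' Removes SNPs with missing rate above \code{maxMissingRate}, pooled minor
#' allele frequency below \code{minMaf}, or a Hardy-Weinberg equilibrium
#' chi-square p-value below \code{hwePFloor}. All criteria are evaluated on
#' the pooled two-population sample; SNP order is preserved.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param maxMissingRate maximum tolerated fraction of missing calls.
#' @param minMaf minimum minor allele frequency.
#' @param hwePFloor minimum HWE p-value.
#' @return the filtered \linkS4class{GenotypeData}, with an attribute
#'   \code{"removed"} giving the removal count per criterion (a SNP failing
#'   several criteria is counted under each).
#' @export
qcFilter <- function(g, maxMissingRate = 0.01, minMaf = 0.05,
                     hwePFloor = 1e-6) {
  codes <- g@codes
  missRate <- colMeans(is.na(codes))
  p <- g@freq
  maf <- pmin(p, 1 - p)
  hwe <- vapply(seq_len(ncol(codes)), function(j) {
    cj <- codes[, j]
    cj <- cj[!is.na(cj)]
    if (!length(cj)) return(0)  # all-missing column: fails missingness anyway
    hweChisq(sum(cj == 0L), sum(cj == 1L), sum(cj == 2L))
  }, numeric(1))
  failMiss <- missRate > maxMissingRate
  failMaf <- is.na(maf) | maf < minMaf
  failHwe <- hwe < hwePFloor
  keep <- !(failMiss | failMaf | failHwe)
  if (!any(keep)) stop("empty panel: all SNPs removed by QC", call. = FALSE)
  out <- g[, which(keep)]
  attr(out, "removed") <- c(missing = sum(failMiss), maf = sum(failMaf),
                            hwe = sum(failHwe), total = sum(!keep))
  out
}

#' Subset a genotype panel
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param i individual indices (or ids), \code{j} SNP column indices.
#' @param j,...,drop see above; \code{drop} is ignored.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@codes))
  if (is.character(i)) i <- match(i, x@iid)
  if (missing(j)) j <- seq_len(ncol(x@codes))
  codes <- x@codes[i, j, drop = FALSE]
  freq <- colMeans(codes, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- NA_real_
  new("GenotypeData", codes = codes, map = x@map[j, , drop = FALSE],
      iid = x@iid[i], pop = factor(x@pop[i]), freq = unname(freq))
})

#' Rank-based inverse-normal (quantile) normalization
#'
#' Maps the value of rank r (average ranks for ties) to the standard normal
#' quantile of (r - 0.5)/n over the non-missing values; the output is
#' rank-identical to the input. Missing values stay missing.
#'
#' @param values numeric vector with at least two distinct non-missing
#'   values.
#' @return the transformed vector.
#' @examples
#' quantileNormalize(c(3, 1, 2))  # middle value maps to 0
#' @export
quantileNormalize <- function(values) {
  obs <- !is.na(values)
  x <- values[obs]
  if (length(x) < 2) stop("need at least 2 non-missing values", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("constant vector: ranks undefined", call. = FALSE)
  r <- rank(x, ties.method = "average")
  out <- values
  out[obs] <- qnorm((r - 0.5) / length(x))
  out
}
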