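#' @import methods
#' @importFrom stats cor pchisq pnorm qnorm rnorm rbinom runif sd var
#'   setNames optimize lm coef complete.cases
#' @importFrom utils read.table write.table
NULL

#' Diploid SNP genotypes for two populations
#'
#' Holds additive genotype codes (0/1/2 copies of the counted allele,
#' \code{NA} for missing) for the individuals of two populations typed on a
#' shared SNP panel, together with the SNP map and the counted-allele
#' frequencies computed on the pooled sample.
#'
#' @slot codes integer matrix, individuals x SNPs, entries in \{0,1,2,NA\}.
#' @slot map data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, \code{a1}, \code{a2}; rows sorted by (chrom, pos_bp).
#'   \code{a1} is the counted allele (code 2 = two copies of \code{a1}).
#' @slot iid character, individual identifiers (rownames of \code{codes}).
#' @slot pop factor with at most two levels, population of each individual.
#' @slot freq numeric, pooled-sample frequency of the counted allele per
#'   SNP; \code{NA} for all-missing columns.
#'
#' @examples
#' g <- simulateGenotypes(scenarioConfig("null", nPerPop = 20))
#' g
#' dim(genotypeCodes(g))
#' @export
setClass("GenotypeData",
  representation(
    codes = "matrix",
    map = "data.frame",
    iid = "character",
    pop = "factor",
    freq = "numeric"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  n <- nrow(object@codes); m <- ncol(object@codes)
  if (length(object@iid) != n) msg <- c(msg, "length(iid) != nrow(codes)")
  if (length(object@pop) != n) msg <- c(msg, "length(pop) != nrow(codes)")
  if (nrow(object@map) != m) msg <- c(msg, "nrow(map) != ncol(codes)")
  if (length(object@freq) != m) msg <- c(msg, "length(freq) != ncol(codes)")
  if (anyDuplicated(object@iid)) msg <- c(msg, "duplicated individual ids")
  if (nlevels(object@pop) > 2) msg <- c(msg, "more than two populations")
  need <- c("snp_id", "chrom", "pos_bp")
  if (!all(need %in% names(object@map))) {
    msg <- c(msg, "map must have snp_id, chrom, pos_bp columns")
  } else if (m > 1) {
    o <- order(object@map$chrom, object@map$pos_bp)
    if (!identical(o, seq_len(m)))
      msg <- c(msg, "map not sorted by (chrom, pos_bp)")
  }
  bad <- object@codes[!is.na(object@codes)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "codes must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Centered genotype matrix for GRM construction
#'
#' VanRaden-centered genotypes \eqn{w_{ij} = m_{ij} - 2 p_j} over a SNP
#' subset, with the scaling denominator \eqn{\sum_j 2 p_j (1 - p_j)}.
#'
#' @slot W numeric matrix, individuals x SNPs in the subset.
#' @slot snpIndex integer, column indices into the parent genotype panel.
#' @slot denom numeric scalar, \eqn{\sum_j 2 p_j (1 - p_j)}.
#' @slot iid character individual ids.
#' @slot pop factor population labels.
#' @export
setClass("CenteredGenotypes",
  representation(
    W = "matrix",
    snpIndex = "integer",
    denom = "numeric",
    iid = "character",
    pop = "factor"
  )
)

setValidity("CenteredGenotypes", function(object) {
  msg <- character()
  if (length(object@snpIndex) != ncol(object@W))
    msg <- c(msg, "snpIndex length != ncol(W)")
  if (length(object@iid) != nrow(object@W))
    msg <- c(msg, "iid length != nrow(W)")
  if (length(object@denom) != 1 || object@denom <= 0)
    msg <- c(msg, "denom must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Genomic relationship matrix
#'
#' A VanRaden GRM \eqn{G = WW'/\sum_j 2p_j(1-p_j)} over a labelled SNP set.
#'
#' @slot values symmetric numeric matrix, individuals x individuals.
#' @slot iid character individual ids.
#' @slot pop factor population labels.
#' @slot snpSet character label of the SNP set (e.g. "ALL", "SIG", "POS").
#' @slot nSnps integer, number of SNPs used.
#' @slot denom numeric, the VanRaden denominator of this SNP set.
#' @export
setClass("GRM",
  representation(
    values = "matrix",
    iid = "character",
    pop = "factor",
    snpSet = "character",
    nSnps = "integer",
    denom = "numeric"
  )
)

setValidity("GRM", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values not square")
  if (length(object@iid) != nrow(v)) msg <- c(msg, "iid length mismatch")
  if (nrow(v) && max(abs(v - t(v))) > 1e-10)
    msg <- c(msg, "values not symmetric within 1e-10")
  if (length(msg)) msg else TRUE
})

#' Genome partition into LD blocks
#'
#' Ordered, disjoint, exhaustive SNP-index blocks that never span
#' chromosomes.
#'
#' @slot blocks data.frame with columns \code{block_id}, \code{chrom},
#'   \code{start_index}, \code{end_index} (global SNP column indices,
#'   inclusive), \code{start_bp}, \code{end_bp}, \code{n_snps}.
#' @export
setClass("GenomePartition", representation(blocks = "data.frame"))

setValidity("GenomePartition", function(object) {
  b <- object@blocks
  need <- c("block_id", "chrom", "start_index", "end_index",
            "start_bp", "end_bp", "n_snps")
  if (!all(need %in% names(b))) return("blocks missing required columns")
  if (nrow(b) == 0) return("empty partition")
  if (any(b$end_index < b$start_index)) return("block with end < start")
  idx <- unlist(mapply(seq, b$start_index, b$end_index, SIMPLIFY = FALSE))
  if (anyDuplicated(idx)) return("blocks overlap")
  if (!identical(sort(idx), seq(min(b$start_index), max(b$end_index))))
    return("blocks not exhaustive over their SNP range")
  TRUE
})

#' Region classification of a genome partition
#'
#' Assignment of every LD block to a region class: SIG/NON under the
#' significance scheme (model 1) or POS/NEG/RES under the magnitude-and-sign
#' scheme (model 2), with the derived SNP index set per class.
#'
#' @slot scheme character, "MODEL1" or "MODEL2".
#' @slot assignment named character, class label per block_id.
#' @slot snpSets named list of integer vectors, SNP column indices per class.
#' @export
setClass("RegionClasses",
  representation(
    scheme = "character",
    assignment = "character",
    snpSets = "list"
  )
)

setValidity("RegionClasses", function(object) {
  if (!object@scheme %in% c("MODEL1", "MODEL2")) return("unknown scheme")
  ok <- switch(object@scheme, MODEL1 = c("SIG", "NON"),
               MODEL2 = c("POS", "NEG", "RES"))
  if (!all(object@assignment %in% ok)) return("invalid class label")
  idx <- unlist(object@snpSets)
  if (anyDuplicated(idx)) return("class SNP sets overlap")
  TRUE
})

#' REML model specification
#'
#' Internal container tying response records to kernels: one record per
#' phenotyped individual, each belonging to exactly one of (at most) two
#' traits (the two populations), with record-level kernel matrices.
#'
#' @slot y numeric response vector (one record per phenotyped individual).
#' @slot trait integer 1/2 per record.
#' @slot X fixed-effect design matrix (full column rank on the records).
#' @slot kernels list of record-level symmetric kernel matrices.
#' @slot kernelNames character labels.
#' @slot iid character, individual id per record.
#' @slot nTraits integer, 1 or 2.
#' @export
setClass("ModelSpec",
  representation(
    y = "numeric",
    trait = "integer",
    X = "matrix",
    kernels = "list",
    kernelNames = "character",
    iid = "character",
    nTraits = "integer"
  )
)

setValidity("ModelSpec", function(object) {
  n <- length(object@y)
  msg <- character()
  if (length(object@trait) != n) msg <- c(msg, "trait length mismatch")
  if (nrow(object@X) != n) msg <- c(msg, "X row mismatch")
  if (!length(object@kernels)) msg <- c(msg, "need at least one kernel")
  for (K in object@kernels)
    if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
      msg <- c(msg, "kernel dimension mismatch")
  if (!object@nTraits %in% 1:2) msg <- c(msg, "nTraits must be 1 or 2")
  if (any(!object@trait %in% seq_len(object@nTraits)))
    msg <- c(msg, "trait index out of range")
  if (qr(object@X)$rank < ncol(object@X))
    msg <- c(msg, "X rank-deficient on the records")
  if (length(msg)) msg else TRUE
})

#' Fitted variance components
#'
#' Result of a (bivariate) multi-kernel REML fit: one 2x2 (or 1x1) genetic
#' (co)variance matrix per kernel and a diagonal residual, with the REML
#' log-likelihood and the average-information matrix at the optimum.
#'
#' @slot M list of per-kernel genetic covariance matrices (t x t).
#' @slot residual numeric residual variance per trait.
#' @slot loglik numeric REML log-likelihood (includes the
#'   \eqn{-(n-p)/2 \log 2\pi} constant).
#' @slot converged logical.
#' @slot nIter integer iterations used.
#' @slot kernelNames character.
#' @slot nTraits integer.
#' @slot AI average-information matrix over the free parameters.
#' @slot freeNames character names of the free parameters (AI row order).
#' @export
setClass("VarianceComponents",
  representation(
    M = "list",
    residual = "numeric",
    loglik = "numeric",
    converged = "logical",
    nIter = "integer",
    kernelNames = "character",
    nTraits = "integer",
    AI = "matrix",
    freeNames = "character"
  )
)

setValidity("VarianceComponents", function(object) {
  msg <- character()
  t <- object@nTraits
  for (M in object@M) {
    if (!all(dim(M) == c(t, t))) msg <- c(msg, "M dimension mismatch")
    if (max(abs(M - t(M))) > 1e-8) msg <- c(msg, "M not symmetric")
    if (t == 2 && abs(M[1, 2]) > sqrt(M[1, 1] * M[2, 2]) + 1e-8)
      msg <- c(msg, "covariance exceeds Cauchy-Schwarz bound")
  }
  if (any(object@residual <= 0)) msg <- c(msg, "residual variances must be > 0")
  if (length(msg)) msg else TRUE
})

#' GEBV prediction result
#'
#' Per-individual genomic estimated breeding values, one column per kernel
#' component plus the total (the exact sum of components), for the trait of
#' the individual's own population.
#'
#' @slot gebv data.frame with columns \code{iid}, \code{pop}, one numeric
#'   column per kernel (named \code{gebv_<kernel>}) and \code{total}.
#' @slot model character model label.
#' @slot vc the \linkS4class{VarianceComponents} used.
#' @export
setClass("PredictionResult",
  representation(
    gebv = "data.frame",
    model = "character",
    vc = "VarianceComponents"
  )
)

setValidity("PredictionResult", function(object) {
  g <- object@gebv
  if (!all(c("iid", "pop", "total") %in% names(g)))
    return("gebv must have iid, pop, total columns")
  comp <- grep("^gebv_", names(g))
  if (length(comp)) {
    tot <- rowSums(g[, comp, drop = FALSE])
    if (max(abs(tot - g$total)) > 1e-10)
      return("total != sum of kernel components")
  }
  TRUE
})
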