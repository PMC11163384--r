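# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny GenotypeData with explicit codes (individuals x SNPs).
makeToyGenotypes <- function(codes, chrom = NULL, pop = NULL) {
  n <- nrow(codes); m <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pop)) pop <- rep(c("pop1", "pop2"), length.out = n)
  map <- data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                    pos_bp = stats::ave(seq_len(m), chrom,
                                        FUN = seq_along) * 100L,
                    stringsAsFactors = FALSE)
  genotypeData(codes, map, iid = sprintf("i%03d", seq_len(n)), pop = pop)
}

# A GRM object wrapped around an explicit relationship matrix.
makeToyGRM <- function(V, pop = NULL, snpSet = "ALL", denom = 1) {
  n <- nrow(V)
  if (is.null(pop)) pop <- rep(c("pop1", "pop2"), length.out = n)
  new("GRM", values = (V + t(V)) / 2, iid = sprintf("i%03d", seq_len(n)),
      pop = factor(pop), snpSet = snpSet, nSnps = 10L, denom = denom)
}

# Random positive-definite GRM over two populations.
randomGRM <- function(n, seed = 1, pop = NULL) {
  set.seed(seed)
  V <- crossprod(matrix(rnorm(n * n), n)) / n + diag(0.05, n)
  makeToyGRM(V, pop = pop)
}

# Fixed VarianceComponents without fitting.
makeVC <- function(M, residual) {
  M <- lapply(M, function(m) if (is.matrix(m)) m else matrix(m, 1, 1))
  t <- nrow(M[[1]])
  kn <- paste0("K", seq_along(M))
  nm <- if (t == 2) {
    c(as.vector(vapply(kn, function(k)
      paste0(c("va1_", "ca12_", "va2_"), k), character(3))), "ve1", "ve2")
  } else {
    c(paste0("va_", kn), "ve")
  }
  new("VarianceComponents", M = M, residual = residual, loglik = 0,
      converged = TRUE, nIter = 1L, kernelNames = kn, nTraits = as.integer(t),
      AI = diag(length(nm)), freeNames = nm)
}

# Small two-population scenario used across tests (cheap but informative:
# strong LD so the GRM is well-conditioned).
smallScenario <- function(seed = 1, nPerPop = 60, rLgc = 0.8) {
  cfg <- simConfig(nPerPop = nPerPop, nChrom = 1, blocksPerChrom = 4,
                   snpsPerBlock = 30, rho = 0.9, rLgcBlocks = rLgc,
                   h2 = c(0.4, 0.4), causalFrac = 0.5, seed = seed)
  simulateScenario(cfg)
}

# Independent re-implementation of the recursive splitter used as an
# oracle: plain loops, correlations straight from cor() on the genotype
# columns, no shared code with partitionChromosome.
oraclePartition <- function(W, maxBlockSnps, minSnps, window) {
  score <- function(st, en, b) {
    li <- max(st, b - window + 1):b
    ri <- (b + 1):min(en, b + window)
    s <- 0
    for (i in li) for (j in ri) s <- s + suppressWarnings(cor(W[, i], W[, j]))^2
    s
  }
  blocks <- list(c(1, ncol(W)))
  repeat {
    sizes <- sapply(blocks, function(b) b[2] - b[1] + 1)
    if (max(sizes) <= maxBlockSnps) break
    k <- which.max(sizes)
    st <- blocks[[k]][1]; en <- blocks[[k]][2]
    cand <- (st + minSnps - 1):(en - minSnps)
    sc <- sapply(cand, function(b) score(st, en, b))
    b <- cand[which.min(sc)]
    blocks <- append(blocks[-k], list(c(st, b), c(b + 1, en)), after = k - 1)
  }
  do.call(rbind, blocks)
}

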