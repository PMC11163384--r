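#' Solve GBLUP for given variance components
#'
#' Fixed effects by generalized least squares on the training records;
#' random effects by the conditional-expectation form: for kernel k the
#' GEBV of individual i for trait p is
#' \deqn{\hat a_{p,k}(i) = \sum_r M_k[p,r]\, G_k[i, obs_r]\,
#'       [V^{-1}(y - X\hat b)]_r}
#' summing over the observed records of each trait r. Validation
#' individuals contribute genotypes through the GRMs but never phenotypes.
#' Each individual is predicted for its own population's trait, and the
#' total GEBV is the exact sum of the per-kernel components.
#'
#' @param grms list of \linkS4class{GRM}s covering training and prediction
#'   individuals.
#' @param pheno training phenotype data.frame.
#' @param vc fitted \linkS4class{VarianceComponents} (same kernel order).
#' @param predictIds individuals to predict (default: all in the GRMs).
#' @param trait trait column name.
#' @param model label stored on the result.
#' @param method \code{"gls"} (conditional expectation, default) or
#'   \code{"mme"} (Henderson mixed-model equations; requires invertible
#'   kernels, used as an independent cross-check).
#' @param perPopIntercept single-trait models only: per-population means.
#' @param intercept set \code{FALSE} for a model with no fixed effects.
#' @return a \linkS4class{PredictionResult}.
#' @export
gblupSolve <- function(grms, pheno, vc, predictIds = NULL,
                       trait = names(pheno)[3], model = "GBLUP",
                       method = c("gls", "mme"), perPopIntercept = FALSE,
                       intercept = TRUE) {
  method <- match.arg(method)
  if (is(grms, "GRM")) grms <- list(grms)
  ref <- grms[[1]]
  if (is.null(predictIds)) predictIds <- ref@iid
  miss <- setdiff(predictIds, ref@iid)
  if (length(miss))
    stop("individuals missing from the GRM: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  spec <- modelSpec(grms, pheno, trait = trait, traits = vc@nTraits,
                    perPopIntercept = perPopIntercept,
                    intercept = intercept)
  obs <- match(spec@iid, ref@iid)
  prd <- match(predictIds, ref@iid)
  if (method == "mme")
    return(.mmeSolve(grms, spec, vc, prd, predictIds, model))
  Vc <- .varComponents(spec)
  theta <- .vcToTheta(vc, spec)
  ev <- .remlEval(spec, Vc, theta)
  if (is.null(ev)) stop("singular covariance matrix", call. = FALSE)
  resid <- spec@y - spec@X %*% ev$beta
  n <- length(spec@y)
  Vr <- ev$Vinv %*% resid                      # V^-1 (y - X b_hat)
  popLevels <- levels(factor(as.character(ref@pop)))
  predPop <- as.character(ref@pop[prd])
  predTrait <- if (vc@nTraits == 2) match(predPop, popLevels) else
    rep(1L, length(prd))
  comp <- matrix(0, length(prd), length(grms))
  for (k in seq_along(grms)) {
    Gk <- grms[[k]]@values
    Mk <- vc@M[[k]]
    for (r in seq_len(vc@nTraits)) {
      rRec <- which(spec@trait == r)
      if (!length(rRec)) next
      contrib <- Gk[prd, obs[rRec], drop = FALSE] %*% Vr[rRec]
      comp[, k] <- comp[, k] +
        Mk[cbind(predTrait, r)] * as.numeric(contrib)
    }
  }
  gdf <- data.frame(iid = predictIds, pop = predPop,
                    stringsAsFactors = FALSE)
  for (k in seq_along(grms)) gdf[[paste0("gebv_", vc@kernelNames[k])]] <-
    comp[, k]
  gdf$total <- rowSums(comp)
  new("PredictionResult", gebv = gdf, model = model, vc = vc)
}

# Henderson MME path: requires each kernel's record+predict submatrix to be
# invertible. Unknowns: b, then per kernel the 2N (or N) breeding values of
# the union of training and prediction individuals.
.mmeSolve <- function(grms, spec, vc, prd, predictIds, model) {
  ref <- grms[[1]]
  ids <- sort(unique(c(match(spec@iid, ref@iid), prd)))
  N <- length(ids)
  t <- vc@nTraits
  n <- length(spec@y)
  K <- length(grms)
  Rinv <- diag(1 / vc@residual[spec@trait])
  # incidence of records on (trait, individual) cells per kernel
  recInd <- match(match(spec@iid, ref@iid), ids)
  Z <- matrix(0, n, t * N)
  for (i in seq_len(n)) Z[i, (spec@trait[i] - 1) * N + recInd[i]] <- 1
  X <- spec@X
  p <- ncol(X)
  nun <- p + K * t * N
  LHS <- matrix(0, nun, nun)
  RHS <- numeric(nun)
  pIdx <- seq_len(p)
  if (p > 0) {
    LHS[pIdx, pIdx] <- crossprod(X, Rinv %*% X)
    RHS[pIdx] <- crossprod(X, Rinv %*% spec@y)
  }
  ZtR <- crossprod(Z, Rinv)
  for (k in seq_len(K)) {
    off <- p + (k - 1) * t * N
    if (p > 0) {
      LHS[(off + 1):(off + t * N), pIdx] <- ZtR %*% X
      LHS[pIdx, (off + 1):(off + t * N)] <- t(ZtR %*% X)
    }
    RHS[(off + 1):(off + t * N)] <- ZtR %*% spec@y
    for (k2 in seq_len(K)) {
      off2 <- p + (k2 - 1) * t * N
      LHS[(off + 1):(off + t * N), (off2 + 1):(off2 + t * N)] <-
        LHS[(off + 1):(off + t * N), (off2 + 1):(off2 + t * N)] +
        ZtR %*% Z
    }
    Gk <- grms[[k]]@values[ids, ids, drop = FALSE]
    Ginv <- solve(Gk)
    Minv <- solve(vc@M[[k]])
    LHS[(off + 1):(off + t * N), (off + 1):(off + t * N)] <-
      LHS[(off + 1):(off + t * N), (off + 1):(off + t * N)] +
      kronecker(Minv, Ginv)
  }
  sol <- solve(LHS, RHS)
  popLevels <- levels(factor(as.character(ref@pop)))
  predPop <- as.character(ref@pop[prd])
  predTrait <- if (t == 2) match(predPop, popLevels) else
    rep(1L, length(prd))
  prdLoc <- match(prd, ids)
  comp <- matrix(0, length(prd), K)
  for (k in seq_len(K)) {
    off <- p + (k - 1) * t * N
    comp[, k] <- sol[off + (predTrait - 1) * N + prdLoc]
  }
  gdf <- data.frame(iid = predictIds, pop = predPop,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) gdf[[paste0("gebv_", vc@kernelNames[k])]] <-
    comp[, k]
  gdf$total <- rowSums(comp)
  new("PredictionResult", gebv = gdf, model = model, vc = vc)
}

#' Single-trait GBLUP within one population
#'
#' Fits single-kernel single-trait REML on the training records of one
#' population (GRM restricted to that population's individuals) and
#' predicts GEBVs.
#'
#' @param grm an all-SNP \linkS4class{GRM} over both populations.
#' @param pheno training phenotypes.
#' @param population which population to run.
#' @param predictIds individuals to predict (default: all of that
#'   population).
#' @param trait trait column name.
#' @param ... passed to [fitREML()].
#' @return a \linkS4class{PredictionResult}.
#' @export
runSTGBLUP <- function(grm, pheno, population, predictIds = NULL,
                       trait = names(pheno)[3], ...) {
  inPop <- which(as.character(grm@pop) == population)
  if (!length(inPop)) stop("unknown population: ", population, call. = FALSE)
  sub <- new("GRM", values = grm@values[inPop, inPop, drop = FALSE],
             iid = grm@iid[inPop], pop = factor(grm@pop[inPop]),
             snpSet = grm@snpSet, nSnps = grm@nSnps, denom = grm@denom)
  ph <- pheno[pheno$pop == population & !is.na(pheno[[trait]]), ,
              drop = FALSE]
  if (!nrow(ph)) stop("empty training set for population ", population,
                      call. = FALSE)
  if (is.null(predictIds)) predictIds <- sub@iid
  spec <- modelSpec(list(sub), ph, trait = trait, traits = 1)
  vc <- fitREML(spec, ...)
  gblupSolve(list(sub), ph, vc, predictIds, trait = trait,
             model = "STGBLUP")
}

#' Single-trait GBLUP on the pooled two-population reference
#'
#' Combines the two populations into one joint reference with a single
#' genetic variance. Requires the responses to be commensurable across
#' populations (e.g. the same corrected phenotype); refuse otherwise. By
#' default one mean is fitted per population.
#'
#' @param grm all-SNP \linkS4class{GRM}.
#' @param pheno training phenotypes for both populations.
#' @param commensurable must be TRUE; set FALSE when responses are
#'   differently derived in the two populations (the model then refuses).
#' @param perPopIntercept fit a separate overall mean per population.
#' @param predictIds,trait see [runSTGBLUP()].
#' @param ... passed to [fitREML()].
#' @return a \linkS4class{PredictionResult}.
#' @export
runSTGBLUPCombined <- function(grm, pheno, commensurable = TRUE,
                               perPopIntercept = TRUE, predictIds = NULL,
                               trait = names(pheno)[3], ...) {
  if (!isTRUE(commensurable))
    stop("responses flagged non-commensurable across populations; ",
         "the combined-reference model is not applicable", call. = FALSE)
  if (is.null(predictIds)) predictIds <- grm@iid
  spec <- modelSpec(list(grm), pheno, trait = trait, traits = 1,
                    perPopIntercept = perPopIntercept)
  vc <- fitREML(spec, ...)
  gblupSolve(list(grm), pheno, vc, predictIds, trait = trait,
             model = "STGBLUP_combined", perPopIntercept = perPopIntercept)
}

#' Multi-trait GBLUP across two populations
#'
#' The same trait in the two populations is treated as two correlated
#' traits sharing one all-SNP kernel; the global genetic correlation is
#' estimated by bivariate REML and exploited in prediction.
#'
#' @inheritParams runSTGBLUPCombined
#' @param constrainZeroCov fix the genetic covariance at zero (diagnostic
#'   decoupling; GEBVs then equal the two single-population runs).
#' @return a \linkS4class{PredictionResult}.
#' @export
runMTGBLUP <- function(grm, pheno, predictIds = NULL,
                       trait = names(pheno)[3],
                       constrainZeroCov = FALSE, ...) {
  if (is.null(predictIds)) predictIds <- grm@iid
  spec <- modelSpec(list(grm), pheno, trait = trait, traits = 2)
  vc <- fitREML(spec, constrainZeroCov = if (constrainZeroCov) 1L else
    integer(0), ...)
  gblupSolve(list(grm), pheno, vc, predictIds, trait = trait,
             model = "MTGBLUP")
}

#' Partitioned-kernel multi-trait GBLUP (SIG/NON regions)
#'
#' Bivariate two-kernel model with one GRM built from the SIG-region SNPs
#' and one from the rest; total GEBV is the sum of the two kernel
#' components. An empty class drops its kernel with a warning.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param pheno training phenotypes.
#' @param classes a MODEL1 \linkS4class{RegionClasses}.
#' @param predictIds,trait see [runSTGBLUP()].
#' @param ... passed to [fitREML()].
#' @return a \linkS4class{PredictionResult}.
#' @export
runLGCModel1 <- function(g, pheno, classes, predictIds = NULL,
                         trait = names(pheno)[3], ...) {
  if (classes@scheme != "MODEL1") stop("classes must use scheme MODEL1",
                                       call. = FALSE)
  .runPartitionedModel(g, pheno, classes, predictIds, trait,
                       "LGC-model-1", ...)
}

#' Partitioned-kernel multi-trait GBLUP (POS/NEG/RES regions)
#'
#' Bivariate three-kernel model with separate GRMs for the strong-positive,
#' strong-negative and residual genome parts; total GEBV is the sum of the
#' three kernel components. Empty classes drop their kernels with a
#' warning.
#'
#' @inheritParams runLGCModel1
#' @param classes a MODEL2 \linkS4class{RegionClasses}.
#' @return a \linkS4class{PredictionResult}.
#' @export
runLGCModel2 <- function(g, pheno, classes, predictIds = NULL,
                         trait = names(pheno)[3], ...) {
  if (classes@scheme != "MODEL2") stop("classes must use scheme MODEL2",
                                       call. = FALSE)
  .runPartitionedModel(g, pheno, classes, predictIds, trait,
                       "LGC-model-2", ...)
}

.runPartitionedModel <- function(g, pheno, classes, predictIds, trait,
                                 label, ...) {
  grms <- grmForPartition(g, classes)
  if (!length(grms)) stop("no non-empty region class", call. = FALSE)
  if (is.null(predictIds)) predictIds <- g@iid
  spec <- modelSpec(grms, pheno, trait = trait, traits = 2)
  vc <- fitREML(spec, ...)
  gblupSolve(grms, pheno, vc, predictIds, trait = trait, model = label)
}

#' GEBV TSV export
#'
#' @param pred a \linkS4class{PredictionResult}.
#' @param path output file.
#' @export
writeGEBV <- function(pred, path) {
  df <- pred@gebv
  df <- cbind(model = pred@model, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
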