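#' Stratified cross-validation folds
#'
#' Randomly assigns individuals to k folds, stratified by population so
#' each fold preserves the population ratio; fold sizes differ by at most
#' one within each population. Reproducible given the seed.
#'
#' @param ids character individual ids.
#' @param pop population label per individual.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return named integer vector: fold (1..k) per individual.
#' @export
makeFolds <- function(ids, pop, k = 10, seed = 1) {
  n <- length(ids)
  if (k > n) stop("more folds than individuals", call. = FALSE)
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(n)
  for (p in unique(as.character(pop))) {
    idx <- which(as.character(pop) == p)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  names(fold) <- ids
  fold
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Prediction accuracy and unbiasedness
#'
#' Accuracy is the Pearson correlation between the validation response and
#' the GEBV; unbiasedness is the ordinary least-squares slope of the
#' response on the GEBV (1 = dispersion-unbiased prediction).
#'
#' @param yVal validation responses.
#' @param gebvVal matching GEBVs.
#' @return list with \code{r} and \code{b}; both \code{NA} (flagged via
#'   attribute \code{"degenerate"}) when the GEBV is constant.
#' @examples
#' accuracyAndBias(1:10, (1:10) * 2)  # r = 1, b = 0.5
#' @export
accuracyAndBias <- function(yVal, gebvVal) {
  ok <- complete.cases(yVal, gebvVal)
  yVal <- yVal[ok]; gebvVal <- gebvVal[ok]
  if (length(yVal) < 3) stop("need at least 3 validation pairs",
                             call. = FALSE)
  if (sd(gebvVal) == 0) {
    out <- list(r = NA_real_, b = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  list(r = cor(yVal, gebvVal),
       b = cov(yVal, gebvVal) / var(gebvVal))
}

#' Repeated stratified k-fold cross-validation of the prediction models
#'
#' For each repeat, individuals are split into k population-stratified
#' folds; each fold in turn is the validation set while the remaining
#' records train the model (variance components — and, for the LGC models,
#' the block classification — are re-estimated on every training split
#' unless \code{refitClasses = FALSE}). Validation phenotypes never enter
#' any training-side computation. Identical folds are used for every model,
#' so per-fold model comparisons are paired. Per repeat, validation
#' predictions are pooled and accuracy/unbiasedness computed per
#' population; summaries are the mean and SD across repeats.
#'
#' @param g a \linkS4class{GenotypeData} (all individuals genotyped).
#' @param pheno phenotype data.frame covering (a subset of) the
#'   individuals.
#' @param models character subset of \code{c("STGBLUP",
#'   "STGBLUP_combined", "MTGBLUP", "LGC-model-1", "LGC-model-2")}.
#' @param partition \linkS4class{GenomePartition}; required for the LGC
#'   models.
#' @param k folds per repeat.
#' @param repeats number of CV repeats.
#' @param seed base seed; repeat i uses \code{seed + i - 1} for its folds.
#' @param trait trait column name.
#' @param topK SIG-region count for LGC-model-1.
#' @param threshold magnitude threshold for LGC-model-2.
#' @param refitClasses re-estimate the LGC classification on every
#'   training split (default) or once on the full data (cheaper, but lets
#'   validation phenotypes influence the classification).
#' @param commensurable passed to [runSTGBLUPCombined()].
#' @param perFold also report per-fold metrics instead of pooling per
#'   repeat.
#' @return list with \code{summary} (model x population means and SDs of r
#'   and b), \code{perRepeat} (one row per model x population x repeat) and
#'   \code{folds}.
#' @export
runCV <- function(g, pheno, models = c("STGBLUP", "MTGBLUP"),
                  partition = NULL, k = 10, repeats = 10, seed = 1,
                  trait = names(pheno)[3], topK = 20, threshold = 0.5,
                  refitClasses = TRUE, commensurable = TRUE,
                  perFold = FALSE) {
  known <- c("STGBLUP", "STGBLUP_combined", "MTGBLUP", "LGC-model-1",
             "LGC-model-2")
  if (!all(models %in% known))
    stop("unknown model: ", paste(setdiff(models, known), collapse = ", "),
         call. = FALSE)
  needLgc <- any(models %in% c("LGC-model-1", "LGC-model-2"))
  if (needLgc && is.null(partition))
    stop("LGC models require a genome partition", call. = FALSE)
  pheno <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  pops <- levels(factor(pheno$pop))
  grmAll <- makeGRM(centerGenotypes(g), snpSet = "ALL")
  bGrms <- if (needLgc) blockGRMs(g, partition) else NULL
  fixedClasses <- NULL
  if (needLgc && !refitClasses) {
    rec <- estimateLGC(g, pheno, partition, trait, blockGrms = bGrms)
    fixedClasses <- list(
      m1 = if ("LGC-model-1" %in% models)
        classifyModel1(rec, topK, partition) else NULL,
      m2 = if ("LGC-model-2" %in% models)
        classifyModel2(rec, threshold, partition) else NULL)
  }
  perRepeat <- list()
  foldStore <- list()
  for (rep_i in seq_len(repeats)) {
    fold <- makeFolds(pheno$iid, pheno$pop, k = k, seed = seed + rep_i - 1)
    foldStore[[rep_i]] <- fold
    preds <- list()  # model -> data.frame(iid, pop, fold, y, gebv)
    for (f in seq_len(k)) {
      valIdx <- which(fold == f)
      trainPh <- pheno[-valIdx, , drop = FALSE]
      valPh <- pheno[valIdx, , drop = FALSE]
      cls1 <- cls2 <- NULL
      if (needLgc) {
        if (refitClasses) {
          rec <- estimateLGC(g, trainPh, partition, trait,
                             blockGrms = bGrms)
          if ("LGC-model-1" %in% models)
            cls1 <- classifyModel1(rec, topK, partition)
          if ("LGC-model-2" %in% models)
            cls2 <- classifyModel2(rec, threshold, partition)
        } else {
          cls1 <- fixedClasses$m1; cls2 <- fixedClasses$m2
        }
      }
      for (mod in models) {
        res <- tryCatch({
          pr <- switch(mod,
            "STGBLUP" = {
              parts <- lapply(pops, function(p) {
                idsP <- valPh$iid[valPh$pop == p]
                if (!length(idsP)) return(NULL)
                gebv(runSTGBLUP(grmAll, trainPh, p, predictIds = idsP,
                                trait = trait))
              })
              do.call(rbind, parts)
            },
            "STGBLUP_combined" = gebv(runSTGBLUPCombined(
              grmAll, trainPh, commensurable = commensurable,
              predictIds = valPh$iid, trait = trait)),
            "MTGBLUP" = gebv(runMTGBLUP(grmAll, trainPh,
                                        predictIds = valPh$iid,
                                        trait = trait)),
            "LGC-model-1" = gebv(suppressWarnings(
              runLGCModel1(g, trainPh, cls1, predictIds = valPh$iid,
                           trait = trait))),
            "LGC-model-2" = gebv(suppressWarnings(
              runLGCModel2(g, trainPh, cls2, predictIds = valPh$iid,
                           trait = trait))))
          pr
        }, error = function(e) {
          warning("model ", mod, " failed on repeat ", rep_i, " fold ", f,
                  ": ", conditionMessage(e), call. = FALSE)
          NULL
        })
        if (is.null(res)) next
        res <- data.frame(iid = res$iid, pop = res$pop, fold = f,
                          gebv = res$total, stringsAsFactors = FALSE)
        res$y <- valPh[[trait]][match(res$iid, valPh$iid)]
        preds[[mod]] <- rbind(preds[[mod]], res)
      }
    }
    for (mod in names(preds)) {
      pd <- preds[[mod]]
      for (p in pops) {
        sub <- pd[pd$pop == p, , drop = FALSE]
        if (nrow(sub) < 3) next
        if (perFold) {
          for (f in unique(sub$fold)) {
            sf <- sub[sub$fold == f, , drop = FALSE]
            if (nrow(sf) < 3) next
            ab <- accuracyAndBias(sf$y, sf$gebv)
            perRepeat[[length(perRepeat) + 1L]] <-
              data.frame(model = mod, population = p, repeat_i = rep_i,
                         fold = f, r = ab$r, b = ab$b,
                         stringsAsFactors = FALSE)
          }
        } else {
          ab <- accuracyAndBias(sub$y, sub$gebv)
          perRepeat[[length(perRepeat) + 1L]] <-
            data.frame(model = mod, population = p, repeat_i = rep_i,
                       fold = NA_integer_, r = ab$r, b = ab$b,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  perRepeat <- do.call(rbind, perRepeat)
  summ <- NULL
  if (!is.null(perRepeat)) {
    agg <- split(perRepeat, list(perRepeat$model, perRepeat$population),
                 drop = TRUE)
    summ <- do.call(rbind, lapply(agg, function(d) data.frame(
      model = d$model[1], population = d$population[1],
      r_mean = mean(d$r, na.rm = TRUE), r_sd = sd(d$r, na.rm = TRUE),
      b_mean = mean(d$b, na.rm = TRUE), b_sd = sd(d$b, na.rm = TRUE),
      n = nrow(d), stringsAsFactors = FALSE)))
    rownames(summ) <- NULL
  }
  list(summary = summ, perRepeat = perRepeat, folds = foldStore)
}

#' @importFrom stats cov
NULL
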