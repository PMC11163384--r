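#' Estimate per-block local genetic correlations
#'
#' For every LD block, fits the bivariate one-kernel mixed model using the
#' block-restricted VanRaden GRM as the single kernel and extracts the
#' local genetic correlation (from the fitted genetic covariance matrix)
#' and a likelihood-ratio p-value for zero genetic covariance. All blocks
#' are analyzed regardless of their univariate signal. A block whose REML
#' fit fails is flagged (\code{converged = FALSE}, \code{NA} estimate) and
#' falls into the default class downstream.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param pheno phenotype data.frame (\code{iid}, \code{pop}, trait).
#' @param partition a \linkS4class{GenomePartition}.
#' @param trait trait column name (default third column).
#' @param blockGrms optional pre-computed list of per-block GRMs (named by
#'   block_id), e.g. to reuse across cross-validation folds; block GRMs
#'   depend only on genotypes, never on phenotypes.
#' @return a data.frame with one row per block: \code{block_id},
#'   \code{chrom}, \code{start_bp}, \code{end_bp}, \code{n_snps},
#'   \code{r_lgc}, \code{p_value}, \code{var1}, \code{var2},
#'   \code{converged}.
#' @export
estimateLGC <- function(g, pheno, partition, trait = names(pheno)[3],
                        blockGrms = NULL) {
  b <- partition@blocks
  if (is.null(blockGrms)) blockGrms <- blockGRMs(g, partition)
  rows <- lapply(seq_len(nrow(b)), function(k) {
    id <- as.character(b$block_id[k])
    base <- data.frame(block_id = b$block_id[k], chrom = b$chrom[k],
                       start_bp = b$start_bp[k], end_bp = b$end_bp[k],
                       n_snps = b$n_snps[k], r_lgc = NA_real_,
                       p_value = NA_real_, var1 = NA_real_,
                       var2 = NA_real_, converged = FALSE,
                       stringsAsFactors = FALSE)
    gr <- blockGrms[[id]]
    if (is.null(gr)) return(base)
    res <- tryCatch({
      spec <- modelSpec(list(gr), pheno, trait = trait, traits = 2)
      lrt <- lrtZeroCovariance(spec, 1)
      vc <- lrt$full
      dp <- deriveParams(vc)
      base$r_lgc <- dp$rg$rg[1]
      base$p_value <- lrt$p
      base$var1 <- vc@M[[1]][1, 1]
      base$var2 <- vc@M[[1]][2, 2]
      base$converged <- vc@converged && lrt$null@converged
      base
    }, error = function(e) base)
    res
  })
  do.call(rbind, rows)
}

#' Per-block GRMs of a genome partition
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param partition a \linkS4class{GenomePartition}.
#' @return named list of \linkS4class{GRM}s, one per block (blocks whose
#'   SNPs are all monomorphic are skipped).
#' @export
blockGRMs <- function(g, partition) {
  sets <- blockSnpSets(partition)
  out <- list()
  for (id in names(sets)) {
    gr <- tryCatch(makeGRM(centerGenotypes(g, sets[[id]]),
                           snpSet = paste0("BLOCK", id)),
                   error = function(e) NULL)
    if (!is.null(gr)) out[[id]] <- gr
  }
  out
}

#' Classify blocks by LGC significance (SIG/NON scheme)
#'
#' Ranks blocks by the p-value of their local genetic correlation and marks
#' the \code{topK} smallest-p blocks as SIG; all others — including blocks
#' with failed fits or undefined p-values — are NON. Exact ties at the
#' boundary are broken by genomic order (the earlier block wins).
#'
#' @param records LGC table from [estimateLGC()].
#' @param topK number of SIG regions (the generic recommendation is 20;
#'   10 is the common alternative).
#' @param partition the \linkS4class{GenomePartition} the records refer to.
#' @return a \linkS4class{RegionClasses} with scheme MODEL1.
#' @export
classifyModel1 <- function(records, topK = 20, partition) {
  defined <- which(!is.na(records$p_value))
  if (topK >= nrow(records))
    stop("topK must be smaller than the number of blocks", call. = FALSE)
  if (length(defined) < topK)
    stop("fewer blocks with defined p-values than topK", call. = FALSE)
  ord <- defined[order(records$p_value[defined], defined)]
  sig <- sort(ord[seq_len(topK)])
  lab <- rep("NON", nrow(records))
  lab[sig] <- "SIG"
  .regionClasses("MODEL1", records$block_id, lab, partition)
}

#' Classify blocks by LGC magnitude and sign (POS/NEG/RES scheme)
#'
#' A block is POS if \eqn{\hat r_{lgc} \ge} \code{threshold}, NEG if
#' \eqn{\hat r_{lgc} \le -}\code{threshold} (boundary inclusive), and RES
#' otherwise, including blocks with undefined estimates.
#'
#' @param records LGC table from [estimateLGC()].
#' @param threshold magnitude threshold in (0, 1); 0.5 is the generic
#'   recommendation, 0.6 the common alternative.
#' @param partition the \linkS4class{GenomePartition}.
#' @return a \linkS4class{RegionClasses} with scheme MODEL2.
#' @export
classifyModel2 <- function(records, threshold = 0.5, partition) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  r <- records$r_lgc
  lab <- rep("RES", nrow(records))
  lab[!is.na(r) & r >= threshold] <- "POS"
  lab[!is.na(r) & r <= -threshold] <- "NEG"
  .regionClasses("MODEL2", records$block_id, lab, partition)
}

.regionClasses <- function(scheme, blockIds, labels, partition) {
  sets <- blockSnpSets(partition)
  classLabels <- switch(scheme, MODEL1 = c("SIG", "NON"),
                        MODEL2 = c("POS", "NEG", "RES"))
  snpSets <- lapply(classLabels, function(cl) {
    ids <- as.character(blockIds[labels == cl])
    as.integer(sort(unlist(sets[ids], use.names = FALSE)))
  })
  names(snpSets) <- classLabels
  assignment <- labels
  names(assignment) <- as.character(blockIds)
  new("RegionClasses", scheme = scheme, assignment = assignment,
      snpSets = snpSets)
}

#' LGC report table
#'
#' Joins the LGC estimates with the class labels under both schemes at the
#' requested thresholds.
#'
#' @param records LGC table from [estimateLGC()].
#' @param partition the \linkS4class{GenomePartition}.
#' @param topK SIG count for the MODEL1 column.
#' @param threshold magnitude threshold for the MODEL2 column.
#' @return the records data.frame with \code{class_model1} and
#'   \code{class_model2} columns added.
#' @export
lgcReport <- function(records, partition, topK = 20, threshold = 0.5) {
  out <- records
  cl1 <- tryCatch(classifyModel1(records, topK, partition)@assignment,
                  error = function(e) NULL)
  cl2 <- classifyModel2(records, threshold, partition)@assignment
  out$class_model1 <- if (is.null(cl1)) NA_character_ else
    unname(cl1[as.character(records$block_id)])
  out$class_model2 <- unname(cl2[as.character(records$block_id)])
  out
}
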