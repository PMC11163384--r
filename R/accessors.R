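#' @rdname GenotypeData-class
#' @export
setMethod("genotypeCodes", "GenotypeData", function(x) x@codes)

#' @rdname GenotypeData-class
#' @export
setMethod("snpMap", "GenotypeData", function(x) x@map)

#' @rdname GenotypeData-class
#' @export
setMethod("individualIds", "GenotypeData", function(x) x@iid)

#' @rdname GenotypeData-class
#' @export
setMethod("populations", "GenotypeData", function(x) x@pop)

#' @rdname GenotypeData-class
#' @export
setMethod("alleleFreq", "GenotypeData", function(x) x@freq)

#' @rdname GenotypeData-class
#' @export
setMethod("nInd", "GenotypeData", function(x) nrow(x@codes))

#' @rdname GenotypeData-class
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@codes))

#' @rdname GRM-class
#' @export
setMethod("grmValues", "GRM", function(x) x@values)

#' @rdname GRM-class
#' @export
setMethod("individualIds", "GRM", function(x) x@iid)

#' @rdname GRM-class
#' @export
setMethod("populations", "GRM", function(x) x@pop)

#' @rdname GenomePartition-class
#' @export
setMethod("blocks", "GenomePartition", function(x) x@blocks)

#' @rdname GenomePartition-class
#' @export
setMethod("nBlocks", "GenomePartition", function(x) nrow(x@blocks))

#' @rdname RegionClasses-class
#' @export
setMethod("classAssignment", "RegionClasses", function(x) x@assignment)

#' @rdname RegionClasses-class
#' @export
setMethod("classSnpSets", "RegionClasses", function(x) x@snpSets)

#' @rdname PredictionResult-class
#' @export
setMethod("gebv", "PredictionResult", function(x) x@gebv)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@codes), "individuals x",
      ncol(object@codes), "SNPs\n")
  tb <- table(object@pop)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "), "\n")
  cat("  chromosomes:",
      paste(unique(object@map$chrom), collapse = ", "), "\n")
  mr <- mean(is.na(object@codes))
  cat(sprintf("  missing rate: %.4f\n", mr))
  invisible(object)
})

setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM (%s): %d individuals, %d SNPs, denom = %.4f\n",
              object@snpSet, nrow(object@values), object@nSnps,
              object@denom))
  cat(sprintf("  mean diagonal: %.4f\n", mean(diag(object@values))))
  invisible(object)
})

setMethod("show", "GenomePartition", function(object) {
  b <- object@blocks
  cat("GenomePartition:", nrow(b), "blocks on",
      length(unique(b$chrom)), "chromosome(s)\n")
  cat(sprintf("  SNPs per block: min %d, median %.0f, max %d\n",
              min(b$n_snps), stats::median(b$n_snps), max(b$n_snps)))
  invisible(object)
})

setMethod("show", "RegionClasses", function(object) {
  cat("RegionClasses (", object@scheme, "):\n", sep = "")
  tb <- table(factor(object@assignment))
  for (cl in names(tb))
    cat(sprintf("  %s: %d blocks, %d SNPs\n", cl, tb[[cl]],
                length(object@snpSets[[cl]])))
  invisible(object)
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: %d trait(s), %d kernel(s), loglik = %.4f%s\n",
              object@nTraits, length(object@M), object@loglik,
              if (object@converged) "" else " (NOT converged)"))
  for (k in seq_along(object@M)) {
    M <- object@M[[k]]
    if (object@nTraits == 2) {
      r <- M[1, 2] / sqrt(M[1, 1] * M[2, 2])
      cat(sprintf("  %s: s2_a1 = %.4f, s_a12 = %.4f, s2_a2 = %.4f (r_g = %.3f)\n",
                  object@kernelNames[k], M[1, 1], M[1, 2], M[2, 2], r))
    } else {
      cat(sprintf("  %s: s2_a = %.4f\n", object@kernelNames[k], M[1, 1]))
    }
  }
  cat("  residual:", paste(sprintf("%.4f", object@residual), collapse = ", "),
      "\n")
  invisible(object)
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult (%s): %d individuals\n", object@model,
              nrow(object@gebv)))
  invisible(object)
})
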