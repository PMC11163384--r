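#' @rdname GenotypeData-class
#' @param object,x a \linkS4class{GenotypeData}.
#' @export
setGeneric("genotypeCodes", function(x) standardGeneric("genotypeCodes"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname GenotypeData-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypeData-class
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GRM-class
#' @param x a \linkS4class{GRM}.
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))

#' @rdname GenomePartition-class
#' @param x a \linkS4class{GenomePartition}.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname GenomePartition-class
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' @rdname RegionClasses-class
#' @param x a \linkS4class{RegionClasses}.
#' @export
setGeneric("classAssignment", function(x) standardGeneric("classAssignment"))

#' @rdname RegionClasses-class
#' @export
setGeneric("classSnpSets", function(x) standardGeneric("classSnpSets"))

#' @rdname PredictionResult-class
#' @param x a \linkS4class{PredictionResult}.
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))
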