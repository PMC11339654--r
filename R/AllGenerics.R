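#' @rdname GenotypePanel-class
#' @param x an object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("genoLikelihoods", function(x) standardGeneric("genoLikelihoods"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("ancestralAllele", function(x) standardGeneric("ancestralAllele"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))

#' @rdname HaplotypePanel-class
#' @param x an object.
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname EnvDesign-class
#' @param x an object.
#' @export
setGeneric("envScores", function(x) standardGeneric("envScores"))

#' @rdname EnvDesign-class
#' @export
setGeneric("geaCoefficients", function(x) standardGeneric("geaCoefficients"))
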