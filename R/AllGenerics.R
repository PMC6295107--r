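#' @rdname SnpSurvivalExperiment
#' @param x a `SnpSurvivalExperiment`.
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname SnpSurvivalExperiment
#' @export
setGeneric("eventStatus", function(x) standardGeneric("eventStatus"))

#' @rdname SnpSurvivalExperiment
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))

#' @rdname SnpSurvivalExperiment
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname SnpSurvivalExperiment
#' @export
setGeneric("snpNames", function(x) standardGeneric("snpNames"))

#' Evaluate a cumulative hazard step function
#'
#' @param object a [CumHazard-class].
#' @param t times at which to evaluate (right-continuous).
#' @return numeric vector of \eqn{\hat\Lambda(t)}.
#' @export
setGeneric("cumhazAt", function(object, t) standardGeneric("cumhazAt"))

#' @rdname UMMDRScan-class
#' @param object an object.
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))

#' @rdname PenetranceModel-class
#' @export
setGeneric("penetrance", function(object) standardGeneric("penetrance"))

#' @rdname PenetranceModel-class
#' @export
setGeneric("heritability", function(object) standardGeneric("heritability"))

#' @rdname PenetranceModel-class
#' @export
setGeneric("prevalence", function(object) standardGeneric("prevalence"))
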