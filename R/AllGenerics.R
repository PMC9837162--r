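#' @rdname PromoterCohort-class
#' @param x,object A `PromoterCohort`.
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname PromoterCohort-class
#' @export
setGeneric("promoterSequences", function(x) standardGeneric("promoterSequences"))

#' @rdname PromoterCohort-class
#' @export
setGeneric("cohortInfo", function(x) standardGeneric("cohortInfo"))

#' @rdname PromoterCohort-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname TataMatrix-class
#' @param x A `TataMatrix`.
#' @export
setGeneric("matrixWidth", function(x) standardGeneric("matrixWidth"))

#' @rdname TataMatrix-class
#' @export
setGeneric("matrixProbs", function(x) standardGeneric("matrixProbs"))

#' @rdname TataMatrix-class
#' @export
setGeneric("matrixBackground", function(x) standardGeneric("matrixBackground"))

#' @rdname TataMatrix-class
#' @export
setGeneric("consensusWindow", function(x) standardGeneric("consensusWindow"))
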