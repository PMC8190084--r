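#' Accessors for package classes
#'
#' Small accessor family for the S4 result and container classes:
#' \code{phenotypes}, \code{genotypes}, \code{variantAnnotations},
#' \code{clinvarRecords}, \code{transcriptModels}, \code{simConfig} for
#' \linkS4class{SyntheticCohort}; \code{effectSize}, \code{stdError},
#' \code{pValue}, \code{confInt}, \code{nCarriers} for
#' \linkS4class{EffectEstimate}; \code{decision}, \code{lofClass},
#' \code{evidence} for the rule-engine outcomes.
#'
#' @param x the object.
#' @return the slot contents (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("variantAnnotations", function(x) standardGeneric("variantAnnotations"))
#' @rdname accessors
#' @export
setGeneric("clinvarRecords", function(x) standardGeneric("clinvarRecords"))
#' @rdname accessors
#' @export
setGeneric("transcriptModels", function(x) standardGeneric("transcriptModels"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
#' @rdname accessors
#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))
#' @rdname accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("nCarriers", function(x) standardGeneric("nCarriers"))
#' @rdname accessors
#' @export
setGeneric("decision", function(x) standardGeneric("decision"))
#' @rdname accessors
#' @export
setGeneric("lofClass", function(x) standardGeneric("lofClass"))
#' @rdname accessors
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))

#' @rdname accessors
#' @export
setMethod("phenotypes", "SyntheticCohort", function(x) x@phenotypes)
#' @rdname accessors
#' @export
setMethod("genotypes", "SyntheticCohort", function(x) x@genotypes)
#' @rdname accessors
#' @export
setMethod("variantAnnotations", "SyntheticCohort", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("clinvarRecords", "SyntheticCohort", function(x) x@clinvar)
#' @rdname accessors
#' @export
setMethod("transcriptModels", "SyntheticCohort", function(x) x@transcripts)
#' @rdname accessors
#' @export
setMethod("simConfig", "SyntheticCohort", function(x) x@config)
#' @rdname accessors
#' @export
setMethod("effectSize", "EffectEstimate", function(x) x@beta)
#' @rdname accessors
#' @export
setMethod("stdError", "EffectEstimate", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("pValue", "EffectEstimate", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("confInt", "EffectEstimate", function(x) c(lower = x@ciLower, upper = x@ciUpper))
#' @rdname accessors
#' @export
setMethod("nCarriers", "EffectEstimate", function(x) x@nCarriers)
#' @rdname accessors
#' @export
setMethod("decision", "TriageDecision", function(x) x@decision)
#' @rdname accessors
#' @export
setMethod("lofClass", "LofCall", function(x) x@lofClass)
#' @rdname accessors
#' @export
setMethod("evidence", "TriageDecision", function(x) x@evidence)
#' @rdname accessors
#' @export
setMethod("evidence", "LofCall", function(x) x@evidence)
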