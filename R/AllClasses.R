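#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importFrom stats rnorm rbinom runif plogis qlogis dnorm pnorm qnorm qbeta
#'   lm lm.fit pchisq qchisq uniroot quantile sd complete.cases setNames
#'   ecdf pt qt
#' @importFrom utils write.table read.table head
NULL

.LOF_LEVELS <- c("not_LoF", "likely_not_LoF", "uncertain", "likely_LoF", "LoF")
.DECISIONS  <- c("clinically_significant", "excluded", "manual_review")

#' Specification of one monogenic condition for simulation
#'
#' Describes a monogenic condition in terms of its gene panel, the population
#' carrier frequency of clinically significant variants, and the additive
#' carrier effect on the proxy trait (in trait units for continuous traits, or
#' log-odds for binary outcomes such as diabetes).
#'
#' @slot condition character(1) condition label, e.g. "high_ldl".
#' @slot genes character vector of panel genes.
#' @slot carrierFrequency numeric(1) in (0, 0.01); probability an individual
#'   carries a qualifying variant in any panel gene.
#' @slot beta numeric(1) additive carrier effect (trait units, or log-odds for
#'   binary traits).
#' @slot trait character(1) the proxy trait the condition acts on
#'   ("ldl", "hdl", "tg", "bmi", or "diabetes").
#' @slot binary logical(1) whether the proxy trait is a binary outcome.
#' @slot penetranceTarget numeric(1) expected fraction of carriers beyond the
#'   clinical cut-off, used only for reporting (NA when not set).
#' @exportClass ConditionSpec
setClass("ConditionSpec",
  representation(condition = "character", genes = "character",
                 carrierFrequency = "numeric", beta = "numeric",
                 trait = "character", binary = "logical",
                 penetranceTarget = "numeric"),
  prototype(binary = FALSE, penetranceTarget = NA_real_))

setValidity("ConditionSpec", function(object) {
  msg <- character()
  if (length(object@genes) < 1L) msg <- c(msg, "gene panel must be non-empty")
  f <- object@carrierFrequency
  if (length(f) != 1L || !is.finite(f) || f <= 0 || f >= 0.01)
    msg <- c(msg, "carrierFrequency must be a single value in (0, 0.01)")
  if (!is.finite(object@beta)) msg <- c(msg, "beta must be finite")
  if (!object@trait %in% c("ldl", "hdl", "tg", "bmi", "diabetes"))
    msg <- c(msg, "trait must be one of ldl, hdl, tg, bmi, diabetes")
  if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic biobank cohort
#'
#' Holds every parameter of the cohort generator: sample size, seed, condition
#' panels, trait heritabilities (variance fraction captured by the simulated
#' polygenic component), trait means and standard deviations, the
#' lipid-lowering treatment model, and the baseline diabetes model.
#'
#' @slot nIndividuals integer(1) cohort size.
#' @slot seed integer(1) master seed; all child streams derive from it.
#' @slot conditions list of \linkS4class{ConditionSpec}.
#' @slot h2 named numeric: per-trait fraction of variance explained by the
#'   polygenic component (each in [0, 1)).
#' @slot traitMeans,traitSds named numeric: per-trait population mean/sd in
#'   mg/dL (lipids) or kg/m2 (BMI).
#' @slot medIntercept,medSlope numeric(1): logistic model of lipid-lowering
#'   treatment probability, \code{plogis(medIntercept + medSlope * (rawLDL - 160)/10)}.
#' @slot diabetesPrevalence numeric(1) baseline (non-carrier) diabetes
#'   prevalence used as the liability-model intercept.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nIndividuals = "integer", seed = "integer",
                 conditions = "list", h2 = "numeric",
                 traitMeans = "numeric", traitSds = "numeric",
                 medIntercept = "numeric", medSlope = "numeric",
                 diabetesPrevalence = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be positive")
  if (any(object@h2 < 0 | object@h2 >= 1))
    msg <- c(msg, "heritabilities must lie in [0, 1)")
  if (any(object@traitSds <= 0)) msg <- c(msg, "trait sds must be positive")
  if (!all(vapply(object@conditions, is, logical(1), "ConditionSpec")))
    msg <- c(msg, "conditions must be a list of ConditionSpec")
  p <- object@diabetesPrevalence
  if (p <= 0 || p >= 1) msg <- c(msg, "diabetesPrevalence must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Transcript model for loss-of-function curation
#'
#' Minimal coding-transcript model: ordered coding exons as genomic intervals
#' (1-based closed at the interface, half-open internally) plus the coding
#' length. Exons are stored 5'-to-3' in transcript orientation, so for minus
#' strand transcripts the first exon has the largest coordinates.
#'
#' @slot gene character(1).
#' @slot strand character(1), "+" or "-".
#' @slot exons an \link[IRanges]{IRanges} of coding exons in transcript order.
#' @slot cdsLength integer(1) total coding bases; defaults to the summed exon
#'   widths.
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(gene = "character", strand = "character",
                 exons = "IRanges", cdsLength = "integer"))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  ex <- object@exons
  if (length(ex) < 1L) msg <- c(msg, "at least one exon required")
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (any(en < st)) msg <- c(msg, "malformed exon intervals")
  ord <- if (object@strand == "+") st else -st
  if (is.unsorted(ord, strictly = TRUE))
    msg <- c(msg, "exons must be ordered 5'->3' in transcript orientation")
  if (length(ex) > 1L) {
    gst <- sort(st); gen <- sort(en)
    if (any(gst[-1] <= gen[-length(gen)])) msg <- c(msg, "exons overlap")
  }
  if (object@cdsLength < 1L) msg <- c(msg, "cdsLength must be positive")
  if (length(msg)) msg else TRUE
})

#' A synthetic cohort with genotypes and annotations
#'
#' Container returned by \code{\link{simulateCohort}}: the per-individual
#' phenotype table, the rare-variant genotype matrix (individuals x variants,
#' alt-allele dosage), the variant annotation sidecar, ClinVar-style
#' submission records, transcript models, and the generating configuration.
#'
#' @slot phenotypes data.frame of per-individual phenotypes, covariates and
#'   carrier flags.
#' @slot genotypes integer matrix, individuals x variants.
#' @slot variants data.frame annotation sidecar (one row per variant).
#' @slot clinvar data.frame of ClinVar-submission-summary-style records.
#' @slot transcripts named list of \linkS4class{TranscriptModel}.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @slot notes character vector of generation warnings (e.g. a condition that
#'   drew zero carriers).
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(phenotypes = "data.frame", genotypes = "matrix",
                 variants = "data.frame", clinvar = "data.frame",
                 transcripts = "list", config = "SimulationConfig",
                 notes = "character"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (nrow(object@phenotypes) != nrow(object@genotypes))
    msg <- c(msg, "phenotype rows and genotype rows disagree")
  if (ncol(object@genotypes) != nrow(object@variants))
    msg <- c(msg, "genotype columns and variant rows disagree")
  if (length(msg)) msg else TRUE
})

#' Result of a carrier burden regression
#'
#' @slot beta numeric(1) effect in trait units (linear) or log-odds (logistic).
#' @slot se numeric(1) standard error.
#' @slot p numeric(1) two-sided p-value.
#' @slot ciLower,ciUpper numeric(1) confidence bounds on the beta scale.
#' @slot nCarriers,nTotal integer(1).
#' @slot covariates character vector of adjustment covariates.
#' @slot method character(1), e.g. "ols", "firth", "glm".
#' @slot note character(1) free-text analysis note (e.g. log-scale analysis).
#' @exportClass EffectEstimate
setClass("EffectEstimate",
  representation(beta = "numeric", se = "numeric", p = "numeric",
                 ciLower = "numeric", ciUpper = "numeric",
                 nCarriers = "integer", nTotal = "integer",
                 covariates = "character", method = "character",
                 note = "character"),
  prototype(note = ""))

setValidity("EffectEstimate", function(object) {
  msg <- character()
  if (!is.na(object@se) && object@se <= 0) msg <- c(msg, "se must be positive")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    msg <- c(msg, "p must lie in (0, 1]")
  if (!is.na(object@ciLower) && !is.na(object@ciUpper) &&
      (object@ciLower > object@beta || object@ciUpper < object@beta))
    msg <- c(msg, "confidence interval must bracket the point estimate")
  if (length(msg)) msg else TRUE
})

#' Outcome of the ClinVar triage rule pass for one variant
#'
#' @slot decision one of "clinically_significant", "excluded", "manual_review".
#' @slot evidence ordered character vector of fired rules.
#' @exportClass TriageDecision
setClass("TriageDecision",
  representation(decision = "character", evidence = "character"))

setValidity("TriageDecision", function(object) {
  msg <- character()
  if (!object@decision %in% .DECISIONS) msg <- c(msg, "unknown decision")
  if (object@decision != "manual_review" && length(object@evidence) == 0L)
    msg <- c(msg, "evidence must be non-empty unless decision is manual_review")
  if (length(msg)) msg else TRUE
})

#' Outcome of the predicted loss-of-function rule engine for one variant
#'
#' @slot lofClass one of "LoF", "likely_LoF", "uncertain", "likely_not_LoF",
#'   "not_LoF".
#' @slot evidence ordered character vector of fired rules.
#' @exportClass LofCall
setClass("LofCall",
  representation(lofClass = "character", evidence = "character"))

setValidity("LofCall", function(object) {
  if (!object@lofClass %in% .LOF_LEVELS) "unknown LoF class" else TRUE
})

#' @describeIn SyntheticCohort compact display
#' @param object a SyntheticCohort
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort with", nrow(object@phenotypes), "individuals,",
      nrow(object@variants), "variants,",
      length(object@config@conditions), "conditions\n")
  cc <- grep("^carrier_", colnames(object@phenotypes), value = TRUE)
  for (col in cc)
    cat("  ", sub("^carrier_", "", col), ": ",
        sum(object@phenotypes[[col]]), " carriers\n", sep = "")
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' @describeIn EffectEstimate compact display
#' @param object an EffectEstimate
#' @export
setMethod("show", "EffectEstimate", function(object) {
  cat(sprintf("EffectEstimate [%s]: beta = %.4g (se %.4g), p = %.3g\n",
              object@method, object@beta, object@se, object@p))
  cat(sprintf("  95%% CI [%.4g, %.4g], %d carriers / %d total\n",
              object@ciLower, object@ciUpper, object@nCarriers, object@nTotal))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' @describeIn TriageDecision compact display
#' @param object a TriageDecision
#' @export
setMethod("show", "TriageDecision", function(object) {
  cat("TriageDecision:", object@decision, "\n")
  if (length(object@evidence))
    cat(paste0("  - ", object@evidence, collapse = "\n"), "\n")
})

#' @describeIn LofCall compact display
#' @param object a LofCall
#' @export
setMethod("show", "LofCall", function(object) {
  cat("LofCall:", object@lofClass, "\n")
  if (length(object@evidence))
    cat(paste0("  - ", object@evidence, collapse = "\n"), "\n")
})
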