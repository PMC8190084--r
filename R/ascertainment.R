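#' Mean of a truncated normal
#'
#' Expected value of a normal trait conditional on lying beyond a selection
#' threshold: for upper-tail selection
#' \code{mu + sigma * dnorm(a) / (1 - pnorm(a))} with
#' \code{a = (threshold - mu) / sigma}; lower-tail selection is symmetric
#' (\code{mu - sigma * dnorm(a) / pnorm(a)}). This is the closed-form
#' oracle for the carrier-mean inflation induced by extreme-phenotype
#' ascertainment.
#'
#' @param mu,sigma trait mean and sd (sigma > 0).
#' @param threshold selection threshold (trait units).
#' @param side "upper" or "lower".
#' @return expected trait mean among selected individuals.
#' @examples
#' truncatedMean(0, 1, 0, "upper")  # 0.7979, the half-normal mean
#' @export
truncatedMean <- function(mu, sigma, threshold, side = c("upper", "lower")) {
  side <- match.arg(side)
  stopifnot(sigma > 0)
  a <- (threshold - mu) / sigma
  if (side == "upper") mu + sigma * dnorm(a) / pnorm(a, lower.tail = FALSE)
  else mu - sigma * dnorm(a) / pnorm(a)
}

#' Phenotypic-ascertainment contrast for carrier trait means
#'
#' Quantifies how selecting individuals for an extreme phenotype inflates
#' the apparent trait mean of monogenic variant carriers, compared to
#' carriers identified genotype-first in an unascertained population.
#' Reports the empirical carrier mean in the ascertained subset, the
#' carrier mean in the full (unascertained) cohort, their difference, and
#' the truncated-normal expectation for the ascertained mean given the
#' carriers' own mean/sd and the selection threshold actually applied.
#' Optional stratification (e.g. by variant) reproduces the single-variant
#' panels of the phenomenon.
#'
#' @param cohort phenotype data.frame or \linkS4class{SyntheticCohort}.
#' @param carrier logical carrier flags aligned to the cohort.
#' @param trait trait column selected on and summarized.
#' @param scheme an \code{\link{extremePhenotypeScheme}} (or
#'   \code{\link{populationScheme}} for a no-selection control).
#' @param stratifyBy optional factor (e.g. variant id per carrier) for
#'   per-stratum contrasts.
#' @return data.frame with one row per stratum (or a single "all" row):
#'   columns stratum, n_ascertained, n_unascertained, mean_ascertained,
#'   mean_unascertained, difference, expected_ascertained_mean,
#'   expected_difference, threshold.
#' @export
ascertainmentContrast <- function(cohort, carrier, trait, scheme,
                                  stratifyBy = NULL) {
  ph <- if (is(cohort, "SyntheticCohort")) phenotypes(cohort) else cohort
  stopifnot(length(carrier) == nrow(ph))
  if (!trait %in% colnames(ph)) stop("trait '", trait, "' absent")
  sel <- applyAscertainment(ph, scheme)
  thr <- attr(sel, "thresholds")
  selected <- rownames(ph) %in% rownames(sel)
  side <- if (scheme$kind == "extreme_phenotype" && scheme$side == "lower")
    "lower" else "upper"
  oneStratum <- function(idx, label) {
    carrU <- idx & carrier
    carrA <- carrU & selected
    if (sum(carrU) == 0L) stop("empty carrier stratum: ", label)
    if (sum(carrA) == 0L) stop("no ascertained carriers in stratum: ", label)
    x <- ph[[trait]]
    muC <- mean(x[carrU]); sdC <- sd(x[carrU])
    expMean <- if (is.null(thr)) muC
      else truncatedMean(muC, sdC, unname(thr[1]), side)
    data.frame(stratum = label,
               n_ascertained = sum(carrA), n_unascertained = sum(carrU),
               mean_ascertained = mean(x[carrA]),
               mean_unascertained = muC,
               difference = mean(x[carrA]) - muC,
               expected_ascertained_mean = expMean,
               expected_difference = expMean - muC,
               threshold = if (is.null(thr)) NA_real_ else unname(thr[1]),
               stringsAsFactors = FALSE)
  }
  if (is.null(stratifyBy))
    return(oneStratum(rep(TRUE, nrow(ph)), "all"))
  strata <- setdiff(unique(stratifyBy[carrier]), NA)
  do.call(rbind, lapply(strata, function(s)
    oneStratum(!is.na(stratifyBy) & stratifyBy == s, s)))
}
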