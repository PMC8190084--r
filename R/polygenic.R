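#' Apply polygenic score weights to genotype dosages
#'
#' Computes per-individual scores as the weighted sum of effect-allele
#' dosages, the standard additive scoring used by PLINK \code{--score}.
#' Weight files whose effect allele is the other strand/allele of the
#' genotype orientation are reconciled by counting \code{2 - dosage};
#' missing dosages are mean-imputed per variant. Scores are then centered
#' and scaled to mean 0, sd 1, percentile bins (1-100) are assigned, and an
#' orientation flag of -1 inverts the score (used for conditions at the low
#' end of a trait, e.g. low LDL analyses use the inverse of the LDL score).
#'
#' @param dosages matrix individuals x variants of alt-allele dosages (0-2,
#'   NA = missing), columns named by variant id.
#' @param weights data.frame with columns \code{variant_id},
#'   \code{effect_allele}, \code{weight}.
#' @param info data.frame with \code{variant_id}, \code{ref}, \code{alt}
#'   giving the dosage orientation; when NULL the effect allele is assumed
#'   to be the counted (alt) allele.
#' @param orientation +1 or -1 sign flag applied to the standardized score.
#' @return data.frame with columns \code{id}, \code{raw}, \code{z},
#'   \code{percentile}.
#' @export
computePgs <- function(dosages, weights, info = NULL, orientation = 1) {
  stopifnot(orientation %in% c(-1, 1))
  common <- intersect(colnames(dosages), weights$variant_id)
  if (length(common) == 0L)
    stop("no overlap between dosage columns and weight variants")
  W <- weights[match(common, weights$variant_id), ]
  D <- dosages[, common, drop = FALSE]
  if (!is.null(info)) {
    inf <- info[match(common, info$variant_id), ]
    flip <- W$effect_allele == inf$ref
    if (any(flip)) D[, flip] <- 2 - D[, flip, drop = FALSE]
    bad <- !(W$effect_allele == inf$alt | flip)
    if (any(bad)) { D <- D[, !bad, drop = FALSE]; W <- W[!bad, ] }
  }
  # per-variant mean imputation of missing dosages
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  raw <- drop(D %*% W$weight)
  z <- if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else raw - mean(raw)
  z <- orientation * z
  pct <- ceiling(rank(z, ties.method = "first") / length(z) * 100)
  data.frame(id = rownames(dosages) %||% seq_along(raw), raw = raw, z = z,
             percentile = as.integer(pct), stringsAsFactors = FALSE)
}

#' Contrast the top polygenic tail against the interquartile range
#'
#' Compares individuals in the top \code{tail} of the standardized score
#' against the interquartile reference (25th-75th percentile) for a trait,
#' with covariate adjustment (linear model, or logistic for binary
#' outcomes); optionally also contrasts monogenic carriers against the top
#' tail. Controls are restricted to the stated minimum age, and percentiles
#' are assigned on the analysis subset after that filter.
#'
#' @param data data.frame with the score column \code{z}, the phenotype,
#'   and covariates.
#' @param phenotype phenotype column name.
#' @param covariates covariate column names.
#' @param tail top tail fraction (default 0.01).
#' @param reference quantile range used as reference, default c(0.25, 0.75).
#' @param ageMin minimum age (applied to the whole analysis subset),
#'   default 60; NULL disables.
#' @param binary logistic instead of linear contrast.
#' @param carrier optional logical carrier flags aligned to \code{data};
#'   when given, a carrier-vs-top-tail contrast is also returned.
#' @return list with \code{tailVsReference} (an
#'   \linkS4class{EffectEstimate}; beta = top-tail minus reference) and,
#'   when carriers are supplied, \code{carrierVsTail}.
#' @export
contrastTopTail <- function(data, phenotype, covariates = NULL, tail = 0.01,
                            reference = c(0.25, 0.75), ageMin = 60,
                            binary = FALSE, carrier = NULL) {
  stopifnot("z" %in% colnames(data))
  if (!is.null(carrier)) data$.carrier <- carrier
  if (!is.null(ageMin)) data <- data[data$age >= ageMin, , drop = FALSE]
  if (nrow(data) == 0L) stop("no individuals left after age filter")
  q <- stats::ecdf(data$z)(data$z)
  inTail <- q >= 1 - tail
  inRef <- q >= reference[1] & q <= reference[2]
  if (!any(inTail)) stop("empty top tail after age filter")
  fitGroups <- function(gA, gB) {
    sub <- data[gA | gB, , drop = FALSE]
    flag <- gA[gA | gB]
    covs <- if (!is.null(covariates)) sub[, covariates, drop = FALSE]
    if (binary) fitFirthLogistic(flag, sub[[phenotype]], covs)
    else fitLinearBurden(flag, sub[[phenotype]], covs)
  }
  out <- list(tailVsReference = fitGroups(inTail, inRef))
  if (!is.null(carrier))
    out$carrierVsTail <- fitGroups(data$.carrier, inTail & !data$.carrier)
  out
}

#' Polygenic score effect within monogenic carriers
#'
#' Regression of the phenotype on the standardized polygenic score within
#' clinically significant variant carriers only, quantifying how polygenic
#' background modifies expressivity among carriers.
#'
#' @param data data.frame restricted to carriers, containing \code{z}, the
#'   phenotype and covariates.
#' @param phenotype phenotype column name.
#' @param covariates covariate column names.
#' @param binary logistic instead of linear.
#' @param minCarriers minimum carrier count (default 10).
#' @return an \linkS4class{EffectEstimate} for the per-SD score effect.
#' @export
carrierGepsRegression <- function(data, phenotype, covariates = NULL,
                                  binary = FALSE, minCarriers = 10L) {
  n <- nrow(data)
  if (n < minCarriers) stop("fewer than ", minCarriers, " carriers")
  nCov <- length(covariates)
  if (n < nCov + 2L) stop("fewer carriers than covariates + 2")
  X <- cbind(z = data$z,
             if (nCov) data.matrix(data[, covariates, drop = FALSE]))
  y <- data[[phenotype]]
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (binary) {
    fit <- .firthCore(cbind(`(Intercept)` = 1, X), as.numeric(y))
    j <- 2L
    b <- fit$beta[j]; se <- sqrt(fit$vcov[j, j])
    p <- 2 * pnorm(-abs(b / se))
    method <- "firth"
  } else {
    lmf <- lm(y ~ X)
    sm <- summary(lmf)$coefficients
    b <- sm["Xz", 1]; se <- sm["Xz", 2]; p <- sm["Xz", 4]
    method <- "ols"
  }
  new("EffectEstimate", beta = unname(b), se = unname(se),
      p = max(unname(p), .Machine$double.xmin),
      ciLower = unname(b - 1.96 * se), ciUpper = unname(b + 1.96 * se),
      nCarriers = as.integer(sum(keep)), nTotal = as.integer(sum(keep)),
      covariates = covariates %||% character(), method = method,
      note = "carrier-only gePS regression")
}

#' Monogenic-by-polygenic interaction test
#'
#' Model with carrier and score main effects plus their product; the
#' reported estimate is the carrier x gePS interaction coefficient with a
#' two-sided p-value.
#'
#' @param data data.frame with \code{z}, the phenotype and covariates.
#' @param carrier logical carrier flags.
#' @param phenotype phenotype column name.
#' @param covariates covariate column names.
#' @param binary logistic instead of linear.
#' @return an \linkS4class{EffectEstimate} for the interaction term.
#' @export
interactionTest <- function(data, carrier, phenotype, covariates = NULL,
                            binary = FALSE) {
  carrier <- as.numeric(carrier)
  if (length(unique(carrier)) < 2L)
    stop("need both carriers and non-carriers for an interaction test")
  X <- cbind(carrier = carrier, z = data$z, carrier_z = carrier * data$z,
             if (length(covariates)) data.matrix(data[, covariates, drop = FALSE]))
  y <- data[[phenotype]]
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (binary) {
    fit <- .firthCore(cbind(`(Intercept)` = 1, X), as.numeric(y))
    j <- which(colnames(X) == "carrier_z") + 1L
    b <- fit$beta[j]; se <- sqrt(fit$vcov[j, j])
    p <- 2 * pnorm(-abs(b / se)); method <- "firth"
  } else {
    lmf <- lm(y ~ X)
    sm <- summary(lmf)$coefficients
    b <- sm["Xcarrier_z", 1]; se <- sm["Xcarrier_z", 2]; p <- sm["Xcarrier_z", 4]
    method <- "ols"
  }
  new("EffectEstimate", beta = unname(b), se = unname(se),
      p = max(unname(p), .Machine$double.xmin),
      ciLower = unname(b - 1.96 * se), ciUpper = unname(b + 1.96 * se),
      nCarriers = as.integer(sum(carrier[keep] > 0)),
      nTotal = as.integer(sum(keep)),
      covariates = covariates %||% character(), method = method,
      note = "carrier x gePS interaction")
}

#' Tail fraction whose polygenic mean equals a target shift
#'
#' For a polygenic score explaining a fraction \code{h2} of the variance of
#' a trait with standard deviation \code{traitSd}, the mean trait shift of
#' the top-q score tail is
#' \code{sqrt(h2) * traitSd * dnorm(qnorm(1 - q)) / q} (the truncated-normal
#' tail mean). This solves that map for the tail fraction q achieving a
#' stated target shift (for example, the carrier mean excess of a monogenic
#' condition), by bracketed root finding; the forward map is strictly
#' decreasing in q, so q is strictly decreasing in the target shift and
#' increasing in h2.
#'
#' @param h2 variance fraction captured by the score, in (0, 1).
#' @param traitSd trait standard deviation (trait units).
#' @param targetShift target mean shift above the population mean (> 0).
#' @return list with \code{q} (tail fraction), \code{impliedTailMean}
#'   (= targetShift at the solution) and \code{zThreshold}
#'   (\code{qnorm(1 - q)}).
#' @examples
#' equivalentTailFraction(0.157, 15, 16.8)$q  # about 6e-3
#' @export
equivalentTailFraction <- function(h2, traitSd, targetShift) {
  stopifnot(h2 > 0, h2 < 1, traitSd > 0)
  if (targetShift <= 0) stop("targetShift must be positive")
  forward <- function(q) sqrt(h2) * traitSd * dnorm(qnorm(1 - q)) / q
  qMin <- 1e-8
  if (targetShift > forward(qMin))
    stop(sprintf("shift %.3g unattainable for any tail fraction >= %g",
                 targetShift, qMin))
  root <- uniroot(function(q) forward(q) - targetShift,
                  lower = qMin, upper = 1 - 1e-8, tol = 1e-12)
  list(q = root$root, impliedTailMean = forward(root$root),
       zThreshold = qnorm(1 - root$root))
}

#' Carriers needed to detect a trait-score correlation
#'
#' Fisher z-approximation sample size for detecting a Pearson correlation
#' \code{r} at significance \code{alpha} and the stated power:
#' \code{n = ceil(((z_(1-alpha) + z_power) / atanh(r))^2 + 3)}. One-sided by
#' default.
#'
#' @param r target correlation, in (0, 1).
#' @param power desired power, in (0, 1).
#' @param alpha significance level, in (0, 0.5).
#' @param sided "one" or "two".
#' @return minimum carrier count (integer).
#' @examples
#' nForCorrelation(0.25, 0.8, 0.05)  # 98
#' @export
nForCorrelation <- function(r, power = 0.8, alpha = 0.05,
                            sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 0.5)
  za <- qnorm(1 - if (sided == "one") alpha else alpha / 2)
  zb <- qnorm(power)
  as.integer(ceiling(((za + zb) / atanh(r))^2 + 3))
}

#' Cohort size needed to observe a carrier count
#'
#' @param nCarriers carriers required (e.g. from
#'   \code{\link{nForCorrelation}}).
#' @param prevalence carrier prevalence, in (0, 1].
#' @return required population-based cohort size.
#' @examples
#' requiredCohortSize(98, 1e-4)  # 980000, i.e. on the order of one million
#' @export
requiredCohortSize <- function(nCarriers, prevalence) {
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must lie in (0, 1]")
  as.integer(ceiling(nCarriers / prevalence))
}
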