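#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion from Beta quantiles:
#' lower bound \code{qbeta(alpha/2, k, n - k + 1)} (0 when k = 0) and upper
#' bound \code{qbeta(1 - alpha/2, k + 1, n - k)} (1 when k = n).
#'
#' @param k number of affected carriers (0 <= k <= n).
#' @param n number of carriers with evaluable phenotype (>= 1).
#' @param level confidence level, default 0.95.
#' @return numeric vector \code{c(lower, upper)}; vectorized over k/n into a
#'   two-column matrix.
#' @examples
#' clopperPearson(7, 7)    # lower 0.590: all 7 carriers affected
#' clopperPearson(19, 22)  # 0.651 to 0.971
#' @export
clopperPearson <- function(k, n, level = 0.95) {
  if (any(n < 1L)) stop("n must be at least 1")
  if (any(k < 0L | k > n)) stop("k must lie in [0, n]")
  alpha <- 1 - level
  lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  if (length(k) == 1L && length(n) == 1L) c(lower = lower, upper = upper)
  else cbind(lower = lower, upper = upper)
}

#' Penetrance estimates with exact confidence intervals
#'
#' Penetrance is the proportion of carriers of a clinically significant
#' variant that exhibit the expected condition. Carriers whose phenotype is
#' missing or indeterminate are excluded from the denominator (never
#' imputed). Rows are produced per grouping label (typically per gene plus
#' the composite panel); groups without evaluable carriers are omitted with
#' a warning.
#'
#' @param carrier logical carrier flags.
#' @param case logical case flags (NA = indeterminate phenotype).
#' @param group optional character vector grouping carriers (e.g. gene); a
#'   "composite" row over all carriers is always emitted.
#' @param condition condition label.
#' @param outcome outcome-definition label carried into the output.
#' @param level confidence level.
#' @return data.frame with columns condition, gene, outcome, k, n, point,
#'   lower, upper.
#' @export
penetranceTable <- function(carrier, case, group = NULL,
                            condition = NA_character_,
                            outcome = NA_character_, level = 0.95) {
  stopifnot(length(carrier) == length(case))
  rowsFor <- function(flags, label) {
    idx <- which(flags & !is.na(case))
    n <- length(idx)
    if (n == 0L) {
      warning("no evaluable carriers for ", label, "; row omitted")
      return(NULL)
    }
    k <- sum(case[idx])
    ci <- clopperPearson(k, n, level)
    data.frame(condition = condition, gene = label, outcome = outcome,
               k = k, n = n, point = k / n,
               lower = unname(ci["lower"]), upper = unname(ci["upper"]),
               stringsAsFactors = FALSE)
  }
  out <- list(rowsFor(carrier, "composite"))
  if (!is.null(group)) {
    for (g in setdiff(unique(group[carrier]), NA))
      out <- c(out, list(rowsFor(carrier & group == g, g)))
  }
  res <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(res) <- NULL
  res
}
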