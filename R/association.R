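# Firth-penalized logistic regression: Newton iterations on the modified
# score U*_k = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ik, where h_i are the
# leverages of W^{1/2} X. The penalized log-likelihood is
# l(beta) + 1/2 log det X'WX (Jeffreys prior), which keeps estimates finite
# under complete separation. `fixed` allows profile-likelihood computations
# by constraining a subset of coefficients.
.firthCore <- function(X, y, beta = NULL, fixed = integer(0),
                       maxit = 50L, tol = 1e-8) {
  p <- ncol(X)
  if (is.null(beta)) beta <- numeric(p)
  free <- setdiff(seq_len(p), fixed)
  pll <- function(b) {
    eta <- drop(X %*% b)
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    XtWX <- crossprod(X * sqrt(w))
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  }
  cur <- pll(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    sw <- sqrt(w)
    XtWX <- crossprod(X * sw)
    Vinv <- tryCatch(solve(XtWX), error = function(e)
      stop("Firth information matrix is singular (collinear predictors?)"))
    h <- rowSums((X %*% Vinv) * X) * w
    Ustar <- drop(crossprod(X, y - pr + h * (0.5 - pr)))
    if (length(free) == 0L) break
    delta <- numeric(p)
    delta[free] <- drop(solve(XtWX[free, free, drop = FALSE], Ustar[free]))
    step <- 1
    repeat {
      cand <- beta + step * delta
      new <- pll(cand)
      if (is.finite(new) && new >= cur - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { new <- cur; cand <- beta; break }
    }
    improve <- abs(new - cur) / (abs(cur) + 1e-8)
    beta <- cand
    if (improve < tol && max(abs(Ustar[free])) < 1e-4) {
      cur <- new; converged <- TRUE; break
    }
    cur <- new
  }
  eta <- drop(X %*% beta)
  pr <- plogis(eta)
  w <- pmax(pr * (1 - pr), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  list(beta = beta, vcov = solve(XtWX), pll = cur,
       converged = converged || length(free) == 0L, iterations = it)
}

.firthProfileCI <- function(X, y, fit, j, level = 0.95) {
  target <- drop(fit$pll) - qchisq(level, 1) / 2
  prof <- function(bj) {
    b0 <- fit$beta; b0[j] <- bj
    drop(.firthCore(X, y, beta = b0, fixed = j)$pll) - target
  }
  hat <- fit$beta[j]
  se <- sqrt(fit$vcov[j, j])
  bound <- function(dir) {
    step <- se
    lo <- hat
    for (k in 1:40) {
      cand <- hat + dir * step
      if (prof(cand) < 0)
        return(uniroot(prof, sort(c(lo, cand)), tol = 1e-6)$root)
      lo <- cand
      step <- step * 1.6
    }
    dir * Inf
  }
  c(lower = bound(-1), upper = bound(1))
}

.designMatrix <- function(carrier, covariates) {
  carrier <- as.numeric(carrier)
  X <- cbind(`(Intercept)` = 1, carrier = carrier)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    M <- as.matrix(data.matrix(covariates))
    colnames(M) <- colnames(covariates)
    X <- cbind(X, M)
  }
  X
}

#' Linear carrier burden regression
#'
#' Ordinary least squares of a continuous trait on the carrier indicator,
#' adjusted for covariates (typically age, sex and 10 principal components),
#' with a two-sided Wald p-value for the carrier term. Triglycerides and BMI
#' are conventionally analyzed on the log scale (\code{logScale = TRUE}),
#' which is recorded in the estimate's note.
#'
#' @param carrier logical/0-1 carrier indicator.
#' @param phenotype continuous trait.
#' @param covariates data.frame/matrix of adjustment covariates (optional).
#' @param logScale analyze \code{log(phenotype)}.
#' @param level confidence level.
#' @return an \linkS4class{EffectEstimate} (method "ols").
#' @export
fitLinearBurden <- function(carrier, phenotype, covariates = NULL,
                            logScale = FALSE, level = 0.95) {
  keep <- !is.na(carrier) & !is.na(phenotype)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  carrier <- as.numeric(carrier[keep])
  y <- phenotype[keep]
  if (logScale) y <- log(y)
  covs <- if (!is.null(covariates)) as.data.frame(covariates)[keep, , drop = FALSE]
  nc <- sum(carrier > 0)
  if (nc == 0L || nc == length(carrier))
    stop("carrier indicator is constant: need both carriers and non-carriers")
  X <- .designMatrix(carrier, covs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design: collinear covariates")
  rdf <- length(y) - ncol(X)
  if (rdf < 1L)
    stop("too few observations for the design: ", length(y),
         " rows, ", ncol(X), " coefficients")
  fit <- lm.fit(X, y)
  sigma2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  b <- fit$coefficients["carrier"]
  s <- se[which(colnames(X) == "carrier")]
  tval <- b / s
  pval <- 2 * stats::pt(-abs(tval), df = rdf)
  z <- stats::qt(1 - (1 - level) / 2, df = rdf)
  new("EffectEstimate", beta = unname(b), se = unname(s),
      p = unname(pval), ciLower = unname(b - z * s),
      ciUpper = unname(b + z * s), nCarriers = as.integer(nc),
      nTotal = length(y),
      covariates = if (is.null(covs)) character() else colnames(covs),
      method = "ols", note = if (logScale) "log-scale analysis" else "")
}

#' Firth penalized logistic carrier burden regression
#'
#' Logistic regression of a binary outcome on the carrier indicator plus
#' covariates, maximizing the Jeffreys-penalized likelihood
#' \code{l(beta) + 0.5 * log det I(beta)}. Estimates remain finite under
#' complete separation, the regime of rare fully penetrant variants. The
#' confidence interval for the carrier log-odds is computed from the profile
#' penalized likelihood (preferable to Wald at small carrier counts); the
#' p-value is the penalized likelihood-ratio test of the carrier term.
#'
#' @inheritParams fitLinearBurden
#' @param outcome binary (logical/0-1) outcome.
#' @param maxit,tol Newton iteration cap and relative penalized-likelihood
#'   convergence tolerance (step-halving on overshoot).
#' @param ci "profile" (default; profile penalized likelihood) or "wald"
#'   (faster, adequate away from separation).
#' @return an \linkS4class{EffectEstimate} (method "firth"; beta and CI on
#'   the log-odds scale).
#' @examples
#' # a separated 2x2 table: carriers 5 cases / 0 controls
#' y <- rep(c(1, 0, 1, 0), c(5, 0, 5, 45))
#' carrier <- rep(c(1, 0), c(5, 50))
#' exp(effectSize(fitFirthLogistic(carrier, y)))  # odds ratio 91
#' @export
fitFirthLogistic <- function(carrier, outcome, covariates = NULL,
                             level = 0.95, maxit = 50L, tol = 1e-8,
                             ci = c("profile", "wald")) {
  ci <- match.arg(ci)
  keep <- !is.na(carrier) & !is.na(outcome)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  carrier <- as.numeric(carrier[keep])
  y <- as.numeric(outcome[keep])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  covs <- if (!is.null(covariates)) as.data.frame(covariates)[keep, , drop = FALSE]
  nc <- sum(carrier > 0)
  if (nc == 0L || nc == length(carrier))
    stop("carrier indicator is constant: need both carriers and non-carriers")
  X <- .designMatrix(carrier, covs)
  fit <- .firthCore(X, y, maxit = maxit, tol = tol)
  if (!fit$converged)
    stop(sprintf(
      "Firth logistic regression did not converge after %d iterations (pll %.6g)",
      fit$iterations, drop(fit$pll)))
  j <- which(colnames(X) == "carrier")
  b <- fit$beta[j]
  se <- sqrt(fit$vcov[j, j])
  # penalized likelihood-ratio p for the carrier term
  fit0 <- .firthCore(X, y, beta = replace(fit$beta, j, 0), fixed = j,
                     maxit = maxit, tol = tol)
  lrt <- 2 * (drop(fit$pll) - drop(fit0$pll))
  pval <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  bounds <- if (ci == "profile") .firthProfileCI(X, y, fit, j, level)
            else c(lower = b - z * se, upper = b + z * se)
  new("EffectEstimate", beta = unname(b), se = unname(se),
      p = max(min(unname(pval), 1), .Machine$double.xmin),
      ciLower = unname(bounds["lower"]), ciUpper = unname(bounds["upper"]),
      nCarriers = as.integer(nc), nTotal = length(y),
      covariates = if (is.null(covs)) character() else colnames(covs),
      method = "firth",
      note = if (ci == "profile") "profile penalized-likelihood CI"
             else "Wald CI")
}

#' Per-gene and composite burden estimates for a condition
#'
#' Fits the carrier burden model for every gene of a panel and for the
#' composite carrier set (the union of per-gene carriers; individuals
#' carrying variants in several panel genes count once).
#'
#' @param geneCarriers logical matrix individuals x genes (TRUE = carrier of
#'   a qualifying variant in that gene).
#' @param phenotype trait (continuous) or binary outcome.
#' @param covariates adjustment covariates.
#' @param binary use Firth logistic instead of linear regression.
#' @param logScale for continuous traits, analyze on the log scale.
#' @param minCarriers genes with fewer carriers are skipped.
#' @return named list of \linkS4class{EffectEstimate} ("composite" plus one
#'   per gene); genes without carriers are skipped with a warning, as is an
#'   empty composite.
#' @export
compositeBurden <- function(geneCarriers, phenotype, covariates = NULL,
                            binary = FALSE, logScale = FALSE,
                            minCarriers = 1L) {
  fitOne <- function(flags, label) {
    if (sum(flags, na.rm = TRUE) < minCarriers) {
      warning("no carriers for ", label, "; skipped")
      return(NULL)
    }
    if (binary) fitFirthLogistic(flags, phenotype, covariates)
    else fitLinearBurden(flags, phenotype, covariates, logScale = logScale)
  }
  composite <- rowSums(geneCarriers, na.rm = TRUE) > 0
  out <- list(composite = fitOne(composite, "composite"))
  for (g in colnames(geneCarriers))
    out[[g]] <- fitOne(geneCarriers[, g], g)
  Filter(Negate(is.null), out)
}

#' Tabulate effect estimates in reporting form
#'
#' Flattens a list of \linkS4class{EffectEstimate} into a results table with
#' one row per gene/composite: carrier count, beta (or odds ratio for
#' logistic fits), standard error or CI, and p-value.
#'
#' @param estimates named list of \linkS4class{EffectEstimate}.
#' @param condition condition label for the output rows.
#' @return data.frame with columns condition, gene, n_carrier, beta, se,
#'   or_, or_lower, or_upper, p, method.
#' @export
effectTable <- function(estimates, condition = NA_character_) {
  rows <- lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    logistic <- e@method == "firth"
    data.frame(condition = condition, gene = nm,
               n_carrier = e@nCarriers,
               beta = if (logistic) NA_real_ else e@beta,
               se = if (logistic) NA_real_ else e@se,
               or_ = if (logistic) exp(e@beta) else NA_real_,
               or_lower = if (logistic) exp(e@ciLower) else NA_real_,
               or_upper = if (logistic) exp(e@ciUpper) else NA_real_,
               p = e@p, method = e@method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
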