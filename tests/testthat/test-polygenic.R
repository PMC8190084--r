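# ---- score arithmetic ------------------------------------------------------

test_that("computePgs is a weighted dosage sum with z-standardization", {
  dos <- matrix(c(0, 1, 2, 2, 0, 1), 3, 2,
                dimnames = list(c("a", "b", "c"), c("v1", "v2")))
  w <- data.frame(variant_id = c("v1", "v2"), effect_allele = "G",
                  weight = c(0.5, -0.2))
  s <- computePgs(dos, w)
  expect_equal(s$raw, c(0 * 0.5 + 2 * -0.2, 1 * 0.5 + 0 * -0.2,
                        2 * 0.5 + 1 * -0.2))
  expect_equal(mean(s$z), 0, tolerance = 1e-10)
  expect_equal(sd(s$z), 1, tolerance = 1e-10)
  expect_identical(s$id, c("a", "b", "c"))
  expect_true(all(s$percentile %in% 1:100))
})

test_that("allele flips are reconciled by counting the complement dosage", {
  set.seed(5)
  panel <- simulateSnpPanel(400, nSnps = 50, seed = 5)
  sc <- computePgs(panel$dosages, panel$weights, panel$info)
  # flip the effect allele of half the weights to the ref allele and negate
  # the weight: the score must be unchanged up to a constant, so z identical
  wFlip <- panel$weights
  idx <- seq(1, 50, by = 2)
  wFlip$effect_allele[idx] <- "A"
  wFlip$weight[idx] <- -wFlip$weight[idx]
  scFlip <- computePgs(panel$dosages, wFlip, panel$info)
  expect_equal(scFlip$z, sc$z, tolerance = 1e-10)
  # weights whose effect allele matches neither strand are dropped
  wBad <- panel$weights
  wBad$effect_allele[1] <- "T"
  expect_silent(computePgs(panel$dosages, wBad, panel$info))
})

test_that("missing dosages are mean-imputed per variant", {
  set.seed(9)
  panel <- simulateSnpPanel(500, nSnps = 20, seed = 9, missingRate = 0.1)
  expect_true(anyNA(panel$dosages))
  s <- computePgs(panel$dosages, panel$weights, panel$info)
  expect_false(anyNA(s$raw))
  # reproduce the imputation by hand and compare raw scores exactly
  mu <- colMeans(panel$dosages, na.rm = TRUE)
  idx <- which(is.na(panel$dosages), arr.ind = TRUE)
  full <- panel$dosages
  full[idx] <- mu[idx[, 2]]
  expect_equal(s$raw, drop(full %*% panel$weights$weight), tolerance = 1e-12)
})

test_that("orientation -1 inverts the score and no overlap errors", {
  panel <- simulateSnpPanel(100, nSnps = 10, seed = 2)
  a <- computePgs(panel$dosages, panel$weights, panel$info)
  b <- computePgs(panel$dosages, panel$weights, panel$info, orientation = -1)
  expect_equal(b$z, -a$z)
  w2 <- panel$weights
  w2$variant_id <- paste0("other", seq_len(nrow(w2)))
  expect_error(computePgs(panel$dosages, w2), "no overlap")
})

# ---- tail contrasts --------------------------------------------------------

test_that("top-1% tail carries the expected truncated-normal trait excess", {
  set.seed(13)
  n <- 60000
  h2 <- 0.16; sdv <- 15
  z <- rnorm(n)
  y <- 52 + sqrt(h2) * sdv * z + sqrt(1 - h2) * sdv * rnorm(n)
  d <- data.frame(z = z, y = y, age = runif(n, 40, 75))
  ct <- contrastTopTail(d, "y", tail = 0.01, ageMin = NULL)
  est <- ct$tailVsReference
  # oracle: E[shift | top 1%] minus E[shift | IQR] of a standard normal
  tailMean <- dnorm(qnorm(0.99)) / 0.01
  iqrMean <- (dnorm(qnorm(0.25)) - dnorm(qnorm(0.75))) / 0.5  # = 0 by symmetry
  oracle <- sqrt(h2) * sdv * (tailMean - iqrMean)
  expect_lt(abs(effectSize(est) - oracle), 3 * stdError(est))
  expect_lt(pValue(est), 1e-10)
})

test_that("carrier-vs-tail contrast and age restriction behave", {
  cfg <- oneConditionConfig(40000, seed = 43, beta = 55, freq = 8e-3)
  ph <- phenotypes(simulateCohort(cfg))
  ph$z <- (ph$pgs_ldl - mean(ph$pgs_ldl)) / sd(ph$pgs_ldl)
  ct <- contrastTopTail(ph, "ldl_raw", covNames, tail = 0.01, ageMin = 60,
                        carrier = ph$carrier_test_cond)
  expect_true(all(ph$age[ph$age >= 60] >= 60))  # sanity on the filter input
  # carriers (+55) exceed the top-1% polygenic tail (~ +15) on average
  expect_gt(effectSize(ct$carrierVsTail), 0)
  expect_lt(pValue(ct$carrierVsTail), 0.01)
  expect_error(contrastTopTail(data.frame(y = 1), "y"), "z")
  ph2 <- ph; ph2$age <- 20
  expect_error(contrastTopTail(ph2, "ldl_raw", ageMin = 60), "age filter")
})

test_that("carrier-only gePS regression recovers the per-SD slope", {
  set.seed(17)
  n <- 400
  d <- data.frame(z = rnorm(n), age = runif(n, 40, 75))
  d$y <- 180 + 8 * d$z + 0.2 * d$age + rnorm(n, 0, 20)
  est <- carrierGepsRegression(d, "y", "age")
  expect_lt(abs(effectSize(est) - 8), 2.5 * stdError(est))
  # null: slope indistinguishable from zero
  d$y0 <- rnorm(n, 180, 20)
  est0 <- carrierGepsRegression(d, "y0", "age")
  expect_gt(pValue(est0), 0.001)
  expect_error(carrierGepsRegression(d[1:5, ], "y"), "fewer than")
})

test_that("interaction test finds a planted carrier x score interaction", {
  set.seed(19)
  n <- 6000
  carrier <- rbinom(n, 1, 0.05)
  d <- data.frame(z = rnorm(n))
  d$y <- 100 + 20 * carrier + 5 * d$z + 6 * carrier * d$z + rnorm(n, 0, 10)
  est <- interactionTest(d, carrier, "y")
  expect_lt(abs(effectSize(est) - 6), 3 * stdError(est))
  expect_lt(pValue(est), 1e-4)
  # no interaction planted: non-significant
  d$y0 <- 100 + 20 * carrier + 5 * d$z + rnorm(n, 0, 10)
  est0 <- interactionTest(d, carrier, "y0")
  expect_gt(pValue(est0), 0.001)
  expect_error(interactionTest(d, rep(0, n), "y"), "both carriers")
})

# ---- equivalent tail fraction ----------------------------------------------

test_that("equivalentTailFraction inverts the truncated-normal tail mean", {
  # frozen bisection oracle for h2 = 0.1572, sd = 15, shift = 16.8
  res <- equivalentTailFraction(0.1572, 15, 16.8)
  expect_equal(res$q, 0.006169733, tolerance = 1e-5)
  expect_equal(res$impliedTailMean, 16.8, tolerance = 1e-6)
  expect_equal(res$zThreshold, qnorm(1 - res$q), tolerance = 1e-10)
  # identity: target equal to the q = 0.5 tail mean returns q = 0.5
  shift50 <- sqrt(0.25) * 10 * dnorm(qnorm(0.5)) / 0.5
  expect_equal(equivalentTailFraction(0.25, 10, shift50)$q, 0.5,
               tolerance = 1e-8)
})

test_that("equivalentTailFraction is monotone and rejects unattainable shifts", {
  qs <- vapply(c(5, 10, 16.8, 25), function(s)
    equivalentTailFraction(0.1572, 15, s)$q, numeric(1))
  expect_true(all(diff(qs) < 0))  # larger shifts need more extreme tails
  q2 <- equivalentTailFraction(0.3, 15, 16.8)$q
  expect_gt(q2, qs[3])            # more informative score: milder tail
  expect_error(equivalentTailFraction(0.1572, 15, 1e6), "unattainable")
  expect_error(equivalentTailFraction(0, 15, 10))
  expect_error(equivalentTailFraction(0.2, 15, -1), "positive")
})

# ---- power planning --------------------------------------------------------

test_that("nForCorrelation reproduces the Fisher-z sample sizes", {
  expect_identical(nForCorrelation(0.25, 0.8, 0.05, "one"), 98L)
  expect_identical(nForCorrelation(0.25, 0.8, 0.05, "two"), 124L)
  # closed form check
  manual <- ceiling(((qnorm(0.95) + qnorm(0.8)) / atanh(0.25))^2 + 3)
  expect_identical(nForCorrelation(0.25), as.integer(manual))
  # the exact-t oracle for r = 0.25 / 80% power is n = 120 two-sided; the
  # Fisher-z approximation is deliberately conservative (124 >= 120)
  expect_gte(nForCorrelation(0.25, 0.8, 0.05, "two"), 120L)
  # monotonicity: stronger correlations need fewer carriers
  ns <- vapply(c(0.1, 0.25, 0.5, 0.9), nForCorrelation, integer(1))
  expect_true(all(diff(ns) < 0))
  expect_gte(nForCorrelation(0.999), 4L)  # floor from the +3 term
  expect_error(nForCorrelation(0), "in \\(0, 1\\)")
  expect_error(nForCorrelation(1.2), "in \\(0, 1\\)")
})

test_that("requiredCohortSize scales carriers by prevalence", {
  expect_identical(requiredCohortSize(98, 1e-4), 980000L)
  expect_identical(requiredCohortSize(10, 0.5), 20L)
  expect_error(requiredCohortSize(10, 0), "prevalence")
  expect_error(requiredCohortSize(10, 1.5), "prevalence")
})
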