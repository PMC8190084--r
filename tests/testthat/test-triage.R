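# ---- genotype-level QC -----------------------------------------------------

test_that("filterGenotype applies GQ, DP and het allele-balance rules", {
  expect_false(filterGenotype("het", 60, 20, adRef = 17, adAlt = 3))  # bal .15
  expect_true(filterGenotype("het", 60, 20, adRef = 14, adAlt = 6))   # bal .30
  expect_false(filterGenotype("het", 60, 20, adRef = 15, adAlt = 5))  # .25 strict
  expect_true(filterGenotype("hom_alt", 60, 20, adRef = 0, adAlt = 20))
  expect_true(filterGenotype("hom_ref", 60, 20, adRef = 20, adAlt = 0))
  expect_false(filterGenotype("het", 19, 20, adRef = 10, adAlt = 10))
  expect_true(filterGenotype("het", 20, 10, adRef = 10, adAlt = 10))  # inclusive
  expect_false(filterGenotype("het", 60, 9, adRef = 5, adAlt = 4))
  expect_false(filterGenotype("missing", 60, 20, adRef = 10, adAlt = 10))
  # zero covering reads on a het fails without erroring
  expect_false(filterGenotype("het", 60, 20, adRef = 0, adAlt = 0))
  # balance is symmetric in which allele is rarer
  expect_identical(filterGenotype("het", 60, 20, adRef = 3, adAlt = 17),
                   filterGenotype("het", 60, 20, adRef = 17, adAlt = 3))
  # vectorized
  expect_identical(
    filterGenotype(c("het", "hom_alt"), c(60, 60), c(20, 20),
                   adRef = c(17, 0), adAlt = c(3, 20)),
    c(FALSE, TRUE))
})

# ---- lab registry ----------------------------------------------------------

test_that("buildLabRegistry applies size, recency and exclusion rules", {
  labs <- data.frame(
    lab = c("Invitae", "GeneDx", "SmallLab", "StaleLab", "Counsyl",
            "EdgeLab", "JustOver"),
    n_submissions = c(120000L, 100000L, 500L, 20000L, 30000L, 15000L, 15001L),
    last_update = c("2019-03-01", "2019-02-01", "2018-06-01", "2016-11-01",
                    "2019-01-15", "2018-01-01", "2018-01-01"),
    stringsAsFactors = FALSE)
  reg <- buildLabRegistry(labs)
  expect_setequal(reg, c("Invitae", "GeneDx", "JustOver"))
  # exactly 15,000 submissions does not qualify (strictly greater than)
  expect_false("EdgeLab" %in% reg)
  # the update-date rule is boundary inclusive
  labs2 <- data.frame(lab = "Boundary", n_submissions = 20000L,
                      last_update = "2017-01-01", stringsAsFactors = FALSE)
  expect_identical(buildLabRegistry(labs2), "Boundary")
  expect_warning(empty <- buildLabRegistry(labs[0, ]), "empty")
  expect_identical(empty, character())
})

# ---- adjusted allele frequency ---------------------------------------------

test_that("adjustedAf subtracts cohort carriers with a floor at zero", {
  expect_equal(adjustedAf(20, 5, 250000), 6e-05)
  expect_equal(adjustedAf(3, 10, 250000), 0)
  expect_equal(adjustedAf(0, 0, 250000), 0)
  expect_error(adjustedAf(5, 0, 0), "positive")
})

# ---- ClinVar triage --------------------------------------------------------

registry <- c("Invitae", "GeneDx")
clinVariant <- function(ac = 2L, an = 250000L)
  data.frame(gnomad_ac = ac, gnomad_an = an)
clinSub <- function(lab, sig, date)
  data.frame(lab = lab, significance = sig, date_reported = date,
             stringsAsFactors = FALSE)

test_that("a recent registry P/LP report is clinically significant", {
  td <- triageClinvar(clinVariant(), clinSub("Invitae", "P", "2018-05-01"),
                      registry, afCutoff = 5e-4)
  expect_identical(decision(td), "clinically_significant")
  expect_true(any(grepl("registry_P(Invitae, 2018-05-01)", evidence(td),
                        fixed = TRUE)))
  expect_true(any(grepl("adjusted_af_below_cutoff", evidence(td))))
  td2 <- triageClinvar(clinVariant(), clinSub("GeneDx", "LP", "2017-01-01"),
                       registry)
  expect_identical(decision(td2), "clinically_significant")
})

test_that("the frequency gate is evaluated before any assertion", {
  td <- triageClinvar(clinVariant(ac = 2500L),
                      clinSub("GeneDx", "P", "2019-01-02"),
                      registry, afCutoff = 5e-4)
  expect_identical(decision(td), "excluded")
  expect_match(evidence(td), "adjusted_af_above_cutoff")
  expect_false(any(grepl("registry_P", evidence(td))))
  # subtracting cohort carriers can bring a variant back under the gate
  td2 <- triageClinvar(clinVariant(ac = 150L),
                       clinSub("GeneDx", "P", "2019-01-02"),
                       registry, cohortCarrierCount = 100L, afCutoff = 5e-4)
  expect_identical(decision(td2), "clinically_significant")
})

test_that("stale, benign, conflicting and non-registry reports route correctly", {
  old <- triageClinvar(clinVariant(), clinSub("Invitae", "P", "2016-06-01"),
                       registry)
  expect_identical(decision(old), "manual_review")
  ben <- triageClinvar(clinVariant(), clinSub("Invitae", "B", "2018-03-03"),
                       registry)
  expect_identical(decision(ben), "excluded")
  expect_match(evidence(ben), "registry_B", all = FALSE)
  conf <- triageClinvar(clinVariant(),
                        rbind(clinSub("Invitae", "P", "2018-01-05"),
                              clinSub("GeneDx", "LB", "2018-07-20")),
                        registry)
  expect_identical(decision(conf), "manual_review")
  expect_identical(evidence(conf), "conflicting_registry_assertions")
  nonreg <- triageClinvar(clinVariant(),
                          clinSub("SmallLab", "P", "2018-09-09"), registry)
  expect_identical(decision(nonreg), "manual_review")
  none <- triageClinvar(clinVariant(), NULL, registry)
  expect_identical(decision(none), "manual_review")
})

# ---- pLoF rule engine ------------------------------------------------------

txA <- layoutATranscript()   # CDS 1800, last exon 1401-1800, penult 1101-1400
txB <- layoutBTranscript()   # CDS 1800, last exon 1101-1800

test_that("clean mid-gene truncations are LoF; non-HC calls are not LoF", {
  lc <- classifyPlof(variantAt(txA, 500L), txA)
  expect_identical(lofClass(lc), "LoF")
  expect_identical(evidence(lc), "loftee_high_confidence")
  non <- classifyPlof(variantAt(txA, 500L, consequence = "missense",
                                loftee = "none"), txA)
  expect_identical(lofClass(non), "not_LoF")
  expect_identical(evidence(non), "loftee_not_high_confidence")
})

test_that("NMD-escape region truncations are not LoF unless >25% of CDS is lost", {
  lastSmall <- classifyPlof(variantAt(txA, 1621L), txA)  # truncates 10%
  expect_identical(lofClass(lastSmall), "not_LoF")
  expect_match(evidence(lastSmall), "nmd_escape_last_exon", all = FALSE)

  penult <- classifyPlof(variantAt(txA, 1381L), txA)     # truncates 23.3%
  expect_identical(lofClass(penult), "not_LoF")
  expect_match(evidence(penult), "nmd_escape_penultimate_exon_tail",
               all = FALSE)
  # 50-base tail boundary: position 1350 is outside the tail, 1351 inside
  expect_identical(lofClass(classifyPlof(variantAt(txA, 1350L), txA)), "LoF")
  expect_identical(lofClass(classifyPlof(variantAt(txA, 1351L), txA)),
                   "not_LoF")

  big <- classifyPlof(variantAt(txB, 1261L), txB)        # truncates 30%
  expect_identical(lofClass(big), "LoF")
  expect_match(evidence(big), "nmd_escape_overridden_truncates_30.0_pct",
               all = FALSE, fixed = TRUE)
  # exactly 25% does not trigger the override (strictly greater than)
  expect_identical(lofClass(classifyPlof(variantAt(txB, 1351L), txB)),
                   "not_LoF")
  expect_identical(lofClass(classifyPlof(variantAt(txB, 1350L), txB)), "LoF")
})

test_that("splice rescue distances map to the documented classes", {
  sp <- function(d, validated = FALSE)
    lofClass(classifyPlof(variantAt(txA, 400L, consequence = "splice_donor",
                                    spliceDist = d,
                                    spliceValidated = validated), txA))
  expect_identical(sp(4L), "likely_not_LoF")
  expect_identical(sp(6L), "likely_not_LoF")      # boundary inclusive
  expect_identical(sp(7L), "uncertain")
  expect_identical(sp(7L, validated = TRUE), "likely_not_LoF")
  expect_identical(sp(21L), "uncertain")
  expect_identical(sp(21L, validated = TRUE), "likely_not_LoF")
  expect_identical(sp(22L), "LoF")                # no rescue site near enough
  expect_identical(sp(NA_integer_), "LoF")
  ev <- evidence(classifyPlof(variantAt(txA, 400L,
                                        consequence = "splice_acceptor",
                                        spliceDist = 15L), txA))
  expect_match(ev, "possible_splice_rescue_6_21bp_unvalidated", all = FALSE)
})

test_that("pext and quality-flag downgrades stack one class each", {
  expect_identical(lofClass(classifyPlof(variantAt(txA, 500L, pext = 0.05),
                                         txA)), "likely_LoF")
  expect_identical(lofClass(classifyPlof(variantAt(txA, 500L, flag = TRUE),
                                         txA)), "likely_LoF")
  expect_identical(
    lofClass(classifyPlof(variantAt(txA, 500L, blacklisted = TRUE), txA)),
    "likely_LoF")
  both <- classifyPlof(variantAt(txA, 500L, pext = 0.05, flag = TRUE), txA)
  expect_identical(lofClass(both), "uncertain")
  # missing pext skips the rule with an evidence note instead of downgrading
  miss <- classifyPlof(variantAt(txA, 500L, pext = NA_real_), txA)
  expect_identical(lofClass(miss), "LoF")
  expect_match(evidence(miss), "pext_missing_rule_skipped", all = FALSE)
  # threshold is strict: pext exactly at the threshold is not low
  expect_identical(lofClass(classifyPlof(variantAt(txA, 500L, pext = 0.2),
                                         txA)), "LoF")
  # downgrades floor at not_LoF rather than wrapping
  floorCase <- classifyPlof(variantAt(txA, 1621L, pext = 0.05, flag = TRUE),
                            txA)
  expect_identical(lofClass(floorCase), "not_LoF")
})

test_that("the engine is pure and monotone in truncation position", {
  v <- variantAt(txA, 1381L, pext = 0.1)
  a <- classifyPlof(v, txA); b <- classifyPlof(v, txA)
  expect_identical(lofClass(a), lofClass(b))
  expect_identical(evidence(a), evidence(b))
  # moving a truncation 3'-ward (weaker evidence) never upgrades toward LoF
  ranks <- vapply(seq(1101L, 1800L, by = 25L), function(p)
    lofRank(lofClass(classifyPlof(variantAt(txB, p), txB))), integer(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("minus-strand coordinates classify identically", {
  w <- c(400L, 350L, 350L, 300L, 400L)
  starts <- c(9000L, 8000L, 7000L, 6000L, 5000L)
  txM <- transcriptModel("GENEM", "-", starts, starts + w - 1L)
  expect_identical(lofClass(classifyPlof(variantAt(txM, 500L), txM)), "LoF")
  expect_identical(lofClass(classifyPlof(variantAt(txM, 1381L), txM)),
                   "not_LoF")
  expect_identical(lofClass(classifyPlof(variantAt(txM, 1621L), txM)),
                   "not_LoF")
  expect_error(classifyPlof(variantAt(txM, 500L)[, ], txA), "outside")
})

# ---- sidecar triage and carrier flags --------------------------------------

test_that("triaged fixture variants land in the documented branches", {
  cfg <- simulationConfig(500, seed = 3)
  fix <- simulateVariantAnnotations(cfg)
  reg <- buildLabRegistry(fix$labSummary)
  expect_setequal(reg, c("Invitae", "GeneDx"))
  tri <- triageVariants(fix$variants, fix$transcripts, fix$clinvar, reg,
                        afCutoffs = 5e-4)
  pick <- function(role) tri[tri$role == role, ]
  expect_true(all(pick("stop_mid")$decision == "clinically_significant"))
  expect_true(all(pick("stop_mid")$lof_class == "LoF"))
  expect_true(all(pick("stop_last_exon_small")$lof_class == "not_LoF"))
  expect_true(all(pick("stop_last_exon_big")$lof_class == "LoF"))
  expect_true(all(pick("stop_penult_tail")$lof_class == "not_LoF"))
  expect_true(all(pick("splice_near")$lof_class == "likely_not_LoF"))
  expect_true(all(pick("splice_mid")$lof_class == "uncertain"))
  expect_true(all(pick("stop_low_pext")$lof_class == "likely_LoF"))
  expect_true(all(pick("frameshift_flagged")$lof_class == "likely_LoF"))
  expect_true(all(pick("missense_path")$decision == "clinically_significant"))
  expect_true(all(pick("missense_old")$decision == "manual_review"))
  expect_true(all(pick("missense_benign")$decision == "excluded"))
  expect_true(all(pick("missense_conflict")$decision == "manual_review"))
  expect_true(all(pick("missense_common")$decision == "excluded"))
  expect_true(all(grepl("adjusted_af_above_cutoff",
                        pick("missense_common")$triage_evidence)))
  expect_true(all(pick("missense_nonregistry")$decision == "manual_review"))
  expect_true(all(tri$lof_class[tri$consequence == "missense"] == "not_LoF"))
})

test_that("carrierMatrix recovers exactly the planted carriers", {
  cfg <- simulationConfig(4000, seed = 17)
  coh <- simulateCohort(cfg)
  fix <- simulateVariantAnnotations(cfg)
  reg <- buildLabRegistry(fix$labSummary)
  counts <- colSums(genotypes(coh) > 0L)
  tri <- triageVariants(variantAnnotations(coh), transcriptModels(coh),
                        clinvarRecords(coh), reg, counts, afCutoffs = 5e-4)
  cm <- carrierMatrix(tri, genotypes(coh), defaultGeneSets())
  ph <- phenotypes(coh)
  for (cond in colnames(cm))
    expect_identical(unname(cm[, cond]), ph[[paste0("carrier_", cond)]])
})

test_that("QC-failed genotypes and orphan genes are handled", {
  cfg <- simulationConfig(2000, seed = 23)
  coh <- simulateCohort(cfg)
  fix <- simulateVariantAnnotations(cfg)
  reg <- buildLabRegistry(fix$labSummary)
  tri <- triageVariants(variantAnnotations(coh), transcriptModels(coh),
                        clinvarRecords(coh), reg, afCutoffs = 5e-4)
  gs <- defaultGeneSets()
  cm <- carrierMatrix(tri, genotypes(coh), gs)
  carrierIdx <- which(cm[, "high_ldl"])
  expect_gt(length(carrierIdx), 0L)
  # fail every genotype of one carrier: they must drop out
  qc <- matrix(TRUE, nrow(genotypes(coh)), ncol(genotypes(coh)))
  qc[carrierIdx[1], ] <- FALSE
  cm2 <- carrierMatrix(tri, genotypes(coh), gs, qcPass = qc)
  expect_false(cm2[carrierIdx[1], "high_ldl"])
  expect_identical(cm2[-carrierIdx[1], ], cm[-carrierIdx[1], ])
  # genes assigned to no panel raise a warning and are excluded
  expect_warning(carrierMatrix(tri, genotypes(coh), gs["mody"]),
                 "outside every panel")
})
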