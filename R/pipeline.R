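#' Default rule configuration for the pipeline
#'
#' Packages the curation thresholds consumed by the triage stage. The pext
#' low-expression threshold and the per-condition allele-frequency cut-offs
#' are deliberately plain configuration values: set them to match your
#' expression annotation release and condition-specific frequency evidence.
#'
#' @param pextThreshold pext downgrade threshold.
#' @param afCutoffs named per-condition adjusted-allele-frequency cut-offs.
#' @param registryMinSubmissions,registryUpdatedSince,registryExclude lab
#'   registry criteria (see \code{\link{buildLabRegistry}}).
#' @param siteBlacklist variant ids excluded for genotyping quality.
#' @return list of class "ruleConfig".
#' @export
ruleConfig <- function(pextThreshold = 0.2,
                       afCutoffs = c(high_ldl = 5e-4, low_ldl = 5e-4,
                                     high_hdl = 5e-4, high_tg = 5e-4,
                                     obesity = 5e-4, mody = 5e-4),
                       registryMinSubmissions = 15000,
                       registryUpdatedSince = "2017-01-01",
                       registryExclude = "Counsyl",
                       siteBlacklist = character()) {
  structure(list(pextThreshold = pextThreshold, afCutoffs = afCutoffs,
                 registryMinSubmissions = registryMinSubmissions,
                 registryUpdatedSince = as.Date(registryUpdatedSince),
                 registryExclude = registryExclude,
                 siteBlacklist = siteBlacklist), class = "ruleConfig")
}

#' Gene panels per condition
#'
#' The default condition gene panels, including the five-gene MODY panel
#' most commonly offered in clinical testing (GCK, HNF1A, HNF1B, HNF4A,
#' PDX1); \code{extendedMody = TRUE} adds the research-extended genes
#' (AKT2, KLF11, APPL1, ABCC8, KCNJ11, NEUROD1, CEL, INS).
#'
#' @param extendedMody include the extended MODY gene list.
#' @return named list of character vectors.
#' @export
defaultGeneSets <- function(extendedMody = FALSE) {
  mody <- c("GCK", "HNF1A", "HNF1B", "HNF4A", "PDX1")
  if (extendedMody)
    mody <- c(mody, "AKT2", "KLF11", "APPL1", "ABCC8", "KCNJ11",
              "NEUROD1", "CEL", "INS")
  list(high_ldl = c("APOB", "LDLR"), low_ldl = c("APOB", "PCSK9"),
       high_hdl = "CETP", high_tg = c("APOA5", "LPL"), obesity = "MC4R",
       mody = mody)
}

.conditionTrait <- function(cond) {
  switch(cond, high_ldl = , low_ldl = "ldl_adj", high_hdl = "hdl",
         high_tg = "tg_adj", obesity = "bmi", mody = "diabetes",
         stop("unknown condition"))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate, triage, harmonize, associate, penetrance,
#' polygenic contrast and ascertainment with one configuration and one
#' master seed, writing per-stage tab-delimited outputs and a provenance
#' manifest (inputs, seed, per-file checksums, configuration hash) that
#' suffices to reproduce every table. Stage outputs are plain TSVs; a rerun
#' with the same configuration is bit-identical. On stage failure, a
#' partial manifest marking the completed stages is written before the
#' error propagates.
#'
#' @param simCfg a \linkS4class{SimulationConfig}.
#' @param rules a \code{\link{ruleConfig}}.
#' @param geneSets named list of condition gene panels.
#' @param outDir output directory (created if needed).
#' @param harmCfg a \code{\link{harmonizationConfig}}.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(simCfg, rules = ruleConfig(),
                        geneSets = defaultGeneSets(),
                        outDir, harmCfg = harmonizationConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  completed <- character()
  outputs <- character()
  results <- list()
  manifestPath <- file.path(outDir, "manifest.json")

  writeManifest <- function(status) {
    md5 <- if (length(outputs)) tools::md5sum(outputs)
           else setNames(character(), character())
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(list(
      seed = simCfg@seed, n_individuals = simCfg@nIndividuals,
      rules = unclass(rules)[c("pextThreshold", "registryMinSubmissions",
                               "registryExclude")],
      af_cutoffs = as.list(rules$afCutoffs),
      gene_sets = geneSets), cfgPath)
    jsonlite::write_json(list(
      status = status, seed = simCfg@seed, completed_stages = completed,
      config_md5 = unname(tools::md5sum(cfgPath)),
      outputs = as.list(setNames(unname(md5), basename(names(md5))))),
      manifestPath, auto_unbox = TRUE, pretty = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeManifest("failed")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    writeTsv(df, p)
    outputs <<- c(outputs, p)
  }

  ## simulate
  coh <- stage("simulate", simulateCohort(simCfg))
  results$cohort <- coh
  emit(phenotypes(coh), "phenotypes.tsv")
  emit(variantAnnotations(coh), "annotations.tsv")

  ## triage
  tri <- stage("triage", {
    fix <- simulateVariantAnnotations(simCfg)
    registry <- buildLabRegistry(fix$labSummary,
                                 rules$registryMinSubmissions,
                                 rules$registryUpdatedSince,
                                 rules$registryExclude)
    v <- variantAnnotations(coh)
    v$site_blacklisted <- v$site_blacklisted |
      v$variant_id %in% rules$siteBlacklist
    counts <- colSums(genotypes(coh) > 0L)
    triageVariants(v, transcriptModels(coh), clinvarRecords(coh), registry,
                   counts, rules$afCutoffs, rules$pextThreshold)
  })
  results$triage <- tri
  emit(tri, "triage_decisions.tsv")

  carriers <- stage("carriers",
                    carrierMatrix(tri, genotypes(coh), geneSets))
  results$carriers <- carriers

  ## harmonize
  ph <- stage("harmonize", harmonizeCohort(phenotypes(coh), harmCfg))
  results$harmonized <- ph
  emit(ph, "harmonized_phenotypes.tsv")

  covNames <- c("age", "sex", paste0("pc", 1:10))

  ## associate: Table-1-style per-condition burden
  assoc <- stage("associate", {
    rows <- list()
    for (cond in names(geneSets)) {
      flags <- carriers[, cond]
      if (sum(flags) == 0L) next
      binary <- cond == "mody"
      trait <- .conditionTrait(cond)
      y <- if (binary) ph$glycemia == "diabetes" else ph[[trait]]
      geneOf <- function(id) tri$gene[match(id, tri$variant_id)]
      qv <- tri$variant_id[(tri$decision == "clinically_significant" |
                              tri$lof_class %in% c("LoF", "likely_LoF")) &
                             tri$gene %in% geneSets[[cond]] &
                             tri$condition == cond]
      gmat <- vapply(geneSets[[cond]], function(g) {
        vs <- intersect(qv[geneOf(qv) == g], colnames(genotypes(coh)))
        if (!length(vs)) return(rep(FALSE, nrow(ph)))
        rowSums(genotypes(coh)[, vs, drop = FALSE] > 0L) > 0L
      }, logical(nrow(ph)))
      ests <- suppressWarnings(compositeBurden(
        gmat, y, ph[, covNames], binary = binary,
        logScale = trait %in% c("tg_adj", "bmi")))
      rows[[cond]] <- effectTable(ests, cond)
    }
    do.call(rbind, rows)
  })
  results$associations <- assoc
  emit(assoc, "burden_estimates.tsv")

  ## penetrance
  pen <- stage("penetrance", {
    rows <- list()
    for (cond in names(geneSets)) {
      flags <- carriers[, cond]
      if (sum(flags) == 0L) next
      if (cond == "mody") {
        rows[[paste0(cond, "_diab")]] <- suppressWarnings(penetranceTable(
          flags, ph$case_mody, condition = cond, outcome = "diabetes"))
        rows[[paste0(cond, "_any")]] <- suppressWarnings(penetranceTable(
          flags, ph$case_mody_any_dysglycemia, condition = cond,
          outcome = "diabetes_or_prediabetes"))
      } else {
        rows[[cond]] <- suppressWarnings(penetranceTable(
          flags, ph[[paste0("case_", cond)]], condition = cond,
          outcome = "clinical_cutoff"))
      }
    }
    do.call(rbind, rows)
  })
  results$penetrance <- pen
  emit(pen, "penetrance_estimates.tsv")

  ## polygenic: top-1% tail contrast per lipid condition + power planning
  pgs <- stage("polygenic", {
    rows <- list()
    for (cond in c("high_ldl", "high_hdl", "high_tg")) {
      trait <- .conditionTrait(cond)
      d <- ph
      d$z <- {
        p <- d[[paste0("pgs_", sub("_adj", "", trait))]]
        (p - mean(p)) / sd(p)
      }
      ct <- tryCatch(
        contrastTopTail(d, trait, covNames, tail = 0.01,
                        ageMin = 60, carrier = carriers[, cond]),
        error = function(e) NULL)
      if (is.null(ct)) next  # too few carriers in the age-restricted subset
      rows[[cond]] <- data.frame(
        condition = cond,
        tail_vs_iqr_beta = effectSize(ct$tailVsReference),
        tail_vs_iqr_p = pValue(ct$tailVsReference),
        carrier_vs_tail_beta = effectSize(ct$carrierVsTail),
        carrier_vs_tail_p = pValue(ct$carrierVsTail),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  results$pgsContrasts <- pgs
  emit(pgs, "pgs_contrasts.tsv")

  power <- stage("power", data.frame(
    r = 0.25, power = 0.8, alpha = 0.05, sided = "one",
    n_carriers = nForCorrelation(0.25, 0.8, 0.05, "one"),
    cohort_at_prevalence_1e4 =
      requiredCohortSize(nForCorrelation(0.25, 0.8, 0.05, "one"), 1e-4)))
  results$power <- power
  emit(power, "power_planning.tsv")

  ## ascertainment
  asc <- stage("ascertain", ascertainmentContrast(
    ph, carriers[, "high_ldl"], "ldl_raw",
    extremePhenotypeScheme("ldl_raw", 0.02, "upper")))
  results$ascertainment <- asc
  emit(asc, "ascertainment_contrast.tsv")

  writeManifest("complete")
  results$manifest <- jsonlite::read_json(manifestPath)
  invisible(results)
}
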