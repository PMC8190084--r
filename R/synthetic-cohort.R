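#' Construct a condition specification
#'
#' @param condition condition label.
#' @param genes character vector of panel genes.
#' @param carrierFrequency carrier probability, in (0, 0.01).
#' @param beta additive carrier effect: trait units for continuous traits,
#'   log-odds for binary ones.
#' @param trait proxy trait ("ldl", "hdl", "tg", "bmi", "diabetes").
#' @param binary whether the proxy trait is binary.
#' @param penetranceTarget optional expected penetrance, reporting only.
#' @return a \linkS4class{ConditionSpec}.
#' @examples
#' conditionSpec("high_hdl", "CETP", 5.2e-4, 16.8, "hdl")
#' @export
conditionSpec <- function(condition, genes, carrierFrequency, beta, trait,
                          binary = identical(trait, "diabetes"),
                          penetranceTarget = NA_real_) {
  new("ConditionSpec", condition = condition, genes = genes,
      carrierFrequency = carrierFrequency, beta = beta, trait = trait,
      binary = binary, penetranceTarget = penetranceTarget)
}

#' Default monogenic condition panels
#'
#' Six monogenic metabolic conditions with gene panels, carrier frequencies
#' and additive effects matching large published biobank estimates: high LDL
#' cholesterol (APOB/LDLR, +54.2 mg/dL), familial hypobetalipoproteinemia
#' (APOB/PCSK9, -56.4 mg/dL), high HDL cholesterol (CETP, +16.8 mg/dL), high
#' triglycerides (APOA5/LPL, +126 mg/dL), monogenic obesity (MC4R,
#' +2.2 kg/m2) and MODY (GCK/HNF1A/HNF1B/HNF4A/PDX1, odds ratio 21 for
#' diabetes). Carrier frequencies reproduce the published carrier counts in a
#' cohort of roughly 38,600 individuals.
#'
#' @return a named list of \linkS4class{ConditionSpec}.
#' @export
defaultConditions <- function() {
  specs <- list(
    conditionSpec("high_ldl", c("APOB", "LDLR"),  83 / 38566,  54.2, "ldl"),
    conditionSpec("low_ldl",  c("APOB", "PCSK9"), 90 / 38566, -56.4, "ldl"),
    conditionSpec("high_hdl", "CETP",             20 / 38566,  16.8, "hdl"),
    conditionSpec("high_tg",  c("APOA5", "LPL"),  54 / 38566, 126.0, "tg"),
    conditionSpec("obesity",  "MC4R",             31 / 38566,   2.2, "bmi"),
    conditionSpec("mody", c("GCK", "HNF1A", "HNF1B", "HNF4A", "PDX1"),
                  16 / 38566, log(21), "diabetes"))
  names(specs) <- vapply(specs, function(s) s@condition, character(1))
  specs
}

#' Construct a simulation configuration
#'
#' Defaults: heritabilities TG 0.1525, LDL 0.1347, HDL 0.1572 (LD-score
#' estimates used to train the polygenic scores) and BMI 0.2; trait means/sds
#' typical of a middle-aged cohort (LDL 130/33, HDL 52/15, TG 140/70 mg/dL,
#' BMI 27/4.5 kg/m2); lipid-lowering treatment probability logistic in raw
#' LDL; baseline diabetes prevalence 10%.
#'
#' @param nIndividuals cohort size.
#' @param seed master seed (integer); every random stream derives from it.
#' @param conditions list of \linkS4class{ConditionSpec}.
#' @param h2 named per-trait heritabilities, each in [0, 1).
#' @param traitMeans,traitSds named per-trait means and sds.
#' @param medIntercept,medSlope treatment model coefficients (logit scale;
#'   slope per 10 mg/dL of raw LDL above 160).
#' @param diabetesPrevalence baseline non-carrier diabetes prevalence.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(2000, seed = 1)
#' @export
simulationConfig <- function(nIndividuals = 20000L, seed = 1L,
                             conditions = defaultConditions(),
                             h2 = c(tg = 0.1525, ldl = 0.1347,
                                    hdl = 0.1572, bmi = 0.2),
                             traitMeans = c(ldl = 130, hdl = 52, tg = 140, bmi = 27),
                             traitSds = c(ldl = 33, hdl = 15, tg = 70, bmi = 4.5),
                             medIntercept = -1.5, medSlope = 0.8,
                             diabetesPrevalence = 0.10) {
  if (any(h2 >= 1)) stop("heritability must be < 1")
  new("SimulationConfig", nIndividuals = as.integer(nIndividuals),
      seed = as.integer(seed), conditions = unname(conditions), h2 = h2,
      traitMeans = traitMeans, traitSds = traitSds,
      medIntercept = medIntercept, medSlope = medSlope,
      diabetesPrevalence = diabetesPrevalence)
}

#' Construct a transcript model
#'
#' @param gene gene symbol.
#' @param strand "+" or "-".
#' @param exonStarts,exonEnds 1-based closed genomic coordinates of coding
#'   exons, ordered 5'-to-3' in transcript orientation (descending for minus
#'   strand).
#' @param cdsLength coding length in bases; defaults to the summed widths.
#' @return a \linkS4class{TranscriptModel}.
#' @export
transcriptModel <- function(gene, strand, exonStarts, exonEnds,
                            cdsLength = sum(exonEnds - exonStarts + 1L)) {
  new("TranscriptModel", gene = gene, strand = strand,
      exons = IRanges::IRanges(start = exonStarts, end = exonEnds),
      cdsLength = as.integer(cdsLength))
}

# Two coding layouts so the fixture suite can reach every rule branch: in a
# single transcript a last-exon stop truncating >25% of the CDS (layout B,
# last exon 700/1800) is incompatible with a penultimate-exon-tail stop
# truncating <=25% (layout A, last exon 400/1800).
.LAYOUTS <- list(A = c(400L, 350L, 350L, 300L, 400L),
                 B = c(300L, 300L, 300L, 200L, 700L))

.geneTranscript <- function(gene, idx) {
  layout <- if (idx %% 2L == 0L) "A" else "B"
  widths <- .LAYOUTS[[layout]]
  strand <- if (idx %% 3L == 0L) "-" else "+"
  base <- 100000L * idx
  starts <- base + cumsum(c(0L, head(widths, -1L) + 100L))
  ends <- starts + widths - 1L
  if (strand == "-") { o <- rev(seq_along(starts)); starts <- starts[o]; ends <- ends[o] }
  tx <- transcriptModel(gene, strand, starts, ends)
  attr(tx, "layout") <- layout
  tx
}

# Genomic position of a 1-based CDS coordinate.
.genomicPos <- function(tx, cdsPos) {
  w <- IRanges::width(tx@exons)
  cum <- cumsum(w)
  ex <- which(cdsPos <= cum)[1]
  if (is.na(ex)) stop("cds position beyond transcript")
  off <- cdsPos - c(0L, cum)[ex] - 1L
  if (tx@strand == "+") IRanges::start(tx@exons)[ex] + off
  else IRanges::end(tx@exons)[ex] - off
}

#' Generate variant fixtures, transcripts and ClinVar-style records
#'
#' Emits, for every gene of every condition, a suite of annotated variants
#' placed at controlled transcript positions so that each branch of the
#' loss-of-function and ClinVar triage rule engines is exercised: clean
#' mid-gene truncations, last-exon stops below and above the 25% truncation
#' override, penultimate-exon-tail stops, splice variants with in-frame
#' rescue sites at 4 bp and 15 bp, low-expression (pext) and gnomAD-flagged
#' variants, and ClinVar submissions from registry and non-registry labs with
#' report dates straddling 2017-01-01, including benign, conflicting and
#' too-common records.
#'
#' @param config a \linkS4class{SimulationConfig} (its conditions and seed
#'   are used), or a list of \linkS4class{ConditionSpec}.
#' @param seed seed used when \code{config} is a bare condition list.
#' @return list with elements \code{variants} (annotation sidecar
#'   data.frame), \code{transcripts} (named list of
#'   \linkS4class{TranscriptModel}), \code{clinvar} (submission records) and
#'   \code{labSummary} (per-lab totals and last-update dates).
#' @export
simulateVariantAnnotations <- function(config, seed = 1L) {
  conditions <- if (is(config, "SimulationConfig")) config@conditions else config
  if (is(config, "SimulationConfig")) seed <- config@seed
  genes <- unique(unlist(lapply(conditions, function(s) s@genes)))
  if (length(genes) == 0L) stop("gene set must be non-empty")
  geneCondition <- lapply(conditions, function(s) s@genes)
  names(geneCondition) <- vapply(conditions, function(s) s@condition, character(1))

  txs <- list()
  rows <- list(); subs <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    tx <- .geneTranscript(g, i)
    txs[[g]] <- tx
    layout <- attr(tx, "layout")
    conds <- names(geneCondition)[vapply(geneCondition, function(x) g %in% x, logical(1))]
    cond <- conds[1]
    chrom <- as.character(i)

    mk <- function(role, cdsPos, consequence, loftee = "HC", pext = 0.95,
                   ac = 2L, an = 250000L, flag = FALSE, blacklisted = FALSE,
                   spliceDist = NA_integer_, spliceValidated = FALSE,
                   qualifying = FALSE) {
      data.frame(variant_id = paste0(g, ":", role), chrom = chrom,
                 pos = .genomicPos(tx, cdsPos), ref = "C", alt = "T",
                 gene = g, condition = cond, consequence = consequence,
                 loftee = loftee, pext = pext, gnomad_ac = ac, gnomad_an = an,
                 gnomad_filter_flag = flag, site_blacklisted = blacklisted,
                 splice_inframe_distance = spliceDist,
                 splice_validated = spliceValidated, role = role,
                 qualifying = qualifying, stringsAsFactors = FALSE)
    }
    sub <- function(role, lab, significance, dateReported) {
      data.frame(variant_id = paste0(g, ":", role), lab = lab,
                 significance = significance, date_reported = dateReported,
                 phenotype = cond, stringsAsFactors = FALSE)
    }

    rows[[g]] <- rbind(
      mk("stop_mid", 500L, "stop_gained", qualifying = TRUE),
      mk("stop_last_exon_small", 1621L, "stop_gained"),
      if (layout == "B") mk("stop_last_exon_big", 1261L, "stop_gained",
                            qualifying = TRUE),
      if (layout == "A") mk("stop_penult_tail", 1381L, "stop_gained"),
      mk("splice_near", 400L, "splice_donor", spliceDist = 4L),
      mk("splice_mid", 400L, "splice_acceptor", spliceDist = 15L),
      mk("stop_low_pext", 520L, "stop_gained", pext = 0.05,
         qualifying = TRUE),
      mk("frameshift_flagged", 540L, "frameshift", flag = TRUE,
         qualifying = TRUE),
      mk("missense_path", 600L, "missense", loftee = "none", qualifying = TRUE),
      mk("missense_old", 620L, "missense", loftee = "none"),
      mk("missense_benign", 640L, "missense", loftee = "none"),
      mk("missense_conflict", 660L, "missense", loftee = "none"),
      mk("missense_common", 680L, "missense", loftee = "none",
         ac = 2500L),
      mk("missense_nonregistry", 700L, "missense", loftee = "none"))

    subs[[g]] <- rbind(
      sub("stop_mid", "Invitae", "P", "2018-05-01"),
      sub("missense_path", "GeneDx", "LP", "2018-02-10"),
      sub("missense_old", "Invitae", "P", "2016-06-01"),
      sub("missense_benign", "Invitae", "B", "2018-03-03"),
      sub("missense_conflict", "Invitae", "P", "2018-01-05"),
      sub("missense_conflict", "GeneDx", "LB", "2018-07-20"),
      sub("missense_common", "GeneDx", "P", "2019-01-02"),
      sub("missense_nonregistry", "SmallLab", "P", "2018-09-09"))
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  clinvar <- do.call(rbind, subs)
  rownames(clinvar) <- NULL
  labSummary <- data.frame(
    lab = c("Invitae", "GeneDx", "SmallLab", "StaleLab", "Counsyl"),
    n_submissions = c(120000L, 100000L, 500L, 20000L, 30000L),
    last_update = c("2019-03-01", "2019-02-01", "2018-06-01",
                    "2016-11-01", "2019-01-15"),
    stringsAsFactors = FALSE)
  list(variants = variants, transcripts = txs, clinvar = clinvar,
       labSummary = labSummary)
}

#' Simulate a biobank-style cohort
#'
#' Generates per-individual phenotypes under an additive model
#' \code{trait = mean + carrier * beta + polygenic + residual}, where the
#' polygenic component is a normal deviate with variance \code{h2 * sd^2} and
#' the residual has variance \code{(1 - h2) * sd^2}. Carriers are drawn
#' Bernoulli per condition and assigned a heterozygous genotype at one
#' qualifying variant fixture of the condition's gene panel. Diabetes follows
#' a logistic liability on age, sex, a diabetes polygenic score and the
#' carrier log-odds; glycemic biomarkers (HbA1c, fasting glucose, OGTT) are
#' generated consistently with diabetes status. Lipid-lowering treatment is
#' assigned by a logistic model in raw LDL, and observed LDL/TG of treated
#' individuals are masked by the usual statin factors (x0.7 LDL, x0.85 TG);
#' the unmasked values are retained in \code{ldl_raw}/\code{tg_raw}.
#' Individuals are aged 40-75 (younger individuals are excluded from the
#' target analyses). Output is deterministic given the configuration seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' coh <- simulateCohort(simulationConfig(2000, seed = 7))
#' coh
#' @export
simulateCohort <- function(config) {
  validObject(config)
  n <- config@nIndividuals
  notes <- character()
  fix <- simulateVariantAnnotations(config)

  set.seed(childSeed(config@seed, "cohort"))
  ph <- data.frame(id = sprintf("S%06d", seq_len(n)),
                   age = round(runif(n, 40, 75)),
                   sex = rbinom(n, 1L, 0.5), stringsAsFactors = FALSE)
  pcs <- matrix(rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("pc", 1:10)))
  ph <- cbind(ph, as.data.frame(pcs))

  conds <- config@conditions
  condNames <- vapply(conds, function(s) s@condition, character(1))
  carrier <- matrix(0L, n, length(conds), dimnames = list(NULL, condNames))
  for (j in seq_along(conds)) {
    carrier[, j] <- rbinom(n, 1L, conds[[j]]@carrierFrequency)
    if (sum(carrier[, j]) == 0L)
      notes <- c(notes, paste0("zero carriers drawn for ", condNames[j]))
  }

  # continuous traits: mean + carrier effects + polygenic + residual
  polyg <- list()
  for (tr in names(config@traitMeans)) {
    h2 <- unname(config@h2[tr]); if (is.na(h2)) h2 <- 0
    sdv <- unname(config@traitSds[tr])
    polyg[[tr]] <- rnorm(n, 0, sqrt(h2) * sdv)
    val <- config@traitMeans[tr] + polyg[[tr]] +
      rnorm(n, 0, sqrt(1 - h2) * sdv)
    for (j in seq_along(conds))
      if (!conds[[j]]@binary && conds[[j]]@trait == tr)
        val <- val + carrier[, j] * conds[[j]]@beta
    ph[[tr]] <- pmax(unname(val), 1)
  }

  # diabetes liability: age, sex, diabetes PGS, carrier log-odds
  zDiab <- rnorm(n)
  lin <- qlogis(config@diabetesPrevalence) + 0.35 * (ph$age - 57.5) / 10 +
    0.25 * ph$sex + 0.45 * zDiab
  for (j in seq_along(conds))
    if (conds[[j]]@binary) lin <- lin + carrier[, j] * conds[[j]]@beta
  diab <- rbinom(n, 1L, plogis(lin))

  # glycemic biomarkers consistent with status after harmonization
  hba1c <- ifelse(diab == 1L,
                  pmin(6.5 + abs(rnorm(n, 0, 0.8)), 12),
                  pmin(pmax(5.35 + 0.2 * zDiab + rnorm(n, 0, 0.3), 4.5), 6.45))
  fg <- ifelse(diab == 1L,
               pmin(pmax(135 + rnorm(n, 0, 20), 100), 300),
               pmin(pmax(88 + 5 * zDiab + rnorm(n, 0, 8), 60), 125))
  ogtt <- ifelse(runif(n) < 0.3,
                 ifelse(diab == 1L, pmax(rnorm(n, 220, 30), 140),
                        pmin(pmax(rnorm(n, 110, 20), 60), 199)),
                 NA_real_)
  ph$hba1c <- round(hba1c, 2)
  ph$fasting_glucose <- round(fg, 1)
  ph$ogtt_2h <- round(ogtt, 1)
  ph$diabetes_record_flag <- diab == 1L
  ph$diabetes <- diab == 1L
  ph$prediabetes <- !ph$diabetes &
    (ph$hba1c >= 5.7 | ph$fasting_glucose >= 100 |
       (!is.na(ph$ogtt_2h) & ph$ogtt_2h >= 140))
  ph$diab_pgs <- zDiab

  # treatment assignment and medication masking of observed lipids
  pTreat <- plogis(config@medIntercept + config@medSlope * (ph$ldl - 160) / 10)
  onMed <- rbinom(n, 1L, pTreat) == 1L
  ph$on_lipid_med <- onMed
  ph$ldl_raw <- ph$ldl
  ph$tg_raw <- ph$tg
  ph$ldl <- ifelse(onMed, ph$ldl * 0.7, ph$ldl)
  ph$tg <- ifelse(onMed, ph$tg * 0.85, ph$tg)

  for (j in seq_along(conds))
    ph[[paste0("carrier_", condNames[j])]] <- carrier[, j] == 1L
  for (tr in names(polyg)) ph[[paste0("pgs_", tr)]] <- polyg[[tr]]

  # genotypes: each planted carrier is heterozygous at one qualifying
  # fixture variant of the condition's panel (round-robin across them)
  geno <- matrix(0L, n, nrow(fix$variants),
                 dimnames = list(ph$id, fix$variants$variant_id))
  for (j in seq_along(conds)) {
    qv <- which(fix$variants$qualifying &
                  fix$variants$condition == condNames[j])
    ids <- which(carrier[, j] == 1L)
    if (length(ids) && length(qv))
      geno[cbind(ids, qv[(seq_along(ids) - 1L) %% length(qv) + 1L])] <- 1L
  }
  # a few carriers of non-qualifying fixtures (must never flag downstream)
  nq <- which(!fix$variants$qualifying)
  for (v in nq) geno[sample.int(n, min(3L, n)), v] <- 1L

  new("SyntheticCohort", phenotypes = ph, genotypes = geno,
      variants = fix$variants, clinvar = fix$clinvar,
      transcripts = fix$transcripts, config = config, notes = notes)
}

#' Simulate a small biallelic SNP panel with weights
#'
#' Independent Hardy-Weinberg SNPs with fixed allele frequencies, plus a
#' weight table, for testing polygenic-score arithmetic without genome-scale
#' data.
#'
#' @param n individuals.
#' @param nSnps panel size (<= 1000).
#' @param seed seed.
#' @param missingRate per-genotype missingness probability.
#' @return list with \code{dosages} (n x nSnps alt-allele dosage matrix, NA
#'   for missing), \code{info} (variant_id, ref, alt, maf) and \code{weights}
#'   (variant_id, effect_allele, weight; effect allele = alt).
#' @export
simulateSnpPanel <- function(n, nSnps = 500L, seed = 1L, missingRate = 0) {
  stopifnot(nSnps <= 1000L)
  set.seed(childSeed(seed, "snp_panel"))
  maf <- runif(nSnps, 0.05, 0.5)
  dos <- vapply(maf, function(p) rbinom(n, 2L, p), integer(n))
  if (missingRate > 0) dos[runif(length(dos)) < missingRate] <- NA_integer_
  ids <- sprintf("snp%04d", seq_len(nSnps))
  colnames(dos) <- ids
  info <- data.frame(variant_id = ids, ref = "A", alt = "G", maf = maf,
                     stringsAsFactors = FALSE)
  weights <- data.frame(variant_id = ids, effect_allele = "G",
                        weight = rnorm(nSnps, 0, 0.05),
                        stringsAsFactors = FALSE)
  list(dosages = dos, info = info, weights = weights)
}

#' Ascertainment schemes
#'
#' Constructors for the sampling schemes applied by
#' \code{\link{applyAscertainment}}: \code{populationScheme} keeps everyone;
#' \code{extremePhenotypeScheme} keeps individuals beyond an empirical tail
#' quantile of a trait (selection blind to carrier status);
#' \code{caseControlScheme} keeps cases of a binary outcome plus all
#' controls (flagging cases for downstream weighting).
#'
#' @param trait phenotype column selected on.
#' @param tail tail fraction in (0, 0.5).
#' @param side "upper", "lower" or "both".
#' @param outcome binary phenotype column.
#' @return a scheme object (list with class "ascertainmentScheme").
#' @name ascertainmentSchemes
NULL

#' @rdname ascertainmentSchemes
#' @export
populationScheme <- function() {
  structure(list(kind = "population"), class = "ascertainmentScheme")
}

#' @rdname ascertainmentSchemes
#' @export
extremePhenotypeScheme <- function(trait, tail = 0.02, side = c("upper", "lower", "both")) {
  side <- match.arg(side)
  if (tail <= 0 || tail >= 0.5) stop("tail fraction must lie in (0, 0.5)")
  structure(list(kind = "extreme_phenotype", trait = trait, tail = tail,
                 side = side), class = "ascertainmentScheme")
}

#' @rdname ascertainmentSchemes
#' @export
caseControlScheme <- function(outcome) {
  structure(list(kind = "case_control", outcome = outcome),
            class = "ascertainmentScheme")
}

#' Subsample a cohort under an ascertainment scheme
#'
#' @param cohort a \linkS4class{SyntheticCohort} or a phenotype data.frame.
#' @param scheme a scheme from \link{ascertainmentSchemes}.
#' @return object of the same type restricted to the selected individuals.
#'   The selection threshold(s) used are attached as attribute
#'   \code{"thresholds"}.
#' @export
applyAscertainment <- function(cohort, scheme) {
  stopifnot(inherits(scheme, "ascertainmentScheme"))
  ph <- if (is(cohort, "SyntheticCohort")) cohort@phenotypes else cohort
  thresholds <- NULL
  keep <- switch(scheme$kind,
    population = rep(TRUE, nrow(ph)),
    extreme_phenotype = {
      if (!scheme$trait %in% colnames(ph))
        stop("trait '", scheme$trait, "' absent from cohort")
      x <- ph[[scheme$trait]]
      hi <- quantile(x, 1 - scheme$tail, na.rm = TRUE, names = FALSE)
      lo <- quantile(x, scheme$tail, na.rm = TRUE, names = FALSE)
      thresholds <- switch(scheme$side, upper = c(upper = hi),
                           lower = c(lower = lo),
                           both = c(lower = lo, upper = hi))
      switch(scheme$side,
             upper = !is.na(x) & x >= hi,
             lower = !is.na(x) & x <= lo,
             both = !is.na(x) & (x >= hi | x <= lo))
    },
    case_control = {
      if (!scheme$outcome %in% colnames(ph))
        stop("outcome '", scheme$outcome, "' absent from cohort")
      !is.na(ph[[scheme$outcome]])
    },
    stop("unknown scheme"))
  out <- if (is(cohort, "SyntheticCohort")) {
    new("SyntheticCohort", phenotypes = ph[keep, , drop = FALSE],
        genotypes = cohort@genotypes[keep, , drop = FALSE],
        variants = cohort@variants, clinvar = cohort@clinvar,
        transcripts = cohort@transcripts, config = cohort@config,
        notes = cohort@notes)
  } else ph[keep, , drop = FALSE]
  attr(out, "thresholds") <- thresholds
  out
}

#' Write a synthetic cohort to standard file formats
#'
#' \code{writeCohortVcf} writes a VCF 4.2 with GT:GQ:DP:AD genotype fields
#' (a small fraction of non-reference genotypes receive failing quality
#' metrics so genotype-QC code paths can be exercised);
#' \code{writePhenotypeTable}, \code{writeAnnotationSidecar},
#' \code{writeClinVarSummary} and \code{writePgsWeights} write the
#' tab-delimited companions.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param path output file path.
#' @param failFraction fraction of non-reference genotypes given failing
#'   QC metrics.
#' @param seed seed for QC-metric generation.
#' @return the path, invisibly.
#' @name cohortWriters
NULL

#' @rdname cohortWriters
#' @export
writeCohortVcf <- function(cohort, path, failFraction = 0.02, seed = 1L) {
  ph <- cohort@phenotypes; gt <- cohort@genotypes; v <- cohort@variants
  set.seed(childSeed(seed, "vcf_qc"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ph$id), collapse = "\t")), con)
  n <- nrow(gt)
  for (j in seq_len(ncol(gt))) {
    d <- gt[, j]
    dp <- sample(20:60, n, replace = TRUE)
    gq <- sample(60:99, n, replace = TRUE)
    adAlt <- ifelse(d == 0L, 0L, ifelse(d == 2L, dp, round(dp * runif(n, 0.35, 0.65))))
    fail <- d > 0L & runif(n) < failFraction
    gq[fail] <- sample(0:19, sum(fail), replace = TRUE)
    gstr <- c("0/0", "0/1", "1/1")[d + 1L]
    fields <- paste0(gstr, ":", gq, ":", dp, ":", dp - adAlt, ",", adAlt)
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", "PASS", ".", "GT:GQ:DP:AD", fields),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname cohortWriters
#' @export
writePhenotypeTable <- function(cohort, path) {
  writeTsv(cohort@phenotypes, path)
}

#' @rdname cohortWriters
#' @export
writeAnnotationSidecar <- function(cohort, path) {
  writeTsv(cohort@variants, path)
}

#' @rdname cohortWriters
#' @param labSummaryPath optional path for the per-lab summary table.
#' @export
writeClinVarSummary <- function(cohort, path, labSummaryPath = NULL) {
  writeTsv(cohort@clinvar, path)
  if (!is.null(labSummaryPath)) {
    fix <- simulateVariantAnnotations(cohort@config)
    writeTsv(fix$labSummary, labSummaryPath)
  }
  invisible(path)
}

#' @rdname cohortWriters
#' @param weights weight table (variant_id, effect_allele, weight).
#' @export
writePgsWeights <- function(weights, path) {
  writeTsv(weights, path)
}
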