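#' Genotype-level quality filter
#'
#' Retains only high-quality genotype calls: genotype quality >= 20, depth
#' >= 10, and minor allele balance > 0.25 for heterozygous genotypes (allele
#' balance computed as alt reads over ref + alt reads; the balance rule
#' applies to heterozygotes only). Failing genotypes are treated as missing
#' downstream. A heterozygous call with zero covering reads fails rather
#' than erroring.
#'
#' @param gt genotype class: "hom_ref", "het", "hom_alt" or "missing"
#'   (vectorized).
#' @param gq phred-scaled genotype quality.
#' @param dp read depth.
#' @param adRef,adAlt reference / alternate allele read counts.
#' @param minGq,minDp,minBalance filter thresholds.
#' @return logical vector: TRUE where the genotype passes.
#' @examples
#' filterGenotype("het", gq = 60, dp = 20, adRef = 17, adAlt = 3)  # FALSE
#' @export
filterGenotype <- function(gt, gq, dp, adRef, adAlt,
                           minGq = 20, minDp = 10, minBalance = 0.25) {
  gt <- as.character(gt)
  pass <- !is.na(gq) & !is.na(dp) & gq >= minGq & dp >= minDp & gt != "missing"
  het <- gt == "het"
  tot <- adRef + adAlt
  bal <- ifelse(tot > 0, pmin(adAlt, adRef) / tot, 0)
  # minor allele balance: fraction of the rarer allele's reads
  pass[het] <- pass[het] & tot[het] > 0 & bal[het] > minBalance
  pass
}

#' Build the high-confidence clinical laboratory registry
#'
#' A lab enters the registry when it has submitted more than
#' \code{minSubmissions} variants to ClinVar and has updated its submission
#' on or after \code{updatedSince}. Labs on the manual exclusion list are
#' removed regardless (the canonical example being a large lab later found
#' to report conflicting phenotypes for the same variant, whose variants are
#' instead routed to manual curation).
#'
#' @param labSummary data.frame with columns \code{lab},
#'   \code{n_submissions} and \code{last_update} (Date or "YYYY-MM-DD").
#' @param minSubmissions registry threshold (exclusive), default 15000.
#' @param updatedSince earliest qualifying last-update date.
#' @param exclude labs removed regardless of the criteria.
#' @return character vector of registry lab names.
#' @export
buildLabRegistry <- function(labSummary, minSubmissions = 15000,
                             updatedSince = as.Date("2017-01-01"),
                             exclude = "Counsyl") {
  if (is.null(labSummary) || nrow(labSummary) == 0L) {
    warning("empty submission summary; registry is empty")
    return(character())
  }
  upd <- as.Date(labSummary$last_update)
  keep <- labSummary$n_submissions > minSubmissions & upd >= updatedSince
  setdiff(labSummary$lab[keep], exclude)
}

#' Cohort-adjusted gnomAD allele frequency
#'
#' Since cohort participants are largely included in gnomAD, the cohort's
#' own carriers are subtracted from the gnomAD allele count before computing
#' the frequency used for gating; the count is floored at zero when cohort
#' carriers exceed the gnomAD count.
#'
#' @param gnomadAc gnomAD allele count (>= 0).
#' @param cohortCarrierCount carriers observed in the analysis cohort.
#' @param gnomadAn gnomAD allele number (> 0).
#' @return adjusted allele frequency.
#' @examples
#' adjustedAf(20, 5, 250000)  # 6e-05
#' @export
adjustedAf <- function(gnomadAc, cohortCarrierCount, gnomadAn) {
  if (any(gnomadAn <= 0)) stop("gnomAD allele number must be positive")
  stopifnot(all(gnomadAc >= 0), all(cohortCarrierCount >= 0))
  pmax(gnomadAc - cohortCarrierCount, 0) / gnomadAn
}

#' ClinVar triage of one variant
#'
#' Deterministic rule pass over the variant's ClinVar submissions for the
#' relevant condition. The allele-frequency gate is evaluated first: a
#' cohort-adjusted gnomAD frequency above the condition's cut-off excludes
#' the variant outright. Otherwise, a pathogenic or likely pathogenic report
#' by a registry lab dated on or after \code{acceptSince} is accepted as
#' clinically significant; a benign/likely-benign registry report (same
#' recency) excludes; conflicting qualifying registry assertions are never
#' silently resolved and, like the absence of any qualifying registry
#' submission, route the variant to manual review.
#'
#' @param variant one row of the annotation sidecar (needs
#'   \code{gnomad_ac}, \code{gnomad_an}).
#' @param submissions data.frame of ClinVar submissions for this variant and
#'   condition (columns \code{lab}, \code{significance}, \code{date_reported}).
#' @param registry registry lab names from \code{\link{buildLabRegistry}}.
#' @param cohortCarrierCount carriers of this variant in the cohort.
#' @param afCutoff condition-specific allele-frequency cut-off (supply from
#'   your curation configuration; \code{Inf} disables the gate).
#' @param acceptSince earliest accepted report date.
#' @return a \linkS4class{TriageDecision}.
#' @export
triageClinvar <- function(variant, submissions, registry,
                          cohortCarrierCount = 0L, afCutoff = Inf,
                          acceptSince = as.Date("2017-01-01")) {
  ev <- character()
  af <- adjustedAf(variant$gnomad_ac, cohortCarrierCount, variant$gnomad_an)
  if (is.finite(afCutoff) && af > afCutoff) {
    return(new("TriageDecision", decision = "excluded",
               evidence = sprintf(
                 "adjusted_af_above_cutoff(af=%.3g, cutoff=%.3g)", af, afCutoff)))
  }
  if (is.finite(afCutoff))
    ev <- c(ev, sprintf("adjusted_af_below_cutoff(af=%.3g)", af))
  if (is.null(submissions) || nrow(submissions) == 0L)
    return(new("TriageDecision", decision = "manual_review",
               evidence = character()))
  qual <- submissions[submissions$lab %in% registry &
                        as.Date(submissions$date_reported) >= acceptSince, ,
                      drop = FALSE]
  if (nrow(qual) == 0L)
    return(new("TriageDecision", decision = "manual_review",
               evidence = character()))
  path <- qual[qual$significance %in% c("P", "LP"), , drop = FALSE]
  benign <- qual[qual$significance %in% c("B", "LB"), , drop = FALSE]
  if (nrow(path) && nrow(benign))
    return(new("TriageDecision", decision = "manual_review",
               evidence = "conflicting_registry_assertions"))
  if (nrow(path)) {
    ev <- c(ev, sprintf("registry_%s(%s, %s)", path$significance[1],
                        path$lab[1], path$date_reported[1]))
    return(new("TriageDecision", decision = "clinically_significant",
               evidence = ev))
  }
  if (nrow(benign)) {
    ev <- c(ev, sprintf("registry_%s(%s, %s)", benign$significance[1],
                        benign$lab[1], benign$date_reported[1]))
    return(new("TriageDecision", decision = "excluded", evidence = ev))
  }
  new("TriageDecision", decision = "manual_review", evidence = character())
}

# 1-based CDS coordinate of a genomic position, plus its exon index
.cdsPosition <- function(tx, pos) {
  st <- IRanges::start(tx@exons); en <- IRanges::end(tx@exons)
  w <- en - st + 1L
  cum <- cumsum(w)
  for (i in seq_along(st)) {
    if (pos >= st[i] && pos <= en[i]) {
      off <- if (tx@strand == "+") pos - st[i] else en[i] - pos
      return(list(cdsPos = c(0L, cum)[i] + off + 1L, exon = i,
                  cumEnd = cum[i], cumStart = c(0L, cum)[i] + 1L))
    }
  }
  stop("variant at position ", pos, " lies outside transcript for ", tx@gene)
}

.downgrade <- function(cls) .LOF_LEVELS[max(match(cls, .LOF_LEVELS) - 1L, 1L)]
.lowerOf <- function(a, b) .LOF_LEVELS[min(match(a, .LOF_LEVELS), match(b, .LOF_LEVELS))]

#' Curate a predicted loss-of-function variant
#'
#' Five-category rule engine refining LOFTEE high-confidence calls into
#' "LoF", "likely_LoF", "uncertain", "likely_not_LoF" or "not_LoF", with an
#' ordered evidence trail. Rules, in evidence order: (1) a gnomAD filter
#' flag or a site on the genotyping-quality blacklist downgrades one class;
#' (2) a truncating variant in the NMD-escape region (last exon, or final 50
#' coding bases of the penultimate exon) is not LoF, unless it is predicted
#' to delete more than 25% of the coding sequence, which overrides the
#' escape; (3) for splice variants, an in-frame alternative splice site
#' within 6 bp is an essential splice-site rescue (likely not LoF), and one
#' between 6 and 21 bp is a possible rescue: likely not LoF when externally
#' validated, otherwise uncertain; (4) a pext value below the
#' low-expression threshold downgrades one class (skipped with an evidence
#' note when pext is missing). Variants not annotated LOFTEE
#' high-confidence are immediately not LoF. The engine is a pure function:
#' identical inputs give identical class and evidence order, and weakening
#' evidence (smaller pext, more 3'-ward truncation) never upgrades a
#' variant toward LoF.
#'
#' @param variant one row of the annotation sidecar (fields
#'   \code{pos}, \code{consequence}, \code{loftee}, \code{pext},
#'   \code{gnomad_filter_flag}, \code{site_blacklisted}, and for splice
#'   variants \code{splice_inframe_distance}, \code{splice_validated}).
#' @param transcript the gene's \linkS4class{TranscriptModel}.
#' @param pextThreshold low-expression threshold for the pext downgrade;
#'   supply the cut-off appropriate to your expression annotation release.
#' @return a \linkS4class{LofCall}.
#' @export
classifyPlof <- function(variant, transcript, pextThreshold = 0.2) {
  if (!identical(variant$loftee, "HC"))
    return(new("LofCall", lofClass = "not_LoF",
               evidence = "loftee_not_high_confidence"))
  ev <- "loftee_high_confidence"
  cls <- "LoF"
  flagged <- isTRUE(variant$gnomad_filter_flag) || isTRUE(variant$site_blacklisted)
  if (flagged)
    ev <- c(ev, if (isTRUE(variant$site_blacklisted)) "site_blacklist_downgrade"
               else "gnomad_filter_flag_downgrade")

  if (variant$consequence %in% c("stop_gained", "frameshift")) {
    cp <- .cdsPosition(transcript, variant$pos)
    nExon <- length(transcript@exons)
    inLast <- cp$exon == nExon
    inPenultTail <- nExon >= 2L && cp$exon == nExon - 1L &&
      cp$cdsPos > cp$cumEnd - 50L
    if (inLast || inPenultTail) {
      truncFrac <- (transcript@cdsLength - cp$cdsPos + 1L) / transcript@cdsLength
      if (truncFrac > 0.25) {
        ev <- c(ev, sprintf(
          "nmd_escape_overridden_truncates_%.1f_pct_of_cds", 100 * truncFrac))
      } else {
        cls <- "not_LoF"
        ev <- c(ev, if (inLast) "nmd_escape_last_exon"
                   else "nmd_escape_penultimate_exon_tail")
      }
    }
  } else if (variant$consequence %in% c("splice_donor", "splice_acceptor")) {
    d <- variant$splice_inframe_distance
    if (!is.null(d) && !is.na(d)) {
      if (d <= 6) {
        cls <- .lowerOf(cls, "likely_not_LoF")
        ev <- c(ev, "essential_splice_rescue_within_6bp")
      } else if (d <= 21) {
        if (isTRUE(variant$splice_validated)) {
          cls <- .lowerOf(cls, "likely_not_LoF")
          ev <- c(ev, "possible_splice_rescue_6_21bp_validated")
        } else {
          cls <- .lowerOf(cls, "uncertain")
          ev <- c(ev, "possible_splice_rescue_6_21bp_unvalidated")
        }
      }
    }
  }

  if (is.null(variant$pext) || is.na(variant$pext)) {
    ev <- c(ev, "pext_missing_rule_skipped")
  } else if (variant$pext < pextThreshold) {
    cls <- .downgrade(cls)
    ev <- c(ev, sprintf("low_pext_downgrade(pext=%.2f)", variant$pext))
  }
  if (flagged) cls <- .downgrade(cls)
  new("LofCall", lofClass = cls, evidence = ev)
}

#' Triage every variant of an annotation sidecar
#'
#' Convenience wrapper running \code{\link{triageClinvar}} and
#' \code{\link{classifyPlof}} over a variant table.
#'
#' @param variants annotation sidecar data.frame.
#' @param transcripts named list of \linkS4class{TranscriptModel}.
#' @param clinvar ClinVar submission records (with \code{variant_id}).
#' @param registry registry lab names.
#' @param cohortCarrierCounts named integer vector of per-variant cohort
#'   carrier counts (default zero).
#' @param afCutoffs named per-condition allele-frequency cut-offs, or a
#'   single value; \code{Inf} disables the gate.
#' @param pextThreshold see \code{\link{classifyPlof}}.
#' @return the sidecar with columns \code{decision}, \code{lof_class},
#'   \code{triage_evidence} and \code{lof_evidence} appended.
#' @export
triageVariants <- function(variants, transcripts, clinvar, registry,
                           cohortCarrierCounts = NULL, afCutoffs = Inf,
                           pextThreshold = 0.2) {
  n <- nrow(variants)
  dec <- character(n); lofc <- character(n)
  tev <- character(n); lev <- character(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    subs <- clinvar[clinvar$variant_id == v$variant_id &
                      clinvar$phenotype == v$condition, , drop = FALSE]
    cc <- if (is.null(cohortCarrierCounts)) 0L
          else unname(cohortCarrierCounts[v$variant_id])
    if (is.null(cc) || is.na(cc)) cc <- 0L
    cut <- if (length(afCutoffs) == 1L && is.null(names(afCutoffs))) afCutoffs
           else unname(afCutoffs[v$condition])
    if (is.null(cut) || is.na(cut)) cut <- Inf
    td <- triageClinvar(v, subs, registry, cc, cut)
    lc <- classifyPlof(v, transcripts[[v$gene]], pextThreshold)
    dec[i] <- td@decision; lofc[i] <- lc@lofClass
    tev[i] <- paste(td@evidence, collapse = ";")
    lev[i] <- paste(lc@evidence, collapse = ";")
  }
  variants$decision <- dec
  variants$lof_class <- lofc
  variants$triage_evidence <- tev
  variants$lof_evidence <- lev
  variants
}

#' Per-individual carrier flags per condition
#'
#' An individual is flagged as a carrier for a condition when they have at
#' least one passing non-reference genotype at a variant that is either
#' ClinVar clinically significant or curated LoF / likely LoF, in any gene
#' of the condition's panel. Composite panels (e.g. the five-gene MODY set)
#' are supported directly. Variants assigned to no panel are dropped with a
#' warning.
#'
#' @param triaged output of \code{\link{triageVariants}} (needs
#'   \code{variant_id}, \code{gene}, \code{decision}, \code{lof_class};
#'   when a \code{condition} column is present — the condition whose
#'   ClinVar phenotype the variant was curated against — a variant counts
#'   only toward that condition, so genes shared between panels, such as
#'   APOB in both the high-LDL and the hypobetalipoproteinemia panel, do
#'   not cross-contaminate).
#' @param genotypes individuals x variants dosage matrix (columns named by
#'   variant id).
#' @param geneSets named list: condition -> character vector of genes.
#' @param qcPass optional logical matrix, same shape as \code{genotypes};
#'   failing genotypes are treated as missing.
#' @return logical matrix individuals x conditions.
#' @export
carrierMatrix <- function(triaged, genotypes, geneSets, qcPass = NULL) {
  qualifying <- triaged$decision == "clinically_significant" |
    triaged$lof_class %in% c("LoF", "likely_LoF")
  allGenes <- unique(unlist(geneSets))
  orphan <- unique(triaged$gene[!triaged$gene %in% allGenes])
  if (length(orphan))
    warning("variants in genes outside every panel excluded: ",
            paste(orphan, collapse = ", "))
  eff <- genotypes
  if (!is.null(qcPass)) eff[!qcPass] <- 0L
  out <- matrix(FALSE, nrow(genotypes), length(geneSets),
                dimnames = list(rownames(genotypes), names(geneSets)))
  for (cond in names(geneSets)) {
    inPanel <- qualifying & triaged$gene %in% geneSets[[cond]]
    if (!is.null(triaged$condition))
      inPanel <- inPanel & triaged$condition == cond
    vs <- triaged$variant_id[inPanel]
    vs <- intersect(vs, colnames(genotypes))
    if (length(vs))
      out[, cond] <- rowSums(eff[, vs, drop = FALSE] > 0L) > 0L
  }
  out
}
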