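# Shared fixture builders; everything is generated in code at test time.

covNames <- c("age", "sex", paste0("pc", 1:10))

# single-condition config for focused simulations
oneConditionConfig <- function(n, seed, beta = 55, freq = 4e-3,
                               trait = "ldl", gene = "LDLR", h2 = NULL) {
  cond <- conditionSpec("test_cond", gene, freq, beta, trait)
  cfg <- simulationConfig(n, seed = seed, conditions = list(cond))
  if (!is.null(h2)) cfg@h2[] <- h2
  cfg
}

# plus-strand transcript with a 400-base last exon (NMD-escape friendly)
layoutATranscript <- function(gene = "GENEA") {
  w <- c(400L, 350L, 350L, 300L, 400L)
  starts <- 1000L + cumsum(c(0L, head(w, -1L) + 100L))
  transcriptModel(gene, "+", starts, starts + w - 1L)
}

# plus-strand transcript with a 700-base last exon (>25% truncations)
layoutBTranscript <- function(gene = "GENEB") {
  w <- c(300L, 300L, 300L, 200L, 700L)
  starts <- 1000L + cumsum(c(0L, head(w, -1L) + 100L))
  transcriptModel(gene, "+", starts, starts + w - 1L)
}

# variant row in annotation-sidecar form; pos given as a CDS coordinate
variantAt <- function(tx, cdsPos, consequence = "stop_gained", loftee = "HC",
                      pext = 0.95, spliceDist = NA_integer_,
                      spliceValidated = FALSE, flag = FALSE,
                      blacklisted = FALSE, ac = 2L, an = 250000L) {
  w <- IRanges::width(tx@exons)
  cum <- cumsum(w)
  ex <- which(cdsPos <= cum)[1]
  off <- cdsPos - c(0L, cum)[ex] - 1L
  pos <- if (tx@strand == "+") IRanges::start(tx@exons)[ex] + off
         else IRanges::end(tx@exons)[ex] - off
  data.frame(variant_id = paste0(tx@gene, ":", cdsPos), chrom = "1",
             pos = pos, ref = "C", alt = "T", gene = tx@gene,
             consequence = consequence, loftee = loftee, pext = pext,
             gnomad_ac = ac, gnomad_an = an, gnomad_filter_flag = flag,
             site_blacklisted = blacklisted,
             splice_inframe_distance = spliceDist,
             splice_validated = spliceValidated, stringsAsFactors = FALSE)
}

lofRank <- function(cls) match(cls, c("not_LoF", "likely_not_LoF",
                                      "uncertain", "likely_LoF", "LoF"))
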