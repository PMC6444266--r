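# Full-scale simulation preset emulating a published four-taxon Sorghum
# plastome comparison: a ~140.8 kb quadripartite genome (LSC 82,686 bp, IR
# 22,783 bp, SSC 12,503 bp, GC 38.5%) and the reported mutation landscape —
# 651 substitution sites with a transition-biased six-class spectrum
# (345 Ts : 306 Tv), 137 indels (43 SSR-indels, 94 NR-indels, largest NR
# deletion 165 bp in a coding region), nine small inversions of 2-6 bp with
# 3-20 bp hairpin stems, and four mutational hotspot spacers (rps16-trnQ,
# trnG-trnM, rbcL-psaI in the LSC; rps15-ndhF in the SSC). One taxon
# (the "taxonD" slot) carries most events, as for the divergent species in
# the published quartet; the reference carries a small number, including the
# long coding deletion. The 518 LSC and 97 SSC substitution sites plus 18
# mirrored IR substitution pairs (36 sites, both copies counted) make the
# 651 total additive across regions.

#' Full-scale "sorghum-like" simulation configuration
#'
#' @param seed integer RNG seed (used both for building the randomized parts
#'   of the plan and, via [simulate_quartet()], for the simulation itself).
#' @param taxa four taxon labels (first = reference).
#' @return a [sim_config()] at genome length 140,755 bp.
#' @export
sorghum_like_config <- function(seed,
                                taxa = c("S_sudanense", "S_propinquum",
                                         "S_bicolor", "S_timorense")) {
  set.seed(seed)
  sud <- taxa[1L]; prop <- taxa[2L]; bic <- taxa[3L]; tim <- taxa[4L]

  hotspots <- data.frame(
    name_a = c("rps16", "trnG", "rbcL", "rps15"),
    name_b = c("trnQ", "trnM", "psaI", "ndhF"),
    region = c("LSC", "LSC", "LSC", "SSC"),
    width = 900L, extra_snps = 0L,
    taxon = tim, stringsAsFactors = FALSE)
  hs_names <- paste0(hotspots$name_a, "-", hotspots$name_b)

  ## --- SNP plan: exact six-class quotas ---------------------------------
  class_quota <- c("A>G/T>C" = 179L, "G>A/C>T" = 166L, "A>C/T>G" = 120L,
                   "C>A/G>T" = 106L, "A>T/T>A" = 50L, "G>C/C>G" = 30L)
  stopifnot(sum(class_quota) == 651L)
  # 18 mirrored IR pair events consume two sites each
  ir_pairs <- rep(names(class_quota), c(5L, 5L, 3L, 3L, 1L, 1L))
  stopifnot(length(ir_pairs) == 18L)
  single_quota <- class_quota - 2L * table(factor(ir_pairs,
                                                  names(class_quota)))
  singles <- sample(rep(names(class_quota), single_quota))
  stopifnot(length(singles) == 651L - 36L)

  # groups of single-site SNPs: (taxa, region, feature, n)
  groups <- data.frame(
    taxa = c(sud, bic, paste(sud, bic, sep = ","), prop, prop,
             tim, tim, rep(tim, 4L)),
    region = c("LSC", "LSC", "LSC", "LSC", "SSC",
               "LSC", "SSC", "LSC", "LSC", "LSC", "SSC"),
    feature = c(rep(NA_character_, 7L), hs_names),
    hotspot = c(rep(NA_character_, 7L), hs_names),
    n = c(2L, 1L, 17L, 18L, 7L, 408L, 66L, 24L, 24L, 24L, 24L),
    stringsAsFactors = FALSE)
  stopifnot(sum(groups$n) == 615L)
  take <- 0L
  snp_rows <- list()
  for (i in seq_len(nrow(groups))) {
    cls <- singles[(take + 1L):(take + groups$n[i])]
    take <- take + groups$n[i]
    snp_rows[[i]] <- data.frame(
      type = "snp", taxa = groups$taxa[i], class = cls,
      region = groups$region[i], feature = groups$feature[i],
      hotspot = groups$hotspot[i], stringsAsFactors = FALSE)
  }
  snp_rows[[length(snp_rows) + 1L]] <- data.frame(
    type = "snp", taxa = tim, class = ir_pairs, region = "IR",
    feature = NA_character_, hotspot = NA_character_,
    stringsAsFactors = FALSE)
  snps <- do.call(rbind, snp_rows)

  ## --- indel plan -------------------------------------------------------
  ssr_deltas <- function(n) sample(c(1L, -1L, 2L, -2L), n, replace = TRUE,
                                   prob = c(0.4, 0.4, 0.1, 0.1))
  ssr_indels <- data.frame(
    type = "ssr_indel",
    taxa = c(rep(sud, 3L), rep(bic, 3L), rep(prop, 7L), rep(tim, 30L)),
    delta = ssr_deltas(43L), stringsAsFactors = FALSE)

  tim_ins_len <- c(152L, rep(1L, 13L), rep(5L, 10L), rep(2L, 4L), rep(3L, 4L),
                   rep(4L, 3L), rep(6L, 3L), 7L, 8L, 9L, 10L, 12L, 15L, 22L,
                   30L)
  tim_del_len <- c(rep(1L, 13L), rep(5L, 9L), rep(2L, 4L), rep(3L, 4L),
                   rep(4L, 3L), rep(6L, 3L), 7L, 9L, 11L, 14L, 18L, 25L)
  stopifnot(length(tim_ins_len) == 46L, length(tim_del_len) == 42L)
  nr_rows <- function(taxon, kind, lens, region, context = NA_character_,
                      feature = NA_character_) {
    data.frame(type = "nr_indel", taxa = taxon, kind = kind, length = lens,
               region = region, context = context, feature = feature,
               stringsAsFactors = FALSE)
  }
  ssc_share <- function(lens) {
    # roughly one NR-indel in six falls in the SSC
    ifelse(seq_along(lens) %% 6L == 0L, "SSC", "LSC")
  }
  ctx_share <- function(lens) {
    # mostly spacers, occasional introns (the published split is ~82/16%)
    ifelse(seq_along(lens) %% 6L == 3L, "intron", "spacer")
  }
  nr_indels <- rbind(
    nr_rows(tim, "ins", tim_ins_len[1L], "LSC", NA, "rps16-trnQ"),
    nr_rows(tim, "ins", tim_ins_len[-1L], ssc_share(tim_ins_len[-1L]),
            ctx_share(tim_ins_len[-1L])),
    nr_rows(tim, "del", tim_del_len, ssc_share(tim_del_len),
            ctx_share(tim_del_len)),
    nr_rows(sud, "del", 165L, "LSC", "exon", "rpoC2"),
    nr_rows(sud, "del", 3L, "LSC", "spacer"),
    nr_rows(sud, "ins", 2L, "LSC", "spacer"),
    nr_rows(prop, "ins", 4L, "LSC", "intron", "rpoC1"),
    nr_rows(bic, "ins", 1L, "LSC", "spacer"),
    nr_rows(bic, "del", 4L, "SSC", "spacer"))
  stopifnot(nrow(nr_indels) == 94L)

  ## --- inversion plan (lengths/stems of the nine published events) ------
  inversions <- data.frame(
    type = "inversion",
    taxa = c(rep(tim, 8L), sud),
    length = c(2L, 2L, 2L, 6L, 6L, 6L, 2L, 4L, 4L),
    flank = c(12L, 6L, 5L, 14L, 8L, 14L, 3L, 8L, 20L),
    region = c(rep("LSC", 8L), "SSC"),
    context = c(rep("spacer", 7L), "intron", "exon"),
    feature = c("rps16-trnQ", rep(NA_character_, 6L), "rpl16", "ccsA"),
    stringsAsFactors = FALSE)

  ## --- SSR plan (48 single-copy loci + 2 mirrored IR loci) --------------
  mono <- data.frame(
    motif = c(rep("A", 14L), rep("T", 11L), rep("A", 3L), "T",
              rep("T", 2L)),
    copies = c(10L, 10L, 11L, 11L, 12L, 12L, 13L, 10L, 11L, 10L, 12L, 10L,
               11L, 13L,
               10L, 10L, 11L, 11L, 12L, 10L, 13L, 10L, 11L, 12L, 10L,
               10L, 11L, 12L, 11L,
               10L, 11L),
    region = c(rep("LSC", 25L), rep("SSC", 4L), rep("IR", 2L)),
    context = c(rep("spacer", 20L), "exon", "exon", "intron", "intron",
                "spacer", rep("spacer", 4L), "spacer", "spacer"),
    stringsAsFactors = FALSE)
  mono_extra <- data.frame(
    motif = c("A", "A", "T", "T", "A", "T"),
    copies = c(10L, 11L, 10L, 12L, 11L, 10L),
    region = "LSC", context = "spacer", stringsAsFactors = FALSE)
  di <- data.frame(
    motif = c("AT", "AT", "AT", "TA", "TA", "AG", "AG", "AT",
              "AT", "TA", "AG", "AT"),
    copies = c(5L, 5L, 6L, 5L, 5L, 5L, 5L, 5L, 6L, 5L, 5L, 5L),
    region = c(rep("LSC", 6L), "SSC", "SSC", rep("LSC", 3L), "SSC"),
    context = c(rep("spacer", 5L), "intron", "spacer", "spacer",
                rep("spacer", 4L)),
    stringsAsFactors = FALSE)
  tri <- data.frame(motif = c("AAT", "AAG"), copies = 4L,
                    region = "LSC", context = c("spacer", "exon"),
                    stringsAsFactors = FALSE)
  tetra <- data.frame(
    motif = c(rep("AAAT", 4L), rep("AATT", 2L), rep("TTTC", 2L)),
    copies = 3L,
    region = c(rep("LSC", 6L), "SSC", "SSC"),
    context = c(rep("spacer", 5L), "intron", "spacer", "spacer"),
    stringsAsFactors = FALSE)
  hexa <- data.frame(motif = "AATCGG", copies = 3L, region = "LSC",
                     context = "spacer", stringsAsFactors = FALSE)
  ssr_plan <- rbind(mono, mono_extra, di, tri, tetra, hexa)

  events <- merge_plans(list(snps, ssr_indels, nr_indels, inversions))
  sim_config(seed = seed,
             genome_length = 140755L,
             gc = 0.385,
             lsc_frac = 82686 / 140755,
             ir_frac = 22783 / 140755,
             taxa = taxa,
             n_genes = 110L,
             ssr_plan = ssr_plan,
             events = events,
             hotspots = hotspots,
             junction_margin = 250L)
}
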