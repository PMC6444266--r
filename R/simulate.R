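# Synthetic plastome-quartet generator: ancestor construction.
#
# The generator builds a circular-convention plastome laid out as
# LSC | IRb | SSC | IRa (IRa = exact reverse complement of IRb), with gene /
# intron / tRNA / rRNA annotation, planted SSR loci, and (in evolve_quartet)
# planted SNP / indel / inversion events on four taxa. Everything planted is
# recorded in a truth ledger and events are kept mutually isolated so the
# true alignment is unambiguous by construction. Accidental microsatellites
# are suppressed by rejection so that the planted loci are the only
# detectable repeats — this makes planted-SSR recall and precision exact on
# generator output.

## ------------------------------------------------------------------ config --

#' Simulation configuration for a plastome quartet
#'
#' The defaults emulate the scale and mutation spectrum of a four-taxon
#' grass plastome comparison at desk scale: a 20 kb quadripartite genome at
#' 38.5% GC with 60 SNPs (40 transitions : 20 transversions), 12 SSR-indels,
#' 15 NR-indels and 3 small inversions distributed over the three
#' non-reference taxa.
#'
#' @param seed integer RNG seed.
#' @param genome_length total length in bp (default 20000).
#' @param gc target GC fraction (default 0.385).
#' @param lsc_frac,ir_frac fractions of the genome for the LSC and for one
#'   IR copy (SSC takes the remainder; LSC must stay the longer single-copy
#'   region).
#' @param taxa four taxon labels; the first is the reference.
#' @param n_genes number of genes to annotate (default scales with length).
#' @param ssr_plan data.frame(motif, copies, region, context) of SSR loci to
#'   plant; `NULL` for a default plan.
#' @param events data.frame of events to plant (see [default_event_plan()]);
#'   `NULL` for the default plan.
#' @param hotspots optional data.frame(name_a, name_b, region, width,
#'   extra_snps, taxon): designated wide spacers that receive concentrated
#'   extra SNPs, emulating mutational hotspots.
#' @param junction_margin bp kept event-free around the four region
#'   junctions (default 40).
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       genome_length = 20000L,
                       gc = 0.385,
                       lsc_frac = 0.5874,
                       ir_frac = 0.1619,
                       taxa = c("taxonA", "taxonB", "taxonC", "taxonD"),
                       n_genes = NULL,
                       ssr_plan = NULL,
                       events = NULL,
                       hotspots = NULL,
                       junction_margin = 40L) {
  stopifnot(length(taxa) == 4L, genome_length >= 4000L)
  ssc_frac <- 1 - lsc_frac - 2 * ir_frac
  if (ssc_frac <= 0 || lsc_frac <= ssc_frac) {
    stop("region fractions must sum to 1 with LSC fraction > SSC fraction")
  }
  n_genes <- n_genes %||% max(10L, round(genome_length / 1400))
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc = gc, lsc_frac = lsc_frac, ir_frac = ir_frac,
              ssc_frac = ssc_frac, taxa = taxa, reference = taxa[1L],
              n_genes = n_genes,
              ssr_plan = ssr_plan %||% default_ssr_plan(),
              events = if (is.null(events)) default_event_plan(taxa)
                       else merge_plans(list(events)),
              hotspots = hotspots,
              junction_margin = as.integer(junction_margin),
              thresholds = default_ssr_thresholds())
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Default plan of SSR loci to plant (desk scale)
#'
#' Mostly A/T mononucleotides near the detection threshold — the composition
#' typical of plastomes — plus a few di-, tri-, tetra- and one
#' hexanucleotide locus. One locus is planted in the IR (mirrored into both
#' copies).
#'
#' @return data.frame(motif, copies, region, context).
#' @export
default_ssr_plan <- function() {
  df <- rbind(
    data.frame(motif = c("A", "A", "A", "T", "T", "A", "T", "A"),
               copies = c(10L, 11L, 12L, 10L, 11L, 13L, 10L, 10L),
               region = c("LSC", "LSC", "LSC", "LSC", "LSC", "SSC", "SSC", "LSC"),
               context = c("spacer", "spacer", "intron", "spacer", "exon",
                           "spacer", "spacer", "spacer")),
    data.frame(motif = c("AT", "AG", "TA", "CT"),
               copies = c(5L, 5L, 6L, 5L),
               region = c("LSC", "LSC", "SSC", "LSC"),
               context = c("spacer", "spacer", "spacer", "intron")),
    data.frame(motif = "AAG", copies = 4L, region = "LSC", context = "exon"),
    data.frame(motif = c("AATC", "TTAG"), copies = c(3L, 3L),
               region = c("LSC", "SSC"), context = c("spacer", "spacer")),
    data.frame(motif = "AATCGG", copies = 3L, region = "LSC",
               context = "spacer"),
    data.frame(motif = "T", copies = 11L, region = "IR", context = "spacer"))
  df$motif <- as.character(df$motif)
  df
}

#' Default event plan for a test-scale quartet
#'
#' 60 SNPs (40 Ts : 20 Tv), 12 SSR-indels, 15 NR-indels, 3 inversions,
#' distributed over the three non-reference taxa with one taxon carrying
#' most events (the pattern seen between a divergent species and a group of
#' close relatives).
#'
#' @param taxa the four taxon labels (first = reference).
#' @return data.frame of events understood by [evolve_quartet()].
#' @export
default_event_plan <- function(taxa) {
  stopifnot(length(taxa) == 4L)
  b <- taxa[2L]; c_ <- taxa[3L]; d <- taxa[4L]
  snp_row <- function(taxon, class, n, region) {
    data.frame(type = "snp", taxa = taxon, class = class, region = region,
               n = n, stringsAsFactors = FALSE)
  }
  snps <- rbind(
    # transitions: 20 + 20
    snp_row(b, "A>G/T>C", 4L, "LSC"), snp_row(c_, "A>G/T>C", 5L, "LSC"),
    snp_row(d, "A>G/T>C", 9L, "LSC"), snp_row(d, "A>G/T>C", 2L, "SSC"),
    snp_row(b, "G>A/C>T", 3L, "LSC"), snp_row(c_, "G>A/C>T", 5L, "LSC"),
    snp_row(d, "G>A/C>T", 9L, "LSC"), snp_row(d, "G>A/C>T", 3L, "SSC"),
    # transversions: 6 + 6 + 4 + 4
    snp_row(b, "A>C/T>G", 1L, "LSC"), snp_row(c_, "A>C/T>G", 2L, "LSC"),
    snp_row(d, "A>C/T>G", 3L, "SSC"),
    snp_row(b, "C>A/G>T", 1L, "LSC"), snp_row(c_, "C>A/G>T", 2L, "LSC"),
    snp_row(d, "C>A/G>T", 3L, "LSC"),
    snp_row(b, "A>T/T>A", 1L, "LSC"), snp_row(d, "A>T/T>A", 3L, "LSC"),
    snp_row(c_, "G>C/C>G", 1L, "SSC"), snp_row(d, "G>C/C>G", 3L, "LSC"))
  ssr_indels <- data.frame(
    type = "ssr_indel",
    taxa = c(b, b, c_, c_, c_, d, d, d, d, d, d, d),
    delta = c(1L, -1L, 2L, -1L, 1L, 1L, -1L, 2L, -2L, 1L, -1L, 1L),
    n = 1L, stringsAsFactors = FALSE)
  nr_indels <- data.frame(
    type = "nr_indel",
    taxa = c(b, b, c_, c_, c_, d, d, d, d, d, d, d, d, d, d),
    kind = c("ins", "del", "ins", "del", "del",
             "ins", "ins", "ins", "ins", "del", "del", "del", "del",
             "ins", "del"),
    length = c(1L, 5L, 2L, 1L, 8L, 5L, 1L, 3L, 22L, 5L, 1L, 4L, 6L, 1L, 12L),
    region = c("LSC", "LSC", "LSC", "SSC", "LSC", "LSC", "LSC", "LSC", "LSC",
               "LSC", "SSC", "LSC", "LSC", "SSC", "LSC"),
    n = 1L, stringsAsFactors = FALSE)
  inversions <- data.frame(
    type = "inversion",
    taxa = c(c_, d, d),
    length = c(4L, 2L, 6L),
    flank = c(5L, 6L, 12L),
    region = c("LSC", "LSC", "SSC"),
    n = 1L, stringsAsFactors = FALSE)
  merge_plans(list(snps, ssr_indels, nr_indels, inversions))
}

# rbind event tables with heterogeneous columns, expanding count column `n`
merge_plans <- function(plans) {
  cols <- c("type", "taxa", "class", "region", "context", "feature",
            "hotspot", "delta", "kind", "length", "flank", "n")
  full <- lapply(plans, function(p) {
    for (cc in setdiff(cols, names(p))) p[[cc]] <- rep(NA, nrow(p))
    p[cols]
  })
  ev <- do.call(rbind, full)
  ev$n[is.na(ev$n)] <- 1L
  idx <- rep(seq_len(nrow(ev)), ev$n)
  ev <- ev[idx, setdiff(cols, "n"), drop = FALSE]
  rownames(ev) <- NULL
  ev
}

## ------------------------------------------------------- ancestor assembly --

# gene name pools in genome order; hotspot-capable adjacent pairs are
# rps16-trnQ, trnG-trnM, rbcL-psaI (LSC) and rps15-ndhF (SSC)
LSC_GENE_POOL <- c("psbA", "matK", "rps16", "trnQ", "psbK", "atpA", "atpF",
                   "rpoC2", "rpoC1", "rpoB", "trnC", "psbM", "petN", "trnD",
                   "trnE", "trnT", "psbD", "psbC", "trnG", "trnM", "rbcL",
                   "psaI", "petA", "psbJ", "rpl33", "rps18", "rpl20", "clpP",
                   "psbB", "petB", "petD", "rpoA", "rps11", "rpl14", "rpl16",
                   "rps3", "rps19")
IR_GENE_POOL <- c("rpl2", "rpl23", "ndhB", "rps7", "rrn16", "trnI", "trnA",
                  "rrn23", "rrn5")
SSC_GENE_POOL <- c("rpl32", "ccsA", "ndhD", "ndhE", "ndhA", "rps15", "ndhF")

is_trna <- function(name) startsWith(name, "trn")
is_rrna <- function(name) startsWith(name, "rrn")

# genes that always carry an intron in the layout (the canonical
# intron-containing plastid genes among the pools above)
INTRON_GENES <- c("rps16", "atpF", "rpoC1", "clpP", "petB", "petD", "rpl16",
                  "rpl2", "ndhB", "ndhA")

# draw random bases at the target GC
rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# scan a character window and return SSR loci (as scan_ssrs but on a vector)
scan_window <- function(chars, thresholds) {
  scan_ssrs(chars_seq(chars), thresholds)
}

# break every detectable SSR in seqv by resampling one base inside each run;
# mirror-aware inside the IRs. Returns the repaired vector.
suppress_ssrs <- function(seqv, thresholds, mirror, protect = NULL) {
  for (iter in 1:60) {
    loci <- scan_ssrs(chars_seq(seqv), thresholds)
    if (!is.null(protect) && nrow(loci)) {
      planted <- paste(protect$start, protect$end)
      loci <- loci[!paste(loci$start, loci$end) %in% planted, , drop = FALSE]
    }
    if (!nrow(loci)) return(seqv)
    for (i in seq_len(nrow(loci))) {
      mid <- (loci$start[i] + loci$end[i]) %/% 2L
      old <- seqv[mid]
      repl <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      seqv[mid] <- repl
      mp <- mirror(mid)
      if (!is.na(mp)) seqv[mp] <- comp_chars(repl)
    }
  }
  stop("failed to suppress accidental SSRs")
}

# layout genes in one region arc; returns feature rows and the hotspot
# intervals it creates. Gene sizes are drawn, hotspot spacers get a fixed
# width. Errors if the plan overflows the region.
layout_genes <- function(pool, arc, hotspot_pairs, hotspot_width,
                         scale = 1) {
  margin <- 60L
  cursor <- arc[1] + margin
  feats <- list()
  hot <- list()
  prev_name <- NULL
  region_len <- arc[2] - arc[1] + 1L
  gap_hi <- max(60L, min(200L, region_len %/% 12L))
  for (nm in pool) {
    gap <- if (!is.null(prev_name) &&
               paste(prev_name, nm) %in% hotspot_pairs) {
      hotspot_width
    } else sample(40:gap_hi, 1L)
    if (!is.null(prev_name) && paste(prev_name, nm) %in% hotspot_pairs) {
      hot[[length(hot) + 1L]] <- data.frame(
        name = paste0(prev_name, "-", nm),
        start = cursor + 1L, end = cursor + gap,
        stringsAsFactors = FALSE)
    }
    cursor <- cursor + gap
    glen <- if (is_trna(nm)) sample(70:90, 1L)
            else if (is_rrna(nm)) as.integer(round(sample(800:1600, 1L) * scale))
            else as.integer(round(sample(280:950, 1L) * scale))
    glen <- max(glen, 60L)
    kind <- if (is_trna(nm)) "tRNA" else if (is_rrna(nm)) "rRNA" else "gene-exon"
    strand <- sample(c(1L, -1L), 1L)
    intron_min <- as.integer(max(150L, round(400L * scale)))
    if (nm %in% INTRON_GENES) glen <- max(glen, intron_min)
    if (kind == "gene-exon" && glen >= intron_min &&
        (nm %in% INTRON_GENES || stats::runif(1) < 0.35)) {
      e1 <- as.integer(round(glen * stats::runif(1, 0.3, 0.6)))
      ilen <- sample(90:240, 1L)
      feats[[length(feats) + 1L]] <- data.frame(
        name = nm, kind = "gene-exon", start = cursor + 1L,
        end = cursor + e1, strand = strand, stringsAsFactors = FALSE)
      feats[[length(feats) + 1L]] <- data.frame(
        name = nm, kind = "intron", start = cursor + e1 + 1L,
        end = cursor + e1 + ilen, strand = strand, stringsAsFactors = FALSE)
      feats[[length(feats) + 1L]] <- data.frame(
        name = nm, kind = "gene-exon", start = cursor + e1 + ilen + 1L,
        end = cursor + glen + ilen, strand = strand, stringsAsFactors = FALSE)
      cursor <- cursor + glen + ilen
    } else {
      feats[[length(feats) + 1L]] <- data.frame(
        name = nm, kind = kind, start = cursor + 1L, end = cursor + glen,
        strand = strand, stringsAsFactors = FALSE)
      cursor <- cursor + glen
    }
    prev_name <- nm
    if (cursor > arc[2] - margin) {
      stop("gene plan overflows region capacity (", arc[1], "-", arc[2], ")")
    }
  }
  list(features = do.call(rbind, feats),
       hotspots = if (length(hot)) do.call(rbind, hot) else NULL)
}

#' Generate the ancestral plastome
#'
#' Builds a random quadripartite genome at the target GC with IRa planted as
#' the exact reverse complement of IRb, gene/intron/tRNA/rRNA annotation in
#' all regions (IR genes mirrored into both copies), and the SSR loci of
#' `config$ssr_plan` planted with non-repeat guard bases. Accidental repeats
#' meeting the detection thresholds are suppressed, so a scan of the
#' ancestor finds exactly the planted loci.
#'
#' @param config a [sim_config()]. The caller is responsible for seeding the
#'   RNG ([simulate_quartet()] does this).
#' @return list with `record` (annotated [plastome_record()]), `structure`,
#'   `ssr_loci` (planted loci incl. mirrored IR copies), `hotspots`,
#'   `reserved` (logical mask of positions unavailable to events), `mirror`
#'   (function mapping an IR position to its mirror or NA), `arcs`.
#' @export
generate_ancestor <- function(config) {
  n <- config$genome_length
  gc <- config$gc
  thresholds <- config$thresholds
  lsc_len <- as.integer(round(n * config$lsc_frac))
  ir_len <- as.integer(round(n * config$ir_frac))
  ssc_len <- n - lsc_len - 2L * ir_len
  stopifnot(ssc_len > 200L, lsc_len > ssc_len)
  arcs <- list(LSC = c(1L, lsc_len),
               IRb = c(lsc_len + 1L, lsc_len + ir_len),
               SSC = c(lsc_len + ir_len + 1L, lsc_len + ir_len + ssc_len),
               IRa = c(n - ir_len + 1L, n))

  mirror <- function(q) {
    if (q >= arcs$IRb[1] && q <= arcs$IRb[2]) {
      arcs$IRa[1] + (arcs$IRb[2] - q)
    } else if (q >= arcs$IRa[1] && q <= arcs$IRa[2]) {
      arcs$IRb[1] + (arcs$IRa[2] - q)
    } else NA_integer_
  }

  for (attempt in 1:6) {
    seqv <- random_dna_chars(n, gc)
    # plant the inverted repeat
    seqv[arcs$IRa[1]:arcs$IRa[2]] <-
      rev(comp_chars(seqv[arcs$IRb[1]:arcs$IRb[2]]))
    # keep the IR maximal: junction bases must not extend it
    fix_junction <- function(seqv, outside, partner_outside) {
      if (seqv[outside] == comp_chars(seqv[partner_outside])) {
        seqv[outside] <- sample(
          setdiff(c("A", "C", "G", "T"),
                  c(comp_chars(seqv[partner_outside]), seqv[outside])), 1L)
      }
      seqv
    }
    seqv <- fix_junction(seqv, arcs$IRb[1] - 1L, arcs$IRa[2] %% n + 1L)
    seqv <- fix_junction(seqv, arcs$IRb[2] + 1L, arcs$IRa[1] - 1L)
    seqv <- suppress_ssrs(seqv, thresholds, mirror)

    # --- annotation ---------------------------------------------------
    scale <- min(1, n / 60000)
    n_lsc_genes <- max(6L, round(config$n_genes * 0.62))
    n_ir_genes <- max(2L, round(config$n_genes * 0.14))
    n_ssc_genes <- max(3L, round(config$n_genes * 0.24))
    hs <- config$hotspots
    hs_pairs_lsc <- character(); hs_pairs_ssc <- character()
    hs_width <- 900L
    if (!is.null(hs)) {
      hs_pairs_lsc <- paste(hs$name_a[hs$region == "LSC"],
                            hs$name_b[hs$region == "LSC"])
      hs_pairs_ssc <- paste(hs$name_a[hs$region == "SSC"],
                            hs$name_b[hs$region == "SSC"])
      hs_width <- hs$width[1L]
    }
    pick_pool <- function(pool, k, needed) {
      k <- min(k, length(pool))
      sel <- sort(unique(c(match(needed, pool),
                           round(seq(1, length(pool), length.out = k)))))
      pool[sel[!is.na(sel)]]
    }
    needed_lsc <- unlist(strsplit(hs_pairs_lsc, " "))
    needed_ssc <- unlist(strsplit(hs_pairs_ssc, " "))
    ok <- TRUE
    lay <- tryCatch({
      lsc_lay <- layout_genes(pick_pool(LSC_GENE_POOL, n_lsc_genes, needed_lsc),
                              arcs$LSC, hs_pairs_lsc, hs_width, scale)
      ir_lay <- layout_genes(pick_pool(IR_GENE_POOL, n_ir_genes, character()),
                             arcs$IRb, character(), hs_width, scale)
      ssc_lay <- layout_genes(pick_pool(SSC_GENE_POOL, n_ssc_genes, needed_ssc),
                              arcs$SSC, hs_pairs_ssc, hs_width, scale)
      list(lsc = lsc_lay, ir = ir_lay, ssc = ssc_lay)
    }, error = function(e) { ok <<- FALSE; NULL })
    if (!ok) next
    # mirror IRb genes into IRa
    irb_feats <- lay$ir$features
    ira_feats <- irb_feats
    ira_feats$start <- vapply(irb_feats$end, mirror, 0L)
    ira_feats$end <- vapply(irb_feats$start, mirror, 0L)
    ira_feats$strand <- -irb_feats$strand
    features <- rbind(lay$lsc$features, irb_feats, ssc_features <- lay$ssc$features,
                      ira_feats)
    hotspots <- rbind(lay$lsc$hotspots, lay$ssc$hotspots)

    # --- plant SSR loci ------------------------------------------------
    rec0 <- plastome_record("ancestor", chars_seq(seqv), features)
    spc <- spacer_intervals(rec0)
    reserved <- rep(FALSE, n)
    jm <- config$junction_margin
    for (a in arcs) {
      reserved[max(1L, a[1] - jm):min(n, a[1] + jm)] <- TRUE
      reserved[max(1L, a[2] - jm):min(n, a[2] + jm)] <- TRUE
    }
    context_mask <- function(context) {
      m <- rep(FALSE, n)
      if (is.na(context) || context == "spacer") {
        lin <- spc[spc$start <= spc$end, , drop = FALSE]
        for (i in seq_len(nrow(lin))) m[lin$start[i]:lin$end[i]] <- TRUE
        if (is.na(context)) m <- rep(TRUE, n)
      } else {
        kinds <- if (context == "exon") c("gene-exon", "tRNA", "rRNA") else "intron"
        f <- features[features$kind %in% kinds, , drop = FALSE]
        for (i in seq_len(nrow(f))) m[f$start[i]:f$end[i]] <- TRUE
      }
      m
    }
    region_mask <- function(region) {
      m <- rep(FALSE, n)
      if (region == "IR") m[arcs$IRb[1]:arcs$IRb[2]] <- TRUE
      else m[arcs[[region]][1]:arcs[[region]][2]] <- TRUE
      m
    }
    plan <- config$ssr_plan
    ssr_rows <- list()
    planted_ok <- TRUE
    for (i in seq_len(nrow(plan))) {
      u <- nchar(plan$motif[i])
      span <- u * plan$copies[i]
      mask <- region_mask(plan$region[i]) &
              context_mask(plan$context[i] %||% NA) & !reserved
      cand <- which(mask)
      placed <- FALSE
      for (try in 1:300) {
        if (!length(cand)) break
        p <- sample(cand, 1L)
        e <- p + span - 1L
        if (e + 2L > n || p < 3L) next
        if (any(reserved[p:(e + 1L)])) next
        motif_chars <- seq_chars(plan$motif[i])
        newseg <- rep(motif_chars, plan$copies[i])
        old <- seqv[(p - 1L):(e + 1L)]
        seqv[p:e] <- newseg
        # guard bases: no extension of the repeat on either side
        gl <- setdiff(c("A", "C", "G", "T"),
                      c(motif_chars[u], seqv[max(1L, p - 2L)]))
        seqv[p - 1L] <- sample(gl, 1L)
        gr <- setdiff(c("A", "C", "G", "T"),
                      c(motif_chars[1L], seqv[min(n, e + 2L)]))
        seqv[e + 1L] <- sample(gr, 1L)
        mp <- mirror(p)
        if (!is.na(mp)) {
          idx <- (p - 1L):(e + 1L)
          seqv[vapply(idx, mirror, 0L)] <- comp_chars(seqv[idx])
        }
        # local acceptance: the window around the locus must contain exactly
        # this locus
        w1 <- max(1L, p - 22L); w2 <- min(n, e + 22L)
        found <- scan_window(seqv[w1:w2], thresholds)
        okloc <- nrow(found) == 1L && found$start == p - w1 + 1L &&
                 found$copy_number == plan$copies[i]
        if (!okloc) {
          seqv[(p - 1L):(e + 1L)] <- old
          if (!is.na(mp)) {
            idx <- (p - 1L):(e + 1L)
            seqv[vapply(idx, mirror, 0L)] <- comp_chars(old)
          }
          next
        }
        reserved[max(1L, p - 26L):min(n, e + 26L)] <- TRUE
        ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
          start = p, end = e, motif = plan$motif[i], copies = plan$copies[i],
          region = plan$region[i], mirrored = FALSE, eligible = TRUE,
          stringsAsFactors = FALSE)
        if (!is.na(mp)) {
          ms <- mirror(e); me <- mirror(p)
          reserved[max(1L, ms - 26L):min(n, me + 26L)] <- TRUE
          ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
            start = ms, end = me, motif = revcomp(plan$motif[i]),
            copies = plan$copies[i], region = plan$region[i], mirrored = TRUE,
            eligible = FALSE, stringsAsFactors = FALSE)
        }
        placed <- TRUE
        break
      }
      if (!placed) { planted_ok <- FALSE; break }
    }
    if (!planted_ok) next
    ssr_loci <- do.call(rbind, ssr_rows)
    ssr_loci$eligible <- ssr_loci$eligible & ssr_loci$region != "IR"

    # --- exact GC adjustment -------------------------------------------
    target_gc <- round(n * gc)
    sc_free <- which(!reserved)
    sc_free <- sc_free[sc_free <= arcs$LSC[2] |
                       (sc_free >= arcs$SSC[1] & sc_free <= arcs$SSC[2])]
    for (gci in 1:4000) {
      cur <- sum(seqv == "G" | seqv == "C")
      if (cur == target_gc) break
      fromset <- if (cur < target_gc) c("A", "T") else c("G", "C")
      toset <- if (cur < target_gc) c("G", "C") else c("A", "T")
      cand <- sc_free[seqv[sc_free] %in% fromset]
      if (!length(cand)) break
      p <- sample(cand, 1L)
      old <- seqv[p]
      seqv[p] <- sample(toset, 1L)
      w1 <- max(1L, p - 14L); w2 <- min(n, p + 14L)
      if (nrow(scan_window(seqv[w1:w2], thresholds))) seqv[p] <- old
    }

    # --- final validation ----------------------------------------------
    found <- scan_ssrs(chars_seq(seqv), thresholds)
    want <- ssr_loci[order(ssr_loci$start), , drop = FALSE]
    same <- nrow(found) == nrow(want) &&
      all(found$start == want$start) && all(found$end == want$end) &&
      all(found$motif == want$motif) && all(found$copy_number == want$copies)
    if (!same) next

    record <- plastome_record("ancestor", chars_seq(seqv), features)
    structure_q <- find_quadripartite(record, min_ir = max(100L, ir_len - 10L))
    stopifnot(structure_q$ir_length == ir_len,
              structure_q$lsc_length == lsc_len,
              structure_q$ssc_length == ssc_len)
    cls <- classify_position(record, structure_q, ssr_loci$start)
    ssr_loci$context <- cls$context
    return(list(record = record, structure = structure_q, ssr_loci = ssr_loci,
                hotspots = hotspots, reserved = reserved, mirror = mirror,
                arcs = arcs, spacers = spc, config = config))
  }
  stop("could not assemble a clean ancestor after 6 attempts")
}
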