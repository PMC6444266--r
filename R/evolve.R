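# Synthetic quartet generator: event planting, true alignment, truth ledger.

# bases an SNP of a given class can start from, and the derived base.
# reversed = TRUE gives the (ancestor, derived) pairs whose *called*
# direction (majority -> variant, ties broken toward the reference allele)
# equals the class — used when the derived subset contains the reference and
# ties the majority vote.
snp_base_options <- function(class, reversed = FALSE) {
  opts <- switch(class,
    "A>G/T>C" = rbind(c("A", "G"), c("T", "C")),
    "G>A/C>T" = rbind(c("G", "A"), c("C", "T")),
    "A>C/T>G" = rbind(c("A", "C"), c("T", "G")),
    "C>A/G>T" = rbind(c("C", "A"), c("G", "T")),
    "A>T/T>A" = rbind(c("A", "T"), c("T", "A")),
    "G>C/C>G" = rbind(c("G", "C"), c("C", "G")),
    stop("unknown substitution class: ", class))
  if (reversed) opts[, 2:1, drop = FALSE] else opts
}

# does substituting `to` at position p (in the given taxon subset) create a
# pattern the inversion caller would accept? Only complement substitutions
# (A<->T, C<->G) in an odd-width self-reverse-complementary context can.
snp_mimics_inversion <- function(seqv, p, to, min_flank = 3L, max_len = 6L) {
  if (to != comp_chars(seqv[p])) return(FALSE)
  n <- length(seqv)
  for (w in c(3L, 5L)) {
    if (w > max_len) next
    h <- (w - 1L) %/% 2L
    a <- p - h; b <- p + h
    if (a < 1L || b > n) next
    seg_ok <- TRUE
    for (i in seq_len(h)) {
      if (seqv[a + i - 1L] != comp_chars(seqv[b - i + 1L])) {
        seg_ok <- FALSE; break
      }
    }
    if (!seg_ok) next
    fl <- 0L
    while (fl < min_flank && a - fl - 1L >= 1L && b + fl + 1L <= n &&
           seqv[a - fl - 1L] == comp_chars(seqv[b + fl + 1L])) fl <- fl + 1L
    if (fl >= min_flank) return(TRUE)
  }
  FALSE
}

# sample a start position of `width` bases where mask & avail hold over the
# whole footprint; NULL when impossible
sample_site <- function(avail, mask, width, tries = 400L) {
  cand <- which(mask & avail)
  if (!length(cand)) return(NULL)
  for (i in seq_len(min(tries, 4L * length(cand)))) {
    p <- cand[sample.int(length(cand), 1L)]
    e <- p + width - 1L
    if (e > length(avail)) next
    if (all(avail[p:e] & mask[p:e])) return(p)
  }
  NULL
}

#' Evolve a quartet of plastomes from an ancestor
#'
#' Applies the event plan of `config$events` (plus concentrated hotspot SNPs
#' if configured): SNPs drawn per six-class plan, SSR-indels that change a
#' planted SSR locus's copy number, NR-indels inserting/deleting
#' non-repetitive sequence, and small inversions planted with exact
#' inverted-repeat flanks. Events are mutually isolated (>= 10 bp apart), so
#' the true alignment is built by construction; events planted in the IR are
#' mirrored into both copies to preserve IR identity. After planting, each
#' mutant genome is validated against the expected SSR content.
#'
#' @param anc output of [generate_ancestor()].
#' @param config the [sim_config()] used to build `anc`.
#' @return list with `records` (named list of per-taxon
#'   [plastome_record()]s), `alignment` (an [alignment_set()]), and `ledger`
#'   (class `TruthLedger`).
#' @export
evolve_quartet <- function(anc, config) {
  n <- config$genome_length
  taxa <- config$taxa
  ref <- config$reference
  k <- length(taxa)
  thresholds <- config$thresholds
  seqv <- seq_chars(anc$record$sequence)
  avail <- !anc$reserved
  arcs <- anc$arcs
  gc <- config$gc

  region_mask <- function(region) {
    m <- rep(FALSE, n)
    if (is.na(region)) {
      m[arcs$LSC[1]:arcs$LSC[2]] <- TRUE
      m[arcs$SSC[1]:arcs$SSC[2]] <- TRUE
    } else if (region == "IR") {
      m[arcs$IRb[1]:arcs$IRb[2]] <- TRUE
    } else m[arcs[[region]][1]:arcs[[region]][2]] <- TRUE
    m
  }
  feature_mask <- function(fname, context) {
    f <- anc$record$features
    m <- rep(FALSE, n)
    if (!is.na(fname)) {
      rows <- f[f$name == fname, , drop = FALSE]
      if (!is.na(context)) {
        kinds <- if (context == "intron") "intron" else c("gene-exon", "tRNA", "rRNA")
        rows <- rows[rows$kind %in% kinds, , drop = FALSE]
      }
      if (!nrow(rows)) {
        sp <- anc$spacers
        sp <- sp[sp$name == fname & sp$start <= sp$end, , drop = FALSE]
        if (!nrow(sp)) stop("no feature or spacer named '", fname, "'")
        rows <- sp
      }
      for (i in seq_len(nrow(rows))) m[rows$start[i]:rows$end[i]] <- TRUE
    } else if (!is.na(context)) {
      if (context == "spacer") {
        sp <- anc$spacers[anc$spacers$start <= anc$spacers$end, , drop = FALSE]
        for (i in seq_len(nrow(sp))) m[sp$start[i]:sp$end[i]] <- TRUE
      } else {
        kinds <- if (context == "intron") "intron" else c("gene-exon", "tRNA", "rRNA")
        rows <- f[f$kind %in% kinds, , drop = FALSE]
        for (i in seq_len(nrow(rows))) m[rows$start[i]:rows$end[i]] <- TRUE
      }
    } else m[] <- TRUE
    m
  }
  reserve <- function(p1, p2) {
    avail[max(1L, p1 - 10L):min(n, p2 + 10L)] <<- FALSE
  }
  local_clean <- function(p1, p2, taxon_seqv) {
    w1 <- max(1L, p1 - 20L); w2 <- min(n, p2 + 20L)
    nrow(scan_window(taxon_seqv[w1:w2], thresholds)) == 0L
  }

  ev_in <- config$events
  # expand hotspot SNP quotas into ordinary SNP events constrained to the
  # hotspot interval
  if (!is.null(config$hotspots) && !is.null(anc$hotspots)) {
    hs <- config$hotspots
    extra <- list()
    for (i in seq_len(nrow(hs))) {
      nm <- paste0(hs$name_a[i], "-", hs$name_b[i])
      if (!nm %in% anc$hotspots$name) stop("hotspot spacer not laid out: ", nm)
      nsnp <- hs$extra_snps[i]
      if (nsnp == 0L) next
      classes <- sample(SUBSTITUTION_CLASSES, nsnp, replace = TRUE,
                        prob = c(0.27, 0.26, 0.15, 0.14, 0.1, 0.08))
      extra[[i]] <- data.frame(type = "snp", taxa = hs$taxon[i],
                               class = classes, region = hs$region[i],
                               context = NA, feature = nm, hotspot = nm,
                               delta = NA, kind = NA, length = NA, flank = NA,
                               stringsAsFactors = FALSE)
    }
    ev_in <- rbind(ev_in, do.call(rbind, extra))
  }
  ord <- order(match(ev_in$type, c("inversion", "nr_indel", "ssr_indel", "snp")))
  ev_in <- ev_in[ord, , drop = FALSE]
  # hotspot SNPs are placed stratified across the hotspot interval so that
  # every full window inside the hotspot stays above the diversity threshold
  hs_total <- table(ev_in$hotspot[ev_in$type == "snp" & !is.na(ev_in$hotspot)])
  hs_seen <- stats::setNames(rep(0L, length(hs_total)), names(hs_total))

  mut <- list()       # per-taxon substitution/inversion edits on ancestor coords
  for (t in taxa) mut[[t]] <- list()
  del_events <- list()  # (taxa, p1, p2)
  ins_events <- list()  # (taxa, anchor, seq)
  ledger_rows <- list()
  snp_positions <- integer()   # background dispersion guard
  used_loci <- integer()
  eligible_loci <- which(anc$ssr_loci$eligible)

  add_ledger <- function(...) {
    ledger_rows[[length(ledger_rows) + 1L]] <<- data.frame(
      ..., stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(ev_in))) {
    ev <- ev_in[i, ]
    tx <- strsplit(ev$taxa, ",", fixed = TRUE)[[1]]
    stopifnot(all(tx %in% taxa))

    if (ev$type == "inversion") {
      w <- ev$length; fl <- ev$flank
      W <- w + 2L * fl + 2L
      mask <- region_mask(ev$region) & feature_mask(ev$feature, ev$context)
      placed <- FALSE
      for (try in 1:300) {
        p <- sample_site(avail, mask, W)
        if (is.null(p)) break
        guardL <- p; guardR <- p + W - 1L
        f1 <- p + 1L; x1 <- f1 + fl; x2 <- x1 + w - 1L; f2e <- x2 + fl
        old <- seqv[guardL:guardR]
        Fl <- rand_bases(fl, gc)
        X <- rand_bases(w, gc); X[1L] <- "A"; X[w] <- "G"
        seqv[f1:(x1 - 1L)] <- Fl
        seqv[x1:x2] <- X
        seqv[(x2 + 1L):f2e] <- rev(comp_chars(Fl))
        # guard bases stop both the stem extension and repeat runs
        gL <- setdiff(c("A", "C", "G", "T"),
                      c(comp_chars(seqv[f2e + 1L]), seqv[p - 1L]))
        seqv[guardL] <- sample(gL, 1L)
        gR <- setdiff(c("A", "C", "G", "T"),
                      c(comp_chars(seqv[guardL]), seqv[guardR + 1L]))
        seqv[guardR] <- sample(gR, 1L)
        if (!local_clean(guardL, guardR, seqv)) {
          seqv[guardL:guardR] <- old
          next
        }
        reserve(guardL, guardR)
        for (t in tx) {
          mut[[t]][[length(mut[[t]]) + 1L]] <-
            list(kind = "inv", p1 = x1, p2 = x2)
        }
        add_ledger(type = "inversion", taxa = ev$taxa, anc_start = x1,
                   anc_end = x2, class = NA, from = NA, to = NA, motif = NA,
                   seq = chars_seq(X), length = w, flank = fl,
                   polarity = NA, classification = NA, mirror = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place inversion event ", i)

    } else if (ev$type == "nr_indel") {
      len <- ev$length
      mask <- region_mask(ev$region) & feature_mask(ev$feature, ev$context)
      placed <- FALSE
      for (try in 1:300) {
        if (ev$kind == "del") {
          p <- sample_site(avail, mask, len)
          if (is.null(p)) break
          removed <- seqv[p:(p + len - 1L)]
          # junction after deletion must not create a repeat, and the
          # removed sequence must not classify as an SSR-indel
          junct <- c(seqv[max(1L, p - 20L):(p - 1L)],
                     seqv[(p + len):min(n, p + len + 19L)])
          if (nrow(scan_window(junct, thresholds)) > 0L) next
          if (is_ssr_like(chars_seq(removed), seqv, p, p + len - 1L,
                          thresholds)) next
          reserve(p, p + len - 1L)
          del_events[[length(del_events) + 1L]] <-
            list(taxa = tx, p1 = p, p2 = p + len - 1L)
          add_ledger(type = "indel", taxa = ev$taxa, anc_start = p,
                     anc_end = p + len - 1L, class = NA, from = NA, to = NA,
                     motif = NA, seq = chars_seq(removed), length = len,
                     flank = NA,
                     polarity = if (length(tx) < k - length(tx)) "deletion"
                                else if (length(tx) > k - length(tx)) "insertion"
                                else "unresolved",
                     classification = "NR-indel", mirror = FALSE)
          placed <- TRUE
        } else {
          p <- sample_site(avail, mask, 1L)
          if (is.null(p)) break
          content <- rand_bases(len, gc)
          widened <- c(seqv[max(1L, p - 19L):p], content,
                       seqv[(p + 1L):min(n, p + 20L)])
          if (nrow(scan_window(widened, thresholds)) > 0L) next
          if (is_ssr_like_inserted(content, seqv, p, thresholds)) next
          reserve(p, p)
          ins_events[[length(ins_events) + 1L]] <-
            list(taxa = tx, anchor = p, seq = content)
          add_ledger(type = "indel", taxa = ev$taxa, anc_start = p,
                     anc_end = p, class = NA, from = NA, to = NA, motif = NA,
                     seq = chars_seq(content), length = len, flank = NA,
                     polarity = if (length(tx) < k - length(tx)) "insertion"
                                else if (length(tx) > k - length(tx)) "deletion"
                                else "unresolved",
                     classification = "NR-indel", mirror = FALSE)
          placed <- TRUE
        }
        if (placed) break
      }
      if (!placed) stop("could not place NR-indel event ", i)

    } else if (ev$type == "ssr_indel") {
      pool <- setdiff(eligible_loci, used_loci)
      delta <- ev$delta
      # slippage is planted on mono/di loci only, matching the unit-length
      # convention of the SSR-indel classifier
      pool <- pool[nchar(anc$ssr_loci$motif[pool]) <= 2L]
      pool <- pool[anc$ssr_loci$copies[pool] + delta >= 1L]
      if (!is.na(ev$region)) pool <- pool[anc$ssr_loci$region[pool] == ev$region]
      if (!length(pool)) stop("no eligible SSR locus left for event ", i)
      li <- if (length(pool) == 1L) pool else sample(pool, 1L)
      used_loci <- c(used_loci, li)
      loc <- anc$ssr_loci[li, ]
      u <- nchar(loc$motif)
      if (delta > 0L) {
        ins_events[[length(ins_events) + 1L]] <-
          list(taxa = tx, anchor = loc$end,
               seq = rep(seq_chars(loc$motif), delta))
        p1 <- loc$end; p2 <- loc$end
      } else {
        p1 <- loc$end + delta * u + 1L
        p2 <- loc$end
        del_events[[length(del_events) + 1L]] <- list(taxa = tx, p1 = p1, p2 = p2)
      }
      add_ledger(type = "indel", taxa = ev$taxa, anc_start = p1, anc_end = p2,
                 class = NA, from = NA, to = NA, motif = loc$motif,
                 seq = strrep(loc$motif, abs(delta)), length = abs(delta) * u,
                 flank = NA,
                 polarity = if (delta > 0L) "insertion" else "deletion",
                 classification = "SSR-indel", mirror = FALSE)

    } else if (ev$type == "snp") {
      reversed <- ref %in% tx && length(tx) == k %/% 2L
      opts <- snp_base_options(ev$class, reversed)
      mask <- region_mask(ev$region) & feature_mask(ev$feature, ev$context)
      binmask <- NULL
      if (!is.na(ev$hotspot)) {
        hs_seen[ev$hotspot] <- hs_seen[[ev$hotspot]] + 1L
        hrow <- anc$hotspots[anc$hotspots$name == ev$hotspot, , drop = FALSE]
        if (nrow(hrow) == 1L) {
          Wtot <- hrow$end - hrow$start + 1L
          cnt <- as.integer(hs_total[[ev$hotspot]])
          j <- hs_seen[[ev$hotspot]]
          b1 <- hrow$start + as.integer(floor((j - 1L) * Wtot / cnt))
          b2 <- hrow$start + as.integer(floor(j * Wtot / cnt)) - 1L
          binmask <- rep(FALSE, n)
          binmask[b1:min(b2 + 6L, hrow$end)] <- TRUE
        }
      }
      in_ir <- !is.na(ev$region) && ev$region == "IR"
      placed <- FALSE
      rej <- c(null = 0L, disp = 0L, mimic = 0L, clean = 0L)
      for (try in 1:500) {
        msk <- if (!is.null(binmask) && try <= 250L) mask & binmask else mask
        p <- sample_site(avail, msk & (seqv %in% opts[, 1L]), 1L)
        if (is.null(p)) { rej["null"] <- rej["null"] + 1L; next }
        to <- opts[match(seqv[p], opts[, 1L]), 2L]
        if (is.na(ev$hotspot) &&
            sum(abs(snp_positions - p) <= 300L) >= 4L) {
          rej["disp"] <- rej["disp"] + 1L; next
        }
        if (snp_mimics_inversion(seqv, p, to)) {
          rej["mimic"] <- rej["mimic"] + 1L; next
        }
        tv <- seqv; tv[p] <- to
        if (!local_clean(p, p, tv)) { rej["clean"] <- rej["clean"] + 1L; next }
        mp <- if (in_ir) anc$mirror(p) else NA_integer_
        if (!is.na(mp)) {
          tv[mp] <- comp_chars(to)
          if (snp_mimics_inversion(seqv, mp, comp_chars(to))) next
          if (!local_clean(mp, mp, tv)) next
        }
        reserve(p, p)
        snp_positions <- c(snp_positions, p)
        for (t in tx) {
          mut[[t]][[length(mut[[t]]) + 1L]] <- list(kind = "sub", p1 = p, to = to)
        }
        add_ledger(type = "snp", taxa = ev$taxa, anc_start = p, anc_end = p,
                   class = ev$class, from = seqv[p], to = to, motif = NA,
                   seq = to, length = 1L, flank = NA, polarity = NA,
                   classification = NA, mirror = FALSE)
        if (!is.na(mp)) {
          reserve(mp, mp)
          snp_positions <- c(snp_positions, mp)
          for (t in tx) {
            mut[[t]][[length(mut[[t]]) + 1L]] <-
              list(kind = "sub", p1 = mp, to = comp_chars(to))
          }
          add_ledger(type = "snp", taxa = ev$taxa, anc_start = mp,
                     anc_end = mp, class = ev$class, from = seqv[mp],
                     to = comp_chars(to), motif = NA, seq = comp_chars(to),
                     length = 1L, flank = NA, polarity = NA,
                     classification = NA, mirror = TRUE)
        }
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place SNP event ", i, " (", ev$class, ", feature=",
             ev$feature, ", free=", sum(avail & mask),
             ", compat=", sum(avail & mask & (seqv %in% opts[, 1L])),
             ", rej=", paste(names(rej), rej, sep = ":", collapse = ","), ")")
      }
    } else stop("unknown event type: ", ev$type)
  }

  ## ------------------------------------------------ build the true alignment
  anc_final <- seqv   # ancestor after inversion-site planting
  rows <- matrix(rep(anc_final, k), nrow = k, byrow = TRUE,
                 dimnames = list(taxa, NULL))
  for (t in taxa) {
    for (e in mut[[t]]) {
      if (e$kind == "sub") rows[t, e$p1] <- e$to
      else rows[t, e$p1:e$p2] <- rev(comp_chars(anc_final[e$p1:e$p2]))
    }
  }
  for (e in del_events) for (t in e$taxa) rows[t, e$p1:e$p2] <- "-"

  anchors <- vapply(ins_events, `[[`, 0L, "anchor")
  ins_ord <- order(anchors)
  ins_events <- ins_events[ins_ord]
  anchors <- anchors[ins_ord]
  ins_lens <- vapply(ins_events, function(e) length(e$seq), 0L)
  col_of_anc <- function(q) {
    q + as.integer(if (length(anchors)) sapply(q, function(qq) {
      sum(ins_lens[anchors < qq])
    }) else 0L)
  }
  aligned <- vapply(taxa, function(t) {
    pieces <- character(0)
    prev <- 1L
    for (j in seq_along(ins_events)) {
      a <- anchors[j]
      pieces <- c(pieces, chars_seq(rows[t, prev:a]),
                  if (t %in% ins_events[[j]]$taxa) chars_seq(ins_events[[j]]$seq)
                  else strrep("-", ins_lens[j]))
      prev <- a + 1L
    }
    pieces <- c(pieces, chars_seq(rows[t, prev:n]))
    paste(pieces, collapse = "")
  }, character(1))
  names(aligned) <- taxa
  aln <- alignment_set(aligned, reference_taxon = ref)

  ledger_ev <- if (length(ledger_rows)) do.call(rbind, ledger_rows) else NULL
  if (!is.null(ledger_ev)) {
    ledger_ev$col_start <- col_of_anc(ledger_ev$anc_start)
    ledger_ev$col_end <- col_of_anc(ledger_ev$anc_end)
    # insertion events occupy the inserted columns, after the anchor
    is_ins <- ledger_ev$type == "indel" & ledger_ev$polarity == "insertion" &
              !is.na(ledger_ev$polarity)
    for (j in which(is_ins)) {
      a <- ledger_ev$anc_start[j]
      ji <- which(anchors == a)
      stopifnot(length(ji) == 1L)
      base <- col_of_anc(a)
      ledger_ev$col_start[j] <- base + 1L
      ledger_ev$col_end[j] <- base + ins_lens[ji]
    }
    cl <- classify_position(anc$record, anc$structure, ledger_ev$anc_start)
    ledger_ev$region <- cl$region
    ledger_ev$context <- cl$context
  }

  ## ------------------------------------- per-taxon records and expected SSRs
  records <- list()
  ssr_expected <- list()
  for (t in taxa) {
    gseq <- ungapped_sequence(aln, t)
    feats <- shift_features(anc$record$features, rows[t, ], ins_events, t, n)
    records[[t]] <- plastome_record(t, gseq, feats)
    exp_loci <- anc$ssr_loci
    exp_loci$copies_t <- exp_loci$copies
    # apply this taxon's SSR-indel deltas
    if (!is.null(ledger_ev)) {
      sel <- which(ledger_ev$classification == "SSR-indel" &
                   !is.na(ledger_ev$classification) &
                   vapply(strsplit(ledger_ev$taxa, ","), function(s) t %in% s, TRUE))
      for (j in sel) {
        li <- which(exp_loci$end == ledger_ev$anc_end[j] |
                    exp_loci$end == ledger_ev$anc_start[j] - 1L)
        li <- li[abs(exp_loci$end[li] - ledger_ev$anc_end[j]) <= 2L *
                 nchar(exp_loci$motif[li])]
        stopifnot(length(li) == 1L)
        dl <- ledger_ev$length[j] / nchar(exp_loci$motif[li])
        sgn <- if (ledger_ev$polarity[j] == "insertion") 1L else -1L
        exp_loci$copies_t[li] <- exp_loci$copies_t[li] + sgn * dl
      }
    }
    exp_loci$start_t <- aln$col_to_pos[t, col_of_anc(exp_loci$start)]
    u <- nchar(exp_loci$motif)
    thr <- thresholds[as.character(u)]
    exp_loci <- exp_loci[exp_loci$copies_t >= thr, , drop = FALSE]
    exp_loci$taxon <- t
    ssr_expected[[t]] <- exp_loci
    # validation: the scan must find exactly the expected loci
    found <- scan_ssrs(gseq, thresholds)
    want <- exp_loci[order(exp_loci$start_t), , drop = FALSE]
    if (!(nrow(found) == nrow(want) &&
          all(found$start == want$start_t) &&
          all(found$motif == want$motif) &&
          all(found$copy_number == want$copies_t))) {
      stop("SSR validation failed for taxon ", t)
    }
    stopifnot(ungapped_sequence(aln, t) == records[[t]]$sequence)
  }

  ancestor_record <- plastome_record("ancestor", chars_seq(anc_final),
                                     anc$record$features)
  ledger <- structure(list(
    ancestor = ancestor_record,
    structure = anc$structure,
    taxa = taxa, reference = ref,
    events = ledger_ev,
    ssr_ancestor = anc$ssr_loci,
    ssr_expected = do.call(rbind, ssr_expected),
    hotspots = anc$hotspots,
    alignment = aln,
    config = config), class = "TruthLedger")
  list(records = records, alignment = aln, ledger = ledger)
}

# SSR-indel lookalike test used to keep NR-indels honestly non-repetitive:
# would `affected` (deleted bases) classify as an SSR-indel given the longer
# allele (the ancestor) around [p1, p2]?
is_ssr_like <- function(affected, seqv, p1, p2, thresholds, max_motif = 2L) {
  L <- nchar(affected)
  for (u in seq_len(min(max_motif, L))) {
    if (L %% u != 0L) next
    unit <- substr(affected, 1L, u)
    if (strrep(unit, L %/% u) != affected) next
    if (minimal_period(unit) != u) next
    g <- chars_seq(seqv)
    left <- p1
    while (left - u >= 1L &&
           substr(g, left - u, left - 1L) == substr(g, left, left + u - 1L)) {
      left <- left - u
    }
    right <- p1
    while (right + 2L * u - 1L <= nchar(g) &&
           substr(g, right + u, right + 2L * u - 1L) ==
           substr(g, right, right + u - 1L)) right <- right + u
    copies <- (right + u - left) %/% u
    if (copies >= thresholds[[as.character(u)]]) return(TRUE)
  }
  FALSE
}

# same test for an insertion: longer allele = ancestor with content spliced
# in after anchor p
is_ssr_like_inserted <- function(content, seqv, p, thresholds, max_motif = 2L) {
  n <- length(seqv)
  w1 <- max(1L, p - 25L)
  allele <- c(seqv[w1:p], content, seqv[min(n, p + 1L):min(n, p + 25L)])
  pos <- p - w1 + 2L  # first inserted base within `allele`
  is_ssr_like(chars_seq(content), allele, pos, pos + length(content) - 1L,
              thresholds)
}

# shift annotation intervals into a mutant taxon's coordinates using its
# gapped row (ancestor coordinates) and the insertion events
shift_features <- function(features, row_t, ins_events, taxon, n) {
  if (!nrow(features)) return(features)
  kept <- row_t != "-"
  newpos <- cumsum(kept)
  ins_before <- rep(0L, n + 1L)
  for (e in ins_events) {
    if (taxon %in% e$taxa) {
      ins_before[(e$anchor + 1L):(n + 1L)] <-
        ins_before[(e$anchor + 1L):(n + 1L)] + length(e$seq)
    }
  }
  # first kept base at or after start; last kept base at or before end
  f <- features
  starts <- integer(nrow(f)); ends <- integer(nrow(f)); drop <- logical(nrow(f))
  kept_idx <- which(kept)
  for (i in seq_len(nrow(f))) {
    a <- f$start[i]; b <- f$end[i]
    ka <- kept_idx[kept_idx >= a]
    kb <- kept_idx[kept_idx <= b]
    if (!length(ka) || !length(kb) || ka[1L] > b) { drop[i] <- TRUE; next }
    a2 <- ka[1L]; b2 <- kb[length(kb)]
    starts[i] <- newpos[a2] + ins_before[a2]
    ends[i] <- newpos[b2] + ins_before[b2]
  }
  f$start <- starts; f$end <- ends
  f <- f[!drop, , drop = FALSE]
  rownames(f) <- NULL
  f
}

#' Generate a full synthetic quartet
#'
#' Seeds the RNG, builds the ancestor, evolves the four taxa, and returns
#' records, true alignment and truth ledger. Retries the stochastic
#' construction a few times if a validation check rejects a draw.
#'
#' @param config a [sim_config()].
#' @return list with `ancestor`, `structure`, `records`, `alignment`,
#'   `ledger`, `config`.
#' @export
simulate_quartet <- function(config) {
  for (attempt in 0:4) {
    set.seed(config$seed + attempt * 100003L)
    res <- tryCatch({
      anc <- generate_ancestor(config)
      ev <- evolve_quartet(anc, config)
      list(ancestor = anc$record, structure = anc$structure,
           records = ev$records, alignment = ev$alignment,
           ledger = ev$ledger, config = config)
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
  }
  stop("simulation failed after retries: ", conditionMessage(res))
}

#' Replay a truth ledger onto its ancestor
#'
#' Applies every recorded event to the ancestor sequence, taxon by taxon,
#' independently of the alignment machinery. Used to verify that the ledger
#' reproduces the simulated genomes bit-exactly.
#'
#' @param ledger a `TruthLedger`.
#' @return named character vector of reconstructed genome sequences.
#' @export
replay_ledger <- function(ledger) {
  ev <- ledger$events
  anc <- ledger$ancestor$sequence
  out <- character(0)
  for (t in ledger$taxa) {
    s <- anc
    if (!is.null(ev)) {
      mine <- ev[vapply(strsplit(ev$taxa, ","), function(x) t %in% x, TRUE), ,
                 drop = FALSE]
      mine <- mine[order(-mine$anc_start), , drop = FALSE]
      for (j in seq_len(nrow(mine))) {
        e <- mine[j, ]
        if (e$type == "snp") {
          substr(s, e$anc_start, e$anc_start) <- e$to
        } else if (e$type == "inversion") {
          s <- paste0(substr(s, 1L, e$anc_start - 1L), revcomp(e$seq),
                      substr(s, e$anc_end + 1L, nchar(s)))
        } else if (e$polarity == "insertion") {
          s <- paste0(substr(s, 1L, e$anc_start), e$seq,
                      substr(s, e$anc_start + 1L, nchar(s)))
        } else {
          s <- paste0(substr(s, 1L, e$anc_start - 1L),
                      substr(s, e$anc_end + 1L, nchar(s)))
        }
      }
    }
    out[t] <- s
  }
  out
}
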