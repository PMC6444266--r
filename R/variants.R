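# Variant calling from a plastome multiple alignment: SNP sites with the
# six-class non-strand-specific substitution spectrum, indel events with
# SSR/NR classification and polarity, and small inversions verified by
# inverted-repeat flanks. Every variable alignment column is attributed to
# exactly one event type: gap columns belong to indels, columns inside an
# accepted inversion segment belong to that inversion, all remaining
# variable gap-free columns are SNPs.

# The six directed substitution classes, collapsed over strand complement.
SUBSTITUTION_CLASSES <- c("A>G/T>C", "G>A/C>T", "A>C/T>G",
                          "C>A/G>T", "A>T/T>A", "G>C/C>G")
TRANSITION_CLASSES <- SUBSTITUTION_CLASSES[1:2]

#' Substitution class of a directed base change
#'
#' @param from,to ancestral and derived bases (vectors of "A","C","G","T").
#' @return one of the six non-strand-specific class labels; a change and its
#'   reverse complement map to the same class.
#' @export
substitution_class <- function(from, to) {
  key <- paste0(from, to)
  ckey <- paste0(comp_chars(from), comp_chars(to))
  map <- c(AG = "A>G/T>C", TC = "A>G/T>C",
           GA = "G>A/C>T", CT = "G>A/C>T",
           AC = "A>C/T>G", TG = "A>C/T>G",
           CA = "C>A/G>T", GT = "C>A/G>T",
           AT = "A>T/T>A", TA = "A>T/T>A",
           GC = "G>C/C>G", CG = "G>C/C>G")
  out <- map[key]
  if (any(is.na(out))) stop("invalid substitution: ", key[is.na(out)][1])
  stopifnot(identical(unname(out), unname(map[ckey])))  # strand symmetry
  unname(out)
}

#' Is a substitution class a transition?
#' @param class class label from [substitution_class()].
#' @return logical.
#' @export
is_transition <- function(class) class %in% TRANSITION_CLASSES

## ------------------------------------------------------------------- SNPs --

#' Call SNP sites from an alignment
#'
#' A SNP site is any gap-free, N-free alignment column with at least two
#' alleles. Each variant (non-majority) allele at a site contributes one
#' directed substitution from the majority allele (ties broken toward the
#' reference allele, then alphabetically) to the variant allele, collapsed
#' by strand complement into the six classes.
#'
#' @param aln an [alignment_set()].
#' @param structure optional `QuadripartiteStructure` of the reference for
#'   per-region tallies.
#' @param exclude_columns columns to skip (used to remove columns already
#'   attributed to inversion events).
#' @return list with `sites` (data.frame: `column`, `ref_position`,
#'   `alleles`, `majority`, `variant`, `class`, `transition`, `region`) and
#'   `summary` (per-class counts, `ts`, `tv`, `tv_ts_ratio`, per-region site
#'   counts, pairwise difference counts).
#' @export
call_snps <- function(aln, structure = NULL, exclude_columns = integer()) {
  m <- aln$matrix
  k <- nrow(m)
  gapfree <- colSums(m == "-" | m == "N") == 0L
  variable <- gapfree & matrixStats_colAnyDiff(m)
  if (!any(gapfree)) warning("no gap-free columns in alignment")
  use <- setdiff(which(variable), exclude_columns)
  ref_allele <- m[aln$reference_taxon, ]
  rows <- list()
  for (cc in use) {
    al <- m[, cc]
    t <- table(al)
    mx <- max(t)
    cand <- names(t)[t == mx]
    maj <- if (ref_allele[cc] %in% cand) ref_allele[cc] else sort(cand)[1L]
    for (va in sort(setdiff(names(t), maj))) {
      rows[[length(rows) + 1L]] <- data.frame(
        column = cc,
        alleles = paste(al, collapse = ""),
        majority = maj, variant = va,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(), alleles = character(),
               majority = character(), variant = character(),
               stringsAsFactors = FALSE)
  if (nrow(sites)) {
    sites$ref_position <- ref_position_of(aln, sites$column)
    sites$class <- substitution_class(sites$majority, sites$variant)
    sites$transition <- is_transition(sites$class)
    sites$region <- if (!is.null(structure)) {
      region_of(structure, sites$ref_position)
    } else NA_character_
  } else {
    sites$ref_position <- integer()
    sites$class <- character()
    sites$transition <- logical()
    sites$region <- character()
  }
  class_counts <- vapply(SUBSTITUTION_CLASSES,
                         function(cl) sum(sites$class == cl), 0L)
  ts <- sum(sites$transition)
  tv <- nrow(sites) - ts
  region_counts <- if (nrow(sites) && !is.null(structure)) {
    vapply(c("LSC", "IR", "SSC"),
           function(r) length(unique(sites$column[sites$region == r])), 0L)
  } else c(LSC = NA_integer_, IR = NA_integer_, SSC = NA_integer_)
  # pairwise difference counts over gap-free columns
  taxa <- aln$taxa
  pairs <- utils::combn(taxa, 2L)
  pw <- apply(pairs, 2L, function(p) {
    sum(m[p[1], gapfree] != m[p[2], gapfree])
  })
  pairwise <- data.frame(taxon_a = pairs[1, ], taxon_b = pairs[2, ],
                         differences = as.integer(pw),
                         stringsAsFactors = FALSE)
  list(sites = sites,
       summary = list(
         n_sites = length(unique(sites$column)),
         n_substitutions = nrow(sites),
         class_counts = class_counts,
         ts = ts, tv = tv,
         tv_ts_ratio = tv_ts_ratio(ts, tv),
         region_counts = region_counts,
         pairwise = pairwise))
}

# TRUE per column if any row differs from the first row
matrixStats_colAnyDiff <- function(m) {
  d <- m[1L, ]
  out <- rep(FALSE, ncol(m))
  for (i in 2:nrow(m)) out <- out | (m[i, ] != d)
  out
}

#' Transversion/transition ratio
#'
#' @param ts,tv transition and transversion counts.
#' @return `tv / ts` rounded to two decimals (`NA` when `ts` is 0).
#' @export
tv_ts_ratio <- function(ts, tv) {
  if (ts == 0) return(NA_real_)
  round(tv / ts, 2)
}

## ------------------------------------------------------------------ indels --

#' Call indel events from an alignment
#'
#' Maximal runs of columns sharing an identical gap pattern become one
#' event. Polarity is "insertion" when the taxa bearing sequence are the
#' minority, "deletion" when the taxa bearing gaps are the minority, and
#' "unresolved" on ties. An event is an SSR-indel when the inserted/deleted
#' sequence is a whole number of copies of a unit of length <= `max_motif`
#' AND the longer allele carries a perfect run of that unit covering the
#' indel site with at least the copy-number threshold used by the SSR scan;
#' otherwise it is an NR-indel.
#'
#' @param aln an [alignment_set()].
#' @param thresholds SSR thresholds, see [default_ssr_thresholds()].
#' @param max_motif longest repeat unit considered for SSR-indels (default 2).
#' @param reference_record optional [plastome_record()] of the reference for
#'   context labels; `structure` for region labels.
#' @param structure optional `QuadripartiteStructure` of the reference.
#' @return data.frame with one row per event: `col_start`, `col_end`,
#'   `ref_position`, `length`, `affected_sequence`, `taxa_with_gap`,
#'   `polarity`, `classification`, `ssr_motif`, `private_taxon`, `region`,
#'   `context`.
#' @export
call_indels <- function(aln, thresholds = default_ssr_thresholds(),
                        max_motif = 2L, reference_record = NULL,
                        structure = NULL) {
  thresholds <- check_thresholds(thresholds)
  m <- aln$matrix
  k <- nrow(m)
  gap <- m == "-"
  pattern <- as.integer(colSums(gap * 2L^(seq_len(k) - 1L)))
  r <- rle(pattern)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L & r$values < 2L^k - 1L
  events <- list()
  for (i in which(keep)) {
    c1 <- starts[i]; c2 <- ends[i]
    gap_taxa <- aln$taxa[gap[, c1]]
    seq_taxa <- setdiff(aln$taxa, gap_taxa)
    carrier <- if (aln$reference_taxon %in% seq_taxa) aln$reference_taxon
               else seq_taxa[1L]
    affected <- chars_seq(m[carrier, c1:c2])
    n_gap <- length(gap_taxa); n_seq <- k - n_gap
    polarity <- if (n_seq < n_gap) "insertion"
                else if (n_gap < n_seq) "deletion"
                else "unresolved"
    cls <- classify_indel(aln, carrier, c1, c2, affected, thresholds, max_motif)
    ref_pos <- ref_position_of(aln, c1)
    events[[length(events) + 1L]] <- data.frame(
      col_start = c1, col_end = c2, ref_position = ref_pos,
      length = c2 - c1 + 1L, affected_sequence = affected,
      taxa_with_gap = paste(gap_taxa, collapse = ","),
      polarity = polarity,
      classification = cls$classification, ssr_motif = cls$motif,
      private_taxon = if (n_gap == 1L) gap_taxa
                      else if (n_seq == 1L) seq_taxa else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(col_start = integer(), col_end = integer(),
               ref_position = integer(), length = integer(),
               affected_sequence = character(), taxa_with_gap = character(),
               polarity = character(), classification = character(),
               ssr_motif = character(), private_taxon = character(),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (!is.null(reference_record)) {
      cl <- classify_position(reference_record, structure, out$ref_position)
      out$region <- cl$region
      out$context <- cl$context
    } else if (!is.null(structure)) {
      out$region <- region_of(structure, out$ref_position)
      out$context <- NA_character_
    } else {
      out$region <- NA_character_
      out$context <- NA_character_
    }
  } else {
    out$region <- character(); out$context <- character()
  }
  rownames(out) <- NULL
  out
}

# SSR-indel test: affected sequence is t >= 1 copies of unit `motif`
# (minimal period), and in the carrier's ungapped genome the run of that
# unit covering the indel site has >= threshold copies.
classify_indel <- function(aln, carrier, c1, c2, affected, thresholds,
                           max_motif) {
  L <- nchar(affected)
  if (grepl("N", affected, fixed = TRUE)) {
    return(list(classification = "NR-indel", motif = NA_character_))
  }
  for (u in seq_len(min(max_motif, L))) {
    if (L %% u != 0L) next
    unit <- substr(affected, 1L, u)
    if (strrep(unit, L %/% u) != affected) next
    if (minimal_period(unit) != u) next
    # count copies of the run covering the site in the longer allele
    g <- ungapped_sequence(aln, carrier)
    pos <- aln$col_to_pos[carrier, c1]   # first affected base, carrier coords
    left <- pos
    while (left - u >= 1L &&
           substr(g, left - u, left - 1L) ==
           substr(g, left, left + u - 1L)) left <- left - u
    right <- pos
    while (right + 2L * u - 1L <= nchar(g) &&
           substr(g, right + u, right + 2L * u - 1L) ==
           substr(g, right, right + u - 1L)) right <- right + u
    copies <- (right + u - left) %/% u
    if (copies >= thresholds[[as.character(u)]]) {
      return(list(classification = "SSR-indel", motif = unit))
    }
  }
  list(classification = "NR-indel", motif = NA_character_)
}

## --------------------------------------------------------------- inversions --

#' Call small inversions from an alignment
#'
#' Clusters of nearby variable gap-free columns are tested as candidate
#' inverted segments: a segment of width `min_len`..`max_len` is an
#' inversion if, for some taxon bipartition, reverse-complementing one
#' side's segment makes it identical to the other side's AND the immediate
#' flanks (identical and gap-free in all taxa) contain an inverted repeat of
#' at least `min_flank` bases ending exactly at the segment boundaries (the
#' hairpin stem). The smaller taxon subset is reported as inverted; on ties
#' the subset excluding the reference. Columns absorbed by an inversion
#' must be removed from the SNP list by the caller (see [call_variants()]).
#'
#' @param aln an [alignment_set()].
#' @param min_len,max_len inversion segment bounds in bp (defaults 2 and 6).
#' @param min_flank,max_flank stem (inverted-repeat flank) bounds in bp
#'   (defaults 3 and 20).
#' @param structure optional reference `QuadripartiteStructure`.
#' @param reference_record optional reference record for context labels.
#' @return data.frame: `col_start`, `col_end`, `ref_start`, `ref_end`,
#'   `length`, `flank_repeat_length`, `inverted_taxa`, `segment`,
#'   `inverted_segment`, `stem_loop`, `region`, `context`.
#' @export
call_inversions <- function(aln, min_len = 2L, max_len = 6L, min_flank = 3L,
                            max_flank = 20L, structure = NULL,
                            reference_record = NULL) {
  m <- aln$matrix
  k <- nrow(m)
  taxa <- aln$taxa
  gapfree <- colSums(m == "-" | m == "N") == 0L
  variable <- gapfree & matrixStats_colAnyDiff(m)
  var_cols <- which(variable)
  events <- list()
  if (length(var_cols)) {
    # cluster variable columns closer than max_len
    brk <- c(0L, which(diff(var_cols) >= max_len), length(var_cols))
    for (ci in seq_len(length(brk) - 1L)) {
      cl_cols <- var_cols[(brk[ci] + 1L):brk[ci + 1L]]
      ev <- test_inversion_cluster(aln, cl_cols, min_len, max_len,
                                   min_flank, max_flank)
      if (!is.null(ev)) events[[length(events) + 1L]] <- ev
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(col_start = integer(), col_end = integer(),
               ref_start = integer(), ref_end = integer(), length = integer(),
               flank_repeat_length = integer(), inverted_taxa = character(),
               segment = character(), inverted_segment = character(),
               stem_loop = logical(), stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (!is.null(reference_record)) {
      cl <- classify_position(reference_record, structure, out$ref_start)
      out$region <- cl$region
      out$context <- cl$context
    } else if (!is.null(structure)) {
      out$region <- region_of(structure, out$ref_start)
      out$context <- NA_character_
    } else {
      out$region <- NA_character_; out$context <- NA_character_
    }
  } else {
    out$region <- character(); out$context <- character()
  }
  rownames(out) <- NULL
  out
}

# try all candidate segments and bipartitions for one cluster of variable
# columns; returns a one-row data.frame or NULL
test_inversion_cluster <- function(aln, cl_cols, min_len, max_len,
                                   min_flank, max_flank) {
  m <- aln$matrix
  k <- nrow(m)
  taxa <- aln$taxa
  span_a <- min(cl_cols); span_b <- max(cl_cols)
  span <- span_b - span_a + 1L
  if (span > max_len) return(NULL)
  gap_or_n <- colSums(m == "-" | m == "N") > 0L
  best <- NULL
  for (w in max(span, min_len):max_len) {
    for (a in (span_b - w + 1L):span_a) {
      b <- a + w - 1L
      if (a < 1L || b > aln$ncol) next
      if (any(gap_or_n[a:b])) next
      seg <- m[, a:b, drop = FALSE]
      # group taxa by their segment string
      segs <- apply(seg, 1L, paste, collapse = "")
      us <- unique(segs)
      if (length(us) != 2L) next
      if (us[1] != revcomp(us[2])) next
      set1 <- taxa[segs == us[1]]
      set2 <- taxa[segs == us[2]]
      # flanks must be identical and gap-free in all taxa
      fl <- flank_repeat_length(aln, a, b, max_flank)
      if (fl < min_flank) next
      inv <- if (length(set1) < length(set2)) set1
             else if (length(set2) < length(set1)) set2
             else if (aln$reference_taxon %in% set1) set2 else set1
      ref_a <- ref_position_of(aln, a)
      ref_b <- ref_position_of(aln, b)
      cand <- data.frame(
        col_start = a, col_end = b, ref_start = ref_a, ref_end = ref_b,
        length = w, flank_repeat_length = fl,
        inverted_taxa = paste(inv, collapse = ","),
        segment = if (identical(sort(inv), sort(set1))) us[2] else us[1],
        inverted_segment = if (identical(sort(inv), sort(set1))) us[1] else us[2],
        stem_loop = TRUE, stringsAsFactors = FALSE)
      if (is.null(best) || cand$length < best$length ||
          (cand$length == best$length && cand$col_start < best$col_start)) {
        best <- cand
      }
    }
  }
  best
}

# longest inverted repeat (<= max_flank) in the flanks immediately adjacent
# to segment [a, b]: left flank ends at a-1, right flank starts at b+1; both
# must be identical across all taxa and gap-free. Returns 0 if none.
flank_repeat_length <- function(aln, a, b, max_flank) {
  m <- aln$matrix
  n <- aln$ncol
  fl <- 0L
  while (fl < max_flank) {
    lc <- a - fl - 1L; rc <- b + fl + 1L
    if (lc < 1L || rc > n) break
    lv <- m[, lc]; rv <- m[, rc]
    if (any(lv == "-") || any(rv == "-") ||
        length(unique(lv)) != 1L || length(unique(rv)) != 1L) break
    if (lv[1] != comp_chars(rv[1])) break
    fl <- fl + 1L
  }
  fl
}

## ------------------------------------------------------------ orchestration --

#' Call all variant classes with single attribution per column
#'
#' Runs [call_indels()], [call_inversions()] and [call_snps()], removing
#' columns absorbed by inversion events from the SNP list so that every
#' variable alignment column is attributed to exactly one event type.
#'
#' @param aln an [alignment_set()].
#' @param structure optional reference `QuadripartiteStructure`.
#' @param reference_record optional reference [plastome_record()].
#' @param thresholds SSR thresholds (see [default_ssr_thresholds()]).
#' @param min_inv,max_inv,min_flank,max_flank inversion parameters.
#' @return list with `snps` (from [call_snps()]), `indels`, `inversions`.
#' @export
call_variants <- function(aln, structure = NULL, reference_record = NULL,
                          thresholds = default_ssr_thresholds(),
                          min_inv = 2L, max_inv = 6L, min_flank = 3L,
                          max_flank = 20L) {
  inversions <- call_inversions(aln, min_inv, max_inv, min_flank, max_flank,
                                structure, reference_record)
  absorbed <- integer()
  if (nrow(inversions)) {
    absorbed <- unlist(mapply(seq.int, inversions$col_start,
                              inversions$col_end, SIMPLIFY = FALSE))
  }
  snps <- call_snps(aln, structure, exclude_columns = absorbed)
  indels <- call_indels(aln, thresholds, 2L, reference_record, structure)
  list(snps = snps, indels = indels, inversions = inversions)
}
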