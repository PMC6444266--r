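# MISA-equivalent perfect microsatellite (SSR) detection.
#
# Default thresholds (minimum copy number per unit length 1..6) are the ones
# commonly used for plastomes: 10, 5, 4, 3, 3, 3. Scanning is on the forward
# strand only; the canonical class collapses rotations and strand so
# reporting is strand-symmetric. Compound/interrupted repeats are not
# merged: every maximal perfect run is reported on its own.

#' Default SSR thresholds
#'
#' Minimum number of repeat copies for unit lengths 1-6.
#' @return named integer vector.
#' @export
default_ssr_thresholds <- function() {
  c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
}

check_thresholds <- function(thresholds) {
  thresholds <- as.integer(thresholds[as.character(1:6)])
  if (any(is.na(thresholds)) || length(thresholds) != 6L) {
    stop("thresholds must give a minimum copy number for every unit length 1-6")
  }
  names(thresholds) <- as.character(1:6)
  thresholds
}

# maximal perfect tandem runs of period u in character vector v; returns
# data.frame(start, copies) of runs with >= min_copies complete copies whose
# unit has minimal period u. Runs containing N are broken at the N.
scan_period_runs <- function(v, u, min_copies) {
  n <- length(v)
  if (n < u * min_copies) {
    return(data.frame(start = integer(), copies = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  eq <- v[seq_len(n - u)] == v[seq_len(n - u) + u] &
        v[seq_len(n - u)] != "N" & v[seq_len(n - u) + u] != "N"
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + u) >= u * min_copies
  res <- list()
  for (i in which(keep)) {
    span <- r$lengths[i] + u          # bases covered by the periodic region
    copies <- span %/% u
    if (copies < min_copies) next
    st <- starts[i]
    motif <- chars_seq(v[st:(st + u - 1L)])
    if (minimal_period(motif) != u) next  # smallest-unit attribution rule
    res[[length(res) + 1L]] <- data.frame(
      start = st, copies = copies, motif = motif, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(start = integer(), copies = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Scan a genome for simple sequence repeats
#'
#' Finds all maximal perfect tandem repeats of unit length 1-6 meeting the
#' copy-number thresholds. Each genomic interval is reported once and is
#' attributed to the smallest unit length whose perfect repetition spans it
#' (an A x 12 run is a mononucleotide SSR, never AA x 6); where loci of
#' different unit lengths would overlap, the smaller unit wins.
#'
#' @param record a [plastome_record()] (or plain DNA string).
#' @param thresholds named vector mapping unit length (`"1"`..`"6"`) to the
#'   minimum copy number; defaults to [default_ssr_thresholds()].
#' @param structure optional `QuadripartiteStructure` for region labels.
#' @return data.frame with one row per SSR locus: `genome_id`, `start`,
#'   `end`, `motif`, `canonical_class`, `unit_length`, `copy_number`,
#'   `region`, `context`, sorted by start.
#' @export
scan_ssrs <- function(record, thresholds = default_ssr_thresholds(),
                      structure = NULL) {
  thresholds <- check_thresholds(thresholds)
  if (!inherits(record, "PlastomeRecord")) record <- plastome_record("seq", record)
  v <- seq_chars(record$sequence)
  loci <- list()
  for (u in 1:6) {
    runs <- scan_period_runs(v, u, thresholds[[as.character(u)]])
    if (nrow(runs)) {
      runs$unit_length <- u
      loci[[length(loci) + 1L]] <- runs
    }
  }
  if (!length(loci)) {
    out <- data.frame(genome_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      canonical_class = character(), unit_length = integer(),
                      copy_number = integer(), region = character(),
                      context = character(), stringsAsFactors = FALSE)
    return(out)
  }
  loci <- do.call(rbind, loci)
  loci$end <- loci$start + loci$unit_length * loci$copies - 1L
  # overlap resolution: smaller unit length wins, then leftmost
  loci <- loci[order(loci$unit_length, loci$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  if (nrow(loci) > 1L) {
    taken_s <- integer(); taken_e <- integer()
    for (i in seq_len(nrow(loci))) {
      if (length(taken_s) &&
          any(loci$start[i] <= taken_e & loci$end[i] >= taken_s)) {
        keep[i] <- FALSE
      } else {
        taken_s <- c(taken_s, loci$start[i])
        taken_e <- c(taken_e, loci$end[i])
      }
    }
  }
  loci <- loci[keep, , drop = FALSE]
  loci <- loci[order(loci$start), , drop = FALSE]
  cls <- classify_position(record, structure, loci$start)
  out <- data.frame(
    genome_id = record$id,
    start = loci$start,
    end = loci$end,
    motif = loci$motif,
    canonical_class = vapply(loci$motif, canonical_motif_class, ""),
    unit_length = loci$unit_length,
    copy_number = loci$copies,
    region = cls$region,
    context = cls$context,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize SSR loci across genomes
#'
#' @param loci data.frame as returned by [scan_ssrs()], possibly rbind-ed
#'   over several genomes.
#' @return list of data.frames: `per_genome` (total per genome), `by_unit`,
#'   `by_class`, `by_region`, `by_context` — each with pooled counts and
#'   proportions (two decimals, in percent).
#' @export
summarize_ssrs <- function(loci) {
  tab <- function(x) {
    if (!nrow(loci)) {
      return(data.frame(level = character(), count = integer(),
                        proportion = numeric(), stringsAsFactors = FALSE))
    }
    t <- table(x)
    data.frame(level = names(t), count = as.integer(t),
               proportion = round(100 * as.integer(t) / nrow(loci), 2),
               stringsAsFactors = FALSE)
  }
  per_genome <- if (nrow(loci)) {
    t <- table(loci$genome_id)
    data.frame(genome_id = names(t), count = as.integer(t),
               stringsAsFactors = FALSE)
  } else data.frame(genome_id = character(), count = integer(),
                    stringsAsFactors = FALSE)
  list(per_genome = per_genome,
       by_unit = tab(loci$unit_length),
       by_class = tab(loci$canonical_class),
       by_region = tab(loci$region),
       by_context = tab(loci$context),
       total = nrow(loci))
}
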