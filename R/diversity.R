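# Sliding-window nucleotide diversity (pi) over the alignment and hotspot
# calling. pi is the average proportion of pairwise differences over usable
# sites (columns gap-free and N-free in all rows), with no multiple-hit
# correction — the plain "Pi" of the standard sliding-window tools. Windows
# are defined over alignment columns (complete deletion within each window)
# and midpoints are projected to reference coordinates.

#' Nucleotide diversity of a set of aligned segments
#'
#' @param rows character vector of aligned sequences (equal length) or an
#'   [alignment_set()].
#' @return list with `pi` (NA when no usable site), `usable_sites`, and
#'   `pair_diffs` (named vector of per-pair difference counts).
#' @export
nucleotide_diversity <- function(rows) {
  m <- if (inherits(rows, "AlignmentSet")) rows$matrix
       else do.call(rbind, strsplit(toupper(unlist(rows)), "", fixed = TRUE))
  k <- nrow(m)
  if (k < 2L) stop("nucleotide diversity needs >= 2 sequences")
  usable <- colSums(m == "-" | m == "N") == 0L
  L <- sum(usable)
  pairs <- utils::combn(seq_len(k), 2L)
  d <- apply(pairs, 2L, function(p) sum(m[p[1], usable] != m[p[2], usable]))
  if (L == 0L) {
    return(list(pi = NA_real_, usable_sites = 0L,
                pair_diffs = as.integer(d)))
  }
  pi <- (2 / (k * (k - 1))) * sum(d / L)
  list(pi = pi, usable_sites = L, pair_diffs = as.integer(d))
}

#' Sliding-window diversity profile with hotspot calling
#'
#' Windows of `window` alignment columns advance by `step`; within each
#' window only columns gap-free and N-free in all taxa are used. The
#' trailing partial window is dropped. Consecutive windows with pi above
#' `threshold` merge into one hotspot interval, annotated with the names of
#' overlapping genes and derived spacers of the reference.
#'
#' @param aln an [alignment_set()].
#' @param window,step window length and step in alignment columns
#'   (defaults 600 and 100).
#' @param threshold hotspot pi threshold (default 0.01).
#' @param reference_record optional reference [plastome_record()] used for
#'   hotspot annotation.
#' @param structure optional reference `QuadripartiteStructure` used to
#'   label window midpoints with a region.
#' @return object of class `DiversityProfile`: list with `windows`
#'   (data.frame `window_index`, `col_start`, `col_end`, `midpoint_ref`,
#'   `usable_sites`, `pi`, `region`), `mean_pi` (over windows with usable
#'   sites), `hotspots` (data.frame `ref_start`, `ref_end`, `peak_pi`,
#'   `features`), and the parameters.
#' @export
sliding_profile <- function(aln, window = 600L, step = 100L, threshold = 0.01,
                            reference_record = NULL, structure = NULL) {
  n <- aln$ncol
  if (window > n) {
    warning("window longer than alignment; using a single whole-alignment window")
    window <- n
  }
  m <- aln$matrix
  k <- nrow(m)
  usable <- colSums(m == "-" | m == "N") == 0L
  # per-column count of differing pairs among usable columns
  npairs <- k * (k - 1L) / 2L
  same <- rep(0, n)
  for (b in c("A", "C", "G", "T")) {
    cnt <- colSums(m == b)
    same <- same + cnt * (cnt - 1) / 2
  }
  coldiff <- ifelse(usable, npairs - same, 0)
  cs_diff <- c(0, cumsum(coldiff))
  cs_use <- c(0L, cumsum(as.integer(usable)))

  starts <- seq(1L, n - window + 1L, by = step)
  L <- cs_use[starts + window] - cs_use[starts]
  D <- cs_diff[starts + window] - cs_diff[starts]
  pi <- ifelse(L > 0L, D / (npairs * L), NA_real_)
  mids <- starts + window %/% 2L
  mid_ref <- ref_position_of(aln, pmin(mids, n))
  region <- if (!is.null(structure)) region_of(structure, mid_ref)
            else rep(NA_character_, length(starts))
  windows <- data.frame(
    window_index = seq_along(starts),
    col_start = starts, col_end = starts + window - 1L,
    midpoint_ref = mid_ref, usable_sites = as.integer(L), pi = pi,
    region = region, stringsAsFactors = FALSE)

  hot <- which(!is.na(pi) & pi > threshold)
  hotspots <- data.frame(ref_start = integer(), ref_end = integer(),
                         peak_pi = numeric(), features = character(),
                         stringsAsFactors = FALSE)
  if (length(hot)) {
    grp <- cumsum(c(1L, diff(hot) != 1L))
    for (g in split(hot, grp)) {
      c1 <- windows$col_start[g[1L]]
      c2 <- windows$col_end[g[length(g)]]
      r1 <- ref_position_of(aln, c1)
      r2 <- ref_position_of(aln, c2)
      feats <- hotspot_features(reference_record, r1, r2)
      hotspots <- rbind(hotspots, data.frame(
        ref_start = r1, ref_end = r2, peak_pi = max(pi[g]),
        features = feats, stringsAsFactors = FALSE))
    }
  }
  structure(list(windows = windows,
                 mean_pi = mean(pi, na.rm = TRUE),
                 hotspots = hotspots,
                 window = window, step = step, threshold = threshold),
            class = "DiversityProfile")
}

#' @export
print.DiversityProfile <- function(x, ...) {
  cat(sprintf(paste0("DiversityProfile: %d windows (%d cols, step %d), ",
                     "mean pi %.5f, %d hotspot(s) > %g\n"),
              nrow(x$windows), x$window, x$step, x$mean_pi,
              nrow(x$hotspots), x$threshold))
  invisible(x)
}

# names of genes/spacers of the reference overlapping [r1, r2]
hotspot_features <- function(record, r1, r2) {
  if (is.null(record)) return(NA_character_)
  hits <- character()
  f <- record$features
  if (nrow(f)) {
    ov <- f$start <= r2 & f$end >= r1
    hits <- unique(f$name[ov])
  }
  sp <- spacer_intervals(record)
  if (nrow(sp)) {
    lin <- sp[sp$start <= sp$end, , drop = FALSE]
    ov <- lin$start <= r2 & lin$end >= r1
    hits <- c(hits, lin$name[ov])
    wrap <- sp[sp$start > sp$end, , drop = FALSE]
    if (nrow(wrap) && (r2 >= wrap$start[1] || r1 <= wrap$end[1])) {
      hits <- c(hits, wrap$name[1])
    }
  }
  if (!length(hits)) return("")
  paste(unique(hits), collapse = ",")
}

#' Plot a diversity profile
#'
#' Simple base-graphics profile of window pi against the reference midpoint
#' position, with the hotspot threshold drawn as a dashed line.
#'
#' @param x a `DiversityProfile`.
#' @param ... passed to [graphics::plot()].
#' @method plot DiversityProfile
#' @export
plot.DiversityProfile <- function(x, ...) {
  w <- x$windows
  graphics::plot(w$midpoint_ref, w$pi, type = "l",
                 xlab = "reference position (window midpoint)",
                 ylab = expression(pi), ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (nrow(x$hotspots)) {
    graphics::rug(x$hotspots$ref_start, col = "red")
  }
  invisible(x)
}
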