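# Low-level sequence helpers shared by all modules. Sequences are plain
# uppercase character strings over {A,C,G,T,N}; per-base work uses character
# vectors. All coordinates are 1-based inclusive.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Reverse complement of a DNA string
#'
#' @param x character string over A,C,G,T,N (gaps `-` allowed and preserved).
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return("")
  paste(rev(DNA_COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

# vectorised complement on a character vector of single bases
comp_chars <- function(v) unname(DNA_COMPLEMENT[v])

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(v) paste(v, collapse = "")

#' @noRd
validate_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    ch <- unique(seq_chars(gsub("[ACGTN]", "", paste(x, collapse = ""))))
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(ch, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# minimal period of a short motif (1 if homopolymer etc.)
minimal_period <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L &&
        motif == strrep(substr(motif, 1L, p), n %/% p)) return(p)
  }
  n
}

rotations <- function(motif) {
  n <- nchar(motif)
  vapply(seq_len(n), function(i) {
    paste0(substr(motif, i, n), substr(motif, 1L, i - 1L))
  }, character(1))
}

#' Canonical class label of an SSR motif
#'
#' Collapses a repeat unit over rotations and strand into a MISA-style class
#' label, e.g. `A` and `T` both map to `"A/T"`, `AG`, `GA`, `CT`, `TC` all
#' map to `"AG/CT"`, and `AT`/`TA` map to `"AT/TA"`.
#'
#' @param motif repeat unit (1-6 bp).
#' @return character class label.
#' @export
canonical_motif_class <- function(motif) {
  stopifnot(nchar(motif) >= 1L)
  fam <- c(rotations(motif), rotations(revcomp(motif)))
  a <- min(fam)
  b <- min(rotations(revcomp(a)))
  if (b == a) {
    # strand-palindromic family (e.g. AT): pair with the next rotation
    rest <- sort(setdiff(unique(fam), a))
    b <- if (length(rest)) rest[1L] else a
  }
  paste0(a, "/", b)
}

# random DNA with fixed GC target; exact base counts up to rounding
random_dna_chars <- function(n, gc = 0.385) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  ngc <- round(n * gc)
  counts["G"] <- ngc %/% 2L
  counts["C"] <- ngc - counts["G"]
  nat <- n - ngc
  counts["A"] <- nat %/% 2L
  counts["T"] <- nat - counts["A"]
  sample(rep(names(counts), counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
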