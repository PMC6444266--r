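# AlignmentSet: a multiple sequence alignment of complete plastomes with
# per-taxon column <-> ungapped-coordinate maps. Rows are equal-length gapped
# strings over {A,C,G,T,N,-}; the reference taxon anchors all genome
# coordinates reported by the variant callers.

#' Construct an alignment set
#'
#' @param rows named character vector (or list) of gapped sequences of equal
#'   length; names are taxon labels.
#' @param reference_taxon label of the coordinate reference (default: first).
#' @return object of class `AlignmentSet` with fields `taxa`, `matrix`
#'   (taxa x columns character matrix), `reference_taxon`, `col_to_pos`
#'   (per-taxon: for each column, the 1-based ungapped position of the last
#'   non-gap base at or before that column; 0 before the first base) and
#'   `is_base` (per-taxon logical: column holds a base).
#' @export
alignment_set <- function(rows, reference_taxon = NULL) {
  rows <- unlist(rows)
  if (length(rows) < 2L) stop("an alignment needs >= 2 rows")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named with taxon labels")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ", paste(widths, collapse = ", "))
  }
  reference_taxon <- reference_taxon %||% names(rows)[1L]
  if (!reference_taxon %in% names(rows)) {
    stop("reference taxon '", reference_taxon, "' absent from alignment")
  }
  m <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  bad <- !(m %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) stop("alignment contains characters outside {A,C,G,T,N,-}")
  is_base <- m != "-"
  col_to_pos <- t(apply(is_base, 1L, cumsum))
  structure(list(taxa = names(rows), matrix = m,
                 reference_taxon = reference_taxon,
                 is_base = is_base, col_to_pos = col_to_pos,
                 ncol = ncol(m)),
            class = "AlignmentSet")
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat(sprintf("AlignmentSet: %d taxa x %d columns (reference: %s)\n",
              length(x$taxa), x$ncol, x$reference_taxon))
  invisible(x)
}

#' Load an alignment from aligned FASTA
#'
#' @param path aligned-FASTA file.
#' @param reference_taxon coordinate reference label (default: first record).
#' @return an [alignment_set()].
#' @export
load_alignment <- function(path, reference_taxon = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 2L) stop("alignment must contain >= 2 sequences: ", path)
  rows <- as.character(set)
  names(rows) <- sub("[[:space:]].*$", "", names(set))
  alignment_set(rows, reference_taxon)
}

#' Ungapped sequence of one taxon
#'
#' @param aln an [alignment_set()].
#' @param taxon taxon label.
#' @return the taxon's genome sequence with gaps removed.
#' @export
ungapped_sequence <- function(aln, taxon) {
  v <- aln$matrix[taxon, ]
  chars_seq(v[v != "-"])
}

# ungapped reference position of an alignment column (position of the last
# reference base at or before the column; 1 if the alignment starts in a gap)
ref_position_of <- function(aln, columns) {
  pmax(1L, aln$col_to_pos[aln$reference_taxon, columns])
}
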