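# Comparison of pipeline output against a simulation truth ledger.
# Events are matched in alignment coordinates, which are shared between the
# ledger and the callers and independent of any taxon's indel shifts.

canonical_bipartition <- function(side, taxa, reference) {
  side <- sort(side)
  other <- sort(setdiff(taxa, side))
  if (length(side) < length(other)) return(paste(side, collapse = ","))
  if (length(other) < length(side)) return(paste(other, collapse = ","))
  if (reference %in% side) paste(other, collapse = ",")
  else paste(side, collapse = ",")
}

prf <- function(true_keys, called_keys) {
  tp <- length(intersect(true_keys, called_keys))
  data.frame(
    n_true = length(true_keys), n_called = length(called_keys), tp = tp,
    precision = if (length(called_keys)) tp / length(called_keys) else NA_real_,
    recall = if (length(true_keys)) tp / length(true_keys) else NA_real_)
}

#' Evaluate pipeline recovery of planted events
#'
#' Matches called SNPs (alignment column + substitution class), indels
#' (column interval + classification + polarity), inversions (column
#' interval + length + flank + unordered taxon bipartition) and per-genome
#' SSR loci (start + motif + copy number) against a truth ledger, and
#' reports precision and recall per event class.
#'
#' @param variants result of [call_variants()] on the ledger's alignment.
#' @param ssr_tables named list (by taxon) of [scan_ssrs()] outputs.
#' @param ledger a `TruthLedger`.
#' @return data.frame with one row per event class: `class`, `n_true`,
#'   `n_called`, `tp`, `precision`, `recall`.
#' @export
evaluate_recovery <- function(variants, ssr_tables, ledger) {
  ev <- ledger$events
  taxa <- ledger$taxa
  ref <- ledger$reference
  out <- list()

  true_snps <- if (is.null(ev)) character() else {
    s <- ev[ev$type == "snp", , drop = FALSE]
    paste(s$col_start, s$class)
  }
  called_snps <- paste(variants$snps$sites$column, variants$snps$sites$class)
  out$snp <- cbind(class = "snp", prf(true_snps, called_snps))

  indel_key <- function(c1, c2, classification, polarity) {
    paste(c1, c2, classification, polarity)
  }
  true_ind <- if (is.null(ev)) character() else {
    d <- ev[ev$type == "indel", , drop = FALSE]
    indel_key(d$col_start, d$col_end, d$classification, d$polarity)
  }
  ci <- variants$indels
  called_ind <- indel_key(ci$col_start, ci$col_end, ci$classification,
                          ci$polarity)
  out$indel <- cbind(class = "indel", prf(true_ind, called_ind))
  for (cls in c("SSR-indel", "NR-indel")) {
    t <- true_ind[grepl(cls, true_ind, fixed = TRUE)]
    c_ <- called_ind[grepl(cls, called_ind, fixed = TRUE)]
    out[[cls]] <- cbind(class = cls, prf(t, c_))
  }

  inv_key <- function(c1, c2, len, flank, sides) {
    paste(c1, c2, len, flank, sides)
  }
  true_inv <- if (is.null(ev)) character() else {
    v <- ev[ev$type == "inversion", , drop = FALSE]
    if (nrow(v)) {
      sides <- vapply(strsplit(v$taxa, ","), canonical_bipartition, "",
                      taxa = taxa, reference = ref)
      inv_key(v$col_start, v$col_end, v$length, v$flank, sides)
    } else character()
  }
  cv <- variants$inversions
  called_inv <- if (nrow(cv)) {
    sides <- vapply(strsplit(cv$inverted_taxa, ","), canonical_bipartition, "",
                    taxa = taxa, reference = ref)
    inv_key(cv$col_start, cv$col_end, cv$length, cv$flank_repeat_length, sides)
  } else character()
  out$inversion <- cbind(class = "inversion", prf(true_inv, called_inv))

  exp_ssr <- ledger$ssr_expected
  true_ssr <- paste(exp_ssr$taxon, exp_ssr$start_t, exp_ssr$motif,
                    exp_ssr$copies_t)
  called_ssr <- unlist(lapply(names(ssr_tables), function(t) {
    s <- ssr_tables[[t]]
    paste(t, s$start, s$motif, s$copy_number)
  }))
  out$ssr <- cbind(class = "ssr", prf(true_ssr, called_ssr))

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
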