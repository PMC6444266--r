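# SNP, indel and inversion calling from alignments.

aln4 <- function(..., ref = NULL) {
  rows <- c(...)
  alignment_set(rows, reference_taxon = ref %||% names(rows)[1])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("alignment loading validates shape and builds coordinate maps", {
  expect_error(alignment_set(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(alignment_set(c(a = "ACGT", b = "ACGT"), "zz"), "absent")
  a <- aln4(a = "AC-GT", b = "ACCGT")
  expect_equal(unname(a$col_to_pos["a", ]), c(1L, 2L, 2L, 3L, 4L))
  expect_equal(ungapped_sequence(a, "a"), "ACGT")
  path <- tempfile(fileext = ".fa")
  writeLines(c(">x", "AC-GT", ">y", "ACCGT"), path)
  a2 <- load_alignment(path, "y")
  expect_equal(a2$reference_taxon, "y")
  expect_equal(a2$ncol, 5L)
})

test_that("substitution classes collapse strand and split Ts/Tv", {
  expect_equal(substitution_class("A", "G"), "A>G/T>C")
  expect_equal(substitution_class("T", "C"), "A>G/T>C")
  expect_equal(substitution_class("G", "C"), "G>C/C>G")
  expect_true(is_transition("G>A/C>T"))
  expect_false(is_transition("A>T/T>A"))
  expect_equal(tv_ts_ratio(345, 306), 0.89)
})

test_that("call_snps assigns directed classes from the majority allele", {
  a <- aln4(w = "GATAG", x = "GATAG", y = "GATAG", z = "GGTAG")
  res <- call_snps(a)
  expect_equal(nrow(res$sites), 1L)
  expect_equal(res$sites$class, "A>G/T>C")
  expect_true(res$sites$transition)
  # strand-complement column gives the same class
  b <- aln4(w = "CTTAG", x = "CTTAG", y = "CTTAG", z = "CCTAG")
  expect_equal(call_snps(b)$sites$class, "A>G/T>C")
  # 2-2 tie polarized toward the reference allele
  d <- aln4(w = "GACAG", x = "GACAG", y = "GATAG", z = "GATAG")
  expect_equal(call_snps(d)$sites$majority, "C")
  expect_equal(call_snps(d)$sites$variant, "T")
})

test_that("gap and N columns are excluded from SNP calling", {
  a <- aln4(w = "GA-AGT", x = "GACAGT", y = "GACAGN", z = "GACAGT")
  res <- call_snps(a)
  expect_equal(nrow(res$sites), 0L)
  expect_warning(call_snps(aln4(w = "----", x = "AAAA")), "no gap-free")
})

test_that("pairwise difference counts cover every taxon pair", {
  sim <- small_sim()
  res <- call_snps(sim$alignment)
  pw <- res$summary$pairwise
  expect_equal(nrow(pw), 6L)
  # symmetric reconstruction from ledger: private events add to all pairs
  # containing that taxon
  expect_true(all(pw$differences >= 0))
  expect_equal(res$summary$ts + res$summary$tv, res$summary$n_substitutions)
})

test_that("the six-class spectrum is invariant under reverse complement", {
  sim <- small_sim()
  a <- sim$alignment
  rc_rows <- vapply(a$taxa, function(t) revcomp(chartr("N", "N",
                    paste(a$matrix[t, ], collapse = ""))), character(1))
  names(rc_rows) <- a$taxa
  b <- alignment_set(rc_rows, a$reference_taxon)
  s1 <- call_snps(a)$summary
  s2 <- call_snps(b)$summary
  expect_equal(s1$class_counts, s2$class_counts)
  expect_equal(s1$ts, s2$ts)
  expect_equal(s1$tv, s2$tv)
})

test_that("indel events segment by maximal shared gap pattern", {
  # SSR slippage: A x 11 in w vs A x 10 elsewhere
  a <- aln4(w = paste0("GC", strrep("A", 11), "GC"),
            x = paste0("GC", strrep("A", 10), "-GC"),
            y = paste0("GC", strrep("A", 10), "-GC"),
            z = paste0("GC", strrep("A", 10), "-GC"))
  ev <- call_indels(a)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$classification, "SSR-indel")
  expect_equal(ev$ssr_motif, "A")
  expect_equal(ev$length, 1L)
  expect_equal(ev$polarity, "insertion")
  expect_equal(ev$private_taxon, "w")
  # a private non-repetitive 5 bp gap is an NR deletion
  b <- aln4(w = "TTGCAAGCGT", x = "TT-----CGT", y = "TTGCAAGCGT",
            z = "TTGCAAGCGT")
  ev2 <- call_indels(b)
  expect_equal(ev2$classification, "NR-indel")
  expect_equal(ev2$length, 5L)
  expect_equal(ev2$polarity, "deletion")
  expect_equal(ev2$taxa_with_gap, "x")
})

test_that("adjacent distinct gap patterns split into separate events", {
  a <- aln4(w = "TTGCA--CGT", x = "TT-----CGT", y = "TTGCAAGCGT",
            z = "TTGCAAGCGT")
  ev <- call_indels(a)
  expect_equal(nrow(ev), 2L)
  expect_equal(sort(ev$col_start), c(3L, 6L))
})

test_that("indel segmentation equals the brute-force gap-pattern oracle", {
  set.seed(23)
  taxa <- c("w", "x", "y", "z")
  for (i in 1:30) {
    m <- matrix(sample(c("A", "C", "G", "T"), 4 * 120, TRUE), nrow = 4,
                dimnames = list(taxa, NULL))
    # plant random gap runs
    for (j in 1:sample(2:6, 1)) {
      t <- sample(4, sample(1:3, 1))
      st <- sample(1:110, 1)
      m[t, st:(st + sample(0:8, 1))] <- "-"
    }
    keep <- colSums(m == "-") < 4   # drop all-gap columns
    m <- m[, keep, drop = FALSE]
    rows <- apply(m, 1, paste, collapse = "")
    a <- alignment_set(rows)
    got <- call_indels(a)
    want <- brute_indels(m)
    expect_equal(got$col_start, want$col_start, info = paste("case", i))
    expect_equal(got$col_end, want$col_end, info = paste("case", i))
    got_taxa <- vapply(strsplit(got$taxa_with_gap, ","),
                       function(x) paste(sort(x), collapse = ","), "")
    expect_equal(got_taxa, want$taxa_with_gap, info = paste("case", i))
  }
})

test_that("a reverse-complement segment with a hairpin stem is an inversion", {
  # 3 taxa carry AATG, one carries CATT = revcomp(AATG); flanks ACGTT /
  # AACGT form a 5 bp stem
  core <- function(mid) paste0("GGCA", "ACGTT", mid, "AACGT", "AGGC")
  a <- aln4(w = core("AATG"), x = core("AATG"), y = core("AATG"),
            z = core("CATT"))
  inv <- call_inversions(a)
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$length, 4L)
  expect_equal(inv$flank_repeat_length, 5L)
  expect_equal(inv$inverted_taxa, "z")
  expect_equal(inv$col_start, 10L)
  # the same columns are not double-reported as SNPs
  v <- call_variants(a)
  expect_equal(nrow(v$snps$sites), 0L)
  expect_equal(nrow(v$inversions), 1L)
})

test_that("non-complementary differences stay SNPs, not inversions", {
  core <- function(mid) paste0("GGCA", "ACGTT", mid, "AACGT", "AGGC")
  a <- aln4(w = core("AATG"), x = core("AATG"), y = core("AATG"),
            z = core("AAGG"))
  expect_equal(nrow(call_inversions(a)), 0L)
  v <- call_variants(a)
  expect_equal(nrow(v$snps$sites), 1L)
})

test_that("an inversion without a qualifying stem is not called", {
  # same reverse-complement segment but random (non-complementary) flanks
  a <- aln4(w = "GGCATTACGAATGTTGGCTGCC", x = "GGCATTACGAATGTTGGCTGCC",
            y = "GGCATTACGAATGTTGGCTGCC", z = "GGCATTACGCATTTTGGCTGCC")
  expect_equal(nrow(call_inversions(a)), 0L)
})

test_that("every variable column is attributed to exactly one event type", {
  sim <- small_sim()
  a <- sim$alignment
  v <- call_variants(a)
  m <- a$matrix
  variable <- logical(a$ncol)
  for (t in a$taxa) variable <- variable | (m[t, ] != m[a$taxa[1], ])
  var_cols <- which(variable)
  snp_cols <- v$snps$sites$column
  indel_cols <- unlist(mapply(seq.int, v$indels$col_start, v$indels$col_end,
                              SIMPLIFY = FALSE))
  inv_cols <- unlist(mapply(seq.int, v$inversions$col_start,
                            v$inversions$col_end, SIMPLIFY = FALSE))
  inv_var <- intersect(inv_cols, var_cols)
  claimed <- c(snp_cols, indel_cols, inv_var)
  expect_equal(sort(unique(claimed)), sort(var_cols))
  expect_equal(anyDuplicated(claimed), 0L)
})
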