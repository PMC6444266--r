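# MISA-style SSR detection.

test_that("thresholds gate detection and must cover unit lengths 1-6", {
  expect_equal(nrow(scan_ssrs(paste0("ACGTAG", strrep("C", 9), "TAGGAT"))), 0L)
  hit <- scan_ssrs(paste0("GATTGA", strrep("C", 10), "ATGATG"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$copy_number, 10L)
  expect_error(scan_ssrs("ACGT", thresholds = c(`1` = 10L)),
               "every unit length")
})

test_that("motif attribution uses the smallest spanning unit", {
  res <- scan_ssrs(paste0("GGTCC", strrep("AG", 5), "GTCCT"))
  expect_equal(nrow(res), 1L)
  expect_equal(res$motif, "AG")
  expect_equal(res$unit_length, 2L)
  expect_equal(res$canonical_class, "AG/CT")
  # AT x 5: a dinucleotide SSR, never a mononucleotide one
  res2 <- scan_ssrs(paste0("CCGG", strrep("AT", 5), "CCGG"))
  expect_equal(res2$unit_length, 2L)
  expect_equal(res2$copy_number, 5L)
  expect_equal(res2$canonical_class, "AT/TA")
  # A x 12 is mononucleotide, not AA x 6
  res3 <- scan_ssrs(paste0("CCGG", strrep("A", 12), "CCGG"))
  expect_equal(res3$unit_length, 1L)
  expect_equal(res3$copy_number, 12L)
})

test_that("canonical classes collapse rotation and strand", {
  expect_equal(canonical_motif_class("A"), "A/T")
  expect_equal(canonical_motif_class("T"), "A/T")
  expect_equal(canonical_motif_class("G"), "C/G")
  expect_equal(canonical_motif_class("GA"), canonical_motif_class("TC"))
  expect_equal(canonical_motif_class("AAG"), "AAG/CTT")
  expect_equal(canonical_motif_class("GAA"), "AAG/CTT")
})

test_that("runs containing N are broken at the N", {
  res <- scan_ssrs(paste0("GC", strrep("A", 6), "N", strrep("A", 6), "GC"))
  expect_equal(nrow(res), 0L)
  res2 <- scan_ssrs(paste0("GC", strrep("A", 10), "N", strrep("A", 10), "GC"))
  expect_equal(nrow(res2), 2L)
})

test_that("scan matches the brute-force enumeration on random sequences", {
  set.seed(31)
  for (i in 1:25) {
    # AT-rich alphabet makes threshold-passing runs common
    s <- random_seq(400, prob = c(A = 0.42, C = 0.08, G = 0.08, T = 0.42))
    got <- scan_ssrs(s)
    want <- brute_ssrs(s)
    expect_equal(got$start, want$start, info = paste("seq", i))
    expect_equal(got$end, want$end, info = paste("seq", i))
    expect_equal(got$motif, want$motif, info = paste("seq", i))
    expect_equal(got$copy_number, want$copy_number, info = paste("seq", i))
  }
})

test_that("reported loci never overlap and never extend by a full unit", {
  set.seed(17)
  for (i in 1:10) {
    s <- random_seq(600, prob = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
    loci <- scan_ssrs(s)
    if (nrow(loci) > 1L) {
      expect_true(all(loci$start[-1] > loci$end[-nrow(loci)]))
    }
    for (j in seq_len(nrow(loci))) {
      u <- loci$unit_length[j]
      left <- loci$start[j] - u
      if (left >= 1) {
        expect_false(substr(s, left, loci$start[j] - 1) == loci$motif[j])
      }
      right <- loci$end[j] + u
      if (right <= nchar(s)) {
        expect_false(substr(s, loci$end[j] + 1, right) == loci$motif[j])
      }
    }
  }
  # maximal run reported in full
  loci <- scan_ssrs(paste0("CG", strrep("A", 11), "CG"))
  expect_equal(loci$start, 3L)
  expect_equal(loci$end, 13L)
})

test_that("scanning is deterministic", {
  set.seed(8)
  s <- random_seq(2000, prob = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
  expect_identical(scan_ssrs(s), scan_ssrs(s))
})

test_that("summaries tally by unit, class, region and context", {
  sim <- small_sim()
  ref <- sim$records[[sim$config$reference]]
  st <- find_quadripartite(ref, min_ir = 1000)
  loci <- scan_ssrs(ref, structure = st)
  sm <- summarize_ssrs(loci)
  expect_equal(sm$total, nrow(loci))
  expect_equal(sum(sm$by_unit$count), nrow(loci))
  expect_equal(sum(sm$by_region$count), nrow(loci))
  expect_equal(sum(sm$by_context$count), nrow(loci))
  expect_true(abs(sum(sm$by_class$proportion) - 100) < 0.5)
  empty <- summarize_ssrs(loci[0, ])
  expect_equal(empty$total, 0L)
  expect_equal(nrow(empty$per_genome), 0L)
})
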