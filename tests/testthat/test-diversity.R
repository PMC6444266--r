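# Nucleotide diversity and hotspot calling.

test_that("pi follows the average pairwise-difference definition", {
  r <- nucleotide_diversity(c("AAAAAAAAAA", "AAAAAAAAAC"))
  expect_equal(r$pi, 0.1)
  expect_equal(r$usable_sites, 10L)
  expect_equal(nucleotide_diversity(rep("ACGTACGT", 4))$pi, 0)
  # gap/N columns drop out of the usable set
  r2 <- nucleotide_diversity(c("AA-AAAAAAAA", "AACAAAAAAAC"))
  expect_equal(r2$usable_sites, 10L)
  expect_equal(r2$pi, 0.1)
  expect_true(is.na(nucleotide_diversity(c("---", "AAA"))$pi))
  expect_error(nucleotide_diversity("ACGT"), ">= 2")
})

test_that("pi matches the brute-force pairwise oracle on random quartets", {
  set.seed(12)
  for (i in 1:20) {
    rows <- vapply(1:4, function(j) {
      s <- strsplit(random_seq(80), "")[[1]]
      s[sample(80, 8)] <- sample(c("A", "C", "G", "T", "-"), 8, TRUE)
      paste(s, collapse = "")
    }, character(1))
    got <- nucleotide_diversity(rows)$pi
    expect_equal(got, brute_pi(rows), info = paste("case", i))
  }
})

test_that("window count, mean and per-window values agree with the oracle", {
  sim <- small_sim()
  a <- sim$alignment
  prof <- sliding_profile(a, window = 600, step = 100)
  expect_equal(nrow(prof$windows), (a$ncol - 600L) %/% 100L + 1L)
  # every window equals the brute-force computation
  rows <- vapply(a$taxa, function(t) paste(a$matrix[t, ], collapse = ""),
                 character(1))
  for (i in sample(nrow(prof$windows), 25)) {
    w <- prof$windows[i, ]
    seg <- substring(rows, w$col_start, w$col_end)
    expect_equal(w$pi, brute_pi(seg), info = paste("window", i))
  }
  defined <- prof$windows$pi[prof$windows$usable_sites > 0]
  expect_equal(prof$mean_pi, sum(defined) / length(defined))
  expect_true(all(prof$windows$pi >= 0 & prof$windows$pi <= 1, na.rm = TRUE))
})

test_that("adding a differing column never decreases a window's pi", {
  base <- rep(paste(rep("A", 50), collapse = ""), 4)
  names(base) <- c("w", "x", "y", "z")
  pis <- vapply(0:5, function(k) {
    rows <- base
    if (k > 0) {
      for (p in seq_len(k)) substr(rows["z"], p, p) <- "G"
    }
    nucleotide_diversity(rows)$pi
  }, numeric(1))
  expect_true(all(diff(pis) >= 0))
})

test_that("identical sequences give a flat zero profile with no hotspots", {
  rows <- rep(random_seq(2000), 4)
  names(rows) <- c("w", "x", "y", "z")
  set.seed(4)
  prof <- sliding_profile(alignment_set(rows), window = 600, step = 100)
  expect_true(all(prof$windows$pi == 0))
  expect_equal(nrow(prof$hotspots), 0L)
})

test_that("a planted high-diversity block is called as exactly one hotspot", {
  set.seed(77)
  n <- 4000
  base <- random_seq(n)
  rows <- rep(base, 4)
  names(rows) <- c("w", "x", "y", "z")
  # concentrate differences in one 600 bp block: ~24 private SNPs in z
  # gives pi ~ 0.02 inside the block and 0 outside
  block <- 1701:2300
  pos <- sort(sample(block, 24))
  zc <- strsplit(rows["z"], "")[[1]]
  for (p in pos) zc[p] <- setdiff(c("A", "C", "G", "T"), zc[p])[1]
  rows["z"] <- paste(zc, collapse = "")
  prof <- sliding_profile(alignment_set(rows), window = 600, step = 100,
                          threshold = 0.01)
  expect_equal(nrow(prof$hotspots), 1L)
  expect_true(prof$hotspots$ref_start < min(pos) &&
              prof$hotspots$ref_end > max(pos))
  peak <- max(prof$windows$pi, na.rm = TRUE)
  expect_gt(peak, 0.015)
  expect_lt(peak, 0.025)
})

test_that("an oversized window collapses to one whole-alignment window", {
  rows <- c(w = "ACGTACGTAC", x = "ACGTACGTAC", y = "ACGTACGTAC",
            z = "ACGTACGTCC")
  expect_warning(prof <- sliding_profile(alignment_set(rows), window = 600),
                 "window longer")
  expect_equal(nrow(prof$windows), 1L)
  expect_equal(prof$windows$usable_sites, 10L)
})

test_that("hotspots are annotated with reference gene and spacer names", {
  sim <- full_sim(seed = 3)
  res <- run_pipeline(sim$records, sim$alignment,
                      reference = sim$config$reference)
  h <- res$diversity$hotspots
  expect_equal(nrow(h), 4L)
  feats <- paste(h$features, collapse = " ")
  for (nm in c("rps16-trnQ", "trnG-trnM", "rbcL-psaI", "rps15-ndhF")) {
    expect_match(feats, nm, fixed = TRUE)
  }
  # IR windows are quieter than LSC windows
  w <- res$diversity$windows
  expect_lt(mean(w$pi[w$region == "IR"], na.rm = TRUE),
            mean(w$pi[w$region == "LSC"], na.rm = TRUE))
})
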