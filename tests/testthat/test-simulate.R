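# The synthetic quartet generator and its truth ledger.

test_that("configs validate region fractions and expose stated defaults", {
  expect_error(sim_config(1, lsc_frac = 0.2, ir_frac = 0.3), "LSC fraction")
  cfg <- sim_config(1)
  expect_equal(cfg$genome_length, 20000L)
  expect_equal(cfg$gc, 0.385)
  expect_equal(unname(cfg$thresholds), c(10L, 5L, 4L, 3L, 3L, 3L))
  ev <- cfg$events
  expect_equal(sum(ev$type == "snp"), 60L)
  expect_equal(sum(ev$type == "ssr_indel"), 12L)
  expect_equal(sum(ev$type == "nr_indel"), 15L)
  expect_equal(sum(ev$type == "inversion"), 3L)
})

test_that("the ancestor hits its construction targets", {
  sim <- small_sim()
  anc <- sim$ancestor
  # GC within half a percentage point of the 38.5% target
  expect_lt(abs(gc_content(anc, percent = TRUE) - 38.5), 0.5)
  # planted quadripartite structure is recovered exactly
  st <- find_quadripartite(anc, min_ir = 1000)
  expect_equal(st$ir_length, sim$structure$ir_length)
  expect_equal(st$lsc_length, sim$structure$lsc_length)
  # a scan of the ancestor finds exactly the planted SSR loci
  found <- scan_ssrs(anc)
  want <- sim$ledger$ssr_ancestor[order(sim$ledger$ssr_ancestor$start), ]
  expect_equal(found$start, want$start)
  expect_equal(found$motif, want$motif)
  expect_equal(found$copy_number, want$copies)
})

test_that("same config and seed give byte-identical output", {
  s1 <- simulate_quartet(sim_config(seed = 11))
  s2 <- simulate_quartet(sim_config(seed = 11))
  for (t in s1$config$taxa) {
    expect_identical(s1$records[[t]]$sequence, s2$records[[t]]$sequence)
  }
  expect_identical(s1$ledger$events, s2$ledger$events)
  s3 <- simulate_quartet(sim_config(seed = 12))
  expect_false(identical(s1$records[[4]]$sequence, s3$records[[4]]$sequence))
})

test_that("replaying the ledger reproduces every genome bit-exactly", {
  sim <- small_sim()
  rp <- replay_ledger(sim$ledger)
  for (t in sim$config$taxa) {
    expect_identical(rp[[t]], sim$records[[t]]$sequence)
  }
})

test_that("the true alignment round-trips to the generated genomes", {
  sim <- small_sim()
  for (t in sim$config$taxa) {
    expect_identical(ungapped_sequence(sim$alignment, t),
                     sim$records[[t]]$sequence)
  }
})

test_that("ledger event counts equal the plan", {
  sim <- small_sim()
  ev <- sim$ledger$events
  expect_equal(sum(ev$type == "snp"), 60L)
  expect_equal(sum(ev$classification == "SSR-indel", na.rm = TRUE), 12L)
  expect_equal(sum(ev$classification == "NR-indel", na.rm = TRUE), 15L)
  expect_equal(sum(ev$type == "inversion"), 3L)
  # the planned Ts:Tv split
  expect_equal(sum(is_transition(ev$class[ev$type == "snp"])), 40L)
})

test_that("a zero-event plan yields four identical genomes with pi zero", {
  cfg <- sim_config(seed = 5, events = default_event_plan(
    c("a", "b", "c", "d"))[0, ],
    taxa = c("a", "b", "c", "d"))
  sim <- simulate_quartet(cfg)
  seqs <- vapply(sim$records, `[[`, "", "sequence")
  expect_equal(length(unique(seqs)), 1L)
  prof <- sliding_profile(sim$alignment)
  expect_true(all(prof$windows$pi == 0))
})

test_that("events planted in the IR are mirrored and preserve IR identity", {
  taxa <- c("a", "b", "c", "d")
  ev <- merge_plan_rows <- data.frame(
    type = "snp", taxa = "d", class = "A>G/T>C", region = "IR",
    context = NA, feature = NA, hotspot = NA, delta = NA, kind = NA,
    length = NA, flank = NA, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 9, taxa = taxa, events = ev)
  sim <- simulate_quartet(cfg)
  led <- sim$ledger$events
  expect_equal(nrow(led), 2L)
  expect_equal(sum(led$mirror), 1L)
  expect_equal(led$class[1], led$class[2])
  # the mutated genome still has an exact full-length IR
  st <- find_quadripartite(sim$records[["d"]], min_ir = 1000)
  expect_equal(st$ir_length, sim$structure$ir_length)
})

test_that("generated contexts and regions match the classification service", {
  sim <- small_sim()
  led <- sim$ledger$ssr_ancestor
  cls <- classify_position(sim$ledger$ancestor, sim$structure, led$start)
  expect_equal(cls$region, led$region)
  expect_equal(cls$context, led$context)
})
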