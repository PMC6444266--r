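# Reading records, quadripartite detection, classification services.

test_that("GenBank parsing maps join() locations to exons and derives introns", {
  path <- write_toy_genbank()
  rec <- read_genbank(path)
  expect_s3_class(rec, "PlastomeRecord")
  expect_equal(rec$length, 100L)
  exons <- rec$features[rec$features$kind == "gene-exon", ]
  expect_equal(exons$start, c(10L, 40L))
  expect_equal(exons$end, c(20L, 60L))
  introns <- rec$features[rec$features$kind == "intron", ]
  expect_equal(introns$start, 21L)
  expect_equal(introns$end, 39L)
  expect_equal(introns$name, "demoA")
  trna <- rec$features[rec$features$kind == "tRNA", ]
  expect_equal(trna$strand, -1L)
  expect_equal(trna$name, "trnX")
})

test_that("FASTA input yields records with empty feature tables", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">tiny", "ACGT"), path)
  rec <- read_genbank(path)
  expect_equal(rec$length, 4L)
  expect_equal(nrow(rec$features), 0L)
  expect_equal(rec$sequence, "ACGT")
})

test_that("malformed and degenerate inputs raise informative errors", {
  bad <- tempfile()
  writeLines(c("LOCUS       X 10 bp", "FEATURES",
               "     CDS             join(oops)", "ORIGIN",
               "        1 acgtacgtac", "//"), bad)
  expect_error(read_genbank(bad), "malformed GenBank location")
  empty <- tempfile()
  writeLines(c("LOCUS       X 0 bp", "ORIGIN", "//"), empty)
  expect_error(read_genbank(empty), "empty sequence")
  expect_error(plastome_record("x", "ACGRT"), "outside \\{A,C,G,T,N\\}")
})

test_that("GenBank read/write round-trips sequence and features bit-exactly", {
  rec <- read_genbank(write_toy_genbank())
  out <- tempfile(fileext = ".gb")
  write_genbank(rec, out)
  rec2 <- read_genbank(out)
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(rec2$features[order(rec2$features$start, rec2$features$kind), ],
                   rec$features[order(rec$features$start, rec$features$kind), ])
})

test_that("FASTA write/read round-trips and wraps at 70 columns", {
  toy <- toy_quadripartite()
  path <- tempfile(fileext = ".fa")
  write_fasta(toy$record, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[-1]) <= 70L))
  rec2 <- read_fasta(path)[[1]]
  expect_identical(rec2$sequence, toy$record$sequence)
})

test_that("find_quadripartite recovers a planted structure exactly", {
  toy <- toy_quadripartite(seed = 3)
  st <- find_quadripartite(toy$record, min_ir = 100)
  expect_equal(st$lsc_length, toy$lsc)
  expect_equal(st$ir_length, toy$ir)
  expect_equal(st$ssc_length, toy$ssc)
  rr <- region_report(st)
  expect_equal(rr$region, c("LSC", "IRb", "SSC", "IRa"))
  expect_equal(rr$length, c(toy$lsc, toy$ir, toy$ssc, toy$ir))
  # IRb is the reverse complement of IRa
  s <- toy$record$sequence
  expect_identical(substr(s, rr$start_1based[2], rr$end_1based[2]),
                   revcomp(substr(s, rr$start_1based[4], rr$end_1based[4])))
})

test_that("quadripartite tiling identity holds and failures are reported", {
  for (seed in 1:5) {
    toy <- toy_quadripartite(seed = seed, lsc = 800 + 37 * seed,
                             ir = 250 + 11 * seed, ssc = 150 + 7 * seed)
    st <- find_quadripartite(toy$record, min_ir = 100)
    expect_equal(st$lsc_length + st$ssc_length + 2L * st$ir_length,
                 toy$record$length)
  }
  set.seed(5)
  norep <- plastome_record("norep", random_seq(2000))
  expect_error(find_quadripartite(norep, min_ir = 100),
               "no inverted repeat")
})

test_that("an IR spanning the circular origin is still found", {
  g <- toy_quadripartite(seed = 11)$record$sequence
  # rotate so the linear origin falls inside IRa
  rot <- 1650
  g2 <- paste0(substr(g, rot + 1, nchar(g)), substr(g, 1, rot))
  st <- find_quadripartite(plastome_record("rot", g2), min_ir = 100)
  expect_equal(st$ir_length, 300L)
  expect_equal(st$lsc_length, 1000L)
  expect_equal(st$ssc_length, 200L)
})

test_that("classify_position distinguishes exon, intron and spacer", {
  rec <- read_genbank(write_toy_genbank())
  cls <- classify_position(rec, NULL, c(15L, 30L, 45L, 65L, 75L))
  expect_equal(cls$context, c("exon", "intron", "exon", "spacer", "exon"))
  expect_error(classify_position(rec, NULL, 101L), "out of range")
})

test_that("derived spacers are named from their flanking genes", {
  rec <- read_genbank(write_toy_genbank())
  sp <- spacer_intervals(rec)
  expect_true("demoA-trnX" %in% sp$name)
  inner <- sp[sp$name == "demoA-trnX", ]
  expect_equal(inner$start, 61L)
  expect_equal(inner$end, 69L)
})

test_that("gc_content follows the percentage convention", {
  expect_equal(gc_content("GGCC", percent = TRUE), 100)
  expect_equal(gc_content("ATAT", percent = TRUE), 0)
  expect_equal(gc_content("GCAT"), 0.5)
  expect_equal(gc_content("GCATN"), 0.5)  # N excluded from the denominator
  expect_error(gc_content("NNNN"), "all-N")
})
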