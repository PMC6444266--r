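# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-column / per-pair loops) so they share no code
# path with the package implementations they check.

# nucleotide diversity by explicit pairwise comparison
brute_pi <- function(rows) {
  chars <- lapply(rows, function(r) strsplit(r, "")[[1]])
  k <- length(chars)
  L <- length(chars[[1]])
  usable <- rep(TRUE, L)
  for (v in chars) usable <- usable & v != "-" & v != "N"
  nu <- sum(usable)
  if (nu == 0) return(NA_real_)
  tot <- 0
  np <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    d <- 0
    for (c in which(usable)) if (chars[[i]][c] != chars[[j]][c]) d <- d + 1
    tot <- tot + d / nu
    np <- np + 1
  }
  tot / np
}

# indel segmentation by walking columns one at a time
brute_indels <- function(m) {
  k <- nrow(m)
  events <- list()
  cur <- NULL
  for (c in seq_len(ncol(m))) {
    gaps <- sort(rownames(m)[m[, c] == "-"])
    key <- paste(gaps, collapse = ",")
    open <- length(gaps) > 0 && length(gaps) < k
    if (open && !is.null(cur) && cur$key == key) {
      cur$end <- c
    } else {
      if (!is.null(cur)) events[[length(events) + 1]] <- cur
      cur <- if (open) list(key = key, start = c, end = c) else NULL
    }
  }
  if (!is.null(cur)) events[[length(events) + 1]] <- cur
  if (!length(events)) {
    return(data.frame(col_start = integer(), col_end = integer(),
                      taxa_with_gap = character(), stringsAsFactors = FALSE))
  }
  data.frame(col_start = vapply(events, `[[`, 0, "start"),
             col_end = vapply(events, `[[`, 0, "end"),
             taxa_with_gap = vapply(events, `[[`, "", "key"),
             stringsAsFactors = FALSE)
}

# maximal perfect tandem repeats by exhaustive enumeration
brute_ssrs <- function(s, thresholds = default_ssr_thresholds()) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  hits <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    for (st in seq_len(n)) {
      motif <- paste(v[st:(st + u - 1)], collapse = "")
      if (st + u - 1 > n || grepl("N", motif)) next
      # minimal period u
      minper <- u
      for (p in seq_len(u - 1)) {
        if (u %% p == 0 &&
            motif == strrep(substr(motif, 1, p), u / p)) { minper <- p; break }
      }
      if (minper != u) next
      # count copies forward
      cp <- 1
      while (st + (cp + 1) * u - 1 <= n &&
             paste(v[(st + cp * u):(st + (cp + 1) * u - 1)], collapse = "") ==
             motif) cp <- cp + 1
      if (cp < thr) next
      # leftmost maximality: cannot extend one full copy left
      if (st - u >= 1 &&
          paste(v[(st - u):(st - 1)], collapse = "") == motif) next
      hits[[length(hits) + 1]] <- data.frame(
        start = st, end = st + cp * u - 1, motif = motif, unit_length = u,
        copy_number = cp, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit_length = integer(), copy_number = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # overlap resolution: smaller unit wins, then leftmost
  out <- out[order(out$unit_length, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i > 1) {
      prior <- out[seq_len(i - 1), , drop = FALSE][keep[seq_len(i - 1)], ,
                                                   drop = FALSE]
      if (nrow(prior) &&
          any(out$start[i] <= prior$end & out$end[i] >= prior$start)) {
        keep[i] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# random DNA string from a possibly skewed alphabet
random_seq <- function(n, prob = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

# a tiny hand-buildable quadripartite genome; junction bases are fixed so
# the planted IR is maximal at exactly the planted length
toy_quadripartite <- function(seed = 1, lsc = 1000, ir = 300, ssc = 200) {
  set.seed(seed)
  v <- strsplit(paste0(random_seq(lsc), random_seq(ir), random_seq(ssc)),
                "")[[1]]
  v <- c(v, strsplit(revcomp(paste(v[(lsc + 1):(lsc + ir)], collapse = "")),
                     "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (v[lsc] == comp[v[1]]) v[lsc] <- setdiff(c("A", "C"), v[lsc])[1]
  if (v[lsc + ir + 1] == comp[v[lsc + ir + ssc]]) {
    v[lsc + ir + 1] <- setdiff(c("A", "C"), v[lsc + ir + 1])[1]
  }
  list(record = plastome_record("toy", paste(v, collapse = "")),
       lsc = lsc, ir = ir, ssc = ssc)
}

# GenBank flat-file text for a 100 bp record with one 2-exon gene
toy_genbank_lines <- function() {
  set.seed(99)
  s <- tolower(random_seq(100))
  c("LOCUS       TOY0001 100 bp    DNA     circular PLN",
    "ACCESSION   TOY0001",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             join(10..20,40..60)",
    "                     /gene=\"demoA\"",
    "     tRNA            complement(70..80)",
    "                     /gene=\"trnX\"",
    "ORIGIN",
    paste0("        1 ", paste(substring(s, seq(1, 51, 10), seq(10, 60, 10)),
                               collapse = " ")),
    paste0("       61 ", paste(substring(s, seq(61, 91, 10),
                                         c(70, 80, 90, 100)),
                               collapse = " ")),
    "//")
}

write_toy_genbank <- function(path = tempfile(fileext = ".gb")) {
  writeLines(toy_genbank_lines(), path)
  path
}

# simulations reused across test files are cached per seed
.sim_cache <- new.env(parent = emptyenv())

small_sim <- function(seed = 42) {
  key <- paste0("small", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_quartet(sim_config(seed = seed))
  }
  .sim_cache[[key]]
}

full_sim <- function(seed = 3) {
  key <- paste0("full", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_quartet(sorghum_like_config(seed = seed))
  }
  .sim_cache[[key]]
}
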