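# Plastome records: reading GenBank flat files / FASTA, quadripartite
# structure detection, and region/context classification services used by
# every other module.
#
# A PlastomeRecord is a list(id, sequence, features, length) where features
# is a data.frame with columns name, kind, start, end, strand and kind is
# one of "gene-exon", "intron", "tRNA", "rRNA" ("spacer" features are always
# derived, never stored). Coordinates are 1-based inclusive throughout.

FEATURE_KINDS <- c("gene-exon", "intron", "tRNA", "rRNA")

#' Construct a plastome record
#'
#' @param id accession or taxon label.
#' @param sequence DNA string over A,C,G,T,N.
#' @param features data.frame with columns `name`, `kind`, `start`, `end`,
#'   `strand` (1-based inclusive intervals). May be empty.
#' @return an object of class `PlastomeRecord`.
#' @export
plastome_record <- function(id, sequence, features = empty_features()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for record '", id, "'")
  validate_dna(sequence, paste0("record '", id, "'"))
  stopifnot(is.data.frame(features))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    stopifnot(all(c("name", "kind", "start", "end", "strand") %in% names(features)))
    if (!all(features$kind %in% FEATURE_KINDS)) {
      stop("unknown feature kind: ",
           paste(setdiff(features$kind, FEATURE_KINDS), collapse = ", "))
    }
    if (any(features$start > features$end)) stop("feature with start > end")
    if (any(features$start < 1L) || any(features$end > nchar(sequence))) {
      stop("feature interval outside [1, genome length]")
    }
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, sequence = sequence, features = features,
                 length = nchar(sequence)),
            class = "PlastomeRecord")
}

#' @export
print.PlastomeRecord <- function(x, ...) {
  cat(sprintf("PlastomeRecord '%s': %d bp, %d features\n",
              x$id, x$length, nrow(x$features)))
  invisible(x)
}

empty_features <- function() {
  data.frame(name = character(), kind = character(), start = integer(),
             end = integer(), strand = integer(), stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------- GenBank --

# Parse a GenBank location string like "join(10..20,40..60)",
# "complement(join(...))", "100..200", "42". Returns list(intervals =
# 2-column matrix, strand). Partial markers < and > are tolerated.
parse_gb_location <- function(loc, line_no = NA) {
  raw <- loc
  strand <- 1L
  loc <- gsub("[<>[:space:]]", "", loc)
  while (grepl("^complement\\(", loc)) {
    strand <- -strand
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ivs <- lapply(parts, function(p) {
    p <- sub("^complement\\((.*)\\)$", "\\1", p)  # per-span complement: rare
    m <- regmatches(p, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", p))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed GenBank location '%s' (line %s)", raw, line_no),
           call. = FALSE)
    }
    a <- as.integer(m[2])
    b <- if (m[4] == "") a else as.integer(m[4])
    c(a, b)
  })
  list(intervals = do.call(rbind, ivs), strand = strand)
}

#' Read a plastome from a GenBank flat file or FASTA
#'
#' GenBank CDS features become `gene-exon` intervals (one per span of a
#' `join()` location) with introns derived as the inter-exon gaps of the
#' same feature; tRNA and rRNA features are kept as such. Spacers are never
#' read from file; they are derived on demand. A FASTA input yields a record
#' with an empty feature table.
#'
#' @param path file path.
#' @return a [plastome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  if (grepl("^>", lines[1])) return(read_fasta(path)[[1L]])
  if (!grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file or FASTA (line 1): ", lines[1])
  }
  id <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "[[:space:]]+")[[1]][1]
  acc_line <- grep("^VERSION|^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    acc <- strsplit(trimws(sub("^[A-Z]+", "", acc_line[1])), "[[:space:]]+")[[1]][1]
    if (!is.na(acc) && nzchar(acc)) id <- acc
  }

  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  if (!length(origin)) stop("no ORIGIN section in ", path)
  terminator <- grep("^//", lines)
  seq_end <- if (length(terminator)) terminator[1] - 1L else length(lines)
  if (seq_end <= origin[1]) stop("empty sequence in ", path)
  seq_lines <- lines[(origin[1] + 1L):seq_end]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("empty sequence in ", path)

  feats <- empty_features()
  if (length(feat_start)) {
    fend <- origin[1] - 1L
    flines <- lines[(feat_start[1] + 1L):fend]
    fnums <- (feat_start[1] + 1L):fend
    # a feature line has a key in columns 6-20; continuation lines are blank there
    is_key <- grepl("^ {5}[A-Za-z]", flines) & !grepl("^ {21}", flines)
    idx <- which(is_key)
    recs <- list()
    for (j in seq_along(idx)) {
      i0 <- idx[j]
      i1 <- if (j < length(idx)) idx[j + 1L] - 1L else length(flines)
      block <- flines[i0:i1]
      key <- sub("^ +([A-Za-z0-9_'-]+).*$", "\\1", block[1])
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      # location: remainder of first line plus continuation lines up to the
      # first qualifier line (starting with /)
      loc <- trimws(sub("^ +[A-Za-z0-9_'-]+ +", "", block[1]))
      kk <- 2L
      while (kk <= length(block) && !grepl("^ +/", block[kk])) {
        loc <- paste0(loc, trimws(block[kk]))
        kk <- kk + 1L
      }
      quals <- block[grepl("^ +/", block)]
      getq <- function(q) {
        hit <- grep(paste0("^ +/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^ +/", q, "="), "", hit[1]))
      }
      name <- getq("gene")
      if (is.na(name)) name <- getq("product")
      if (is.na(name)) name <- paste0(key, "_", fnums[i0])
      pl <- parse_gb_location(loc, line_no = fnums[i0])
      kind <- switch(key, CDS = "gene-exon", tRNA = "tRNA", rRNA = "rRNA")
      iv <- pl$intervals[order(pl$intervals[, 1]), , drop = FALSE]
      recs[[length(recs) + 1L]] <- data.frame(
        name = name, kind = kind, start = iv[, 1], end = iv[, 2],
        strand = pl$strand, stringsAsFactors = FALSE)
      if (nrow(iv) > 1L) {
        gaps <- cbind(iv[-nrow(iv), 2] + 1L, iv[-1L, 1] - 1L)
        gaps <- gaps[gaps[, 1] <= gaps[, 2], , drop = FALSE]
        if (nrow(gaps)) {
          recs[[length(recs) + 1L]] <- data.frame(
            name = name, kind = "intron", start = gaps[, 1], end = gaps[, 2],
            strand = pl$strand, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(recs)) feats <- do.call(rbind, recs)
  }
  plastome_record(id, sequence, feats)
}

#' Write a plastome record as a GenBank flat file
#'
#' Emits LOCUS, FEATURES (CDS with join() locations rebuilt from the exon
#' intervals, tRNA/rRNA as single spans) and ORIGIN. Derived introns are not
#' written; [read_genbank()] re-derives them, so read/write round-trips.
#'
#' @param record a [plastome_record()].
#' @param path output file.
#' @export
write_genbank <- function(record, path) {
  out <- c(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                   record$id, record$length),
           sprintf("ACCESSION   %s", record$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", record$length))
  f <- record$features
  f <- f[f$kind != "intron", , drop = FALSE]
  if (nrow(f)) {
    for (nm in unique(paste(f$name, f$kind, sep = "\r"))) {
      g <- f[paste(f$name, f$kind, sep = "\r") == nm, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      spans <- sprintf("%d..%d", g$start, g$end)
      loc <- if (length(spans) > 1L) paste0("join(", paste(spans, collapse = ","), ")")
             else spans
      if (g$strand[1] < 0L) loc <- paste0("complement(", loc, ")")
      key <- switch(g$kind[1], `gene-exon` = "CDS", tRNA = "tRNA", rRNA = "rRNA")
      out <- c(out,
               sprintf("     %-16s%s", key, loc),
               sprintf("                     /gene=\"%s\"", g$name[1]))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  starts <- seq(1L, record$length, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, record$length))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ------------------------------------------------------------------ FASTA --

#' Read plastome records from a FASTA file
#'
#' @param path FASTA file.
#' @return list of [plastome_record()]s (empty feature tables).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("empty FASTA: ", path)
  ids <- sub("[[:space:]].*$", "", names(set))
  lapply(seq_along(set), function(i) {
    plastome_record(ids[i], as.character(set[[i]]))
  })
}

#' Write plastome records to FASTA (70-column wrapped)
#'
#' @param records a record or list of records.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "PlastomeRecord")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

## ---------------------------------------------------- quadripartite split --

# circular arc [start, end] (1-based inclusive; start > end means the arc
# wraps through the origin)
arc_length <- function(arc, n) {
  if (arc[1] <= arc[2]) arc[2] - arc[1] + 1L else n - arc[1] + 1L + arc[2]
}

arc_contains <- function(arc, pos, n) {
  if (arc[1] <= arc[2]) pos >= arc[1] & pos <= arc[2]
  else pos >= arc[1] | pos <= arc[2]
}

arc_seq <- function(seq, arc) {
  if (arc[1] <= arc[2]) substr(seq, arc[1], arc[2])
  else paste0(substr(seq, arc[1], nchar(seq)), substr(seq, 1L, arc[2]))
}

# longest shared prefix length of two strings, by doubling block comparison
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  got <- 0L
  block <- 1024L
  while (got < n) {
    w <- min(block, n - got)
    if (substr(a, got + 1L, got + w) == substr(b, got + 1L, got + w)) {
      got <- got + w
      block <- block * 2L
    } else {
      # narrow down within this block
      lo <- 0L; hi <- w
      while (lo < hi) {
        mid <- (lo + hi + 1L) %/% 2L
        if (substr(a, got + 1L, got + mid) == substr(b, got + 1L, got + mid)) {
          lo <- mid
        } else hi <- mid - 1L
      }
      return(got + lo)
    }
  }
  got
}

#' Detect the quadripartite LSC/IRb/SSC/IRa structure
#'
#' Finds the longest pair of exact reverse-complement repeats of length >=
#' `min_ir` whose copies do not overlap (the genome is treated as circular,
#' so the wrap-around junction is searched too). The longer inter-repeat
#' segment is the LSC, the shorter the SSC; the IR copy immediately
#' following the LSC in genome order is IRb.
#'
#' @param record a [plastome_record()].
#' @param min_ir minimum inverted-repeat length in bp (default 10000).
#' @return an object of class `QuadripartiteStructure` with arcs `lsc`,
#'   `irb`, `ssc`, `ira` (1-based inclusive; `start > end` denotes a wrap
#'   through the origin) and lengths.
#' @export
find_quadripartite <- function(record, min_ir = 10000L) {
  s <- record$sequence
  n <- record$length
  if (min_ir < 4L) stop("min_ir must be >= 4")
  if (n < 2L * min_ir) stop("no inverted repeat found (genome shorter than 2*min_ir)")
  s2 <- paste0(s, s)
  rc2 <- revcomp(s2)
  k <- min(min_ir, 24L)
  stride <- max(1L, min_ir - k + 1L)
  probes <- seq(1L, n, by = stride)
  rc2d <- Biostrings::DNAString(gsub("N", "A", rc2))  # N never matches planted IRs
  pairs <- list()
  seen <- character()
  for (p in probes) {
    kmer <- substr(s2, p, p + k - 1L)
    if (grepl("N", kmer, fixed = TRUE)) next
    hits <- Biostrings::start(Biostrings::matchPattern(kmer, rc2d))
    for (h in hits) {
      # extend the exact match maximally in both directions
      right <- common_prefix_len(substr(s2, p + k, 2L * n),
                                 substr(rc2, h + k, 2L * n))
      # leftward: compare reversed prefixes via mirrored coordinates
      lo <- 0L
      while (p - lo - 1L >= 1L && h - lo - 1L >= 1L &&
             substr(s2, p - lo - 1L, p - lo - 1L) ==
             substr(rc2, h - lo - 1L, h - lo - 1L)) lo <- lo + 1L
      A <- p - lo
      B <- h - lo
      L <- k + right + lo
      if (L < min_ir) next
      if (L > n %/% 2L) L <- n %/% 2L
      # map rc2 occurrence back to forward coordinates in s2
      fwdB <- 2L * n - (B + L - 1L) + 1L
      a0 <- (A - 1L) %% n + 1L
      b0 <- (fwdB - 1L) %% n + 1L
      key <- paste(min(a0, b0), max(a0, b0), L)
      if (key %in% seen) next
      seen <- c(seen, key)
      arc1 <- c(a0, (a0 + L - 2L) %% n + 1L)
      arc2 <- c(b0, (b0 + L - 2L) %% n + 1L)
      # copies must be disjoint on the circle
      if (arc_contains(arc1, arc2[1], n) || arc_contains(arc1, arc2[2], n) ||
          arc_contains(arc2, arc1[1], n) || arc_contains(arc2, arc1[2], n)) next
      pairs[[length(pairs) + 1L]] <- list(a = arc1, b = arc2, L = L)
    }
  }
  if (!length(pairs)) stop("no inverted repeat found (>= ", min_ir, " bp)")
  Ls <- vapply(pairs, function(x) as.integer(x$L), 0L)
  starts <- vapply(pairs, function(x) as.integer(min(x$a[1], x$b[1])), 0L)
  best <- pairs[[order(-Ls, starts)[1L]]]
  # the two single-copy arcs between the IR copies
  gap_after <- function(ir1, ir2) {
    st <- ir1[2] %% n + 1L
    en <- (ir2[1] - 2L) %% n + 1L
    len <- (ir2[1] - 1L - ir1[2]) %% n
    list(arc = c(st, en), len = len)
  }
  g1 <- gap_after(best$a, best$b)  # after copy a, before copy b
  g2 <- gap_after(best$b, best$a)
  if (g1$len == 0L || g2$len == 0L) {
    stop("degenerate structure: inverted repeat copies are adjacent")
  }
  if (g1$len >= g2$len) {
    lsc <- g1; ssc <- g2; irb <- best$b; ira <- best$a
  } else {
    lsc <- g2; ssc <- g1; irb <- best$a; ira <- best$b
  }
  st <- structure(list(
    lsc = lsc$arc, irb = irb, ssc = ssc$arc, ira = ira,
    lsc_length = lsc$len, ssc_length = ssc$len, ir_length = best$L,
    genome_length = n), class = "QuadripartiteStructure")
  stopifnot(st$lsc_length + st$ssc_length + 2L * st$ir_length == n)
  st
}

#' @export
print.QuadripartiteStructure <- function(x, ...) {
  cat(sprintf("Quadripartite structure (%d bp): LSC %d bp, IR %d bp x2, SSC %d bp\n",
              x$genome_length, x$lsc_length, x$ir_length, x$ssc_length))
  invisible(x)
}

#' Region of genome positions
#'
#' @param structure a `QuadripartiteStructure`.
#' @param positions integer vector of 1-based genome positions.
#' @return character vector over `"LSC"`, `"SSC"`, `"IR"` (both IR copies
#'   are one region class).
#' @export
region_of <- function(structure, positions) {
  n <- structure$genome_length
  if (any(positions < 1L | positions > n)) stop("position out of range")
  out <- rep("IR", length(positions))
  out[arc_contains(structure$lsc, positions, n)] <- "LSC"
  out[arc_contains(structure$ssc, positions, n)] <- "SSC"
  out
}

## ------------------------------------------------------- context labeling --

#' Derived intergenic spacers
#'
#' Gene spans (union of each named feature's exons and introns) are merged;
#' the gaps between consecutive spans are spacers named `"geneA-geneB"`.
#' The wrap-around gap between the last and first span is included.
#'
#' @param record a [plastome_record()].
#' @return data.frame with columns `name`, `start`, `end` (a wrap-around
#'   spacer has `start > end`).
#' @export
spacer_intervals <- function(record) {
  f <- record$features
  if (!nrow(f)) {
    return(data.frame(name = "genome", start = 1L, end = record$length,
                      stringsAsFactors = FALSE))
  }
  # one span per gene locus: same-name features further apart than a
  # plausible intron (IR-duplicated genes, trans-spliced exons) form
  # separate loci
  spans <- do.call(rbind, lapply(split(f, f$name), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    cl <- cumsum(c(1L, diff(g$start) > 3000L))
    do.call(rbind, lapply(split(g, cl), function(h) {
      data.frame(name = h$name[1], start = min(h$start), end = max(h$end),
                 stringsAsFactors = FALSE)
    }))
  }))
  spans <- spans[order(spans$start), , drop = FALSE]
  # merge overlapping gene spans, keeping a compound name for flank lookup
  merged <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1L) for (i in 2:nrow(spans)) {
    last <- nrow(merged)
    if (spans$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], spans$end[i])
    } else merged <- rbind(merged, spans[i, ])
  }
  rownames(merged) <- NULL
  out <- list()
  if (nrow(merged) > 1L) for (i in 1:(nrow(merged) - 1L)) {
    a <- merged$end[i] + 1L; b <- merged$start[i + 1L] - 1L
    if (a <= b) out[[length(out) + 1L]] <- data.frame(
      name = paste0(merged$name[i], "-", merged$name[i + 1L]),
      start = a, end = b, stringsAsFactors = FALSE)
  }
  # circular wrap spacer (possibly split across the origin, start > end)
  a <- merged$end[nrow(merged)] + 1L
  b <- merged$start[1L] - 1L
  wrap_name <- paste0(merged$name[nrow(merged)], "-", merged$name[1L])
  if (a <= record$length && b >= 1L) {
    out[[length(out) + 1L]] <- data.frame(name = wrap_name, start = a, end = b,
                                          stringsAsFactors = FALSE)
  } else if (a <= record$length) {
    out[[length(out) + 1L]] <- data.frame(name = wrap_name, start = a,
                                          end = record$length,
                                          stringsAsFactors = FALSE)
  } else if (b >= 1L) {
    out[[length(out) + 1L]] <- data.frame(name = wrap_name, start = 1L, end = b,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify genome positions by region and genic context
#'
#' Context is `"exon"` if the position lies in any exon, tRNA or rRNA
#' interval, `"intron"` if it lies in a derived intron, otherwise
#' `"spacer"`. Interval features (an SSR locus, an indel) are labeled by
#' their start position.
#'
#' @param record a [plastome_record()].
#' @param structure its `QuadripartiteStructure` (or `NULL` for context only).
#' @param positions 1-based genome positions.
#' @return data.frame with columns `position`, `region`, `context`.
#' @export
classify_position <- function(record, structure, positions) {
  if (any(positions < 1L | positions > record$length)) {
    stop("position out of range [1, ", record$length, "]")
  }
  f <- record$features
  context <- rep("spacer", length(positions))
  if (nrow(f)) {
    ex <- f[f$kind %in% c("gene-exon", "tRNA", "rRNA"), , drop = FALSE]
    intr <- f[f$kind == "intron", , drop = FALSE]
    in_any <- function(tab, pos) {
      if (!nrow(tab)) return(rep(FALSE, length(pos)))
      ir <- IRanges::IRanges(tab$start, tab$end)
      IRanges::overlapsAny(IRanges::IRanges(pos, pos), ir)
    }
    context[in_any(intr, positions)] <- "intron"
    context[in_any(ex, positions)] <- "exon"
  }
  region <- if (is.null(structure)) rep(NA_character_, length(positions))
            else region_of(structure, positions)
  data.frame(position = positions, region = region, context = context,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------- reports --

#' GC content of a record
#'
#' @param record a [plastome_record()] (or a plain DNA string).
#' @param percent if `TRUE`, return a percentage rounded to one decimal
#'   (the convention of published plastome tables); otherwise a fraction.
#' @return numeric scalar; counts G+C over non-N bases.
#' @export
gc_content <- function(record, percent = FALSE) {
  s <- if (inherits(record, "PlastomeRecord")) record$sequence else toupper(record)
  v <- seq_chars(s)
  den <- sum(v != "N")
  if (den == 0L) stop("all-N sequence: GC content undefined")
  frac <- sum(v == "G" | v == "C") / den
  if (percent) round(100 * frac, 1) else frac
}

#' Quadripartite region report
#'
#' @param structure a `QuadripartiteStructure`.
#' @return data.frame with columns `region`, `start_1based`, `end_1based`,
#'   `length`, rows LSC, IRb, SSC, IRa.
#' @export
region_report <- function(structure) {
  n <- structure$genome_length
  rows <- list(c("LSC", structure$lsc), c("IRb", structure$irb),
               c("SSC", structure$ssc), c("IRa", structure$ira))
  data.frame(
    region = vapply(rows, `[`, "", 1),
    start_1based = as.integer(vapply(rows, `[`, "", 2)),
    end_1based = as.integer(vapply(rows, `[`, "", 3)),
    length = vapply(rows, function(r) {
      arc_length(as.integer(r[2:3]), n)
    }, 0L),
    stringsAsFactors = FALSE)
}
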