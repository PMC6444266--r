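# End-to-end orchestration: partition -> SSR -> variants -> diversity, with
# TSV/BED/GFF3/JSON outputs and an internally consistent summary.

#' Run the comparative plastome pipeline
#'
#' Executes quadripartite partitioning and SSR scanning on every genome,
#' then — when an alignment is available — SNP/indel/inversion calling and
#' the sliding-window diversity profile, and aggregates the per-module
#' tables into one summary. All thresholds default to the standard values
#' (SSR 10/5/4/3/3/3, window 600, step 100, hotspot pi > 0.01, inversions
#' 2-6 bp with 3-20 bp stems).
#'
#' @param genomes named list of [plastome_record()]s, or a character vector
#'   of GenBank/FASTA paths.
#' @param alignment an [alignment_set()], an aligned-FASTA path, or `NULL`
#'   for single-genome (SSR + partition) mode.
#' @param reference taxon used as coordinate reference (default: first
#'   genome).
#' @param outdir optional output directory for TSV/BED/JSON files.
#' @param thresholds SSR thresholds.
#' @param min_ir minimum IR length for partitioning.
#' @param window,step,pi_threshold diversity parameters.
#' @param min_inv,max_inv,min_flank,max_flank inversion parameters.
#' @return list of class `PipelineResult`: `genomes`, `structures`, `ssr`
#'   (per-genome tables), `ssr_summary`, `variants`, `diversity`, `summary`.
#' @export
run_pipeline <- function(genomes, alignment = NULL, reference = NULL,
                         outdir = NULL,
                         thresholds = default_ssr_thresholds(),
                         min_ir = 10000L, window = 600L, step = 100L,
                         pi_threshold = 0.01, min_inv = 2L, max_inv = 6L,
                         min_flank = 3L, max_flank = 20L) {
  if (is.character(genomes)) {
    genomes <- lapply(genomes, read_genbank)
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  }
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  }
  reference <- reference %||% names(genomes)[1L]
  stopifnot(reference %in% names(genomes))

  structures <- lapply(genomes, function(g) {
    tryCatch(find_quadripartite(g, min_ir = min_ir), error = function(e) NULL)
  })
  ssr <- lapply(names(genomes), function(nm) {
    scan_ssrs(genomes[[nm]], thresholds, structures[[nm]])
  })
  names(ssr) <- names(genomes)
  ssr_all <- do.call(rbind, ssr)
  ssr_summary <- summarize_ssrs(ssr_all)

  variants <- NULL
  diversity <- NULL
  if (!is.null(alignment)) {
    aln <- if (inherits(alignment, "AlignmentSet")) alignment
           else load_alignment(alignment, reference)
    stopifnot(aln$reference_taxon == reference)
    ref_rec <- genomes[[reference]]
    ref_str <- structures[[reference]]
    variants <- call_variants(aln, ref_str, ref_rec, thresholds,
                              min_inv, max_inv, min_flank, max_flank)
    diversity <- sliding_profile(aln, window, step, pi_threshold,
                                 ref_rec, ref_str)
  }

  summary <- build_summary(genomes, structures, ssr, ssr_summary,
                           variants, diversity)
  res <- structure(list(genomes = genomes, structures = structures,
                        ssr = ssr, ssr_summary = ssr_summary,
                        variants = variants, diversity = diversity,
                        summary = summary),
                   class = "PipelineResult")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

build_summary <- function(genomes, structures, ssr, ssr_summary, variants,
                          diversity) {
  per_genome <- lapply(names(genomes), function(nm) {
    g <- genomes[[nm]]; st <- structures[[nm]]
    list(id = nm, size_bp = g$length,
         lsc_length = if (is.null(st)) NA else st$lsc_length,
         ir_length = if (is.null(st)) NA else st$ir_length,
         ssc_length = if (is.null(st)) NA else st$ssc_length,
         gc_percent = gc_content(g, percent = TRUE),
         n_genes = length(unique(g$features$name[
           g$features$kind %in% c("gene-exon", "tRNA", "rRNA")])),
         n_ssrs = nrow(ssr[[nm]]))
  })
  out <- list(genomes = per_genome,
              ssr = list(total = ssr_summary$total,
                         by_unit = ssr_summary$by_unit,
                         by_region = ssr_summary$by_region,
                         by_context = ssr_summary$by_context))
  if (!is.null(variants)) {
    sm <- variants$snps$summary
    ind <- variants$indels
    out$snps <- list(total_sites = sm$n_sites,
                     substitutions = sm$n_substitutions,
                     class_counts = as.list(sm$class_counts),
                     ts = sm$ts, tv = sm$tv, tv_ts_ratio = sm$tv_ts_ratio,
                     region_counts = as.list(sm$region_counts),
                     pairwise = sm$pairwise)
    out$indels <- list(
      total = nrow(ind),
      ssr_indels = sum(ind$classification == "SSR-indel"),
      nr_indels = sum(ind$classification == "NR-indel"),
      largest_nr = if (any(ind$classification == "NR-indel")) {
        max(ind$length[ind$classification == "NR-indel"])
      } else 0L,
      insertions = sum(ind$polarity == "insertion"),
      deletions = sum(ind$polarity == "deletion"))
    out$inversions <- list(total = nrow(variants$inversions),
                           table = variants$inversions)
    # internal consistency of the headline tallies
    stopifnot(out$indels$ssr_indels + out$indels$nr_indels == out$indels$total)
    stopifnot(sum(sm$class_counts) == sm$ts + sm$tv)
  }
  if (!is.null(diversity)) {
    out$diversity <- list(mean_pi = diversity$mean_pi,
                          n_windows = nrow(diversity$windows),
                          n_hotspots = nrow(diversity$hotspots),
                          hotspots = diversity$hotspots)
  }
  out
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("Plastome pipeline result\n")
  for (g in x$summary$genomes) {
    cat(sprintf("  %s: %d bp, GC %.1f%%, %d SSRs\n",
                g$id, g$size_bp, g$gc_percent, g$n_ssrs))
  }
  if (!is.null(x$summary$snps)) {
    s <- x$summary$snps
    cat(sprintf("  SNP sites: %d (Ts %d, Tv %d, Tv/Ts %.2f)\n",
                s$total_sites, s$ts, s$tv, s$tv_ts_ratio))
    i <- x$summary$indels
    cat(sprintf("  indels: %d (%d SSR, %d NR), inversions: %d\n",
                i$total, i$ssr_indels, i$nr_indels,
                x$summary$inversions$total))
  }
  if (!is.null(x$summary$diversity)) {
    d <- x$summary$diversity
    cat(sprintf("  mean pi %.5f over %d windows, %d hotspot(s)\n",
                d$mean_pi, d$n_windows, d$n_hotspots))
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' Per-genome region-report and SSR TSVs, SNP/indel/inversion TSVs, window
#' profile TSV, hotspot BED (0-based half-open) and a `summary.json`.
#'
#' @param res a `PipelineResult`.
#' @param outdir directory (created if needed).
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$genomes)) {
    if (!is.null(res$structures[[nm]])) {
      write_tsv(region_report(res$structures[[nm]]),
                file.path(outdir, paste0(nm, ".regions.tsv")))
    }
  }
  ssr_all <- do.call(rbind, res$ssr)
  ssr_out <- data.frame(genome_id = ssr_all$genome_id,
                        start_1based = ssr_all$start,
                        end_1based = ssr_all$end,
                        motif = ssr_all$motif,
                        canonical_class = ssr_all$canonical_class,
                        unit_length = ssr_all$unit_length,
                        copy_number = ssr_all$copy_number,
                        region = ssr_all$region, context = ssr_all$context)
  write_tsv(ssr_out, file.path(outdir, "ssr.tsv"))
  if (!is.null(res$variants)) {
    s <- res$variants$snps$sites
    write_tsv(data.frame(column = s$column, ref_position = s$ref_position,
                         alleles = s$alleles, class = s$class,
                         region = s$region),
              file.path(outdir, "snps.tsv"))
    write_tsv(res$variants$indels, file.path(outdir, "indels.tsv"))
    write_tsv(res$variants$inversions, file.path(outdir, "inversions.tsv"))
  }
  if (!is.null(res$diversity)) {
    w <- res$diversity$windows
    write_tsv(data.frame(window_index = w$window_index,
                         midpoint_ref_1based = w$midpoint_ref,
                         usable_sites = w$usable_sites, pi = w$pi),
              file.path(outdir, "diversity.tsv"))
    h <- res$diversity$hotspots
    if (nrow(h)) {
      bed <- data.frame(chrom = "reference", start = h$ref_start - 1L,
                        end = h$ref_end, name = gsub("[ ,]+", "|", h$features),
                        score = h$peak_pi)
      utils::write.table(bed, file.path(outdir, "hotspots.bed"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  json <- summary_for_json(res$summary)
  jsonlite::write_json(json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

# data.frames -> plain lists for stable JSON
summary_for_json <- function(s) {
  rapply(s, function(x) x, how = "replace")
}

#' Export a record's annotation as GFF3
#'
#' @param record a [plastome_record()].
#' @param path output file.
#' @export
write_gff3 <- function(record, path) {
  f <- record$features
  type <- c(`gene-exon` = "exon", intron = "intron", tRNA = "tRNA",
            rRNA = "rRNA")[f$kind]
  gr <- GenomicRanges::GRanges(
    seqnames = record$id,
    ranges = IRanges::IRanges(f$start, f$end),
    strand = ifelse(f$strand < 0, "-", "+"),
    type = type, Name = f$name, gene = f$name)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
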