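# Pipeline orchestration and serialization: extract -> scan (PWM + consensus)
# -> optional enrichment; merged hit tables written as TSV, BED6 and JSON.

#' Pipeline configuration
#'
#' @param fasta path to the genomic/promoter FASTA.
#' @param seq_id record id to use (default: first record).
#' @param tss_genomic 1-based TSS coordinate (NA when `fasta` already contains
#'   the extracted promoter; then the whole first record is the window).
#' @param upstream_len window length (default 3000).
#' @param gene_strand strand of the gene, `"+"` or `"-"`.
#' @param jaspar path to a JASPAR PFM file, or NULL to skip the PWM arm.
#' @param motifs consensus families (default the six bundled circadian
#'   families), or a config-file path for [circadian_motifs()].
#' @param pwm_config,consensus_cfg scan configurations.
#' @param enrich run the enrichment stage (default FALSE).
#' @param enrich_config an [enrichment_config()].
#' @param markov_order background order for enrichment.
#' @param out_prefix if non-NULL, write `<prefix>_hits.tsv`, `<prefix>.bed`,
#'   `<prefix>_report.json` (and `<prefix>_enrichment.tsv` when enriching).
#' @param seed global seed (used by the enrichment stage only; scanning is
#'   deterministic).
#' @param assembly_label free-text assembly tag.
#' @param verbose log stage-by-stage cardinalities via [message()].
#' @return a `run_config` list.
#' @export
run_config <- function(fasta, seq_id = NULL, tss_genomic = NA,
                       upstream_len = 3000, gene_strand = "+",
                       jaspar = NULL, motifs = circadian_motifs(),
                       pwm_config = scan_config(),
                       consensus_cfg = consensus_config(),
                       enrich = FALSE, enrich_config = enrichment_config(),
                       markov_order = 0, out_prefix = NULL, seed = NULL,
                       assembly_label = "", verbose = FALSE) {
  if (is.character(motifs) && length(motifs) == 1) {
    motifs <- circadian_motifs(motifs)
  }
  structure(list(fasta = fasta, seq_id = seq_id, tss_genomic = tss_genomic,
                 upstream_len = upstream_len, gene_strand = gene_strand,
                 jaspar = jaspar, motifs = motifs, pwm_config = pwm_config,
                 consensus_cfg = consensus_cfg, enrich = enrich,
                 enrich_config = enrich_config, markov_order = markov_order,
                 out_prefix = out_prefix, seed = seed,
                 assembly_label = assembly_label, verbose = verbose),
            class = "run_config")
}

#' Run the full promoter motif pipeline
#'
#' Extracts the TSS-anchored window (unless the FASTA is already a promoter),
#' runs the consensus scan and, when PFMs are supplied, the PWM scan over the
#' same window, merges the hits, and optionally tests enrichment. Scanning is
#' deterministic; the seed covers only the enrichment resampling.
#'
#' @param config a [run_config()].
#' @return a `hit_report`: list with `region`, `hits` (merged `motif_hits`),
#'   `counts_by_family`, `counts_by_source`, `enrichment` (or NULL), `config`.
#'   Files are written when `out_prefix` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message("[circamotif] ", ...)

  records <- read_fasta(config$fasta)
  rec <- if (is.null(config$seq_id)) records[[1]] else {
    ids <- vapply(records, `[[`, character(1), "id")
    hit <- which(ids == config$seq_id)
    if (!length(hit)) stop("extract stage: record '", config$seq_id,
                           "' not found in ", config$fasta)
    records[[hit[1]]]
  }
  say("extract: record '", rec$id, "' (", nchar(rec$sequence), " bases)")

  region <- if (is.na(config$tss_genomic)) {
    structure(list(source_id = rec$id, tss_genomic = NA_integer_,
                   strand = "+", length = nchar(rec$sequence),
                   sequence = rec$sequence,
                   assembly_label = config$assembly_label),
              class = "promoter_region")
  } else {
    extract_promoter(rec, config$tss_genomic, config$upstream_len,
                     config$gene_strand,
                     assembly_label = config$assembly_label)
  }
  say("extract: window ", -region$length, " .. -1")

  cons_hits <- scan_consensus(region, config$motifs, config$consensus_cfg)
  say("scan-consensus: ", nrow(cons_hits), " hits across ",
      length(config$motifs), " families")

  pwm_hits <- empty_hits()
  pwms <- NULL
  if (!is.null(config$jaspar)) {
    pfms <- parse_jaspar(config$jaspar, is_file = TRUE)
    pwms <- lapply(pfms, pfm_to_pwm)
    pwm_hits <- do.call(rbind, c(lapply(pwms, scan_pwm, region = region,
                                        config = config$pwm_config),
                                 list(empty_hits())))
    say("scan-pwm: ", nrow(pwm_hits), " hits from ", length(pwms),
        " matrices at threshold ", config$pwm_config$rel_threshold)
  }

  hits <- rbind(as.data.frame(cons_hits), as.data.frame(pwm_hits))
  hits <- hits[order(hits$rel_start, hits$family,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  rownames(hits) <- NULL
  hits <- as_motif_hits(hits, region)

  enrichment <- NULL
  if (config$enrich) {
    ecfg <- config$enrich_config
    if (!is.null(config$seed) && is.null(ecfg$seed)) ecfg$seed <- config$seed
    enrichment <- test_enrichment(region, config$motifs, pwms = pwms,
                                  order = config$markov_order, config = ecfg,
                                  consensus_cfg = config$consensus_cfg,
                                  pwm_config = config$pwm_config)
    say("enrich: ", sum(enrichment$enriched), "/", nrow(enrichment),
        " families flagged at alpha ", ecfg$alpha)
  }

  report <- structure(
    list(region = region, hits = hits,
         counts_by_family = count_by_family(hits),
         counts_by_source = count_by_family(
           as_motif_hits(transform(as.data.frame(hits), family = source))),
         enrichment = enrichment, config = config,
         version = as.character(utils::packageVersion("circamotif"))),
    class = "hit_report")

  if (!is.null(config$out_prefix)) {
    p <- config$out_prefix
    write_hits_tsv(hits, paste0(p, "_hits.tsv"))
    write_bed(hits, region, paste0(p, ".bed"))
    write_report_json(report, paste0(p, "_report.json"))
    if (!is.null(enrichment)) {
      utils::write.table(as.data.frame(enrichment),
                         paste0(p, "_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    say("wrote outputs with prefix '", p, "'")
  }
  report
}

#' Write hits as a TSV table
#'
#' Columns: family, source, rel_start (TSS-relative, negative = upstream),
#' strand, matched, raw_score, rel_score.
#'
#' @param hits a `motif_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write hits as BED6
#'
#' Genomic coordinates are 0-based half-open. For a + strand region,
#' `chromStart = tss_genomic - 1 + rel_start`; for a − strand region the
#' interval is mirrored downstream of the TSS and the hit strand is flipped.
#' PWM hits carry `score = round(1000 * rel_score)`; consensus hits carry 0.
#' Regions without a genomic anchor (`tss_genomic` NA) use window-local
#' coordinates `rel_start + L`.
#'
#' @param hits a `motif_hits` data frame.
#' @param region the `promoter_region` the hits came from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, region, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# BED6; promoter window ", -region$length, "..-1 of TSS ",
                    region$tss_genomic, " (", region$source_id, ")"), con)
  if (nrow(hits) == 0) return(invisible(path))
  w <- nchar(hits$matched)
  if (is.na(region$tss_genomic)) {
    start0 <- hits$rel_start + region$length
    strand <- hits$strand
  } else if (region$strand == "+") {
    start0 <- region$tss_genomic - 1 + hits$rel_start
    strand <- hits$strand
  } else {
    start0 <- region$tss_genomic - hits$rel_start - w
    strand <- ifelse(hits$strand == "+", "-", "+")
  }
  score <- ifelse(hits$source == "pwm" & !is.na(hits$rel_score),
                  round(1000 * hits$rel_score), 0)
  lines <- paste(region$source_id, start0, start0 + w,
                 paste0(hits$family, ":", hits$source), score, strand,
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Back-transform BED genomic starts to TSS-relative positions
#'
#' Inverse of the coordinate mapping used by [write_bed()] for + strand
#' regions: `rel_start = chromStart - (tss_genomic - 1)`.
#'
#' @param chrom_start 0-based genomic start(s).
#' @param region the `promoter_region`.
#' @return TSS-relative start position(s).
#' @export
bed_start_to_rel <- function(chrom_start, region) {
  if (region$strand != "+") stop("only + strand regions supported")
  chrom_start - (region$tss_genomic - 1)
}

#' Write the full report as JSON
#'
#' @param report a `hit_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  cfg <- report$config
  out <- list(
    source_id = report$region$source_id,
    assembly = report$region$assembly_label,
    tss_genomic = report$region$tss_genomic,
    window_length = report$region$length,
    gene_strand = report$region$strand,
    seed = cfg$seed,
    version = report$version,
    pwm_threshold = cfg$pwm_config$rel_threshold,
    counts_by_family = as.list(report$counts_by_family),
    counts_by_source = as.list(report$counts_by_source),
    hits = as.data.frame(report$hits),
    enrichment = if (is.null(report$enrichment)) NULL else
      as.data.frame(report$enrichment)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Summarize a hit list
#'
#' @param object a `motif_hits` data frame.
#' @param ... unused.
#' @return a `hits_summary`: per-family counts, per-source counts, and a
#'   TSS-relative site map ordered upstream to downstream.
#' @export
summary.motif_hits <- function(object, ...) {
  map <- as.data.frame(object)[, c("family", "rel_start", "strand", "source")]
  map <- map[order(map$rel_start), , drop = FALSE]
  rownames(map) <- NULL
  structure(list(
    n = nrow(object),
    by_family = count_by_family(object),
    by_source = count_by_family(
      as_motif_hits(transform(as.data.frame(object), family = source))),
    map = map),
    class = "hits_summary")
}

#' @export
print.hits_summary <- function(x, ...) {
  cat("Motif hits:", x$n, "\n")
  if (x$n == 0) return(invisible(x))
  cat("  by source: ",
      paste(sprintf("%s=%d", names(x$by_source), x$by_source),
            collapse = ", "), "\n", sep = "")
  cat("  by family: ",
      paste(sprintf("%s=%d", names(x$by_family), x$by_family),
            collapse = ", "), "\n", sep = "")
  cat("  TSS-relative map (upstream -> downstream):\n")
  for (i in seq_len(nrow(x$map))) {
    cat(sprintf("    %6d  %s %-16s [%s]\n", x$map$rel_start[i],
                x$map$strand[i], x$map$family[i], x$map$source[i]))
  }
  invisible(x)
}

#' @export
print.hit_report <- function(x, ...) {
  cat("circamotif hit report - ", x$region$source_id, "\n", sep = "")
  print(summary(x$hits))
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}

#' @export
print.motif_hits <- function(x, ...) {
  cat("Motif hits (", nrow(x), ")\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}
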