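# Synthetic promoter fixtures with known ground truth.
#
# Backgrounds are drawn from a Markov model and optionally purged of all
# consensus cores; exact cores (or PWM-sampled words) are then planted at
# specified TSS-relative positions, and a truth table records exactly what was
# planted where. Everything is a pure function of (seed, parameters).

#' Sample a background sequence, optionally purged of motif cores
#'
#' Draws one sequence from a Markov model; if `purge_families` is given, any
#' window matching a listed family's alternatives is locally resampled (the
#' offending window redrawn from the model's base frequencies) until the
#' sequence is clean, up to `max_iter` passes.
#'
#' @param length sequence length in bases.
#' @param model a `markov_model` (default uniform order 0).
#' @param seed integer seed.
#' @param purge_families list of [consensus_motif()] whose cores must not
#'   occur, or NULL for no purging.
#' @param both_strands also purge reverse-complement matches (default FALSE,
#'   mirroring the scanner's plus_only default).
#' @param max_iter resampling passes before giving up.
#' @return a nucleotide string.
#' @export
generate_background <- function(length, model = markov_model(), seed = NULL,
                                purge_families = NULL, both_strands = FALSE,
                                max_iter = 100) {
  stopifnot(length >= 1)
  with_seed(seed, {
    s <- int_matrix_to_strings(sample_int_matrix(model, length, 1))
    if (!is.null(purge_families)) {
      s <- purge_cores(s, purge_families, model, both_strands, max_iter)
    }
    s
  })
}

# Locally resample windows matching any family pattern until none remain.
purge_cores <- function(s, families, model, both_strands, max_iter) {
  cfg <- consensus_config(
    strands = if (both_strands) "both" else "plus_only",
    dedup_degenerate_ebox = FALSE)
  for (iter in seq_len(max_iter)) {
    hits <- scan_consensus(s, families, cfg)
    if (nrow(hits) == 0) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(chars)
    widths <- stats::setNames(
      vapply(families, function(m) m$width, integer(1)),
      vapply(families, function(m) m$family, character(1)))
    for (k in seq_len(nrow(hits))) {
      w <- widths[[hits$family[k]]]
      i0 <- hits$rel_start[k] + L + 1   # 1-based start
      chars[i0:(i0 + w - 1)] <-
        DNA_BASES[sample.int(4, w, replace = TRUE, prob = model$initial)]
    }
    s <- paste(chars, collapse = "")
  }
  stop("purge did not converge within ", max_iter,
       " passes (pathological model?)")
}

#' Specify a motif site to plant
#'
#' @param family family label.
#' @param site_sequence the exact nucleotide word to plant (an alternative of
#'   the family's consensus, or a PWM-sampled word).
#' @param rel_start TSS-relative start (5'-most base on the + strand); the
#'   site must lie fully inside the window, i.e. its last base at or before
#'   -1.
#' @param strand `"+"` (plant as written) or `"-"` (plant the reverse
#'   complement).
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(family, site_sequence, rel_start, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  structure(list(family = family, site_sequence = toupper(site_sequence),
                 rel_start = as.integer(rel_start), strand = strand),
            class = "plant_spec")
}

#' Plant motif sites into a background sequence
#'
#' Replaces the bases at each plant's TSS-relative position with its site
#' sequence (reverse-complemented for − strand plants) and returns the
#' resulting `promoter_region` together with a truth table recording exactly
#' what was planted.
#'
#' @param background nucleotide string of length L.
#' @param plants list of [plant_spec()]s; pairwise non-overlapping and fully
#'   inside the window.
#' @param source_id,tss_genomic,assembly_label metadata for the emitted
#'   region.
#' @return list with `region` (a `promoter_region`) and `truth` (a data frame
#'   `family`, `rel_start`, `strand`, `site_sequence`).
#' @export
plant_motifs <- function(background, plants, source_id = "synthetic",
                         tss_genomic = NA_integer_, assembly_label = "") {
  L <- nchar(background)
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  widths <- vapply(plants, function(p) nchar(p$site_sequence), integer(1))
  starts <- vapply(plants, function(p) p$rel_start, integer(1))
  for (i in seq_along(plants)) {
    if (starts[i] < -L || starts[i] + widths[i] > 0) {
      stop("plant ", i, " (", plants[[i]]$family, " at ", starts[i],
           ", width ", widths[i], ") outside window [-", L, ", -1]")
    }
  }
  if (length(plants) > 1) {
    ord <- order(starts)
    for (k in seq_len(length(plants) - 1)) {
      a <- ord[k]; b <- ord[k + 1]
      if (starts[a] + widths[a] > starts[b]) {
        stop("overlapping plants: ", plants[[a]]$family, " at ", starts[a],
             " (width ", widths[a], ") and ", plants[[b]]$family, " at ",
             starts[b])
      }
    }
  }
  chars <- strsplit(toupper(background), "", fixed = TRUE)[[1]]
  for (p in plants) {
    word <- if (p$strand == "+") p$site_sequence else revcomp(p$site_sequence)
    i0 <- p$rel_start + L + 1
    chars[i0:(i0 + nchar(word) - 1)] <- strsplit(word, "", fixed = TRUE)[[1]]
  }
  region <- structure(list(source_id = source_id, tss_genomic = tss_genomic,
                           strand = "+", length = L,
                           sequence = paste(chars, collapse = ""),
                           assembly_label = assembly_label),
                      class = "promoter_region")
  truth <- data.frame(
    family = vapply(plants, function(p) p$family, character(1)),
    rel_start = starts,
    strand = vapply(plants, function(p) p$strand, character(1)),
    site_sequence = vapply(plants, function(p) p$site_sequence, character(1)),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$rel_start), , drop = FALSE]
  rownames(truth) <- NULL
  list(region = region, truth = truth)
}

#' The published AmMTR promoter site layout
#'
#' The TSS-relative positions reported for circadian cis-elements in the 3 kb
#' honey-bee melatonin-receptor (AmMTR) promoter: three clustered Pdp1 cores
#' at -820, -357 and -102; degenerate E-boxes at -2762, -1580 and -1383; a
#' canonical (CLOCK-type) E-box at -1334; a CRE 93 bp upstream of the TSS; and
#' D-box sites from the distal (-2701, -2498) to the proximal (-457, -132)
#' promoter. Degenerate E-box plants use CAGTTG (a CANNTG word that is not
#' CACGTG) so the canonical and degenerate families stay disjoint in fixtures.
#'
#' @return list of [plant_spec()]s, all on the + strand, valid for a 3000 bp
#'   window.
#' @export
ammtr_site_layout <- function() {
  list(
    plant_spec("Ebox_degenerate", "CAGTTG", -2762),
    plant_spec("Dbox", "TTATGCAA", -2701),
    plant_spec("Dbox", "TTATGCAA", -2498),
    plant_spec("Ebox_degenerate", "CAGTTG", -1580),
    plant_spec("Ebox_degenerate", "CAGTTG", -1383),
    plant_spec("Ebox_canonical", "CACGTG", -1334),
    plant_spec("Pdp1", "ATTTAT", -820),
    plant_spec("Dbox", "TTATGCAA", -457),
    plant_spec("Pdp1", "ATTTAT", -357),
    plant_spec("Dbox", "TTATGCAA", -132),
    plant_spec("Pdp1", "ATTTAT", -102),
    plant_spec("CRE", "TGACGTCA", -93)
  )
}

#' Simulate a promoter fixture with planted sites and a truth table
#'
#' High-level generator: draws a purged background, plants the requested
#' layout, and (by default) verifies that a consensus scan of the result
#' returns exactly the truth table — redrawing the background within the
#' seeded stream if a planting junction happened to create a spurious core —
#' so that recall/precision against the truth table is exact by construction.
#'
#' @param length window length (default 3000).
#' @param order Markov order of the background (0 or 1; fitted models may be
#'   passed via `model`).
#' @param seed integer seed; the fixture is a pure function of it.
#' @param layout list of [plant_spec()]s (default [ammtr_site_layout()]).
#' @param model background `markov_model` (default uniform order 0).
#' @param purge_families families to purge from the background (default the
#'   six bundled circadian families).
#' @param ensure_clean redraw until the planted fixture scans to exactly its
#'   truth table (default TRUE; capped at `max_attempts`).
#' @param max_attempts redraw cap for `ensure_clean`.
#' @param tss_genomic,source_id,assembly_label metadata for the region.
#' @return list with `region`, `truth`, and `meta` (seed, order, purge flag,
#'   attempts used).
#' @export
simulate_promoter <- function(length = 3000, order = 0, seed = NULL,
                              layout = ammtr_site_layout(),
                              model = NULL,
                              purge_families = circadian_motifs(),
                              ensure_clean = TRUE, max_attempts = 50,
                              tss_genomic = NA_integer_,
                              source_id = "synthetic_promoter",
                              assembly_label = "synthetic") {
  if (is.null(model)) {
    model <- if (order == 0) markov_model() else
      markov_model(transitions = matrix(0.25, 4, 4))
  }
  scan_families <- purge_families %||% circadian_motifs()
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      bg <- int_matrix_to_strings(sample_int_matrix(model, length, 1))
      if (!is.null(purge_families)) {
        bg <- purge_cores(bg, purge_families, model, both_strands = FALSE,
                          max_iter = 100)
      }
      fx <- plant_motifs(bg, layout, source_id = source_id,
                         tss_genomic = tss_genomic,
                         assembly_label = assembly_label)
      if (!ensure_clean) break
      hits <- scan_consensus(fx$region, scan_families, consensus_config())
      found <- paste(hits$family, hits$rel_start)
      want <- paste(fx$truth$family, fx$truth$rel_start)
      if (setequal(found, want) && nrow(hits) == nrow(fx$truth)) break
      if (attempt == max_attempts) {
        stop("could not generate a clean fixture in ", max_attempts,
             " attempts")
      }
    }
    fx$meta <- list(seed = seed, order = model$order,
                    purged = !is.null(purge_families),
                    ensure_clean = ensure_clean, attempts = attempt)
    fx
  })
}

#' Sample an above-threshold site from a PWM
#'
#' Draws a word column-by-column from the PFM's corrected column frequencies
#' and accepts it if its relative score reaches `min_rel_score`; after
#' `max_tries` rejections it falls back to the consensus word (per-column
#' argmax weight), which always attains relative score 1.
#'
#' @param pwm a `pwm`.
#' @param min_rel_score minimum relative score in `[0, 1]`.
#' @param seed integer seed.
#' @param max_tries rejection cap before the consensus fallback.
#' @return a nucleotide string of the motif's width.
#' @export
sample_pwm_site <- function(pwm, min_rel_score = 0.85, seed = NULL,
                            max_tries = 200) {
  stopifnot(inherits(pwm, "pwm"), min_rel_score >= 0, min_rel_score <= 1)
  w <- ncol(pwm$weights)
  bg <- pwm$params$background
  # column sampling probabilities implied by the weights: freq = bg * 2^weight
  freqs <- sweep(2^pwm$weights, 1, bg, "*")
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  score_word <- function(v) sum(pwm$weights[cbind(v, seq_len(w))])
  with_seed(seed, {
    for (k in seq_len(max_tries)) {
      v <- vapply(seq_len(w), function(j) {
        sample.int(4, 1, prob = freqs[, j])
      }, integer(1))
      if (relative_score(pwm, score_word(v)) >= min_rel_score) {
        return(int_to_seq(v))
      }
    }
    int_to_seq(apply(pwm$weights, 2, which.max))
  })
}

#' Write a simulated fixture to disk
#'
#' Emits the promoter as FASTA, the truth table as TSV, and the generator
#' metadata as JSON.
#'
#' @param fixture result of [simulate_promoter()].
#' @param prefix output path prefix; writes `<prefix>.fa`, `<prefix>_truth.tsv`
#'   and `<prefix>_meta.json`.
#' @return character vector of the paths written, invisibly.
#' @export
write_fixture <- function(fixture, prefix) {
  fa <- paste0(prefix, ".fa")
  tsv <- paste0(prefix, "_truth.tsv")
  js <- paste0(prefix, "_meta.json")
  write_fasta(stats::setNames(fixture$region$sequence,
                              fixture$region$source_id), fa)
  utils::write.table(fixture$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(fixture$meta, js, auto_unbox = TRUE, null = "null")
  invisible(c(fa, tsv, js))
}
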