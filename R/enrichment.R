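# Resampling-based motif enrichment.
#
# Observed per-family counts in the query promoter are compared with counts in
# n background sequences of the same length, drawn either from a Markov model
# (default: fitted to the query promoter itself) or from a user-supplied
# promoter set. The p-value is the one-sided empirical
#     p = (1 + #{null >= observed}) / (1 + n)
# (add-one permutation-test form: never zero), corrected across families with
# Benjamini-Hochberg or Bonferroni.

#' Enrichment test configuration
#'
#' @param n_samples number of background sequences (default 999).
#' @param seed integer seed for the resampling stream.
#' @param alpha significance level for the `enriched` flag (default 0.05).
#' @param correction `"BH"` (default) or `"Bonferroni"`.
#' @param alternative `"enrichment"` (one-sided, default) or `"depletion"`
#'   (counts `null <= observed` instead).
#' @param background_mode `"markov_shuffle"` (default: resample from a Markov
#'   model) or `"promoter_set"` (draw counts from user promoters).
#' @return an `enrichment_config` list.
#' @export
enrichment_config <- function(n_samples = 999, seed = NULL, alpha = 0.05,
                              correction = c("BH", "Bonferroni"),
                              alternative = c("enrichment", "depletion"),
                              background_mode = c("markov_shuffle",
                                                  "promoter_set")) {
  correction <- match.arg(correction)
  alternative <- match.arg(alternative)
  background_mode <- match.arg(background_mode)
  stopifnot(n_samples >= 1, alpha > 0, alpha < 1)
  structure(list(n_samples = as.integer(n_samples), seed = seed, alpha = alpha,
                 correction = correction, alternative = alternative,
                 background_mode = background_mode),
            class = "enrichment_config")
}

#' Multiple-testing correction
#'
#' Thin wrapper over [stats::p.adjust()]: Benjamini-Hochberg step-up (with
#' enforced monotonicity, capped at 1) or Bonferroni (`min(1, p * m)`).
#' Output order matches input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param method `"BH"` or `"Bonferroni"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "Bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
}

#' Empirical enrichment p-values from null count distributions
#'
#' @param observed named numeric vector of per-family observed counts.
#' @param null_counts named list: per family, the vector of counts from the
#'   `n` background sequences (every family in `observed` must be present,
#'   each with exactly `n` entries).
#' @param config an [enrichment_config()].
#' @return an `enrichment_result` data frame: `family`, `observed`,
#'   `null_mean`, `null_sd`, `p_raw`, `q_adj`, `enriched`.
#' @examples
#' empirical_enrichment(c(Pdp1 = 5), list(Pdp1 = 0:9),
#'                      enrichment_config(n_samples = 10))
#' @export
empirical_enrichment <- function(observed, null_counts,
                                 config = enrichment_config()) {
  stopifnot(inherits(config, "enrichment_config"))
  fams <- names(observed)
  if (is.null(fams) || any(!nzchar(fams))) stop("observed counts must be named")
  missing <- setdiff(fams, names(null_counts))
  if (length(missing)) {
    stop("null counts missing for family: ", paste(missing, collapse = ", "))
  }
  n <- config$n_samples
  rows <- lapply(fams, function(f) {
    nv <- null_counts[[f]]
    if (length(nv) != n) {
      stop("family '", f, "': expected ", n, " null counts, got ", length(nv))
    }
    extreme <- if (config$alternative == "enrichment") {
      sum(nv >= observed[[f]])
    } else {
      sum(nv <= observed[[f]])
    }
    data.frame(family = f, observed = as.numeric(observed[[f]]),
               null_mean = mean(nv), null_sd = stats::sd(nv),
               p_raw = (1 + extreme) / (1 + n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_adj <- adjust_pvalues(out$p_raw, config$correction)
  out$enriched <- out$q_adj <= config$alpha
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            config = config)
}

# Per-sequence consensus-core counts across many N-free sequences, matching
# scan_consensus semantics (plus_only / both; optional degenerate-E-box
# dedup). Hot path of the resampling null: pattern matching is delegated to
# Biostrings (C code); sampled backgrounds contain no N, so the "sequence N
# never matches" policy is not in play here.
count_cores_many <- function(seqs, motifs, strands = "plus_only",
                             dedup_degenerate_ebox = TRUE) {
  set <- Biostrings::DNAStringSet(seqs)
  count_patterns <- function(patterns) {
    total <- integer(length(seqs))
    for (p in patterns) {
      total <- total + Biostrings::vcountPattern(p, set, fixed = "subject")
    }
    total
  }
  fams <- vapply(motifs, function(m) m$family, character(1))
  out <- lapply(motifs, function(m) {
    pats <- m$patterns
    if (strands == "both") pats <- unique(c(pats, revcomp(pats)))
    count_patterns(pats)
  })
  names(out) <- fams
  if (dedup_degenerate_ebox &&
      all(c("Ebox_canonical", "Ebox_degenerate") %in% fams)) {
    # every canonical site is also a degenerate window at the same position
    out[["Ebox_degenerate"]] <- out[["Ebox_degenerate"]] -
      out[["Ebox_canonical"]]
  }
  out
}

#' Test motif enrichment in a promoter against a resampled background
#'
#' Counts each family's hits in the promoter (consensus scan, plus any PWMs at
#' the relative-score threshold), then compares against counts in
#' `n_samples` background sequences of the same length. By default the
#' background is a Markov model fitted to the promoter itself
#' (`markov_shuffle`); with `background_mode = "promoter_set"` the model is
#' replaced by counts taken directly from `background_seqs` sequences sampled
#' with replacement.
#'
#' @param region a `promoter_region` (or plain nucleotide string).
#' @param motifs consensus families to test (default the six bundled ones).
#' @param pwms optional list of `pwm` objects, each tested as its own family
#'   at `pwm_config`'s threshold.
#' @param order Markov background order, 0 or 1.
#' @param config an [enrichment_config()].
#' @param consensus_cfg a [consensus_config()] (controls strand mode and
#'   E-box dedup for both observed and null counting).
#' @param pwm_config a [scan_config()] for the PWM arm.
#' @param background_seqs character vector of background promoter sequences
#'   (required for `promoter_set` mode; also usable to fit the Markov model
#'   instead of the query promoter).
#' @param fit_to what to fit the Markov model to: `"query"` (default) or
#'   `"background_seqs"`.
#' @return an `enrichment_result` data frame (see [empirical_enrichment()]),
#'   with the fitted model and config attached as attributes.
#' @export
test_enrichment <- function(region, motifs = circadian_motifs(), pwms = NULL,
                            order = 0, config = enrichment_config(),
                            consensus_cfg = consensus_config(),
                            pwm_config = scan_config(),
                            background_seqs = NULL,
                            fit_to = c("query", "background_seqs")) {
  fit_to <- match.arg(fit_to)
  if (is.character(region)) {
    region <- structure(list(source_id = "seq", tss_genomic = NA_integer_,
                             strand = "+", length = nchar(region),
                             sequence = region, assembly_label = ""),
                        class = "promoter_region")
  }
  L <- region$length
  fams <- vapply(motifs, function(m) m$family, character(1))

  observed <- count_by_family(scan_consensus(region, motifs, consensus_cfg),
                              families = fams)
  pwm_fams <- character(0)
  if (!is.null(pwms)) {
    if (inherits(pwms, "pwm")) pwms <- list(pwms)
    pwm_fams <- vapply(pwms, function(p) p$name, character(1))
    pwm_obs <- vapply(pwms, function(p) {
      nrow(scan_pwm(p, region, pwm_config))
    }, integer(1))
    observed <- c(observed, stats::setNames(pwm_obs, pwm_fams))
  }

  if (config$background_mode == "promoter_set") {
    if (is.null(background_seqs) || length(background_seqs) == 0) {
      stop("promoter_set background mode requires background_seqs")
    }
    null_seqs <- with_seed(config$seed, {
      sample(background_seqs, config$n_samples, replace = TRUE)
    })
    model <- NULL
  } else {
    fit_input <- if (fit_to == "background_seqs") {
      if (is.null(background_seqs)) stop("fit_to='background_seqs' requires background_seqs")
      background_seqs
    } else region$sequence
    model <- fit_markov(fit_input, order = order)
    null_seqs <- sample_sequences(model, L, config$n_samples,
                                  seed = config$seed)
  }

  has_n <- any(grepl("N", null_seqs, fixed = TRUE))
  null_counts <- if (has_n) {
    # promoter-set sequences may contain N; fall back to the package scanner
    lapply_counts <- lapply(null_seqs, function(s) {
      count_by_family(scan_consensus(s, motifs, consensus_cfg),
                      families = fams)
    })
    stats::setNames(lapply(fams, function(f) {
      vapply(lapply_counts, `[[`, numeric(1), f)
    }), fams)
  } else {
    count_cores_many(null_seqs, motifs, strands = consensus_cfg$strands,
                     dedup_degenerate_ebox = consensus_cfg$dedup_degenerate_ebox)
  }
  if (!is.null(pwms)) {
    for (i in seq_along(pwms)) {
      null_counts[[pwm_fams[i]]] <- vapply(null_seqs, function(s) {
        nrow(scan_pwm(pwms[[i]], s, pwm_config))
      }, integer(1), USE.NAMES = FALSE)
    }
  }

  res <- empirical_enrichment(observed, null_counts, config)
  attr(res, "model") <- model
  attr(res, "window_length") <- L
  attr(res, "source_id") <- region$source_id
  res
}

#' @export
print.enrichment_result <- function(x, digits = 4, ...) {
  cfg <- attr(x, "config")
  cat("Motif enrichment vs resampled background",
      if (!is.null(cfg)) sprintf(" (n = %d, %s, one-sided %s)",
                                 cfg$n_samples, cfg$correction,
                                 cfg$alternative),
      "\n", sep = "")
  df <- as.data.frame(x)
  df$null_mean <- round(df$null_mean, 3)
  df$null_sd <- round(df$null_sd, 3)
  df$p_raw <- signif(df$p_raw, digits)
  df$q_adj <- signif(df$q_adj, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
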