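# Position weight matrix scanning with min-max relative scoring.
#
# The scan retains windows whose relative score
#     (raw - s_min) / (s_max - s_min)
# meets a threshold (default >= 0.85, inclusive); s_min/s_max are the sums of
# per-column weight minima/maxima, so the relative score is invariant to the
# log base used for the weights.

#' Parse JASPAR raw-format position frequency matrices
#'
#' Accepts the JASPAR PFM text dialect: a header line `>ID name` followed by
#' four labelled count rows, e.g. `A  [ 4  0 ]` (brackets optional). Rows may
#' appear in any order; they are assigned by label. Multiple records per file
#' are supported.
#'
#' @param text the PFM text, either a single string, a character vector of
#'   lines, or a file path (when `is_file = TRUE`).
#' @param is_file treat `text` as a path and read it.
#' @return list of `pfm` objects: `motif_id`, `name`, `counts` (4 x w matrix,
#'   rows A,C,G,T), `width`.
#' @export
parse_jaspar <- function(text, is_file = FALSE) {
  if (is_file) text <- readLines(text, warn = FALSE)
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- trimws(text)
  text <- text[nzchar(text)]
  if (length(text) == 0) stop("empty JASPAR input")
  starts <- grep("^>", text)
  if (length(starts) == 0) stop("no JASPAR record header ('>') found")
  ends <- c(starts[-1] - 1, length(text))
  lapply(seq_along(starts), function(k) {
    header <- sub("^>\\s*", "", text[starts[k]])
    motif_id <- sub("\\s.*$", "", header)
    name <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else motif_id
    body <- text[seq(starts[k] + 1, ends[k])]
    rows <- list()
    for (line in body) {
      base <- toupper(sub("^([ACGTacgt]).*$", "\\1", line))
      if (!base %in% DNA_BASES || !grepl("^[ACGTacgt][^ACGTacgt]", paste0(line, " "))) {
        stop("motif '", motif_id, "': unrecognized PFM row: ", line)
      }
      nums <- gsub("[\\[\\]]", " ", substring(line, 2), perl = TRUE)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) == 0) {
        stop("motif '", motif_id, "': cannot parse counts in row: ", line)
      }
      if (any(vals < 0)) stop("motif '", motif_id, "': negative count in row ", base)
      rows[[base]] <- vals
    }
    missing <- setdiff(DNA_BASES, names(rows))
    if (length(missing)) {
      stop("motif '", motif_id, "': missing row(s): ", paste(missing, collapse = ", "))
    }
    w <- unique(vapply(rows[DNA_BASES], length, integer(1)))
    if (length(w) != 1) {
      stop("motif '", motif_id, "': ragged rows (widths ",
           paste(vapply(rows[DNA_BASES], length, integer(1)), collapse = "/"), ")")
    }
    counts <- do.call(rbind, rows[DNA_BASES])
    rownames(counts) <- DNA_BASES
    zero <- which(colSums(counts) == 0)
    if (length(zero)) {
      stop("motif '", motif_id, "': all-zero column ", zero[1])
    }
    structure(list(motif_id = motif_id, name = name, counts = counts,
                   width = as.integer(w)),
              class = "pfm")
  })
}

#' Build a PFM from explicit counts
#'
#' @param counts 4 x w numeric matrix in A,C,G,T row order.
#' @param motif_id,name identifiers.
#' @return a `pfm`.
#' @export
pfm <- function(counts, motif_id = "pfm", name = motif_id) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1, all(counts >= 0))
  if (any(colSums(counts) == 0)) stop("PFM has an all-zero column")
  rownames(counts) <- DNA_BASES
  structure(list(motif_id = motif_id, name = name, counts = counts,
                 width = ncol(counts)),
            class = "pfm")
}

#' Scoring constants for PFM -> PWM conversion
#'
#' @param pseudocount total pseudocount added per column, distributed by the
#'   background (default 0.8).
#' @param background length-4 probability vector over A,C,G,T (default
#'   uniform). Must be strictly positive and sum to 1.
#' @return a `score_params` list. Weights are log2 odds; the min-max relative
#'   score is unaffected by the log base.
#' @export
score_params <- function(pseudocount = 0.8, background = rep(0.25, 4)) {
  stopifnot(pseudocount >= 0, length(background) == 4, all(background > 0))
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  structure(list(pseudocount = pseudocount, background = background,
                 log_base = 2),
            class = "score_params")
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Per column j with total N_j, the corrected frequency of base b is
#' `(counts[b,j] + pseudocount * background[b]) / (N_j + pseudocount)` and the
#' weight is `log2(freq / background[b])`. `s_min`/`s_max` are the sums of
#' column minima/maxima and anchor the relative score.
#'
#' @param x a `pfm`.
#' @param params a [score_params()].
#' @return a `pwm`: `motif_id`, `weights` (4 x w), `s_min`, `s_max`, plus the
#'   parameters used.
#' @export
pfm_to_pwm <- function(x, params = score_params()) {
  stopifnot(inherits(x, "pfm"), inherits(params, "score_params"))
  counts <- x$counts
  totals <- colSums(counts)
  freq <- sweep(counts + params$pseudocount * params$background, 2,
                totals + params$pseudocount, "/")
  weights <- log2(freq / params$background)
  s_min <- sum(apply(weights, 2, min))
  s_max <- sum(apply(weights, 2, max))
  if (s_max - s_min <= 1e-12) {
    stop("degenerate PWM '", x$motif_id, "': s_min == s_max (constant columns)")
  }
  structure(list(motif_id = x$motif_id, name = x$name, weights = weights,
                 s_min = s_min, s_max = s_max, params = params),
            class = "pwm")
}

#' Min-max relative PWM score
#'
#' `(raw - s_min) / (s_max - s_min)`: 0 at the worst possible word, 1 at the
#' consensus word.
#'
#' @param pwm a `pwm`.
#' @param raw raw log-odds score(s).
#' @return relative score(s) in `[0, 1]` for attainable raw scores.
#' @export
relative_score <- function(pwm, raw) {
  stopifnot(inherits(pwm, "pwm"))
  (raw - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

#' PWM scan configuration
#'
#' @param rel_threshold minimum relative score, inclusive (default 0.85).
#' @param strands `"both"` (default) or `"plus_only"`.
#' @param skip_ambiguous skip windows containing N (default TRUE).
#' @param prune_overlaps greedily drop overlapping hits of the same motif,
#'   keeping the highest relative score (ties: 5'-most, then + strand).
#'   Off by default: all above-threshold windows are reported.
#' @return a `scan_config` list.
#' @export
scan_config <- function(rel_threshold = 0.85,
                        strands = c("both", "plus_only"),
                        skip_ambiguous = TRUE, prune_overlaps = FALSE) {
  strands <- match.arg(strands)
  stopifnot(rel_threshold >= 0, rel_threshold <= 1)
  structure(list(rel_threshold = rel_threshold, strands = strands,
                 skip_ambiguous = skip_ambiguous,
                 prune_overlaps = prune_overlaps),
            class = "scan_config")
}

# Raw PWM scores of every window of `enc` (integer-encoded sequence); windows
# containing NA (i.e. N) score NA.
pwm_window_scores <- function(weights, enc) {
  w <- ncol(weights)
  L <- length(enc)
  n_win <- L - w + 1
  if (n_win < 1) stop("motif (width ", w, ") wider than sequence (", L, " bases)")
  scores <- numeric(n_win)
  for (j in seq_len(w)) {
    col <- weights[, j]
    scores <- scores + col[enc[j:(j + n_win - 1)]]
  }
  scores
}

# Reverse-complement PWM: scanning the forward strand with it equals scanning
# the reverse-complement window with the original PWM.
rc_pwm_weights <- function(weights) {
  weights[4:1, ncol(weights):1, drop = FALSE]
}

#' Scan a promoter window with a PWM
#'
#' Slides the PWM over every window of the promoter (both strands by default),
#' skipping windows that contain N, and reports each window whose relative
#' score meets the threshold. Reverse-strand hits are scored on the
#' reverse-complement of the window but reported anchored to the + strand:
#' `rel_start` is the TSS-relative position of the window's 5'-most base on
#' the + strand and `matched` is the + strand substring.
#'
#' @param pwm a `pwm`.
#' @param region a `promoter_region` (or plain string, treated as a window of
#'   its own length).
#' @param config a [scan_config()].
#' @param family family label for the hits (defaults to the motif name).
#' @return a `motif_hits` data frame: `family`, `source` ("pwm"), `rel_start`,
#'   `strand`, `matched`, `raw_score`, `rel_score`, sorted by `rel_start` then
#'   strand (+ before −).
#' @export
scan_pwm <- function(pwm, region, config = scan_config(), family = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.character(region)) {
    region <- structure(list(source_id = "seq", tss_genomic = NA_integer_,
                             strand = "+", length = nchar(region),
                             sequence = region, assembly_label = ""),
                        class = "promoter_region")
  }
  family <- family %||% pwm$name
  w <- ncol(pwm$weights)
  L <- region$length
  if (w > L) stop("motif '", pwm$motif_id, "' (width ", w,
                  ") wider than promoter window (", L, " bases)")
  enc <- seq_to_int(region$sequence)
  span <- pwm$s_max - pwm$s_min

  collect <- function(weights, strand) {
    raw <- pwm_window_scores(weights, enc)
    rel <- (raw - pwm$s_min) / span
    # windows containing N score NA and can never be hits
    idx <- which(!is.na(rel) & rel >= config$rel_threshold)
    if (!length(idx)) return(NULL)
    data.frame(family = family, source = "pwm",
               rel_start = (idx - 1) - L, strand = strand,
               matched = substring(region$sequence, idx, idx + w - 1),
               raw_score = raw[idx], rel_score = rel[idx],
               stringsAsFactors = FALSE)
  }

  out <- collect(pwm$weights, "+")
  if (config$strands == "both") {
    out <- rbind(out, collect(rc_pwm_weights(pwm$weights), "-"))
  }
  out <- if (is.null(out)) empty_hits() else out
  out <- out[order(out$rel_start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (config$prune_overlaps && nrow(out) > 1) out <- prune_overlapping(out, w)
  as_motif_hits(out, region)
}

# Greedy non-overlap pruning within one motif's hit list: keep the best
# relative score; ties broken 5'-most, then + strand.
prune_overlapping <- function(hits, w) {
  ord <- order(-hits$rel_score, hits$rel_start, hits$strand)
  kept <- logical(nrow(hits))
  occupied <- integer(0)
  for (i in ord) {
    win <- hits$rel_start[i] + 0:(w - 1)
    if (!any(win %in% occupied)) {
      kept[i] <- TRUE
      occupied <- c(occupied, win)
    }
  }
  out <- hits[kept, , drop = FALSE]
  out <- out[order(out$rel_start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(family = character(0), source = character(0),
             rel_start = integer(0), strand = character(0),
             matched = character(0), raw_score = numeric(0),
             rel_score = numeric(0), stringsAsFactors = FALSE)
}

as_motif_hits <- function(df, region = NULL) {
  class(df) <- c("motif_hits", "data.frame")
  if (!is.null(region)) {
    attr(df, "source_id") <- region$source_id
    attr(df, "tss_genomic") <- region$tss_genomic
    attr(df, "window_length") <- region$length
  }
  df
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$motif_id, "' (", x$name, "), width ", ncol(x$weights),
      "\n  score range [", format(x$s_min, digits = 4), ", ",
      format(x$s_max, digits = 4), "] (log2 odds)\n", sep = "")
  print(round(x$weights, 3))
  invisible(x)
}

#' @export
print.pfm <- function(x, ...) {
  cat("PFM '", x$motif_id, "' (", x$name, "), width ", x$width, "\n", sep = "")
  print(x$counts)
  invisible(x)
}
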