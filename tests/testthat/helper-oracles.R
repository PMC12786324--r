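# Independent brute-force oracles. These deliberately share no internals with
# the package scanners: character-by-character scoring, explicit window loops,
# full-word enumeration.

BASES <- c("A", "C", "G", "T")

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(unname(oracle_complement[chars])), collapse = "")
}

# Raw score of a single word against a weight matrix, looping characters.
oracle_score_word <- function(weights, word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  total <- 0
  for (j in seq_along(chars)) {
    b <- match(chars[j], BASES)
    if (is.na(b)) return(NA_real_)
    total <- total + weights[b, j]
  }
  total
}

# All 4^w words of width w (w small).
oracle_all_words <- function(w) {
  grids <- rev(rep(list(BASES), w))
  words <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  apply(words[, rev(seq_len(w)), drop = FALSE], 1, paste, collapse = "")
}

# Exhaustive per-window PWM scan: every window, both strands, explicit loops.
oracle_scan_pwm <- function(pwm, sequence, threshold, both_strands = TRUE) {
  w <- ncol(pwm$weights)
  L <- nchar(sequence)
  span <- pwm$s_max - pwm$s_min
  rows <- list()
  for (i in seq_len(L - w + 1)) {
    window <- substr(sequence, i, i + w - 1)
    for (strand in if (both_strands) c("+", "-") else "+") {
      word <- if (strand == "+") window else oracle_revcomp(window)
      raw <- oracle_score_word(pwm$weights, word)
      if (is.na(raw)) next
      rel <- (raw - pwm$s_min) / span
      if (rel >= threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          rel_start = (i - 1) - L, strand = strand, matched = window,
          raw_score = raw, rel_score = rel, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(rel_start = integer(0), strand = character(0),
                      matched = character(0), raw_score = numeric(0),
                      rel_score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$rel_start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

# Biostrings-backed consensus oracle (independent matcher); N-free input only.
oracle_count_core <- function(sequence, patterns) {
  subj <- Biostrings::DNAString(sequence)
  sum(vapply(patterns, function(p) {
    Biostrings::countPattern(p, subj, fixed = "subject")
  }, integer(1)))
}
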