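# Markov background models: fitting, and seeded sequence resampling.
#
# These supply the null for the enrichment test: either a zero-order model
# (base composition) or a first-order model (dinucleotide transitions), fitted
# to the query promoter itself or to a user-supplied promoter set. N bases are
# excluded from counting; pseudocount smoothing keeps all probabilities
# strictly positive.

#' Fit a zero- or first-order Markov background model
#'
#' Order 0 estimates smoothed base frequencies; order 1 additionally estimates
#' a 4x4 row-stochastic transition matrix from adjacent pairs (pairs touching
#' an N are skipped). The initial distribution of an order-1 model is the
#' order-0 frequency vector.
#'
#' @param seqs character vector (or list of records / a `promoter_region`) of
#'   nucleotide sequences.
#' @param order 0 or 1.
#' @param pseudocount added per cell before normalization (default 1).
#' @return a `markov_model`: `order`, `initial` (named length-4), `transitions`
#'   (4x4, order 1 only), `pseudocount`.
#' @export
fit_markov <- function(seqs, order = 0, pseudocount = 1) {
  stopifnot(order %in% c(0, 1), pseudocount >= 0)
  if (inherits(seqs, "promoter_region")) seqs <- seqs$sequence
  if (is.list(seqs)) seqs <- vapply(seqs, function(r) r$sequence, character(1))
  stopifnot(is.character(seqs), length(seqs) >= 1)
  encs <- lapply(toupper(seqs), seq_to_int)
  base_counts <- rep(0, 4)
  for (e in encs) {
    tab <- tabulate(e[!is.na(e)], nbins = 4)
    base_counts <- base_counts + tab
  }
  if (sum(base_counts) == 0) stop("no usable (non-N) bases in input")
  if (pseudocount == 0 && any(base_counts == 0)) {
    stop("zero-count base with pseudocount 0; increase pseudocount")
  }
  initial <- (base_counts + pseudocount) / (sum(base_counts) + 4 * pseudocount)
  names(initial) <- DNA_BASES
  transitions <- NULL
  if (order == 1) {
    tc <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    for (e in encs) {
      if (length(e) < 2) next
      from <- e[-length(e)]
      to <- e[-1]
      ok <- !is.na(from) & !is.na(to)
      if (any(ok)) {
        tc <- tc + table(factor(from[ok], levels = 1:4),
                         factor(to[ok], levels = 1:4))
      }
    }
    sm <- tc + pseudocount
    if (any(rowSums(sm) == 0)) {
      stop("empty transition row with pseudocount 0; increase pseudocount")
    }
    transitions <- sm / rowSums(sm)
  }
  structure(list(order = order, initial = initial, transitions = transitions,
                 pseudocount = pseudocount),
            class = "markov_model")
}

#' A Markov model from explicit probabilities
#'
#' @param initial length-4 probability vector over A,C,G,T.
#' @param transitions optional 4x4 row-stochastic matrix (makes the model
#'   order 1).
#' @return a `markov_model`.
#' @export
markov_model <- function(initial = rep(0.25, 4), transitions = NULL) {
  stopifnot(length(initial) == 4, all(initial > 0),
            abs(sum(initial) - 1) < 1e-9)
  initial <- stats::setNames(as.numeric(initial), DNA_BASES)
  if (!is.null(transitions)) {
    transitions <- as.matrix(transitions)
    stopifnot(all(dim(transitions) == c(4, 4)), all(transitions > 0),
              all(abs(rowSums(transitions) - 1) < 1e-9))
    dimnames(transitions) <- list(DNA_BASES, DNA_BASES)
  }
  structure(list(order = if (is.null(transitions)) 0 else 1,
                 initial = initial, transitions = transitions,
                 pseudocount = NA_real_),
            class = "markov_model")
}

# Sample an n x length integer matrix (1..4) from the model. Order-1 sampling
# is vectorized across sequences, looping over positions.
sample_int_matrix <- function(model, length, n) {
  if (model$order == 0) {
    matrix(sample.int(4, n * length, replace = TRUE, prob = model$initial),
           nrow = n, ncol = length)
  } else {
    m <- matrix(0L, nrow = n, ncol = length)
    m[, 1] <- sample.int(4, n, replace = TRUE, prob = model$initial)
    cum <- t(apply(model$transitions, 1, cumsum))
    for (t in seq_len(length - 1)) {
      u <- stats::runif(n)
      cm <- cum[m[, t], , drop = FALSE]
      m[, t + 1] <- 1L + (u > cm[, 1]) + (u > cm[, 2]) + (u > cm[, 3])
    }
    m
  }
}

int_matrix_to_strings <- function(m) {
  ch <- matrix(DNA_BASES[m], nrow = nrow(m))
  vapply(seq_len(nrow(m)), function(i) paste(ch[i, ], collapse = ""),
         character(1))
}

#' Sample sequences from a Markov background model
#'
#' @param model a `markov_model`.
#' @param length sequence length in bases.
#' @param n number of sequences.
#' @param seed optional integer; same seed, same output. The caller's RNG
#'   state is untouched.
#' @return character vector of `n` sequences of the requested length.
#' @export
sample_sequences <- function(model, length, n, seed = NULL) {
  stopifnot(inherits(model, "markov_model"), length >= 1, n >= 0)
  if (n == 0) return(character(0))
  with_seed(seed, int_matrix_to_strings(sample_int_matrix(model, length, n)))
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Markov background model, order ", x$order, "\n", sep = "")
  cat("  base frequencies: ",
      paste(sprintf("%s=%.3f", DNA_BASES, x$initial), collapse = " "), "\n",
      sep = "")
  if (x$order == 1) {
    cat("  transition matrix (rows = from):\n")
    print(round(x$transitions, 3))
  }
  invisible(x)
}
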