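# Shared fixtures built in code.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# PFM whose consensus is `word`: `n` counts on the consensus base per column,
# `off` on the others (off > 0 keeps columns non-constant in weight space).
consensus_pfm <- function(word, n = 10, off = 0) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  m <- vapply(chars, function(ch) {
    v <- rep(off, 4)
    v[match(ch, c("A", "C", "G", "T"))] <- n
    v
  }, numeric(4))
  pfm(matrix(m, nrow = 4), motif_id = paste0("pfm_", word))
}

random_pfm <- function(width, seed = NULL) {
  draw <- function() {
    m <- matrix(stats::rpois(4 * width, lambda = 5) + stats::runif(4 * width),
                nrow = 4)
    pfm(m, motif_id = sprintf("rnd_w%d", width))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

toy_region <- function(sequence, tss_genomic = NA_integer_) {
  structure(list(source_id = "toy", tss_genomic = tss_genomic, strand = "+",
                 length = nchar(sequence), sequence = sequence,
                 assembly_label = ""),
            class = "promoter_region")
}
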