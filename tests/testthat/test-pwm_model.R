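test_that("parse_jaspar handles brackets, bare rows and label-driven order", {
  txt <- c(">M1 toy", "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]", "T [ 0 0 ]")
  p1 <- parse_jaspar(txt)[[1]]
  expect_equal(p1$motif_id, "M1")
  expect_equal(p1$name, "toy")
  expect_equal(p1$width, 2L)
  expect_equal(unname(p1$counts), matrix(c(4, 0, 0, 0, 0, 4, 0, 0), nrow = 4))

  # rows in T,G,C,A order, no brackets -> identical matrix
  txt2 <- c(">M1 toy", "T 0 0", "G 0 0", "C 0 4", "A 4 0")
  expect_equal(parse_jaspar(txt2)[[1]]$counts, p1$counts)

  # multi-record input
  both <- parse_jaspar(c(txt, txt2))
  expect_length(both, 2)

  # column sums 3,3 with one all-zero row is fine
  txt3 <- c(">M3", "A 1 1", "C 1 1", "G 1 1", "T 0 0")
  expect_equal(colSums(parse_jaspar(txt3)[[1]]$counts), c(3, 3))
})

test_that("parse_jaspar rejects malformed records with informative errors", {
  expect_error(parse_jaspar(c(">M1", "A 1 1", "C 1 1", "G 1 1")),
               "missing row.*T")
  expect_error(parse_jaspar(c(">M1", "A 1 1 1", "C 1 1", "G 1 1", "T 1 1")),
               "ragged")
  expect_error(parse_jaspar(c(">M1", "A 0 1", "C 0 1", "G 0 1", "T 0 1")),
               "all-zero column 1")
  expect_error(parse_jaspar(character(0)), "empty")
})

test_that("pfm_to_pwm reproduces the smoothed log-odds arithmetic by hand", {
  p <- pfm(matrix(c(4, 0, 0, 0, 1, 1, 1, 1), nrow = 4), "toy")
  w <- pfm_to_pwm(p, score_params(pseudocount = 0.8))
  # column 1: f_A = (4 + 0.8*0.25)/(4 + 0.8) = 4.2/4.8 = 0.875
  expect_equal(unname(w$weights["A", 1]), log2(0.875 / 0.25))
  expect_equal(unname(w$weights["A", 1]), log2(3.5))
  # f_C = 0.2/4.8
  expect_equal(unname(w$weights["C", 1]), log2((0.2 / 4.8) / 0.25))
  # uniform column, uniform background -> exactly zero weights
  expect_equal(unname(w$weights[, 2]), rep(0, 4))
})

test_that("s_min and s_max equal brute-force extrema over all words", {
  for (seed in 1:6) {
    width <- withr::with_seed(seed, sample(1:5, 1))
    p <- random_pfm(width, seed = seed + 100)
    w <- pfm_to_pwm(p)
    scores <- vapply(oracle_all_words(width),
                     function(word) oracle_score_word(w$weights, word),
                     numeric(1))
    expect_equal(w$s_min, min(scores), tolerance = 1e-12)
    expect_equal(w$s_max, max(scores), tolerance = 1e-12)
  }
})

test_that("max-weight base tracks the count argmax under uniform background", {
  for (seed in 1:10) {
    p <- random_pfm(4, seed = seed)
    w <- pfm_to_pwm(p)
    for (j in 1:4) {
      expect_equal(which.max(w$weights[, j]), which.max(p$counts[, j]))
    }
  }
})

test_that("degenerate PWMs are rejected at build time", {
  counts <- matrix(1, nrow = 4, ncol = 3)  # every column uniform
  expect_error(pfm_to_pwm(pfm(counts, "flat")), "degenerate")
})

test_that("relative_score is an exact min-max normalization", {
  w <- pfm_to_pwm(random_pfm(4, seed = 2))
  expect_identical(relative_score(w, w$s_max), 1)
  expect_identical(relative_score(w, w$s_min), 0)
  # monotone in raw
  raws <- seq(w$s_min, w$s_max, length.out = 20)
  expect_true(all(diff(relative_score(w, raws)) > 0))
  # toy two-column PFM: score of "AC" agrees with exhaustive enumeration
  p2 <- pfm(matrix(c(4, 0, 0, 0, 0, 4, 0, 0), nrow = 4), "toy2")
  w2 <- pfm_to_pwm(p2)
  all_scores <- vapply(oracle_all_words(2),
                       function(word) oracle_score_word(w2$weights, word),
                       numeric(1))
  raw_ac <- unname(w2$weights["A", 1] + w2$weights["C", 2])
  expect_equal(relative_score(w2, raw_ac),
               (raw_ac - min(all_scores)) / (max(all_scores) - min(all_scores)))
  expect_equal(relative_score(w2, raw_ac), 1)  # AC is the consensus word
})

test_that("scan_pwm finds a planted consensus word on both strands", {
  pw <- pfm_to_pwm(consensus_pfm("CACGTG"))
  hits <- scan_pwm(pw, "TTTTCACGTGTT")
  expect_equal(nrow(hits), 2)  # palindrome: one per strand
  expect_equal(hits$rel_start, c(-8, -8))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$rel_score, c(1, 1))
  expect_equal(hits$matched, c("CACGTG", "CACGTG"))

  # all-T promoter: nothing passes
  expect_equal(nrow(scan_pwm(pw, strrep("T", 40))), 0)

  # windows containing N are skipped
  expect_equal(nrow(scan_pwm(pw, "TTTTCACGTNTT")), 0)

  # motif wider than window errors
  expect_error(scan_pwm(pw, "CACG"), "wider than")
})

test_that("scan_pwm equals the exhaustive per-window oracle", {
  for (seed in 1:10) {
    width <- withr::with_seed(seed, sample(2:5, 1))
    pw <- pfm_to_pwm(random_pfm(width, seed = seed + 500))
    s <- random_dna(200, seed = seed + 900)
    tau <- 0.8
    got <- scan_pwm(pw, s, scan_config(rel_threshold = tau))
    want <- oracle_scan_pwm(pw, s, tau)
    expect_equal(got$rel_start, want$rel_start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$matched, want$matched)
    expect_equal(got$raw_score, want$raw_score, tolerance = 1e-9)
    expect_equal(got$rel_score, want$rel_score, tolerance = 1e-9)
  }
})

test_that("raising the threshold only removes hits", {
  pw <- pfm_to_pwm(random_pfm(4, seed = 3))
  s <- random_dna(300, seed = 33)
  lo <- scan_pwm(pw, s, scan_config(rel_threshold = 0.6))
  hi <- scan_pwm(pw, s, scan_config(rel_threshold = 0.85))
  expect_true(all(hi$rel_score >= 0.85))
  expect_true(all(lo$rel_score >= 0.6 & lo$rel_score <= 1))
  key <- function(h) paste(h$rel_start, h$strand)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("both-strand scans mirror under reverse complement", {
  for (seed in 1:5) {
    pw <- pfm_to_pwm(random_pfm(4, seed = seed + 40))
    s <- random_dna(150, seed = seed + 60)
    h_fwd <- scan_pwm(pw, s, scan_config(rel_threshold = 0.7))
    h_rc <- scan_pwm(pw, revcomp(s), scan_config(rel_threshold = 0.7))
    expect_equal(nrow(h_fwd), nrow(h_rc))
    # a + hit at index i maps to a - hit at L - i - w in the revcomp
    L <- 150; w <- 4
    mirrored <- sort((-(h_fwd$rel_start) - w) - L)  # mirror of rel_start
    expect_equal(sort(h_rc$rel_start), mirrored)
  }
})

test_that("hits anchor to the TSS: growing the window TSS-ward shifts rel_start by -k", {
  pw <- pfm_to_pwm(consensus_pfm("TGACGTCA"))
  s <- paste0(strrep("T", 20), "TGACGTCA", strrep("T", 10))
  base <- scan_pwm(pw, s)
  k <- 17
  # appending k bases at the TSS-proximal end pushes old hits k bp upstream
  shifted <- scan_pwm(pw, paste0(s, strrep("T", k)))
  expect_true(all((base$rel_start - k) %in% shifted$rel_start))
  # while extending the window upstream leaves TSS-relative positions alone
  grown <- scan_pwm(pw, paste0(random_dna(k, seed = 8), s))
  expect_true(all(base$rel_start %in% grown$rel_start))
})

test_that("overlap pruning keeps the best-scoring representative", {
  pw <- pfm_to_pwm(consensus_pfm("AAAA", n = 10, off = 1))
  s <- paste0("TTT", strrep("A", 8), "TTT")  # run of As: many overlapping hits
  all_hits <- scan_pwm(pw, s, scan_config(rel_threshold = 0.9,
                                          strands = "plus_only"))
  pruned <- scan_pwm(pw, s, scan_config(rel_threshold = 0.9,
                                        strands = "plus_only",
                                        prune_overlaps = TRUE))
  expect_gt(nrow(all_hits), nrow(pruned))
  expect_true(all(pruned$rel_score == 1))
  starts <- sort(pruned$rel_start)
  if (length(starts) > 1) expect_true(all(diff(starts) >= 4))
})
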