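test_that("fit_markov order 0 reproduces add-one smoothing by hand", {
  m <- fit_markov("AACG", order = 0, pseudocount = 1)
  expect_equal(unname(m$initial), c(3, 2, 2, 1) / 8)  # (2+1)/8 etc.
  # N bases are excluded from counting
  m2 <- fit_markov("AACGNNNN", order = 0, pseudocount = 1)
  expect_equal(m2$initial, m$initial)
  expect_error(fit_markov("NNNN"), "no usable")
})

test_that("fit_markov order 1 smooths every transition row", {
  m <- fit_markov("AAAA", order = 1, pseudocount = 1)
  expect_true(all(m$transitions > 0))
  expect_equal(unname(rowSums(m$transitions)), rep(1, 4))
  # A->A saw 3 of 3 pairs: (3+1)/(3+4)
  expect_equal(m$transitions["A", "A"], 4 / 7)
  expect_equal(m$transitions["C", "G"], 1 / 4)  # unseen row: uniform
})

test_that("fitted frequencies recover the generating model", {
  truth <- c(0.4, 0.3, 0.2, 0.1)
  seqs <- sample_sequences(markov_model(truth), length = 500, n = 100,
                           seed = 55)
  m <- fit_markov(seqs, order = 0)
  expect_true(all(abs(m$initial - truth) < 0.02))

  # order-1 recovery of a biased transition matrix
  tr <- matrix(c(0.7, 0.1, 0.1, 0.1,
                 0.1, 0.7, 0.1, 0.1,
                 0.1, 0.1, 0.7, 0.1,
                 0.1, 0.1, 0.1, 0.7), 4, 4, byrow = TRUE)
  seqs1 <- sample_sequences(markov_model(transitions = tr), 500, 100,
                            seed = 56)
  m1 <- fit_markov(seqs1, order = 1)
  expect_true(all(abs(m1$transitions - tr) < 0.03))
})

test_that("sample_sequences is seeded, sized and degenerate-safe", {
  model <- markov_model()
  expect_identical(sample_sequences(model, 50, 0), character(0))
  a <- sample_sequences(model, 80, 5, seed = 9)
  b <- sample_sequences(model, 80, 5, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, sample_sequences(model, 80, 5, seed = 10)))
  expect_true(all(nchar(a) == 80))

  forced <- markov_model(c(1 - 3e-10, 1e-10, 1e-10, 1e-10))
  expect_equal(sample_sequences(forced, 5, 1, seed = 1), "AAAAA")
})

test_that("per-sequence canonical E-box counts match the closed form", {
  # E[CACGTG per 3000 bp strand] = 2995 * 4^-6
  expected <- 2995 / 4^6
  seqs <- sample_sequences(markov_model(), 3000, 200, seed = 71)
  counts <- Biostrings::vcountPattern("CACGTG", Biostrings::DNAStringSet(seqs))
  sd3 <- 3 * sqrt(expected * (1 - 4^-6) / 200)  # ~binomial SE of the mean
  expect_lt(abs(mean(counts) - expected), sd3)
})

test_that("empirical p-values follow the add-one permutation form", {
  cfg10 <- enrichment_config(n_samples = 10)
  r <- empirical_enrichment(c(f = 5), list(f = 0:9), cfg10)
  expect_equal(r$p_raw, 6 / 11)
  expect_equal(r$null_mean, 4.5)

  # observed exceeds all null counts -> add-one floor
  cfg99 <- enrichment_config(n_samples = 99)
  r2 <- empirical_enrichment(c(f = 50), list(f = rep(0:4, length.out = 99)),
                             cfg99)
  expect_equal(r2$p_raw, 1 / 100)

  # observed 0 -> p = 1 (every null >= 0)
  r3 <- empirical_enrichment(c(f = 0), list(f = rep(0:4, length.out = 99)),
                             cfg99)
  expect_equal(r3$p_raw, 1)

  expect_error(empirical_enrichment(c(g = 1), list(f = 0:9), cfg10),
               "missing for family: g")
  expect_error(empirical_enrichment(c(f = 1), list(f = 0:8), cfg10),
               "expected 10 null counts")
})

test_that("depletion flips the tail", {
  cfg <- enrichment_config(n_samples = 10, alternative = "depletion")
  r <- empirical_enrichment(c(f = 0), list(f = c(rep(0, 2), rep(3, 8))), cfg)
  expect_equal(r$p_raw, 3 / 11)
})

test_that("multiple-testing correction matches the textbook step-up/Bonferroni", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.01, "Bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.5, 0.9), "Bonferroni"), c(1, 1))
  expect_identical(adjust_pvalues(numeric(0)), numeric(0))

  # BH <= Bonferroni pointwise; both preserve ranks; both >= raw
  for (seed in 1:5) {
    p <- withr::with_seed(seed, sort(runif(8)))
    bh <- adjust_pvalues(p, "BH")
    bf <- adjust_pvalues(p, "Bonferroni")
    expect_true(all(bh <= bf + 1e-12))
    expect_true(all(bh >= p) && all(bf >= p))
    expect_equal(order(bh), order(p))
    expect_true(all(diff(bh) >= 0) && all(diff(bf) >= 0))
  }
})

test_that("test_enrichment flags planted enrichment end to end", {
  fx <- simulate_promoter(seed = 5)
  res <- test_enrichment(fx$region,
                         config = enrichment_config(n_samples = 199,
                                                    seed = 17))
  expect_s3_class(res, "enrichment_result")
  expect_setequal(res$family, names(circadian_motifs()))
  # planted D-box count (4) is far above the Markov null (mean ~0.09)
  dbox <- res[res$family == "Dbox", ]
  expect_lt(dbox$p_raw, 0.05)
  expect_true(all(res$p_raw >= 1 / 200 & res$p_raw <= 1))
  expect_true(all(res$q_adj >= res$p_raw - 1e-12))
  # determinism under the seed
  res2 <- test_enrichment(fx$region,
                          config = enrichment_config(n_samples = 199,
                                                     seed = 17))
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("null counting agrees between Biostrings path and the scanner", {
  fams <- circadian_motifs()
  seqs <- sample_sequences(markov_model(), 800, 20, seed = 31)
  fast <- circamotif:::count_cores_many(seqs, fams)
  slow <- lapply(seqs, function(s) {
    count_by_family(scan_consensus(s, fams), families = names(fams))
  })
  for (f in names(fams)) {
    expect_equal(fast[[f]], vapply(slow, `[[`, integer(1), f))
  }
})

test_that("promoter_set background mode draws counts from user promoters", {
  bg <- sample_sequences(markov_model(), 400, 30, seed = 3)
  res <- test_enrichment(bg[1], motifs = circadian_motifs()["Pdp1"],
                         config = enrichment_config(
                           n_samples = 49, seed = 2,
                           background_mode = "promoter_set"),
                         background_seqs = bg)
  expect_equal(nrow(res), 1)
  expect_true(res$p_raw >= 1 / 50 && res$p_raw <= 1)
  expect_error(test_enrichment(bg[1],
                               config = enrichment_config(
                                 n_samples = 9,
                                 background_mode = "promoter_set")),
               "requires background_seqs")
})

test_that("PWM families join the correction family-wise", {
  fx <- simulate_promoter(seed = 8)
  pw <- pfm_to_pwm(consensus_pfm("CACGTG"))
  res <- test_enrichment(fx$region, pwms = list(pw),
                         config = enrichment_config(n_samples = 99, seed = 4))
  expect_equal(nrow(res), 7)  # six consensus families + one PWM
  expect_true("pfm_CACGTG" %in% res$family)
  # q values computed over all 7 tests: Bonferroni-style bound check via BH <= m*p
  expect_true(all(res$q_adj <= pmin(1, res$p_raw * 7) + 1e-12))
})
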