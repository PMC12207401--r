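test_that("cosinor scoring is exact for pure cosines and zero for constants", {
  tt <- seq(0, 46, by = 2)
  cosine <- 100 + 50 * cos(2 * pi * (tt - 5) / 24)
  m <- expression_matrix(rbind(per = cosine, flat = rep(7, 24),
                               noisy = abs(sin(tt) + 2)),
                         times = tt)
  r <- rank_periodicity(m, period = 24)
  expect_equal(r$score[r$gene_id == "per"], 1, tolerance = 1e-9)
  expect_equal(r$score[r$gene_id == "flat"], 0)
  expect_equal(r$gene_id[1], "per")
  expect_true(all(diff(r$score) <= 0))
  expect_error(rank_periodicity(m, period = -1), "positive")
})

test_that("cosinor R^2 matches the lm oracle on a linear-trend gene", {
  tt <- 0:11
  m <- expression_matrix(rbind(g = as.numeric(tt)), times = tt)
  got <- rank_periodicity(m, period = 12)$score
  ref <- summary(stats::lm(tt ~ cos(2 * pi * tt / 12) +
                             sin(2 * pi * tt / 12)))$r.squared
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("alignment fractions follow the window arithmetic", {
  tt <- seq(0, 46, by = 2)
  # genes whose max sits on the (single) stripe time 12 by construction
  vals <- matrix(1, nrow = 5, ncol = 24)
  vals[, 7] <- 10
  m <- expression_matrix(vals + outer(1:5 / 100, 1:24 / 1000),
                         gene_ids = paste0("g", 1:5), times = tt)
  rep1 <- stripe_alignment_fraction(m, 12, top_n = 5, period = 24)
  expect_equal(rep1$aligned_fraction, 1)
  expect_equal(rep1$expected_fraction, 1 / 12)

  # no extremum on any stripe time
  m2 <- expression_matrix(matrix(rep(sin(1:24) + 2, each = 3), nrow = 3,
                                 byrow = FALSE) +
                            outer(1:3 / 50, rep(0, 24)),
                          gene_ids = paste0("h", 1:3), times = tt)
  rep2 <- stripe_alignment_fraction(m2, 12, top_n = 3, period = 24)
  expect_equal(rep2$aligned_fraction, 0)

  # empty stripe list
  rep3 <- stripe_alignment_fraction(m, numeric(), top_n = 5, period = 24)
  expect_equal(rep3$aligned_fraction, 0)
  expect_equal(rep3$expected_fraction, 0)

  # 2 stripe times among 12 first-period points: the ~17% expectation
  rep4 <- stripe_alignment_fraction(m, c(16, 18), top_n = 5, period = 24)
  expect_equal(rep4$expected_fraction, 2 / 12)
  expect_equal(rep4$n_window_points, 12)
})

test_that("alignment validates its inputs", {
  m <- rand_matrix(G = 10, T = 6, seed = 2)
  expect_error(stripe_alignment_fraction(m, 999, top_n = 5, period = 40),
               "subset")
  expect_error(stripe_alignment_fraction(m, m$times[2], top_n = 50,
                                         period = 40), "top_n")
})

test_that("on anomaly-free uniform-phase data alignment calibrates to the uniform rate", {
  # With phases uniform and the trough half a period from the peak, the
  # peak-OR-trough rule aligns with probability ~ 2k/m for k stripe points
  # among m window points (twice the single-extremum expectation k/m that
  # the report also prints). Check within ~3 binomial standard errors.
  hits <- sapply(1:5, function(seed) {
    sim <- simulate_timecourse(simulation_config(n_genes = 1000,
                                                 frac_periodic = 1,
                                                 seed = seed))
    stripe_alignment_fraction(sim$matrix, c(16, 18), top_n = 300,
                              period = 24)$aligned_fraction
  })
  p <- 4 / 12
  se3 <- 3 * sqrt(p * (1 - p) / 300)
  expect_true(all(abs(hits - p) < se3 + 0.02))
})

test_that("top-N overlaps enumerate exactly", {
  mk <- function(ids, scores) as_periodicity_ranking(
    data.frame(gene_id = ids, score = scores))
  univ <- letters[1:6]
  A <- mk(univ, c(6, 5, 4, 3, 2, 1))
  B <- mk(univ, c(1, 6, 5, 4, 3, 2))
  same <- topn_overlap(list(A = A, B = A), top_n = 3)
  expect_equal(unname(same["A_B"]), 3L)
  expect_equal(sum(same), 3L)  # counts sum to |union|

  two <- topn_overlap(list(A = A, B = B), top_n = 3)
  # top-3 sets {a,b,c} and {b,c,d} overlap in 2
  expect_equal(unname(two["A_B"]), 2L)
  expect_equal(unname(two["A_only"]), 1L)
  expect_equal(sum(two), 4L)

  C <- mk(univ, c(1, 2, 3, 4, 5, 6))
  three <- topn_overlap(list(A = A, B = B, C = C), top_n = 3)
  expect_equal(sum(three), length(unique(c(
    head(A$gene_id, 3), head(B$gene_id, 3), head(C$gene_id, 3)))))
  disjoint <- topn_overlap(list(A = A, C = C), top_n = 3)
  expect_equal(unname(disjoint["A_C"]), 0L)

  D <- mk(LETTERS[1:6], 1:6)
  expect_error(topn_overlap(list(A, D), top_n = 3), "universe")
})

test_that("subsampling keeps full-series behavior at k = 1 and reports dropped points as absent", {
  sim <- sim_with_stripe(1, kind = "high", n_genes = 600)
  full <- detect_stripes(sim$matrix, 0.3)

  k1 <- sampling_sensitivity(sim$matrix, 0.3, "keep-every-k", k = 1)
  expect_equal(k1[[1]]$labels$label, as.character(full$label))
  expect_equal(k1[[1]]$status, "ok")

  loo <- sampling_sensitivity(sim$matrix, 0.3, "leave-one-out")
  drop7 <- loo[["drop_12"]]
  expect_equal(drop7$labels$label[drop7$labels$time == 12], "absent")
  expect_false(any(drop7$labels$label == "absent" &
                     drop7$labels$time != 12))

  k2 <- sampling_sensitivity(sim$matrix, 0.3, "keep-every-k", k = 2)
  lab <- k2[[1]]$labels
  expect_equal(lab$label[lab$time == 12], "1")  # anomaly retained and found
})
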