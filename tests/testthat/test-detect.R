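test_that("two-sample KS distance handles canonical cases", {
  ks <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ks$D, 0)
  expect_equal(ks$p, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1, 3))$D, 0.5)
  expect_error(ks_two_sample(numeric(), 1), "non-empty")
})

test_that("KS distance and p-value match independent oracles on random pairs", {
  set.seed(42)
  max_d_err <- 0
  for (i in 1:300) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    # integer draws force plenty of ties, the hard case
    a <- if (i %% 2) rnorm(n1) else sample(0:8, n1, replace = TRUE)
    b <- if (i %% 2) rnorm(n2, 0.3) else sample(0:8, n2, replace = TRUE)
    ks <- ks_two_sample(a, b)
    max_d_err <- max(max_d_err, abs(ks$D - ks_oracle(a, b)))
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
    # ks.test evaluates the Kolmogorov CDF only to ~1e-6, hence the looser
    # comparison for p
    expect_equal(ks$p, max(min(ref$p.value, 1), .Machine$double.xmin),
                 tolerance = 1e-3)
  }
  expect_lte(max_d_err, 1e-12)
})

test_that("KS distance behaves as a metric on empirical CDFs", {
  set.seed(7)
  for (i in 1:100) {
    a <- rnorm(sample(3:30, 1)); b <- runif(sample(3:30, 1), -1, 2)
    c_ <- rexp(sample(3:30, 1))
    dab <- ks_two_sample(a, b)$D
    dba <- ks_two_sample(b, a)$D
    dac <- ks_two_sample(a, c_)$D
    dcb <- ks_two_sample(c_, b)$D
    expect_identical(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
  }
})

test_that("a stripe-free simulation yields all-zero labels in a forward pass", {
  sim <- simulate_timecourse(simulation_config(seed = 1))
  calls <- detect_stripes(sim$matrix, 0.3)
  expect_equal(sum(calls$label), 0L)
  expect_equal(attr(calls, "direction"), "forward")
  # oracle: every consecutive-pair distance in the all-by-all matrix is
  # below the threshold
  dm <- pairwise_distance_matrix(sim$matrix)
  T <- length(dm$times)
  expect_true(all(dm$D[cbind(1:(T - 1), 2:T)] < 0.3))
})

test_that("a mid-series anomaly is flagged alone and anchoring skips it", {
  sim <- sim_with_stripe(1, kind = "high", time = 12)  # 7th of 24 points
  calls <- detect_stripes(sim$matrix, 0.3)
  expect_equal(which(calls$label == 1L), 7L)
  expect_equal(calls$anchor_time[8], calls$time[6])  # point 8 anchored at 6
  expect_equal(attr(calls, "direction"), "forward")
  # oracle: only row/column 7 exceeds the threshold against its neighbors
  dm <- pairwise_distance_matrix(sim$matrix)
  T <- length(dm$times)
  nb <- dm$D[cbind(1:(T - 1), 2:T)]
  expect_identical(which(nb > 0.3), c(6L, 7L))
})

test_that("an anomaly at the first point triggers the reverse pass", {
  sim <- sim_with_stripe(1, kind = "high", time = 0)
  calls <- detect_stripes(sim$matrix, 0.3)
  expect_equal(attr(calls, "direction"), "reverse")
  expect_equal(which(calls$label == 1L), 1L)
  # the reverse start anchor is the last point, self-anchored
  T <- nrow(calls)
  expect_equal(calls$anchor_time[T], calls$time[T])
  expect_equal(calls$label[T], 0L)
})

test_that("detection is invariant to gene-row permutation", {
  sim <- sim_with_stripe(3, kind = "bimodal", n_genes = 500)
  set.seed(9)
  perm <- sample(nrow(sim$matrix$values))
  mp <- expression_matrix(sim$matrix$values[perm, ],
                          gene_ids = sim$matrix$gene_ids[perm],
                          times = sim$matrix$times)
  expect_equal(detect_stripes(mp, 0.3)$label,
               detect_stripes(sim$matrix, 0.3)$label)
})

test_that("exhausting the consecutive budget in both directions is ambiguous", {
  # every column drawn from a disjoint range: every comparison crosses
  set.seed(5)
  T <- 12
  vals <- sapply(1:T, function(j) runif(300, 10 * j, 10 * j + 1))
  m <- expression_matrix(vals, gene_ids = sprintf("g%03d", 1:300),
                         times = 1:T)
  expect_error(detect_stripes(m, 0.3, preprocess = "none"),
               class = "stripe_ambiguous")
  expect_error(detect_stripes(m, 0.3, preprocess = "none"),
               "pairwise_distance_matrix")
})

test_that("detector input contracts are enforced", {
  m <- expression_matrix(matrix(runif(20), 10), gene_ids = letters[1:10],
                         times = c(0, 1))
  expect_error(detect_stripes(m, 0.3), "at least 3 time points")
  expect_error(threshold_spec(0), "inside \\(0, 1\\)")
  expect_error(threshold_spec(1.2), "inside \\(0, 1\\)")
})

test_that("the distance matrix is symmetric with a zero diagonal", {
  m <- expression_matrix(cbind(c(1, 2), c(1, 3), c(10, 11)),
                         gene_ids = c("a", "b"), times = c(0, 1, 2))
  dm <- pairwise_distance_matrix(m, preprocess = "none")
  expect_identical(dm$D, t(dm$D))
  expect_equal(unname(diag(dm$D)), c(0, 0, 0))
  # hand-derived pairwise distances for these tiny samples
  expect_equal(dm$D[1, 2], 0.5)
  expect_equal(dm$D[1, 3], 1)
  expect_equal(dm$D[2, 3], 1)
})

test_that("robust outlier rule flags large neighbor distances and handles MAD = 0", {
  ro <- stripeqc:::robust_outliers(c(0.10, 0.12, 0.11, 0.60))
  expect_identical(which(ro$flag), 4L)
  expect_gt(ro$robust_z[4], 3.5)
  expect_warning(ro0 <- stripeqc:::robust_outliers(rep(0.2, 5)),
                 "identical")
  expect_false(any(ro0$flag))
})

test_that("threshold suggestion flags injected anomalies and nothing else", {
  sim0 <- simulate_timecourse(simulation_config(seed = 1))
  rep0 <- suggest_threshold(sim0$matrix)
  expect_length(rep0$suggested_outliers, 0L)

  sim1 <- sim_with_stripe(1, kind = "low", time = 12)
  rep1 <- suggest_threshold(sim1$matrix)
  # both comparisons into and out of the anomaly stand out; the flagged
  # labels must include the stripe time
  expect_true(12 %in% rep1$suggested_outliers)
  expect_error(suggest_threshold(
    expression_matrix(matrix(runif(9), 3), gene_ids = letters[1:3],
                      times = 0:2)), "at least 4")
})
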