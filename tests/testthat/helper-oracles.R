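# Independent oracles and small fixture builders used across the suite.

# Brute-force two-sample KS distance: evaluate both empirical CDFs at every
# pooled sample point and take the largest absolute difference.
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

# Independent shape-preserving cubic Hermite interpolant with the
# Fritsch-Carlson derivative rule: zero slope where adjacent secants change
# sign, weighted harmonic mean of the secants otherwise, and the standard
# shape-preserving one-sided three-point formula at the ends. Evaluated
# through the cubic Hermite basis, written without reference to any library
# implementation.
pchip_oracle <- function(xk, yk, x) {
  n <- length(xk)
  h <- diff(xk)
  delta <- diff(yk) / h
  d <- numeric(n)
  if (n == 2) {
    d[] <- delta[1]
  } else {
    for (i in 2:(n - 1)) {
      if (delta[i - 1] * delta[i] <= 0) {
        d[i] <- 0
      } else {
        w1 <- 2 * h[i] + h[i - 1]
        w2 <- h[i] + 2 * h[i - 1]
        d[i] <- (w1 + w2) / (w1 / delta[i - 1] + w2 / delta[i])
      }
    }
    edge <- function(h0, h1, d0, d1) {
      dd <- ((2 * h0 + h1) * d0 - h0 * d1) / (h0 + h1)
      if (sign(dd) != sign(d0)) dd <- 0
      else if (sign(d0) != sign(d1) && abs(dd) > 3 * abs(d0)) dd <- 3 * d0
      dd
    }
    d[1] <- edge(h[1], h[2], delta[1], delta[2])
    d[n] <- edge(h[n - 1], h[n - 2], delta[n - 1], delta[n - 2])
  }
  vapply(x, function(xx) {
    i <- min(max(findInterval(xx, xk), 1L), n - 1L)
    t <- (xx - xk[i]) / h[i]
    (2 * t^3 - 3 * t^2 + 1) * yk[i] +
      (t^3 - 2 * t^2 + t) * h[i] * d[i] +
      (-2 * t^3 + 3 * t^2) * yk[i + 1] +
      (t^3 - t^2) * h[i] * d[i + 1]
  }, numeric(1))
}

# Small random raw-scale matrix (continuous values, ties essentially
# impossible).
rand_matrix <- function(G = 20, T = 6, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(stats::rlnorm(G * T, 3, 1), nrow = G),
                    gene_ids = sprintf("g%03d", seq_len(G)),
                    times = seq(0, by = 10, length.out = T))
}

# Simulated time course with one injected anomaly at t = 12 (the 7th of 24
# points), the workhorse scenario of the detection/correction tests.
sim_with_stripe <- function(seed, kind = "high", delta = 2, time = 12,
                            n_genes = 2000) {
  simulate_timecourse(
    simulation_config(n_genes = n_genes, seed = seed),
    stripes = list(stripe_spec(time, kind, delta)))
}

# Minimal hand-built call set for scoring tests.
fake_calls <- function(times, labels) {
  structure(data.frame(time = times, label = as.integer(labels),
                       ks_distance = NA_real_, p_value = NA_real_,
                       anchor_time = NA_real_),
            class = c("stripe_calls", "data.frame"),
            direction = "forward", threshold = threshold_spec(0.3),
            max_consecutive = 5L, preprocess = "zscore")
}

# Minimal truth object carrying only injected stripe times.
fake_truth <- function(times, injected) {
  structure(list(genes = data.frame(), times = times,
                 injected = lapply(injected, function(t)
                   list(time = t, kind = "high", magnitude = 2,
                        fraction = 1))),
            class = "simulation_truth")
}
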