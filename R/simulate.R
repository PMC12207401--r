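# Run code under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for the synthetic periodic time course
#'
#' The defaults mirror the shape of a mammalian cell-cycle time course: 24
#' time points at 2-unit spacing (two full cycles of a 24-unit period, i.e.
#' 12 time points per cycle), a few thousand genes, half of them periodic.
#' Expression is cosine-on-log2-scale with multiplicative (log-normal)
#' noise: per gene g and time t,
#' `log2 x = log2 b_g + A_g * cos(2*pi*(t - phi_g)/period) * [g periodic] + eps`,
#' `eps ~ N(0, noise_sd^2)`, with baseline `log2 b_g ~ N(log2_baseline_mean,
#' log2_baseline_sd^2)`, phase `phi_g` uniform over one period and amplitude
#' `A_g` uniform over `amplitude_range`. Values are emitted on the linear
#' (`2^`) scale, like TPM/FPKM.
#'
#' @param n_genes number of genes, default 2000.
#' @param frac_periodic fraction of genes given a periodic component,
#'   default 0.5.
#' @param times numeric `c(start, step, count)`; default `c(0, 2, 24)`.
#' @param period oscillation period in the same unit as `times`, default 24.
#' @param log2_baseline_mean,log2_baseline_sd log2-scale baseline abundance
#'   distribution; defaults 6 and 2 (median ~64 TPM with a wide dynamic
#'   range).
#' @param amplitude_range uniform range `c(lo, hi)` of peak-to-mean log2
#'   amplitudes for periodic genes, default `c(0.5, 2)`.
#' @param noise_sd multiplicative noise sd in log2 units, default 0.25.
#' @param seed integer RNG seed; the simulation is fully reproducible from
#'   it.
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000L, frac_periodic = 0.5,
                              times = c(0, 2, 24), period = 24,
                              log2_baseline_mean = 6, log2_baseline_sd = 2,
                              amplitude_range = c(0.5, 2), noise_sd = 0.25,
                              seed = 1L) {
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1L, frac_periodic >= 0, frac_periodic <= 1,
            length(times) == 3L, times[3] >= 3, times[2] > 0, period > 0,
            length(amplitude_range) == 2L, amplitude_range[1] >= 0,
            amplitude_range[2] >= amplitude_range[1], noise_sd >= 0)
  structure(list(n_genes = n_genes, frac_periodic = frac_periodic,
                 times = c(start = as.numeric(times[1]),
                           step = as.numeric(times[2]),
                           count = as.integer(times[3])),
                 period = period,
                 log2_baseline_mean = log2_baseline_mean,
                 log2_baseline_sd = log2_baseline_sd,
                 amplitude_range = amplitude_range, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Describe a STRIPE to inject into a simulated matrix
#'
#' The three anomaly subtypes seen in real time courses: `low` (every
#' affected gene depressed), `high` (elevated) and `bimodal` (each affected
#' gene independently depressed or elevated with probability 1/2). The shift
#' is multiplicative: affected values in the target column are multiplied by
#' `2^(+/- magnitude)`.
#'
#' @param time time label of the column to perturb.
#' @param kind `"low"`, `"high"` or `"bimodal"`.
#' @param magnitude log2-scale shift `delta > 0`.
#' @param fraction fraction of genes affected, in (0, 1]; default 1
#'   (transcriptome-wide, as observed in real anomalies).
#' @param seed optional seed for the affected-gene subset and bimodal sign
#'   assignment; if `NULL` the ambient RNG stream is used (so injection
#'   inside [simulate_timecourse()] is reproducible from the config seed).
#' @return an object of class `"stripe_spec"`.
#' @export
stripe_spec <- function(time, kind = c("low", "high", "bimodal"), magnitude,
                        fraction = 1, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time), length(time) == 1L,
            is.numeric(magnitude), length(magnitude) == 1L)
  if (magnitude <= 0) stop("stripe magnitude (log2 delta) must be > 0")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  structure(list(time = as.numeric(time), kind = kind,
                 magnitude = as.numeric(magnitude), fraction = fraction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "stripe_spec")
}

#' Simulate a periodic expression time course
#'
#' Generates an [expression_matrix] under the cosine-on-log2 model of
#' [simulation_config()], optionally injecting STRIPEs, and returns the
#' ground truth needed to score detection: per-gene periodic flag, phase,
#' amplitude and baseline, plus a record of every injected anomaly.
#'
#' @param cfg a [simulation_config()].
#' @param stripes list of [stripe_spec()] objects to inject (may be empty).
#' @return a list with elements `matrix` (an [expression_matrix], scale
#'   `"raw"`) and `truth` (class `"simulation_truth"`: list with `genes`
#'   data frame, `times`, and `injected` -- one record per injected stripe
#'   with the affected genes and their signed log2 shifts).
#' @export
#' @examples
#' sim <- simulate_timecourse(simulation_config(n_genes = 50, seed = 7),
#'                            stripes = list(stripe_spec(12, "high", 2)))
#' sim$matrix
simulate_timecourse <- function(cfg, stripes = list()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (inherits(stripes, "stripe_spec")) stripes <- list(stripes)
  G <- cfg$n_genes
  times <- cfg$times["start"] + cfg$times["step"] * (0:(cfg$times["count"] - 1L))
  names(times) <- NULL
  with_local_seed(cfg$seed, {
    log2_b <- stats::rnorm(G, cfg$log2_baseline_mean, cfg$log2_baseline_sd)
    periodic <- rep(FALSE, G)
    n_per <- round(cfg$frac_periodic * G)
    if (n_per > 0) periodic[sample.int(G, n_per)] <- TRUE
    phase <- stats::runif(G, 0, cfg$period)
    amp_drawn <- stats::runif(G, cfg$amplitude_range[1],
                              cfg$amplitude_range[2])
    amp <- ifelse(periodic, amp_drawn, 0)
    osc <- outer(amp, times, function(a, t) a) *
      cos(2 * pi * outer(-phase, times, "+") / cfg$period)
    eps <- matrix(stats::rnorm(G * length(times), 0, cfg$noise_sd),
                  nrow = G)
    log2x <- log2_b + osc + eps
    gene_ids <- sprintf("g%05d", seq_len(G))
    m <- expression_matrix(2^log2x, gene_ids = gene_ids, times = times,
                           scale_tag = "raw")
    truth <- structure(list(
      genes = data.frame(gene_id = gene_ids, periodic = periodic,
                         phase = phase, amplitude = amp,
                         baseline = 2^log2_b,
                         stringsAsFactors = FALSE),
      times = times, injected = list()), class = "simulation_truth")
    for (sp in stripes) {
      inj <- inject_stripe(m, sp)
      m <- inj$matrix
      truth$injected <- c(truth$injected, list(inj$injection))
    }
    list(matrix = m, truth = truth)
  })
}

#' Inject a STRIPE into an expression matrix
#'
#' Multiplies the affected genes' values in exactly one column by
#' `2^(+/- magnitude)` according to the anomaly subtype; every other entry
#' is bit-identical to the input.
#'
#' @param m an [expression_matrix].
#' @param spec a [stripe_spec()] whose `time` is one of `m$times`.
#' @return list with `matrix` (the perturbed [expression_matrix]) and
#'   `injection` (record: `time`, `kind`, `magnitude`, `fraction`,
#'   `affected_genes`, and the named per-gene `log2_shift` vector).
#' @export
inject_stripe <- function(m, spec) {
  stopifnot(inherits(m, "expression_matrix"), inherits(spec, "stripe_spec"))
  col <- match(spec$time, m$times)
  if (is.na(col))
    stop("stripe time ", spec$time, " is not a time point of the matrix")
  G <- nrow(m$values)
  draw <- function() {
    affected <- if (spec$fraction < 1)
      sort(sample.int(G, round(spec$fraction * G))) else seq_len(G)
    sign <- switch(spec$kind,
      low = rep(-1, length(affected)),
      high = rep(1, length(affected)),
      bimodal = sample(c(-1, 1), length(affected), replace = TRUE))
    list(affected = affected, sign = sign)
  }
  d <- if (is.null(spec$seed)) draw() else with_local_seed(spec$seed, draw())
  shift <- d$sign * spec$magnitude
  vals <- m$values
  vals[d$affected, col] <- vals[d$affected, col] * 2^shift
  out <- expression_matrix(vals, gene_ids = m$gene_ids, times = m$times,
                           scale_tag = m$scale_tag)
  injection <- list(time = spec$time, kind = spec$kind,
                    magnitude = spec$magnitude, fraction = spec$fraction,
                    affected_genes = m$gene_ids[d$affected],
                    log2_shift = stats::setNames(shift,
                                                 m$gene_ids[d$affected]))
  list(matrix = out, injection = injection)
}

#' Injected STRIPE times recorded in a simulation truth
#' @param truth a `simulation_truth` object.
#' @return numeric vector of injected time labels (unique, sorted).
#' @export
injected_times <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  sort(unique(vapply(truth$injected, `[[`, numeric(1), "time")))
}

#' Score detector calls against simulation ground truth
#'
#' @param calls a `stripe_calls` object from [detect_stripes()].
#' @param truth the `simulation_truth` for the same matrix.
#' @return list with `sensitivity` (fraction of injected time points labeled
#'   1) and `specificity` (fraction of non-injected time points labeled 0);
#'   either is `NA` when its denominator is empty.
#' @export
score_detection <- function(calls, truth) {
  stopifnot(inherits(calls, "stripe_calls"),
            inherits(truth, "simulation_truth"))
  if (!isTRUE(all.equal(calls$time, truth$times)))
    stop("calls and truth do not share the same time axis")
  inj <- calls$time %in% injected_times(truth)
  list(sensitivity = if (any(inj)) mean(calls$label[inj] == 1L) else NA_real_,
       specificity = if (any(!inj)) mean(calls$label[!inj] == 0L)
                     else NA_real_)
}
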