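#' Simulate a noisy measurement series with known truth
#'
#' Generates replicate measurements of a smooth low-inflexion curve at
#' evenly spaced time points, emulating the sparse quantitative time
#' courses the method targets (6-16 time points, 2-3 noisy replicates).
#' Curve families:
#'
#' * `"logistic"`: a sigmoid rise (or fall, via a negative `amplitude`),
#'   `baseline + amplitude / (1 + exp(-steepness * (t - t_mid)))`; the
#'   sampled path has at most one inflexion.
#' * `"peak"`: a single Gaussian bump,
#'   `baseline + amplitude * exp(-(t - t_mid)^2 / (2 * width^2))`.
#' * `"damped"`: a damped oscillation,
#'   `baseline + amplitude * exp(-t / tau) * cos(2 * pi * t / period)`,
#'   whose number of sign alternations grows with the sampled span over
#'   `period`.
#'
#' Replicate values are the true curve value plus independent normal noise.
#' Amplitudes default to 2 (think log2 expression change) and `noise_sd`
#' to 0.2, i.e. a tenth of the default dynamic range.
#'
#' @param n_points Number of time points (>= 3), at times `0..n_points - 1`.
#' @param curve Curve family: `"logistic"`, `"peak"` or `"damped"`.
#' @param noise_sd Replicate noise standard deviation.
#' @param n_reps Replicates per time point (default 3).
#' @param seed Optional integer seed.
#' @param conf Confidence level for the resulting series.
#' @param params Optional named list overriding curve parameters
#'   (`baseline`, `amplitude`, `t_mid`, `steepness`, `width`, `tau`,
#'   `period`).
#' @param id Series identifier.
#' @return List with `series` (an `iq_series`), `truth` (function of t),
#'   `truth_dense` (data frame `t`, `y` at 512 points) and `inflexions`
#'   (inflexion count of the true curve at the sampled resolution).
#' @examples
#' sim <- simulate_series(7, "peak", noise_sd = 0.1, seed = 1)
#' sim$inflexions
#' @export
simulate_series <- function(n_points = 7,
                            curve = c("logistic", "peak", "damped"),
                            noise_sd = 0.2, n_reps = 3, seed = NULL,
                            conf = 0.99, params = list(), id = NULL) {
  curve <- match.arg(curve)
  stopifnot(n_points >= 3, n_reps >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, n_points - 1)
  span <- n_points - 1
  p <- utils::modifyList(list(baseline = 0, amplitude = 2, t_mid = span / 2,
                              steepness = 8 / span, width = span / 6,
                              tau = span / 2, period = span / 1.5), params)
  truth <- switch(curve,
    logistic = function(tt)
      p$baseline + p$amplitude / (1 + exp(-p$steepness * (tt - p$t_mid))),
    peak = function(tt)
      p$baseline + p$amplitude * exp(-(tt - p$t_mid)^2 / (2 * p$width^2)),
    damped = function(tt)
      p$baseline + p$amplitude * exp(-tt / p$tau) * cos(2 * pi * tt / p$period))
  values <- lapply(t, function(tt) truth(tt) + stats::rnorm(n_reps, 0, noise_sd))
  td <- seq(min(t), max(t), length.out = 512)
  list(series = measurement_series(t, values,
                                   id = if (is.null(id)) curve else id,
                                   conf = conf),
       truth = truth,
       truth_dense = data.frame(t = td, y = truth(td)),
       inflexions = count_inflexions(t, truth(t)))
}

#' Draw one truth path uniformly from the plausible set of a series
#'
#' Samples a single accepted guide configuration for the retained series
#' (treating the means as exact) and returns the piecewise-linear path
#' through the measured means and the sampled guide points, evaluable at
#' any position in the measured range. Used as ground truth in calibration
#' experiments: by construction the returned path satisfies the
#' plausibility constraint of the retained points.
#'
#' @param retained An [measurement_series()].
#' @param seed Optional integer seed.
#' @inheritParams sample_plausible_paths
#' @param clip_factor,n_grid,grid_n,tol_y Bounds controls, see
#'   [path_bounds()].
#' @param bounds Optional precomputed `iq_bounds` for the mean path (saves
#'   recomputation in repeated draws).
#' @return List with `fun` (function of t), `guide_x`, `guide_y`, and the
#'   merged `path` (data frame `x`, `y`).
#' @export
simulate_truth_from_plausible_set <- function(retained, seed = NULL,
                                              bounds = NULL,
                                              clip_factor = 1, n_grid = 101,
                                              grid_n = 64, tol_y = 1e-8,
                                              max_attempts = 1e7,
                                              acceptance = c("le", "eq"),
                                              tol = 1e-12) {
  acceptance <- match.arg(acceptance)
  stopifnot(inherits(retained, "iq_series"))
  if (!is.null(seed)) set.seed(seed)
  t <- retained$t
  means <- series_means(retained)
  if (is.null(bounds))
    bounds <- path_bounds(t, means, clip_factor = clip_factor,
                          n_grid = n_grid, grid_n = grid_n, tol_y = tol_y,
                          acceptance = acceptance, tol = tol)
  mc <- sample_plausible_paths(t, means, bounds, n_accept = 1,
                               max_attempts = max_attempts,
                               acceptance = acceptance, tol = tol)
  merged <- merge_path(t, means, mc$guide_x, as.vector(mc$samples[1, ]))
  list(fun = stats::approxfun(merged$x, merged$y),
       guide_x = mc$guide_x, guide_y = as.vector(mc$samples[1, ]),
       path = data.frame(x = merged$x, y = merged$y))
}

#' Calibration experiment: coverage of envelopes against sampled truths
#'
#' Repeats, for `n_series` simulated series: withhold time points, draw a
#' truth path uniformly from the plausible set of the retained means, build
#' the likelihood field and envelopes from the retained points (means
#' treated as exact, matching the truth generator), and score whether the
#' truth value at each withheld time falls inside each envelope. Pools the
#' indicator counts over all series.
#'
#' @param n_series Number of simulated series.
#' @param n_points Time points per series (odd, so `"every_other"` keeps
#'   both endpoints).
#' @param levels Envelope levels to score.
#' @param pattern Withholding rule, see [withhold()].
#' @param method Field method, `"direct"` or `"mc"`.
#' @param V Grid intervals per guide column.
#' @param n_accept Accepted samples per series for `method = "mc"`.
#' @param noise_sd,n_reps Simulation noise controls.
#' @param seed Integer seed for the whole experiment.
#' @return Data frame `level`, `n`, `n_inside`, `fraction`, `se`
#'   (binomial standard error at the nominal level).
#' @export
calibrate_coverage <- function(n_series = 200, n_points = 7,
                               levels = c(0.20, 0.75, 0.95),
                               pattern = "every_other",
                               method = c("direct", "mc"), V = 40,
                               n_accept = 4000,
                               noise_sd = 0.2, n_reps = 3, seed = 1) {
  method <- match.arg(method)
  set.seed(seed)
  families <- c("logistic", "peak", "damped")
  n_in <- stats::setNames(numeric(length(levels)), levels)
  n_tot <- 0
  for (i in seq_len(n_series)) {
    sim <- simulate_series(n_points, families[(i - 1) %% 3 + 1],
                           noise_sd = noise_sd, n_reps = n_reps)
    parts <- withhold(sim$series, pattern)
    retained <- parts$retained
    truth <- simulate_truth_from_plausible_set(retained)
    field <- estimate_field(retained, method = method, error = "none",
                            V = V, n_accept = n_accept)
    env <- build_envelope_set(field, levels = levels)
    wt <- parts$withheld$t
    wy <- truth$fun(wt)
    cov <- coverage(data.frame(t = wt, y = wy), env)
    n_tot <- n_tot + length(wt)
    n_in <- n_in + stats::setNames(cov$n_inside, cov$level)[as.character(levels)]
  }
  data.frame(level = levels, n = n_tot, n_inside = as.numeric(n_in),
             fraction = as.numeric(n_in) / n_tot,
             se = sqrt(levels * (1 - levels) / n_tot))
}
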