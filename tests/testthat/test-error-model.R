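test_that("replicate summaries reproduce the t-interval", {
  s <- summarize_replicates(c(1, 2, 3), conf = 0.99)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  # frozen from the independent oracle qt(0.995, df = 2) / sqrt(3)
  expect_equal((s$ci_hi - s$ci_lo) / 2, 5.7301, tolerance = 1e-4)
  # identical replicates give a zero-width interval
  s0 <- summarize_replicates(c(5, 5, 5))
  expect_equal(c(s0$ci_lo, s0$ci_hi), c(5, 5))
  # conf 0 collapses onto the mean
  sc <- summarize_replicates(c(1, 3), conf = 0)
  expect_equal(c(sc$ci_lo, sc$ci_hi), c(2, 2))
  expect_error(summarize_replicates(4), "insufficient replicates")
  expect_equal(summarize_replicates(4, sd = 1)$df, Inf)
})

test_that("CI sub-intervals have equal probability mass for every df and m", {
  for (df in c(1, 2, 5, 29)) {
    for (m in c(1, 2, 4, 16, 50)) {
      conf <- 0.99
      n <- df + 1
      meas <- list(mean = 0.7, sd = 1.3, n = n, df = df, conf = conf)
      mids <- equal_probability_midpoints(meas, m)
      expect_length(mids, m)
      if (m > 1) expect_true(all(diff(mids) > 0))
      # numerical integration of the scaled t density over each sub-interval
      probs <- (1 - conf) / 2 + (0:m) * conf / m
      bounds <- 0.7 + qt(probs, df) * 1.3 / sqrt(n)
      mass <- vapply(seq_len(m), function(j) {
        f <- function(y) dt((y - 0.7) / (1.3 / sqrt(n)), df) / (1.3 / sqrt(n))
        integrate(f, bounds[j], bounds[j + 1], rel.tol = 1e-10)$value
      }, numeric(1))
      expect_true(all(abs(mass - conf / m) <= 1e-6))
      # midpoints are the arithmetic centers of their sub-intervals
      expect_equal(mids, (bounds[-1] + bounds[-(m + 1)]) / 2)
    }
  }
})

test_that("midpoint edge cases behave", {
  meas <- list(mean = 3, sd = 2, n = 3, df = 2, conf = 0.99)
  expect_equal(equal_probability_midpoints(meas, 1), 3)  # symmetric t
  m2 <- equal_probability_midpoints(meas, 2)
  expect_equal(mean(m2), 3)                              # symmetric about mean
  degenerate <- list(mean = 3, sd = 0, n = 3, df = 2, conf = 0.99)
  expect_equal(equal_probability_midpoints(degenerate, 4), rep(3, 4))
  expect_error(equal_probability_midpoints(meas, 0), "at least 1")
})

test_that("LHS realizations use every midpoint exactly once when cycles = m", {
  s <- noisy_series(c(0, 1, 0.5, 1.2), noise_sd = 0.2, seed = 6)
  m <- 8
  r <- lhs_realizations(s, m = m, cycles = m, seed = 2)
  mids <- attr(r, "midpoints")
  for (i in seq_along(s$t)) {
    used <- sort(vapply(r, function(rk) rk$values[i], numeric(1)))
    expect_equal(used, sort(mids[[i]]))
  }
  # fixed seed reproduces the realization list
  r2 <- lhs_realizations(s, m = m, cycles = m, seed = 2)
  expect_identical(r, r2)
  # each realization carries its own inflexion count
  for (rk in r)
    expect_identical(rk$reference, count_inflexions(s$t, rk$values))
  expect_error(lhs_realizations(s, m = 4, cycles = 5), "cannot exceed")
})

test_that("field aggregation is an equal-weight mixture", {
  f <- fixture3()
  cols <- direct_columns(f$x, f$y, V = 6)
  mk <- function(cols) structure(
    list(series = NULL, reference = 1, bounds = NULL, columns = cols,
         measured_columns = list()), class = "iq_field")
  a <- mk(cols)
  # idempotence
  agg <- aggregate_fields(list(a, a))
  for (j in seq_along(cols))
    expect_equal(agg$columns[[j]]$p_joint, cols[[j]]$p_joint)
  # disjoint spikes average to a 0.5 / 0.5 bimodal column
  spike <- function(k) {
    cl <- cols
    for (j in seq_along(cl)) {
      p <- rep(0, 6); p[k] <- 1
      cl[[j]]$p_joint <- p; cl[[j]]$p_left <- p; cl[[j]]$p_right <- p
    }
    mk(cl)
  }
  bi <- aggregate_fields(list(spike(2), spike(5)))
  expect_equal(bi$columns[[1]]$p_joint,
               c(0, 0.5, 0, 0, 0.5, 0))
  expect_equal(sum(bi$columns[[1]]$p_joint), 1, tolerance = 1e-12)
  # mismatched grids are rejected
  cols2 <- direct_columns(f$x, f$y * 2, V = 6)
  expect_error(aggregate_fields(list(mk(cols), mk(cols2))),
               "mismatched grids")
})

test_that("shrinking CIs makes the error-model field converge to zero-error", {
  base <- c(2, 1, 2)
  tv_for <- function(noise) {
    s <- noisy_series(base, noise_sd = noise, seed = 12)
    # rescale replicates toward their means so means match across noise levels
    f_err <- suppressWarnings(
      estimate_field(s, error = "lhs", V = 10, m = 4, cycles = 4, seed = 1))
    f_zero <- estimate_field(
      measurement_series(s$t, lapply(series_means(s), function(v) rep(v, 3))),
      error = "none", V = 10, seed = 1)
    # compare on the shared guide grid: distributions live on different
    # spans, so compare envelope midlines instead of raw vectors
    e1 <- build_envelope_set(f_err, levels = 0.75)
    e2 <- build_envelope_set(f_zero, levels = 0.75)
    mean(abs(e1$lo - e2$lo) + abs(e1$hi - e2$hi))
  }
  d_big <- tv_for(0.4)
  d_small <- tv_for(0.02)
  expect_lt(d_small, d_big)
  expect_lt(d_small, 0.1)
})
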