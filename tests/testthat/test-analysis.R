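test_that("withholding rules retain the stated indices", {
  s7 <- noisy_series(rep(c(1, 2), length.out = 7), seed = 1)
  w <- withhold(s7, "every_other")
  expect_equal(w$retained$t, c(0, 2, 4, 6))
  expect_equal(w$withheld$t, c(1, 3, 5))
  s16 <- noisy_series(rep(c(1, 2), length.out = 16), seed = 2)
  w3 <- withhold(s16, "every_third")
  expect_equal(length(w3$retained$t), 6)
  expect_equal(w3$retained$t, c(0, 3, 6, 9, 12, 15))
  # explicit full list withholds nothing
  wall <- withhold(s7, 1:7)
  expect_null(wall$withheld)
  # dropping an endpoint is an error
  expect_error(withhold(s16, "every_other"), "endpoint")
  expect_error(withhold(s7, c(1, 3, 5)), "endpoint")
})

test_that("envelope quantiles invert a uniform column correctly and nest", {
  f <- fixture3()
  field <- estimate_field(noisy_series(f$y, seed = 3), error = "none", V = 40)
  # overwrite one column with a uniform distribution on [0, 1]
  field$columns[[1]]$lo <- 0; field$columns[[1]]$hi <- 1
  field$columns[[1]]$midpoints <- discretize_column(0, 1, 0.5, 40)$midpoints
  field$columns[[1]]$p_joint <- rep(1 / 40, 40)
  env <- build_envelope_set(field, levels = c(0.20, 0.75, 0.95))
  e95 <- env[env$level == 0.95 & abs(env$x - field$columns[[1]]$x) < 1e-9, ]
  expect_equal(e95$lo, 0.025, tolerance = 1 / 40)
  expect_equal(e95$hi, 0.975, tolerance = 1 / 40)
  # nesting at every vertex
  for (xx in unique(env$x)) {
    sub <- env[abs(env$x - xx) < 1e-9, ]
    sub <- sub[order(sub$level), ]
    expect_true(all(diff(sub$lo) <= 1e-9))
    expect_true(all(diff(sub$hi) >= -1e-9))
  }
})

test_that("a single-spike column gives a zero-width interval at the spike", {
  f <- fixture3()
  field <- estimate_field(noisy_series(f$y, seed = 3), error = "none", V = 20)
  p <- rep(0, 20); p[7] <- 1
  field$columns[[2]]$p_joint <- p
  env <- build_envelope_set(field, levels = c(0.20, 0.95))
  spike_y <- field$columns[[2]]$midpoints[7]
  bin_w <- diff(field$columns[[2]]$midpoints[1:2])
  e <- env[abs(env$x - field$columns[[2]]$x) < 1e-9, ]
  expect_true(all(abs(e$lo - spike_y) <= bin_w))
  expect_true(all(abs(e$hi - spike_y) <= bin_w))
  expect_true(all(e$hi - e$lo <= bin_w))
})

test_that("envelopes stay inside the plausible bounds", {
  s <- noisy_series(c(2, 1, 2.2, 1.4), noise_sd = 0.15, seed = 8)
  field <- suppressWarnings(
    estimate_field(s, error = "lhs", V = 16, m = 4, cycles = 4, seed = 2))
  env <- build_envelope_set(field)
  gx <- vapply(field$columns, `[[`, numeric(1), "x")
  b <- bounds_at(field$bounds, gx)
  for (q in attr(env, "levels")) {
    e <- env[env$level == q & env$x %in% gx, ]
    expect_true(all(e$lo >= b$lo - 1e-6))
    expect_true(all(e$hi <= b$hi + 1e-6))
  }
})

test_that("coverage counts withheld means inside interpolated boundaries", {
  f <- fixture3()
  field <- estimate_field(noisy_series(f$y, seed = 3), error = "none", V = 40)
  env <- build_envelope_set(field)
  # a point at the column median is inside every level
  cl <- field$columns[[2]]
  med <- cl$midpoints[which(cumsum(cl$p_joint) >= 0.5)[1]]
  cov_in <- coverage(data.frame(t = cl$x, y = med), env)
  expect_equal(cov_in$fraction, rep(1, 3))
  # a point above the 95% hi at its x is in no level
  hi95 <- envelope_at(env, 0.95, cl$x)$hi
  cov_out <- coverage(data.frame(t = cl$x, y = hi95 + 0.5), env)
  expect_equal(cov_out$fraction, rep(0, 3))
  expect_error(coverage(data.frame(t = 99, y = 0), env), "out of range")
})

test_that("hdi intervals are never wider than central ones", {
  f <- fixture3()
  field <- estimate_field(noisy_series(f$y, seed = 4), error = "none", V = 40)
  ec <- build_envelope_set(field, levels = 0.75, type = "central")
  eh <- build_envelope_set(field, levels = 0.75, type = "hdi")
  gx <- vapply(field$columns, `[[`, numeric(1), "x")
  wc <- ec[ec$x %in% gx, ]; wh <- eh[eh$x %in% gx, ]
  expect_true(all(wh$hi - wh$lo <= wc$hi - wc$lo + 1e-9))
})

test_that("PC1 summarization recovers rank-1 structure and is sign-stable", {
  set.seed(17)
  times <- rep(0:5, each = 3)
  profile <- c(0, 0.5, 2, 3, 2.5, 1)
  loading <- rnorm(40)
  mat <- outer(loading, profile[times + 1])
  colnames(mat) <- paste(times, rep(1:3, 6), sep = "_")
  res <- pc1_series(mat)
  expect_equal(res$var_frac, 1, tolerance = 1e-10)
  expect_equal(length(res$series$t), 6)
  expect_equal(res$series$stats$n, rep(3, 6))
  # variance fractions over all components sum to 1 by construction
  noisy <- mat + matrix(rnorm(length(mat), 0, 0.1), nrow(mat))
  colnames(noisy) <- colnames(mat)
  p <- prcomp(t(noisy), center = TRUE)
  expect_equal(sum(p$sdev^2 / sum(p$sdev^2)), 1)
  res_n <- pc1_series(noisy)
  expect_lt(res_n$var_frac, 1)
  # permuting gene order leaves scores unchanged up to global sign
  perm <- sample(nrow(noisy))
  res_p <- pc1_series(noisy[perm, ])
  expect_equal(abs(series_means(res_p$series)), abs(series_means(res_n$series)),
               tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  expect_gt(res_n$loadings[which.max(abs(res_n$loadings))], 0)
  bad <- noisy; bad[1, 1] <- NA
  expect_error(pc1_series(bad), "missing values")
})
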