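test_that("column discretization places midpoints of equal-width intervals", {
  expect_equal(discretize_column(0, 1, 0.5, 4)$midpoints,
               c(0.125, 0.375, 0.625, 0.875))
  expect_equal(discretize_column(3, 3, 1, 5)$midpoints, rep(3, 5))
  expect_equal(discretize_column(-1, 2, 0, 1)$midpoints, 0.5)
  expect_error(discretize_column(0, 1, 0, 0), "at least 1")
})

test_that("directional passes: boundary columns are uniform, columns normalize", {
  f <- fixture3()
  cols <- direct_columns(f$x, f$y, V = 8)
  expect_equal(cols[[1]]$p_left, rep(1 / 8, 8))
  expect_equal(cols[[length(cols)]]$p_right, rep(1 / 8, 8))
  for (cl in cols) {
    expect_equal(sum(cl$p_left), 1, tolerance = 1e-12)
    expect_equal(sum(cl$p_right), 1, tolerance = 1e-12)
    expect_equal(sum(cl$p_joint), 1, tolerance = 1e-12)
    expect_true(all(cl$p_left >= 0 & cl$p_right >= 0 & cl$p_joint >= 0))
  }
})

test_that("an all-plausible configuration yields uniform columns", {
  # two measured points: no pair or triple of insertions is ever constrained
  # enough to break the budget within the envelope
  x <- c(0, 1); y <- c(0, 1)
  b <- path_bounds(x, y)
  gx <- guide_positions(x)
  gb <- bounds_at(b, gx)
  cols <- lapply(seq_along(gx), function(j)
    discretize_column(gb$lo[j], gb$hi[j], gx[j], 6))
  # reference for two points is 0 but any two insertions can alternate;
  # use a large budget to make everything plausible explicitly
  cols <- directional_pass(cols, x, y, "left", reference = 10)
  cols <- directional_pass(cols, x, y, "right", reference = 10)
  cols <- joint_combine(cols, x, y, reference = 10)
  for (cl in cols) {
    expect_equal(cl$p_left, rep(1 / 6, 6))
    expect_equal(cl$p_right, rep(1 / 6, 6))
    expect_equal(cl$p_joint, rep(1 / 6, 6))
  }
})

test_that("a directional pass reproduces explicit summation over the previous column", {
  f <- fixture3()
  cols <- direct_columns(f$x, f$y, V = 8)
  ref <- count_inflexions(f$x, f$y)
  # recompute p_left of column 2 by hand from column 1
  c1 <- cols[[1]]; c2 <- cols[[2]]
  w <- vapply(c2$midpoints, function(a) {
    sum(vapply(seq_along(c1$midpoints), function(bi) {
      xx <- c(f$x, c1$x, c2$x); yy <- c(f$y, c1$midpoints[bi], a)
      ord <- order(xx)
      ok <- ref_count_inflexions(xx[ord], yy[ord]) <= ref
      if (ok) c1$p_left[bi] else 0
    }, numeric(1)))
  }, numeric(1))
  expect_equal(c2$p_left, w / sum(w), tolerance = 1e-12)
})

test_that("joint distributions agree with the enumeration oracle on 3-point fixtures", {
  fixtures <- list(fixture3(),
                   list(x = c(0, 1, 2), y = c(1, 0, 1)),
                   list(x = c(0, 1.5, 2), y = c(0.3, 2, 1.4)))
  for (f in fixtures) {
    cols <- direct_columns(f$x, f$y, V = 8)
    orc <- enumerate_joint_oracle(cols, f$x, f$y)
    tv <- vapply(seq_along(cols), function(j)
      total_variation(cols[[j]]$p_joint, orc[[j]]), numeric(1))
    expect_true(all(tv <= 0.10))
  }
})

test_that("the enumeration oracle counts and filters combinations exactly", {
  # 2 guide columns of 5 midpoints: 25 combinations examined
  x <- c(0, 1); y <- c(0, 1)
  gx <- guide_positions(x)
  cols <- lapply(seq_along(gx), function(j)
    discretize_column(-1, 2, gx[j], 5))
  res <- enumerate_joint_cpp(x, y, gx, lapply(cols, `[[`, "midpoints"),
                             10L, 1e-12, TRUE)
  expect_equal(res$examined, 25)
  expect_equal(res$survivors, 25)  # budget 10: everything passes
  # all-plausible: uniform marginals
  orc <- enumerate_joint_oracle(cols, x, y, reference = 10)
  expect_equal(orc[[1]], rep(1 / 5, 5))
  # collinear measured points concentrate marginals on the bin containing
  # the line (columns spanning line +/- 0.5, odd V so the center bin is on it)
  f <- list(x = 0:2, y = c(0, 1, 2))
  gxc <- guide_positions(f$x)
  colsc <- lapply(seq_along(gxc), function(j)
    discretize_column(gxc[j] - 0.5, gxc[j] + 0.5, gxc[j], 5))
  orcc <- enumerate_joint_oracle(colsc, f$x, f$y)
  for (j in seq_along(orcc))
    expect_gte(orcc[[j]][3], max(orcc[[j]][-3]))
  # cap is enforced with a size report
  big <- lapply(guide_positions(0:4), function(g) discretize_column(0, 1, g, 8))
  expect_error(enumerate_joint_oracle(big, 0:4, c(0, 1, 0, 1, 0), cap = 1e3),
               "cap exceeded")
})

test_that("mirroring the fixture in x swaps the directional passes", {
  f <- list(x = c(0, 1, 2.5), y = c(0.2, 1.6, 1.0))
  colsA <- direct_columns(f$x, f$y, V = 10)
  xm <- sort(-f$x); ym <- rev(f$y)
  colsB <- direct_columns(xm, ym, V = 10)
  G <- length(colsA)
  for (j in seq_len(G)) {
    jm <- G + 1 - j
    expect_equal(colsA[[j]]$p_left, colsB[[jm]]$p_right, tolerance = 1e-9)
    expect_equal(colsA[[j]]$p_right, colsB[[jm]]$p_left, tolerance = 1e-9)
    expect_equal(colsA[[j]]$p_joint, colsB[[jm]]$p_joint, tolerance = 1e-9)
  }
})

test_that("joint_combine requires both passes", {
  f <- fixture3()
  b <- path_bounds(f$x, f$y)
  gx <- guide_positions(f$x)
  gb <- bounds_at(b, gx)
  cols <- lapply(seq_along(gx), function(j)
    discretize_column(gb$lo[j], gb$hi[j], gx[j], 4))
  expect_error(joint_combine(cols, f$x, f$y), "state error")
})
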