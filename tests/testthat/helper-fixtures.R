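# Independent R reimplementation of the inflexion count (sign alternations of
# second differences, zeros transparent); the oracle against the C++ path.
ref_count_inflexions <- function(x, y, tol = 1e-12) {
  g <- diff(y) / diff(x)
  d <- diff(g)
  s <- sign(d)
  s[abs(d) <= tol] <- 0
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

# Brute-force plausible interval for a single insertion: exhaustive y-scan.
ref_insertion_interval <- function(x, y, at, dy = 1e-4, clip = 1) {
  ref <- ref_count_inflexions(x, y)
  R <- diff(range(y))
  ys <- seq(min(y) - clip * R, max(y) + clip * R, by = dy)
  ok <- vapply(ys, function(yy) {
    ord <- order(c(x, at))
    ref_count_inflexions(c(x, at)[ord], c(y, yy)[ord]) <= ref
  }, logical(1))
  range(ys[ok])
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Shared small fixture: 3 measured points, one inflexion, non-symmetric.
fixture3 <- function() list(x = c(0, 1, 2), y = c(0, 1, 0.2))

# Full direct-method column set for a zero-error path.
direct_columns <- function(x, y, V = 8, acceptance = "le") {
  b <- path_bounds(x, y, acceptance = acceptance)
  gx <- guide_positions(x)
  gb <- bounds_at(b, gx)
  cols <- lapply(seq_along(gx), function(j)
    discretize_column(gb$lo[j], gb$hi[j], gx[j], V))
  cols <- directional_pass(cols, x, y, "left", acceptance = acceptance)
  cols <- directional_pass(cols, x, y, "right", acceptance = acceptance)
  joint_combine(cols, x, y, acceptance = acceptance)
}

# Series with replicate noise around a fixed shape, reproducibly.
noisy_series <- function(y, noise_sd = 0.1, n_reps = 3, seed = 1,
                         conf = 0.99) {
  set.seed(seed)
  measurement_series(seq_along(y) - 1,
                     lapply(y, function(v) v + rnorm(n_reps, 0, noise_sd)),
                     conf = conf)
}
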