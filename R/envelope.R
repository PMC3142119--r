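#' Pointwise plausible-interpolation bounds for a zero-error path
#'
#' At an interior position `at`, the plausible interval is the set of values
#' `y` such that inserting the single point `(at, y)` into the measured path
#' keeps the inflexion count within the reference budget. Candidate values
#' are searched inside the clipped window
#' `[min(y) - clip_factor * R, max(y) + clip_factor * R]` where `R` is the
#' measured y-range; the window edge is returned when every value in the
#' window is plausible (with very few points a single insertion can be
#' unconstrained). The interval edges are located by a grid scan followed by
#' bisection to `tol_y`; the value of the path itself at `at` is always
#' plausible and anchors the search.
#'
#' @param x,y Measured path (strictly increasing `x`).
#' @param at Numeric vector of evaluation positions inside `[min(x), max(x)]`.
#'   Positions equal to a measured `x` return that measurement's value for
#'   both edges.
#' @param reference Inflexion budget; defaults to the path's own count.
#' @param clip_factor Half-width of the search window in units of the
#'   measured y-range (default 1).
#' @param grid_n Number of grid points scanned before bisection.
#' @param tol_y Bisection tolerance on the bound values.
#' @param acceptance Plausibility rule, see [is_plausible()].
#' @param tol Zero-gradient-change tolerance, see [count_inflexions()].
#' @return Data frame with columns `x`, `lo`, `hi`.
#' @examples
#' pointwise_bounds(0:3, c(0, 1, 2, 3), at = 0.5)   # collinear: collapses
#' @export
pointwise_bounds <- function(x, y, at, reference = NULL, clip_factor = 1,
                             grid_n = 64, tol_y = 1e-8,
                             acceptance = c("le", "eq"), tol = 1e-12) {
  acceptance <- match.arg(acceptance)
  if (any(diff(x) <= 0)) stop("invalid path: x must be strictly increasing")
  if (any(at < min(x) | at > max(x)))
    stop("out of range: bounds are defined only on the measured range")
  if (is.null(reference)) reference <- count_inflexions(x, y, tol)
  R <- diff(range(y))
  win_lo <- min(y) - clip_factor * R
  win_hi <- max(y) + clip_factor * R
  out <- vapply(at, function(xi) {
    hit <- which(abs(x - xi) <= .Machine$double.eps * 4 * max(1, abs(xi)))
    if (length(hit)) return(rep(y[hit[1]], 2))
    anchor <- stats::approx(x, y, xout = xi)$y
    pointwise_bounds_cpp(x, y, xi, reference, win_lo, win_hi, anchor,
                         as.integer(grid_n), tol_y, tol,
                         acceptance == "le")
  }, numeric(2))
  data.frame(x = at, lo = out[1, ], hi = out[2, ])
}

#' Plausible bounds of the mean path as an evaluable bounds function
#'
#' @inheritParams pointwise_bounds
#' @param at Positions at which bounds are computed exactly; defaults to the
#'   measured positions, their guide points, and an even grid of `n_grid`
#'   points. Between these vertices the bounds function interpolates
#'   linearly.
#' @param n_grid Number of additional evenly spaced evaluation points.
#' @return An object of class `iq_bounds` (fields `x`, `lo`, `hi`),
#'   evaluable with [bounds_at()].
#' @export
path_bounds <- function(x, y, at = NULL, reference = NULL, clip_factor = 1,
                        n_grid = 101, grid_n = 64, tol_y = 1e-8,
                        acceptance = c("le", "eq"), tol = 1e-12) {
  acceptance <- match.arg(acceptance)
  if (is.null(at))
    at <- sort(unique(c(x, guide_positions(x),
                        seq(min(x), max(x), length.out = n_grid))))
  b <- pointwise_bounds(x, y, at, reference = reference,
                        clip_factor = clip_factor, grid_n = grid_n,
                        tol_y = tol_y, acceptance = acceptance, tol = tol)
  structure(list(x = b$x, lo = b$lo, hi = b$hi), class = "iq_bounds")
}

#' Evaluate a bounds function
#' @param bounds An `iq_bounds` object.
#' @param x Positions inside the bounds' range.
#' @return Data frame with columns `x`, `lo`, `hi` (linear interpolation
#'   between computed vertices).
#' @export
bounds_at <- function(bounds, x) {
  if (any(x < min(bounds$x) | x > max(bounds$x)))
    stop("out of range: bounds are defined only on the measured range")
  data.frame(x = x,
             lo = stats::approx(bounds$x, bounds$lo, xout = x)$y,
             hi = stats::approx(bounds$x, bounds$hi, xout = x)$y)
}

#' @export
print.iq_bounds <- function(x, ...) {
  cat(sprintf("<iq_bounds> %d vertices on [%g, %g]\n",
              length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' Extended plausible bounds under measurement error (corner union)
#'
#' Measurement error widens the plausible bounds: with `n` measured points,
#' each set to either its lower or upper confidence limit, there are `2^n`
#' corner assignments, each implying its own measured shape (and its own
#' reference inflexion count). The extended bounds are the union (pointwise
#' min of lower edges, max of upper edges) of the pointwise bounds of every
#' corner path, plus the all-means path so the union always contains the
#' zero-error bounds. At a measured position the union reduces to the span
#' of the corner values there, i.e. the measurement's confidence interval.
#'
#' For `n > corner_cap` exact enumeration is replaced by `n_corner_sample`
#' random corner assignments (plus the all-means path); a message reports
#' the subsampling.
#'
#' @param series An [measurement_series()] whose measurements all carry a
#'   confidence interval.
#' @param at Evaluation positions; defaults as in [path_bounds()].
#' @inheritParams path_bounds
#' @param corner_cap Largest `n` for exact `2^n` enumeration (default 12).
#' @param n_corner_sample Number of random corners beyond the cap.
#' @return An `iq_bounds` object.
#' @export
corner_union_bounds <- function(series, at = NULL, clip_factor = 1,
                                n_grid = 101, grid_n = 64, tol_y = 1e-8,
                                acceptance = c("le", "eq"), tol = 1e-12,
                                corner_cap = 12, n_corner_sample = 4096) {
  acceptance <- match.arg(acceptance)
  stopifnot(inherits(series, "iq_series"))
  st <- series$stats
  if (anyNA(st$ci_lo) || anyNA(st$ci_hi))
    stop("configuration error: every measurement needs a confidence interval")
  t <- series$t
  n <- length(t)
  if (is.null(at))
    at <- sort(unique(c(t, guide_positions(t),
                        seq(min(t), max(t), length.out = n_grid))))
  if (n <= corner_cap) {
    corners <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  } else {
    message(sprintf(
      "corner union: n = %d exceeds cap %d; using %d random corners + means",
      n, corner_cap, n_corner_sample))
    corners <- matrix(stats::rbinom(n_corner_sample * n, 1, 0.5),
                      ncol = n)
  }
  lo <- rep(Inf, length(at))
  hi <- rep(-Inf, length(at))
  eval_corner <- function(yc) {
    b <- pointwise_bounds(t, yc, at, reference = NULL,
                          clip_factor = clip_factor, grid_n = grid_n,
                          tol_y = tol_y, acceptance = acceptance, tol = tol)
    lo <<- pmin(lo, b$lo)
    hi <<- pmax(hi, b$hi)
  }
  for (k in seq_len(nrow(corners)))
    eval_corner(ifelse(corners[k, ] == 1, st$ci_hi, st$ci_lo))
  eval_corner(st$mean)
  structure(list(x = at, lo = lo, hi = hi), class = "iq_bounds")
}
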