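#' Count inflexion points of a piecewise-linear path
#'
#' An inflexion point is counted for every adjacent sign alternation in the
#' sequence of gradient changes (second differences) of the piecewise-linear
#' path through the ordered points. Gradient changes whose magnitude does not
#' exceed `tol` are treated as transparent: a flat kink is neither a positive
#' nor a negative curvature event and is skipped when scanning for
#' alternations. Paths with fewer than three points, collinear paths, and
#' paths whose gradient changes never alternate in sign all count zero.
#'
#' Biologically, each alternation stands for a regulatory event (a switch
#' between acceleration and deceleration of expression) that the measurements
#' force upon any curve through them.
#'
#' @param x Numeric vector of strictly increasing positions (time or
#'   treatment level).
#' @param y Numeric vector of values, same length as `x`.
#' @param tol Magnitude below which a gradient change is considered zero.
#' @return Non-negative integer count of sign alternations.
#' @examples
#' count_inflexions(0:2, c(0, 1, 2))                  # collinear: 0
#' count_inflexions(0:4, c(0, 2, 0, 2, 0))            # zig-zag: 2
#' @export
count_inflexions <- function(x, y, tol = 1e-12) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (anyNA(x) || anyNA(y)) stop("invalid path: NA coordinates")
  count_inflexions_cpp(as.double(x), as.double(y), tol)
}

#' Test whether a path respects an inflexion budget
#'
#' A path is plausible when its inflexion count does not exceed
#' `reference` (rule `"le"`, the default) or equals it exactly (rule
#' `"eq"`). The reference is normally the inflexion count of the measured
#' points alone, so plausibility encodes the parsimony constraint that no
#' unobserved regulatory event is postulated between measurements.
#'
#' @inheritParams count_inflexions
#' @param reference Non-negative integer inflexion budget.
#' @param acceptance `"le"` (default) or `"eq"`.
#' @return Logical scalar.
#' @export
is_plausible <- function(x, y, reference, acceptance = c("le", "eq"),
                         tol = 1e-12) {
  acceptance <- match.arg(acceptance)
  n <- count_inflexions(x, y, tol)
  if (acceptance == "le") n <= reference else n == reference
}

#' Guide-point positions for a measured grid
#'
#' Two guide points per measured interval, at the interior trisection points
#' (each interval is split into exactly three sub-intervals).
#'
#' @param t Strictly increasing numeric vector of measured positions.
#' @return Numeric vector of `2 * (length(t) - 1)` guide positions.
#' @export
guide_positions <- function(t) {
  stopifnot(length(t) >= 2)
  if (any(diff(t) <= 0)) stop("invalid path: x must be strictly increasing")
  as.vector(vapply(seq_len(length(t) - 1L), function(i) {
    t[i] + diff(t[c(i, i + 1L)]) * c(1, 2) / 3
  }, numeric(2)))
}

# internal: merge measured path with extra points, sorted by x
merge_path <- function(x, y, x_extra, y_extra) {
  ord <- order(c(x, x_extra))
  list(x = c(x, x_extra)[ord], y = c(y, y_extra)[ord])
}
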