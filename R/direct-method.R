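#' Discretize an envelope span into a guide column
#'
#' The envelope width at a guide position is divided into `V` evenly spaced
#' intervals, each represented by its midpoint
#' `lo + (i + 0.5) * (hi - lo) / V`. The column's three probability vectors
#' (left-conditional, right-conditional, joint) start unset.
#'
#' @param lo,hi Envelope bounds at the column (`lo <= hi`; equal for a
#'   degenerate envelope).
#' @param x Column position.
#' @param V Number of intervals (>= 1).
#' @return A list with fields `x`, `lo`, `hi`, `midpoints`, `p_left`,
#'   `p_right`, `p_joint`.
#' @export
discretize_column <- function(lo, hi, x, V) {
  if (V < 1) stop("V must be at least 1")
  if (hi < lo) stop("invalid column: hi < lo")
  V <- as.integer(V)
  list(x = x, lo = lo, hi = hi,
       midpoints = lo + (seq_len(V) - 0.5) * (hi - lo) / V,
       p_left = NULL, p_right = NULL, p_joint = NULL)
}

# internal: normalize a weight vector. An all-zero column means the grid
# midpoints all missed the (nonempty but thin) plausible band - the band
# always contains the path's own interpolated value - so mass is placed on
# the bin nearest that value rather than spread uniformly, and a warning is
# logged.
normalize_or_fallback <- function(w, what, x, path_y, midpoints) {
  s <- sum(w)
  if (s <= 0) {
    warning(sprintf(
      "all-zero %s weights at column x = %g; falling back to the on-path bin",
      what, x))
    out <- numeric(length(w))
    out[which.min(abs(midpoints - path_y))] <- 1
    return(out)
  }
  w / s
}

#' Directional conditional-probability pass over guide columns
#'
#' Computes, for every guide column, the likelihood of each midpoint
#' conditional on the points to one side. The starting boundary column (the
#' leftmost for the left pass, the rightmost for the right pass) is uniform,
#' since nothing constrains it from that side. Sweeping away from it, each
#' midpoint `a` of the current column accumulates the probability of every
#' midpoint `b` of the previously processed adjacent column for which the
#' path through all measured points plus `(x_cur, a)` and `(x_prev, b)`
#' stays within the inflexion budget; each column is then normalized to
#' sum one.
#'
#' @param columns List of guide columns from [discretize_column()], ordered
#'   by increasing `x`.
#' @param x,y Measured path (one representative value per measurement).
#' @param direction `"left"` fills `p_left` (conditional on points to the
#'   left), `"right"` fills `p_right`.
#' @param reference Inflexion budget; defaults to the measured path's count.
#' @inheritParams is_plausible
#' @return The column list with the corresponding probability vectors filled.
#' @export
directional_pass <- function(columns, x, y, direction = c("left", "right"),
                             reference = NULL, acceptance = c("le", "eq"),
                             tol = 1e-12) {
  direction <- match.arg(direction)
  acceptance <- match.arg(acceptance)
  if (is.null(reference)) reference <- count_inflexions(x, y, tol)
  le <- acceptance == "le"
  G <- length(columns)
  ord <- if (direction == "left") seq_len(G) else rev(seq_len(G))
  slot <- paste0("p_", direction)
  p_prev <- rep(1 / length(columns[[ord[1]]]$midpoints),
                length(columns[[ord[1]]]$midpoints))
  columns[[ord[1]]][[slot]] <- p_prev
  for (k in seq_len(G)[-1]) {
    j <- ord[k]; jp <- ord[k - 1]
    w <- pass_weights_cpp(x, y,
                          columns[[j]]$x, columns[[j]]$midpoints,
                          columns[[jp]]$x, columns[[jp]]$midpoints,
                          p_prev, reference, tol, le)
    p_prev <- normalize_or_fallback(w, direction, columns[[j]]$x,
                                    stats::approx(x, y,
                                                  xout = columns[[j]]$x)$y,
                                    columns[[j]]$midpoints)
    columns[[j]][[slot]] <- p_prev
  }
  columns
}

#' Combine the directional passes into joint column distributions
#'
#' The first guide column's joint distribution is its right-conditional one
#' (there is nothing further left to condition on) and the last column's is
#' its left-conditional one. For an interior column `j`, the joint weight of
#' midpoint `b` sums, over midpoints `a` of column `j - 1` and `c` of column
#' `j + 1`, the product `p_left(a) * p_right(c)` whenever the path through
#' the measured points plus the three guide points stays within the
#' inflexion budget; columns are normalized afterwards.
#'
#' @inheritParams directional_pass
#' @return The column list with `p_joint` filled.
#' @export
joint_combine <- function(columns, x, y, reference = NULL,
                          acceptance = c("le", "eq"), tol = 1e-12) {
  acceptance <- match.arg(acceptance)
  if (is.null(reference)) reference <- count_inflexions(x, y, tol)
  le <- acceptance == "le"
  G <- length(columns)
  if (is.null(columns[[1]]$p_right) || is.null(columns[[G]]$p_left))
    stop("state error: run both directional passes before joint_combine")
  columns[[1]]$p_joint <- columns[[1]]$p_right
  columns[[G]]$p_joint <- columns[[G]]$p_left
  if (G > 2) {
    for (j in seq(2, G - 1)) {
      w <- joint_weights_cpp(x, y,
                             columns[[j - 1]]$x, columns[[j - 1]]$midpoints,
                             columns[[j - 1]]$p_left,
                             columns[[j]]$x, columns[[j]]$midpoints,
                             columns[[j + 1]]$x, columns[[j + 1]]$midpoints,
                             columns[[j + 1]]$p_right,
                             reference, tol, le)
      columns[[j]]$p_joint <- normalize_or_fallback(
        w, "joint", columns[[j]]$x,
        stats::approx(x, y, xout = columns[[j]]$x)$y,
        columns[[j]]$midpoints)
    }
  }
  columns
}

#' Exact per-column marginals by full enumeration (test oracle)
#'
#' Enumerates every combination of one midpoint per guide column, keeps the
#' combinations whose full merged path stays within the inflexion budget,
#' and returns the normalized per-column marginals under a uniform prior
#' over combinations. Exponential in the number of columns; intended as an
#' independent oracle for the dynamic-programming and Monte Carlo routes on
#' small fixtures.
#'
#' @inheritParams directional_pass
#' @param cap Refuse to enumerate more than this many combinations.
#' @return List of normalized marginal probability vectors, one per column.
#' @export
enumerate_joint_oracle <- function(columns, x, y, reference = NULL,
                                   acceptance = c("le", "eq"), tol = 1e-12,
                                   cap = 1e6) {
  acceptance <- match.arg(acceptance)
  if (is.null(reference)) reference <- count_inflexions(x, y, tol)
  sizes <- vapply(columns, function(cl) length(cl$midpoints), integer(1))
  total <- prod(as.double(sizes))
  if (total > cap)
    stop(sprintf("enumeration cap exceeded: %.3g combinations > cap %.3g",
                 total, cap))
  res <- enumerate_joint_cpp(x, y,
                             vapply(columns, `[[`, numeric(1), "x"),
                             lapply(columns, `[[`, "midpoints"),
                             reference, tol, acceptance == "le")
  if (res$survivors == 0)
    stop("degenerate constraint: no plausible combination survives")
  lapply(res$counts, function(ct) ct / sum(ct))
}
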