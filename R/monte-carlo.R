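#' Acceptance-rejection sampling of plausible guide configurations
#'
#' Draws guide configurations by sampling every guide point's value
#' independently and uniformly within the envelope bounds at its position,
#' accepting a configuration iff the merged path (measured points plus all
#' guide points) stays within the inflexion budget, until `n_accept`
#' configurations have been accepted. Randomness comes from R's global RNG,
#' so `set.seed()` (or the `seed` argument) makes the output reproducible.
#'
#' @param x,y Measured path (one representative value per measurement).
#' @param bounds An `iq_bounds` object covering the measured range.
#' @param n_accept Number of accepted configurations required.
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @param reference Inflexion budget; defaults to the measured path's count.
#' @param max_attempts Attempt cap; exceeded caps raise a sampling-exhausted
#'   error with diagnostics.
#' @inheritParams is_plausible
#' @return An object of class `iq_mc`: list with `guide_x`, `lo`, `hi`
#'   (bounds at the guide positions), `samples` (matrix `n_accept` x
#'   `length(guide_x)` of accepted guide values), `attempts`, `reference`.
#' @export
sample_plausible_paths <- function(x, y, bounds, n_accept, seed = NULL,
                                   reference = NULL, max_attempts = 1e7,
                                   acceptance = c("le", "eq"), tol = 1e-12) {
  acceptance <- match.arg(acceptance)
  stopifnot(n_accept >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) reference <- count_inflexions(x, y, tol)
  gx <- guide_positions(x)
  b <- bounds_at(bounds, gx)
  res <- mc_sample_cpp(x, y, gx, b$lo, b$hi, as.integer(n_accept),
                       reference, tol, acceptance == "le", max_attempts)
  structure(list(guide_x = gx, lo = b$lo, hi = b$hi,
                 samples = res$samples, attempts = res$attempts,
                 reference = reference),
            class = "iq_mc")
}

#' @export
print.iq_mc <- function(x, ...) {
  cat(sprintf(
    "<iq_mc> %d accepted configurations over %d guide columns (%.0f attempts, rate %.3g)\n",
    nrow(x$samples), length(x$guide_x), x$attempts,
    nrow(x$samples) / x$attempts))
  invisible(x)
}

#' Empirical column distributions of accepted configurations
#'
#' For each guide column, a normalized histogram of the accepted guide
#' values over `bins` equal-width intervals of the envelope span at that
#' column. The bin midpoints coincide with the direct method's column
#' midpoints for `V = bins`, so the two routes are directly comparable as
#' piecewise-constant densities.
#'
#' @param mc An `iq_mc` object (all configurations share their guide
#'   positions by construction).
#' @param bins Number of equal-width bins (default 40).
#' @return List of guide columns (as in [discretize_column()]) with
#'   `p_joint` set to the empirical histogram.
#' @export
mc_column_distributions <- function(mc, bins = 40) {
  stopifnot(inherits(mc, "iq_mc"))
  if (nrow(mc$samples) == 0) stop("no accepted configurations")
  lapply(seq_along(mc$guide_x), function(j) {
    col <- discretize_column(mc$lo[j], mc$hi[j], mc$guide_x[j], bins)
    w <- col$hi - col$lo
    ys <- mc$samples[, j]
    idx <- if (w <= 0) rep(1L, length(ys)) else
      pmin(bins, pmax(1L, floor((ys - col$lo) / w * bins) + 1L))
    col$p_joint <- tabulate(idx, nbins = bins) / length(ys)
    col
  })
}
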