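#' Estimate the likelihood field of plausible interpolations for a series
#'
#' The full pipeline for one measurement series:
#'
#' 1. Plausible-interpolation bounds are computed - from the mean path alone
#'    (`error = "none"`), or as the union over confidence-limit corner
#'    assignments (`error = "lhs"`, the default; see
#'    [corner_union_bounds()]).
#' 2. Two guide columns per measured interval (at the trisection points) are
#'    discretized into `V` equal-width intervals of the envelope span.
#' 3. Column distributions are computed by the direct dynamic-programming
#'    method ([directional_pass()] + [joint_combine()]) or by
#'    acceptance-rejection Monte Carlo ([sample_plausible_paths()]).
#' 4. Under `error = "lhs"`, steps 2-3 run once per Latin Hypercube
#'    realization of the measurements (each with its own reference inflexion
#'    count) and the per-realization fields are averaged with
#'    [aggregate_fields()].
#'
#' @param series An [measurement_series()].
#' @param method `"direct"` (dynamic programming, default) or `"mc"`.
#' @param error `"lhs"` (propagate replicate-based measurement error,
#'   default) or `"none"` (treat the means as exact).
#' @param V Number of grid intervals per guide column (default 40).
#' @param m Number of equal-probability CI sub-intervals per measurement
#'   (default 20, so that every Latin Hypercube cycle has its own stratum).
#' @param cycles Number of Latin Hypercube realizations (default 20).
#' @param clip_factor Envelope search-window factor, see
#'   [pointwise_bounds()].
#' @param n_accept Total accepted Monte Carlo configurations
#'   (`method = "mc"`), split evenly across realizations.
#' @param seed Optional integer; seeds all randomness in the pipeline.
#' @param max_attempts Monte Carlo attempt cap.
#' @inheritParams is_plausible
#' @param n_grid,grid_n,tol_y Bounds evaluation controls, see
#'   [path_bounds()].
#' @return An object of class `iq_field`: list with `series`, `reference`
#'   (mean-path inflexion count), `bounds` (`iq_bounds`), `columns` (guide
#'   columns with probability vectors), `measured_columns` (per measured
#'   point: position, representative midpoints and their uniform weights)
#'   and `params`.
#' @examples
#' s <- measurement_series(0:3, list(c(2, 2.1), c(1, 1.1), c(2, 2.2), c(1, 0.9)))
#' f <- estimate_field(s, V = 10, m = 4, cycles = 4, seed = 1)
#' @export
estimate_field <- function(series, method = c("direct", "mc"),
                           error = c("lhs", "none"),
                           V = 40, m = 20, cycles = 20,
                           clip_factor = 1, n_accept = 10000, seed = NULL,
                           max_attempts = 1e7,
                           acceptance = c("le", "eq"), tol = 1e-12,
                           n_grid = 101, grid_n = 64, tol_y = 1e-8) {
  method <- match.arg(method)
  error <- match.arg(error)
  acceptance <- match.arg(acceptance)
  stopifnot(inherits(series, "iq_series"))
  if (!is.null(seed)) set.seed(seed)
  t <- series$t
  means <- series_means(series)
  reference_mean <- count_inflexions(t, means, tol)
  gx <- guide_positions(t)

  if (error == "none") {
    bounds <- path_bounds(t, means, reference = reference_mean,
                          clip_factor = clip_factor, n_grid = n_grid,
                          grid_n = grid_n, tol_y = tol_y,
                          acceptance = acceptance, tol = tol)
    realizations <- list(list(values = means, reference = reference_mean))
    measured_columns <- lapply(seq_along(t), function(i)
      list(x = t[i], midpoints = means[i], p = 1))
  } else {
    bounds <- corner_union_bounds(series, clip_factor = clip_factor,
                                  n_grid = n_grid, grid_n = grid_n,
                                  tol_y = tol_y, acceptance = acceptance,
                                  tol = tol)
    realizations <- lhs_realizations(series, m = m, cycles = cycles,
                                     tol = tol)
    mids <- attr(realizations, "midpoints")
    measured_columns <- lapply(seq_along(t), function(i)
      list(x = t[i], midpoints = mids[[i]], p = rep(1 / m, m)))
  }

  gb <- bounds_at(bounds, gx)
  template <- lapply(seq_along(gx), function(j)
    discretize_column(gb$lo[j], gb$hi[j], gx[j], V))

  build_one <- function(realization, n_acc) {
    if (method == "direct") {
      cols <- directional_pass(template, t, realization$values, "left",
                               reference = realization$reference,
                               acceptance = acceptance, tol = tol)
      cols <- directional_pass(cols, t, realization$values, "right",
                               reference = realization$reference,
                               acceptance = acceptance, tol = tol)
      joint_combine(cols, t, realization$values,
                    reference = realization$reference,
                    acceptance = acceptance, tol = tol)
    } else {
      mc <- sample_plausible_paths(t, realization$values, bounds,
                                   n_accept = n_acc,
                                   reference = realization$reference,
                                   max_attempts = max_attempts,
                                   acceptance = acceptance, tol = tol)
      mc_column_distributions(mc, bins = V)
    }
  }

  n_per <- ceiling(n_accept / length(realizations))
  n_fallback <- 0L
  fields <- lapply(realizations, function(r) {
    cols <- withCallingHandlers(
      build_one(r, n_per),
      warning = function(w) {
        if (grepl("all-zero", conditionMessage(w))) {
          n_fallback <<- n_fallback + 1L
          invokeRestart("muffleWarning")
        }
      })
    structure(list(series = series, reference = reference_mean,
                   bounds = bounds, columns = cols,
                   measured_columns = measured_columns),
              class = "iq_field")
  })
  if (n_fallback > 0)
    warning(sprintf(
      "%d column distribution(s) across %d realization(s) had no plausible pairing at grid resolution V = %d and fell back to the on-path bin",
      n_fallback, length(realizations), V))
  out <- if (length(fields) == 1) fields[[1]] else aggregate_fields(fields)
  out$params <- list(method = method, error = error, V = V, m = m,
                     cycles = if (error == "lhs") cycles else NA_integer_,
                     conf = series$conf, clip_factor = clip_factor,
                     acceptance = acceptance, tol = tol,
                     n_accept = if (method == "mc") n_accept else NA_integer_,
                     seed = seed)
  out
}

#' @export
print.iq_field <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<iq_field '%s'> %d measured points, %d guide columns (V = %d)\n",
    x$series$id, length(x$series$t), length(x$columns), p$V))
  cat(sprintf("  method = %s, error = %s, reference inflexions = %d\n",
              p$method, p$error, x$reference))
  invisible(x)
}

#' Flatten a likelihood field into a tidy table
#'
#' One row per (column, midpoint): `series_id`, `column_x`, `column_kind`
#' (`"measured"` or `"guide"`), `midpoint_y`, `p_left`, `p_right`,
#' `p_joint`. Measured columns carry their representative midpoints with
#' their (uniform) weights in all three probability slots.
#'
#' @param field An `iq_field`.
#' @return A data frame.
#' @export
field_table <- function(field) {
  stopifnot(inherits(field, "iq_field"))
  num_or_na <- function(v, len) if (is.null(v)) rep(NA_real_, len) else v
  rows <- c(
    lapply(field$measured_columns, function(mc) {
      k <- length(mc$midpoints)
      data.frame(series_id = field$series$id, column_x = mc$x,
                 column_kind = "measured", midpoint_y = mc$midpoints,
                 p_left = mc$p, p_right = mc$p, p_joint = mc$p)
    }),
    lapply(field$columns, function(cl) {
      k <- length(cl$midpoints)
      data.frame(series_id = field$series$id, column_x = cl$x,
                 column_kind = "guide", midpoint_y = cl$midpoints,
                 p_left = num_or_na(cl$p_left, k),
                 p_right = num_or_na(cl$p_right, k),
                 p_joint = num_or_na(cl$p_joint, k))
    }))
  out <- do.call(rbind, rows)
  out[order(out$column_x, out$midpoint_y), , drop = FALSE]
}
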