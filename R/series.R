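#' Construct a measurement series from replicate values
#'
#' A measurement series holds, for one gene (or one summarized component),
#' the replicate values observed at each time point or treatment level
#' together with their t-based confidence intervals. It is the basic input
#' to every downstream computation.
#'
#' @param t Strictly increasing numeric vector of times / treatment levels.
#' @param values List of numeric replicate vectors, one per time point
#'   (replicate counts may differ between time points), or a numeric matrix
#'   with one row per time point.
#' @param id Series identifier.
#' @param conf Confidence level used for the measurement intervals
#'   (default 0.99).
#' @param sd Optional numeric vector of externally supplied standard
#'   deviations, required wherever a time point has a single replicate.
#' @return An object of class `iq_series`: a list with elements `id`, `t`,
#'   `values`, `conf` and `stats` (a data frame with one row per time point:
#'   `t`, `mean`, `sd`, `n`, `df`, `ci_lo`, `ci_hi`).
#' @examples
#' s <- measurement_series(0:3, list(c(1, 2), c(4, 5), c(3, 3.5), c(1, 2)))
#' series_means(s)
#' @export
measurement_series <- function(t, values, id = "series", conf = 0.99,
                               sd = NULL) {
  stopifnot(is.numeric(t), length(t) >= 1)
  if (any(diff(t) <= 0)) stop("invalid series: t must be strictly increasing")
  if (is.matrix(values)) values <- split(values, row(values))
  stopifnot(length(values) == length(t))
  values <- lapply(values, function(v) as.double(v[!is.na(v)]))
  stats <- do.call(rbind, lapply(seq_along(t), function(i) {
    s <- summarize_replicates(values[[i]], conf = conf,
                              sd = if (!is.null(sd)) sd[i] else NULL)
    data.frame(t = t[i], mean = s$mean, sd = s$sd, n = s$n, df = s$df,
               ci_lo = s$ci_lo, ci_hi = s$ci_hi)
  }))
  rownames(stats) <- NULL
  structure(list(id = id, t = as.double(t), values = values,
                 conf = conf, stats = stats),
            class = "iq_series")
}

#' @export
print.iq_series <- function(x, ...) {
  cat(sprintf("<iq_series '%s'> %d time points, %s replicates, %.0f%% CI\n",
              x$id, length(x$t),
              paste(range(x$stats$n), collapse = "-"), 100 * x$conf))
  print(x$stats, ...)
  invisible(x)
}

#' Replicate means of a series
#' @param series An `iq_series`.
#' @return Numeric vector of per-time-point means.
#' @export
series_means <- function(series) series$stats$mean

#' Summarize replicate values into a t-based confidence interval
#'
#' The confidence interval for the true value is
#' `mean +/- qt((1 + conf) / 2, n - 1) * sd / sqrt(n)`, the standard
#' t-interval for the mean of `n` replicates.
#'
#' @param values Numeric vector of replicate values (length >= 2, or length 1
#'   with `sd` supplied).
#' @param conf Confidence level in `[0, 1)`.
#' @param sd Externally supplied standard deviation; required for a single
#'   replicate, in which case a normal (infinite-df) interval is used.
#' @return List with `mean`, `sd`, `n`, `df`, `ci_lo`, `ci_hi`, `conf`.
#' @export
summarize_replicates <- function(values, conf = 0.99, sd = NULL) {
  values <- as.double(values)
  n <- length(values)
  if (n < 1) stop("insufficient replicates: no values")
  if (n == 1 && is.null(sd))
    stop("insufficient replicates: a single value needs an external sd")
  m <- mean(values)
  if (is.null(sd)) {
    s <- stats::sd(values)
    df <- n - 1
  } else {
    s <- as.double(sd)
    df <- if (n >= 2) n - 1 else Inf
  }
  stopifnot(conf >= 0, conf < 1)
  half <- if (conf == 0 || s == 0) 0 else
    stats::qt((1 + conf) / 2, df) * s / sqrt(n)
  list(mean = m, sd = s, n = n, df = df,
       ci_lo = m - half, ci_hi = m + half, conf = conf)
}

#' Subset a series by time-point index
#' @param series An `iq_series`.
#' @param idx Integer indices of time points to keep (in order).
#' @return A new `iq_series`.
#' @export
series_subset <- function(series, idx) {
  measurement_series(series$t[idx], series$values[idx],
                     id = series$id, conf = series$conf)
}
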