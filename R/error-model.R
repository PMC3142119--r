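#' Equal-probability representative midpoints of a measurement's CI
#'
#' The confidence interval of a measurement is divided into `m`
#' sub-intervals of variable width but equal probability under the t-based
#' sampling distribution of the mean (`mean + T * sd / sqrt(n)`, `T` a
#' t-variable with the replicate degrees of freedom). The sub-interval
#' boundaries are the quantiles of that distribution at cumulative
#' probabilities `(1 - conf) / 2 + j * conf / m`, `j = 0..m`, computed with
#' the inverse t-distribution; each sub-interval is represented by the
#' arithmetic midpoint of its two boundaries.
#'
#' @param measurement A list with fields `mean`, `sd`, `n`, `df`, `conf`
#'   (e.g. one row of an `iq_series`' `stats`, or the result of
#'   [summarize_replicates()]).
#' @param m Number of sub-intervals (>= 1).
#' @return Numeric vector of `m` midpoints, strictly increasing (all equal
#'   to the mean for a degenerate CI).
#' @examples
#' ms <- summarize_replicates(c(1, 2, 3), conf = 0.99)
#' equal_probability_midpoints(ms, 4)
#' @export
equal_probability_midpoints <- function(measurement, m) {
  if (m < 1) stop("m must be at least 1")
  m <- as.integer(m)
  mu <- measurement$mean
  s <- measurement$sd
  n <- measurement$n
  df <- measurement$df
  conf <- measurement$conf
  if (s == 0 || conf == 0) return(rep(mu, m))
  probs <- (1 - conf) / 2 + (0:m) * conf / m
  bounds <- mu + stats::qt(probs, df) * s / sqrt(n)
  (bounds[-1] + bounds[-(m + 1)]) / 2
}

#' Latin Hypercube realizations of a measurement series
#'
#' Stratified sampling of the plausible true values of every measurement:
#' each measurement's CI is split into `m` equal-probability sub-intervals
#' (see [equal_probability_midpoints()]); the midpoint indices of each
#' measurement are permuted independently (Fisher-Yates, via R's
#' [sample.int()]); realization `k` then takes the `k`-th-ranked permuted
#' midpoint from every measurement, for `k = 1..cycles`. With
#' `cycles = m` every midpoint of every measurement is used exactly once.
#' Each realization carries its own reference inflexion count, since
#' different realizations imply different measured shapes.
#'
#' @param series An [measurement_series()].
#' @param m Number of equal-probability sub-intervals per measurement.
#' @param cycles Number of realizations (must not exceed `m`; default 20).
#' @param seed Optional integer seed.
#' @inheritParams is_plausible
#' @return List of `cycles` realizations; each is a list with `values`
#'   (one representative per measurement) and `reference` (its inflexion
#'   count). The per-measurement midpoints are attached as attribute
#'   `"midpoints"`.
#' @export
lhs_realizations <- function(series, m = 20, cycles = 20, seed = NULL,
                             tol = 1e-12) {
  stopifnot(inherits(series, "iq_series"))
  if (cycles > m)
    stop(sprintf("cycles (%d) cannot exceed the number of midpoints m (%d)",
                 cycles, m))
  if (!is.null(seed)) set.seed(seed)
  st <- series$stats
  mids <- lapply(seq_len(nrow(st)), function(i)
    equal_probability_midpoints(
      list(mean = st$mean[i], sd = st$sd[i], n = st$n[i], df = st$df[i],
           conf = series$conf), m))
  perms <- lapply(seq_len(nrow(st)), function(i) sample.int(m))
  out <- lapply(seq_len(cycles), function(k) {
    vals <- vapply(seq_along(mids), function(i) mids[[i]][perms[[i]][k]],
                   numeric(1))
    list(values = vals,
         reference = count_inflexions(series$t, vals, tol))
  })
  attr(out, "midpoints") <- mids
  out
}

#' Average likelihood fields across measurement realizations
#'
#' Combines per-realization fields into one: each guide column's joint
#' vector is the equal-weight average of the realizations' joint vectors,
#' renormalized (each realization is equally probable by construction of
#' the equal-mass strata). The directional vectors are averaged the same
#' way. All fields must share the same column positions and grids, which
#' they do when built over one shared envelope.
#'
#' @param fields List of `iq_field` objects (see [estimate_field()]).
#' @return A single `iq_field` whose guide columns hold the mixture
#'   distributions.
#' @export
aggregate_fields <- function(fields) {
  stopifnot(length(fields) >= 1)
  f0 <- fields[[1]]
  for (f in fields[-1]) {
    if (length(f$columns) != length(f0$columns) ||
        any(abs(vapply(f$columns, `[[`, numeric(1), "x") -
                vapply(f0$columns, `[[`, numeric(1), "x")) > 1e-12) ||
        any(vapply(seq_along(f$columns), function(j)
          length(f$columns[[j]]$midpoints) !=
            length(f0$columns[[j]]$midpoints) ||
            any(abs(f$columns[[j]]$midpoints -
                    f0$columns[[j]]$midpoints) > 1e-9), logical(1))))
      stop("mismatched grids: fields must share column positions and midpoints")
  }
  avg <- function(slot, j) {
    vs <- lapply(fields, function(f) f$columns[[j]][[slot]])
    if (any(vapply(vs, is.null, logical(1)))) return(NULL)
    v <- Reduce(`+`, vs) / length(vs)
    v / sum(v)
  }
  for (j in seq_along(f0$columns)) {
    for (slot in c("p_left", "p_right", "p_joint")) {
      v <- avg(slot, j)
      if (!is.null(v)) f0$columns[[j]][[slot]] <- v
    }
  }
  f0$n_realizations <- length(fields)
  f0
}
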