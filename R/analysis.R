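#' Withhold time points from a series
#'
#' Deterministically splits a series into a retained part (used to build
#' the likelihood field) and a withheld part (used to score predictive
#' coverage). Supported rules: `"every_other"` retains indices 1, 3, 5, ...;
#' `"every_third"` retains 1, 4, 7, ...; a numeric vector gives explicit
#' retained indices. The first and last time points must be retained - the
#' method interpolates, it does not extrapolate.
#'
#' @param series An [measurement_series()].
#' @param pattern `"every_other"`, `"every_third"`, or integer indices.
#' @return List with `retained` and `withheld`, both `iq_series` (the
#'   withheld part is `NULL` when nothing is withheld).
#' @examples
#' s <- measurement_series(0:6, as.list(sin(0:6)), sd = rep(0.1, 7))
#' w <- withhold(s, "every_other")
#' w$retained$t  # 0 2 4 6
#' @export
withhold <- function(series, pattern = "every_other") {
  stopifnot(inherits(series, "iq_series"))
  n <- length(series$t)
  keep <- if (is.numeric(pattern)) {
    sort(unique(as.integer(pattern)))
  } else {
    switch(match.arg(pattern, c("every_other", "every_third")),
           every_other = seq(1L, n, by = 2L),
           every_third = seq(1L, n, by = 3L))
  }
  if (any(keep < 1L | keep > n)) stop("retained indices out of range")
  if (!(1L %in% keep) || !(n %in% keep))
    stop("pattern drops an endpoint: the first and last points must be retained")
  drop <- setdiff(seq_len(n), keep)
  list(retained = series_subset(series, keep),
       withheld = if (length(drop)) series_subset(series, drop) else NULL)
}

# internal: central equal-tailed interval of a discrete column distribution,
# with linear interpolation inside the equal-width midpoint bins.
discrete_central_interval <- function(p, lo, hi, level) {
  V <- length(p)
  if (hi <= lo) return(c(lo, hi))
  edges <- seq(lo, hi, length.out = V + 1)
  cdf <- c(0, cumsum(p))
  cdf[V + 1] <- 1  # guard against rounding
  qfun <- function(q) {
    i <- which(cdf >= q - 1e-15)[1]
    if (i == 1) return(edges[1])
    dp <- cdf[i] - cdf[i - 1]
    if (dp <= 0) return(edges[i])
    edges[i - 1] + (q - cdf[i - 1]) / dp * (edges[i] - edges[i - 1])
  }
  c(qfun((1 - level) / 2), qfun((1 + level) / 2))
}

# internal: highest-density interval of a discrete column distribution
# (contiguous interval of bins of minimal width reaching the level).
discrete_hdi <- function(p, lo, hi, level) {
  V <- length(p)
  if (hi <= lo) return(c(lo, hi))
  edges <- seq(lo, hi, length.out = V + 1)
  cdf <- c(0, cumsum(p))
  best <- c(edges[1], edges[V + 1])
  for (i in seq_len(V)) {
    j <- which(cdf[-seq_len(i)] - cdf[i] >= level - 1e-12)[1]
    if (is.na(j)) next
    j <- j + i
    # shrink the right edge inside bin j-1..j by interpolation
    need <- level - (cdf[j - 1] - cdf[i])
    dp <- cdf[j] - cdf[j - 1]
    right <- if (dp > 0) edges[j - 1] + need / dp * (edges[j] - edges[j - 1])
             else edges[j]
    if (right - edges[i] < best[2] - best[1]) best <- c(edges[i], right)
  }
  best
}

#' Build nested likelihood envelopes from a field
#'
#' For each level `q`, the envelope polyline has one vertex per column. At
#' a guide column the interval is the central (equal-tailed) interval of
#' the discrete joint distribution - between the `(1 - q) / 2` and
#' `(1 + q) / 2` cumulative points, with linear interpolation inside the
#' equal-width midpoint bins (`type = "hdi"` switches to highest-density
#' intervals). At a measured column it is the t-based central confidence
#' interval at level `q` from the replicate statistics. Vertices are
#' connected by straight lines; evaluation between vertices is linear.
#'
#' @param field An `iq_field` with joint distributions filled.
#' @param levels Probability levels (default `c(0.20, 0.75, 0.95)`).
#' @param type `"central"` (default) or `"hdi"`.
#' @return An object of class `iq_envelope_set`: a data frame with columns
#'   `level`, `x`, `lo`, `hi`, plus the levels as attribute.
#' @export
build_envelope_set <- function(field, levels = c(0.20, 0.75, 0.95),
                               type = c("central", "hdi")) {
  type <- match.arg(type)
  stopifnot(inherits(field, "iq_field"))
  for (cl in field$columns) {
    if (is.null(cl$p_joint)) stop("field not normalized: p_joint missing")
    if (abs(sum(cl$p_joint) - 1) > 1e-8)
      stop("field not normalized: p_joint does not sum to 1")
  }
  st <- field$series$stats
  rows <- list()
  for (q in sort(levels)) {
    half <- ifelse(st$sd == 0, 0,
                   stats::qt((1 + q) / 2, st$df) * st$sd / sqrt(st$n))
    meas <- data.frame(level = q, x = st$t, lo = st$mean - half,
                       hi = st$mean + half)
    gui <- do.call(rbind, lapply(field$columns, function(cl) {
      iv <- if (type == "central")
        discrete_central_interval(cl$p_joint, cl$lo, cl$hi, q)
      else discrete_hdi(cl$p_joint, cl$lo, cl$hi, q)
      data.frame(level = q, x = cl$x, lo = iv[1], hi = iv[2])
    }))
    rows[[length(rows) + 1]] <- rbind(meas, gui)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$level, out$x), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, levels = sort(levels), class = c("iq_envelope_set",
                                                  "data.frame"))
}

#' Evaluate envelope boundaries at arbitrary positions
#' @param envelopes An `iq_envelope_set`.
#' @param level One of its levels.
#' @param x Positions inside the envelope range.
#' @return Data frame `x`, `lo`, `hi` (linear interpolation between
#'   vertices).
#' @export
envelope_at <- function(envelopes, level, x) {
  e <- envelopes[abs(envelopes$level - level) < 1e-12, ]
  if (nrow(e) == 0) stop("level not present in the envelope set")
  if (any(x < min(e$x) | x > max(e$x)))
    stop("out of range: x outside the envelope range")
  data.frame(x = x,
             lo = stats::approx(e$x, e$lo, xout = x)$y,
             hi = stats::approx(e$x, e$hi, xout = x)$y)
}

#' Predictive coverage of withheld measurements
#'
#' For each envelope level, the fraction of withheld measurement means that
#' lie inside the linearly interpolated envelope boundaries at their
#' positions. The error of the withheld measurements themselves is ignored:
#' the score asks where the new measurement means actually fell.
#'
#' @param withheld An `iq_series` of withheld measurements, or a data frame
#'   with columns `t` and `y`.
#' @param envelopes An `iq_envelope_set` built from the retained points.
#' @param tol Absolute slack on the boundary comparison (guards the
#'   degenerate case of zero-width envelopes evaluated at grid tolerance).
#' @return Data frame with columns `level`, `n`, `n_inside`, `fraction`.
#' @export
coverage <- function(withheld, envelopes, tol = 1e-6) {
  if (inherits(withheld, "iq_series"))
    withheld <- data.frame(t = withheld$t, y = series_means(withheld))
  stopifnot(all(c("t", "y") %in% names(withheld)))
  levels <- attr(envelopes, "levels")
  out <- do.call(rbind, lapply(levels, function(q) {
    b <- envelope_at(envelopes, q, withheld$t)
    inside <- withheld$y >= b$lo - tol & withheld$y <= b$hi + tol
    data.frame(level = q, n = nrow(withheld), n_inside = sum(inside),
               fraction = mean(inside))
  }))
  rownames(out) <- NULL
  out
}

#' Summarize a genome-wide matrix by its first principal component
#'
#' Mean-centered principal components analysis across the gene dimension:
#' each (time, replicate) sample is projected onto the first component,
#' producing a univariate series with replicates that the interpolation
#' machinery can consume. The component's sign is fixed so that the
#' largest-magnitude loading is positive.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns; no missing
#'   values (imputation is out of scope).
#' @param times Numeric vector of sample times. Defaults to parsing column
#'   names of the form `time_rep` (e.g. `"0_1"`, `"0_2"`, `"15_1"`, ...).
#' @param id Series identifier for the result.
#' @param conf Confidence level for the resulting series.
#' @return List with `series` (an `iq_series` of PC1 scores), `var_frac`
#'   (fraction of total variance carried by PC1) and `loadings`.
#' @export
pc1_series <- function(mat, times = NULL, id = "PC1", conf = 0.99) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values: supply a complete expression matrix")
  if (is.null(times)) {
    parts <- strsplit(colnames(mat), "_", fixed = TRUE)
    times <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])),
                    numeric(1))
    if (anyNA(times))
      stop("cannot parse times from column names; supply `times`")
  }
  pca <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  v <- pca$rotation[, 1]
  flip <- if (v[which.max(abs(v))] < 0) -1 else 1
  scores <- flip * pca$x[, 1]
  var_frac <- pca$sdev[1]^2 / sum(pca$sdev^2)
  ord <- order(unique(times))
  ut <- sort(unique(times))
  values <- lapply(ut, function(tt) unname(scores[times == tt]))
  list(series = measurement_series(ut, values, id = id, conf = conf),
       var_frac = var_frac, loadings = flip * v)
}
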