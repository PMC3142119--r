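#' Read measurement series from a tidy or wide table
#'
#' Tidy format: header `series_id, time, replicate, value`, tab- or
#' comma-delimited (chosen by sniffing the header line), UTF-8, `.` decimal.
#' Wide format: first column a gene/series id, remaining columns named
#' `time_rep` (e.g. `0_1`, `0_2`, `15_1`); one series per row.
#'
#' @param path File path.
#' @param format `"tidy"` (default) or `"wide"`.
#' @param conf Confidence level attached to the series.
#' @return Named list of [measurement_series()] objects.
#' @export
read_series <- function(path, format = c("tidy", "wide"), conf = 0.99) {
  format <- match.arg(format)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           fileEncoding = "UTF-8")
  if (format == "tidy") {
    need <- c("series_id", "time", "replicate", "value")
    if (!all(need %in% names(raw)))
      stop("tidy input needs columns: ", paste(need, collapse = ", "))
    num <- suppressWarnings(as.numeric(raw$value))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop(sprintf("non-numeric value '%s' at line %d", raw$value[bad],
                   bad + 1L))
    }
    key <- paste(raw$series_id, raw$time, raw$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      bad <- which(duplicated(key))[1]
      stop(sprintf("duplicate (series, time, replicate) key at line %d",
                   bad + 1L))
    }
    out <- lapply(split(seq_len(nrow(raw)), raw$series_id), function(idx) {
      tt <- as.numeric(raw$time[idx])
      vv <- num[idx]
      ut <- sort(unique(tt))
      measurement_series(ut, lapply(ut, function(x) vv[tt == x]),
                         id = raw$series_id[idx[1]], conf = conf)
    })
  } else {
    parts <- strsplit(names(raw)[-1], "_", fixed = TRUE)
    tt <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])),
                 numeric(1))
    if (anyNA(tt))
      stop("wide input needs columns named time_rep (e.g. 0_1, 0_2, 15_1)")
    vals <- suppressWarnings(
      matrix(as.numeric(as.matrix(raw[, -1, drop = FALSE])),
             nrow = nrow(raw)))
    if (anyNA(vals)) stop("non-numeric value in wide input")
    ut <- sort(unique(tt))
    out <- lapply(seq_len(nrow(raw)), function(i) {
      measurement_series(ut,
                         lapply(ut, function(x) vals[i, tt == x]),
                         id = raw[[1]][i], conf = conf)
    })
    names(out) <- raw[[1]]
  }
  out
}

# internal: format doubles so that read-back reproduces them bit-exactly
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write measurement series as a tidy TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces them bit-exactly.
#'
#' @param series An `iq_series` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  if (inherits(series, "iq_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    do.call(rbind, lapply(seq_along(s$t), function(i) {
      v <- s$values[[i]]
      data.frame(series_id = s$id, time = fmt_num(rep(s$t[i], length(v))),
                 replicate = seq_along(v), value = fmt_num(v))
    }))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# internal: write a data frame as TSV with stable numeric formatting
write_tsv_stable <- function(df, path) {
  for (nm in names(df)) if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
    df[[nm]] <- fmt_num(df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the field, envelope and coverage tables of a run
#'
#' @param field An `iq_field`.
#' @param envelopes An `iq_envelope_set` (optional).
#' @param cov Coverage data frame from [coverage()] (optional).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (defaults to the series id).
#' @return Named character vector of the files written, invisibly.
#' @export
write_run <- function(field, envelopes = NULL, cov = NULL, dir = ".",
                      prefix = NULL) {
  stopifnot(inherits(field, "iq_field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- field$series$id
  files <- c(field = file.path(dir, paste0(prefix, "_field.tsv")))
  write_tsv_stable(field_table(field), files[["field"]])
  if (!is.null(envelopes)) {
    files[["envelopes"]] <- file.path(dir, paste0(prefix, "_envelopes.tsv"))
    e <- as.data.frame(envelopes)
    e <- data.frame(series_id = field$series$id, e)
    write_tsv_stable(e, files[["envelopes"]])
  }
  if (!is.null(cov)) {
    files[["coverage"]] <- file.path(dir, paste0(prefix, "_coverage.tsv"))
    write_tsv_stable(data.frame(series_id = field$series$id, cov),
                     files[["coverage"]])
  }
  files[["manifest"]] <- file.path(dir, paste0(prefix, "_manifest.json"))
  manifest <- c(field$params,
                list(series_id = field$series$id,
                     n_points = length(field$series$t),
                     reference_inflexions = field$reference,
                     package = "interpuq",
                     version = as.character(utils::packageVersion("interpuq"))))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(files)
}
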