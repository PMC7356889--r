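#' Construct a sensor time series
#'
#' The elementary container for one signal of one lot: a strictly increasing
#' time grid (seconds since the start of the series) and the measured values.
#' Absolute datetimes are deliberately not stored here -- the phase-setting
#' algorithms operate on relative time; absolute timestamps live only in the
#' quality-database record (see [qdb_record()]).
#'
#' @param signal_name Signal identifier, e.g. `"LP4"` or `"SF2"`.
#' @param times Numeric vector of sample times in seconds, non-negative and
#'   strictly increasing.
#' @param values Numeric vector of measurements, same length as `times`.
#' @param unit Measurement unit as text (e.g. `"bar"`, `"degC"`, `"kg"`).
#' @param lot_id Optional lot identifier the series belongs to.
#' @return An object of class `fff_ts`.
#' @examples
#' ts <- fff_ts("LP1", times = 0:9, values = rnorm(10), unit = "degC")
#' print(ts)
#' @export
fff_ts <- function(signal_name, times, values, unit = "", lot_id = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a time series needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("non-finite times in signal ", signal_name, call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("non-finite values in signal ", signal_name, call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing in signal ", signal_name,
         call. = FALSE)
  }
  if (times[1L] < 0) {
    stop("times must be non-negative in signal ", signal_name, call. = FALSE)
  }
  structure(
    list(signal_name = as.character(signal_name), times = times,
         values = values, unit = as.character(unit),
         lot_id = if (is.null(lot_id)) NULL else as.character(lot_id)),
    class = "fff_ts"
  )
}

#' @export
print.fff_ts <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<fff_ts> %s%s: %d samples over %.1f s%s\n",
              x$signal_name,
              if (!is.null(x$lot_id)) paste0(" [lot ", x$lot_id, "]") else "",
              n, x$times[n] - x$times[1L],
              if (nzchar(x$unit)) paste0(" (", x$unit, ")") else ""))
  invisible(x)
}

#' @export
length.fff_ts <- function(x) length(x$times)

#' @export
as.data.frame.fff_ts <- function(x, ...) {
  data.frame(lot_id = if (is.null(x$lot_id)) NA_character_ else x$lot_id,
             signal = x$signal_name, t_seconds = x$times, value = x$values,
             unit = x$unit, stringsAsFactors = FALSE)
}

# Subset a series by sample index, preserving metadata. Internal.
ts_subset <- function(ts, idx) {
  fff_ts(ts$signal_name, ts$times[idx], ts$values[idx], ts$unit, ts$lot_id)
}

# Linear interpolation of a series at arbitrary times (no extrapolation:
# clamped to end values, which is what boundary predicates need). Internal.
ts_interp <- function(ts, at) {
  stats::approx(ts$times, ts$values, xout = at, rule = 2)$y
}

#' Construct a quality-database record for one lot
#'
#' One row of the quality database (QDB): single-point features (typically
#' critical quality attributes of the bulk drug substance) plus the absolute
#' start/end timestamps of the process steps used to contextualize unlabeled
#' sensor streams.
#'
#' @param lot_id Lot identifier, unique within a campaign.
#' @param features Named numeric vector of single-point features; `NA` marks
#'   a missing value.
#' @param step_intervals Named list; each element is a length-2 `POSIXct`
#'   vector `c(start, end)` with `start < end`. Canonical step names are
#'   `"sterile_filtration"` and `"lyophilization"`.
#' @return An object of class `qdb_record`.
#' @export
qdb_record <- function(lot_id, features = numeric(), step_intervals = list()) {
  lot_id <- as.character(lot_id)
  features <- unlist(features)
  if (length(features) && is.null(names(features))) {
    stop("QDB features must be named", call. = FALSE)
  }
  for (nm in names(step_intervals)) {
    iv <- step_intervals[[nm]]
    if (length(iv) != 2L) {
      stop("step interval '", nm, "' must have a start and an end",
           call. = FALSE)
    }
    if (!anyNA(iv) && !(iv[1L] < iv[2L])) {
      stop("lot ", lot_id, ", step '", nm, "': interval end precedes start",
           call. = FALSE)
    }
  }
  structure(list(lot_id = lot_id, features = features,
                 step_intervals = step_intervals),
            class = "qdb_record")
}

#' @export
print.qdb_record <- function(x, ...) {
  cat(sprintf("<qdb_record> lot %s: %d features, steps: %s\n", x$lot_id,
              length(x$features),
              paste(names(x$step_intervals), collapse = ", ")))
  invisible(x)
}

#' Construct a batch object
#'
#' A batch is the aligned record of one lot: all of its time series keyed by
#' signal name together with its quality-database record. Downstream stages
#' tolerate missing signals (a batch may lack a source) and record the
#' omission rather than failing the campaign.
#'
#' @param lot_id Lot identifier.
#' @param series Named list of [fff_ts()] objects; each series' `lot_id` must
#'   match (it is filled in when absent).
#' @param qdb A [qdb_record()] for the same lot.
#' @return An object of class `fff_batch`.
#' @export
fff_batch <- function(lot_id, series = list(), qdb = NULL) {
  lot_id <- as.character(lot_id)
  if (length(series)) {
    nm <- vapply(series, function(s) s$signal_name, character(1))
    if (anyDuplicated(nm)) {
      stop("duplicate signal names in batch ", lot_id, call. = FALSE)
    }
    names(series) <- nm
    series <- lapply(series, function(s) {
      if (is.null(s$lot_id)) s$lot_id <- lot_id
      if (!identical(s$lot_id, lot_id)) {
        stop("series lot_id '", s$lot_id, "' does not match batch '",
             lot_id, "'", call. = FALSE)
      }
      s
    })
  }
  if (is.null(qdb)) qdb <- qdb_record(lot_id)
  if (!identical(qdb$lot_id, lot_id)) {
    stop("QDB record lot_id does not match batch lot_id", call. = FALSE)
  }
  structure(list(lot_id = lot_id, series = series, qdb = qdb),
            class = "fff_batch")
}

#' @export
print.fff_batch <- function(x, ...) {
  cat(sprintf("<fff_batch> lot %s: signals [%s], %d QDB features\n",
              x$lot_id, paste(names(x$series), collapse = ", "),
              length(x$qdb$features)))
  invisible(x)
}
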