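#' Parse a quality-database table
#'
#' Reads the per-lot quality database (QDB): one row per lot with single-point
#' feature columns and the absolute start/end timestamps of process steps.
#' Timestamp columns are recognized in pairs named `<step>_start` /
#' `<step>_end` (e.g. `sterile_filtration_start`); everything else apart from
#' `lot_id` is treated as a feature column. Non-numeric feature cells become
#' missing values. All timestamps are parsed to a single timezone-naive
#' convention (interpreted as UTC).
#'
#' @param table_source Path to a delimited text file, or a `data.frame`.
#' @param delimiter Field delimiter when reading from a file (default `,`).
#' @return A list of [qdb_record()] objects, one per row.
#' @export
parse_qdb_table <- function(table_source, delimiter = ",") {
  df <- if (is.data.frame(table_source)) table_source else
    utils::read.table(table_source, header = TRUE, sep = delimiter,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", fileEncoding = "UTF-8")
  if (!"lot_id" %in% names(df)) {
    stop("QDB table needs a 'lot_id' column", call. = FALSE)
  }
  lot_ids <- as.character(df[["lot_id"]])
  if (anyDuplicated(lot_ids)) {
    stop("duplicate lot_id in QDB table: ",
         paste(unique(lot_ids[duplicated(lot_ids)]), collapse = ", "),
         call. = FALSE)
  }
  ts_cols <- grep("_(start|end)$", names(df), value = TRUE)
  steps <- unique(sub("_(start|end)$", "", ts_cols))
  steps <- steps[paste0(steps, "_start") %in% names(df) &
                 paste0(steps, "_end") %in% names(df)]
  feat_cols <- setdiff(names(df), c("lot_id", paste0(steps, "_start"),
                                    paste0(steps, "_end")))
  lapply(seq_len(nrow(df)), function(i) {
    feats <- vapply(feat_cols, function(cl) {
      suppressWarnings(as.numeric(df[[cl]][i]))
    }, numeric(1))
    ivs <- list()
    for (st in steps) {
      a <- parse_iso8601(df[[paste0(st, "_start")]][i])
      b <- parse_iso8601(df[[paste0(st, "_end")]][i])
      if (is.na(a) || is.na(b)) {
        warning("lot ", lot_ids[i], ": missing timestamp for step '", st,
                "'; record retained", call. = FALSE)
        next
      }
      if (!(a < b)) {
        stop("lot ", lot_ids[i], ", step '", st,
             "': end timestamp precedes start", call. = FALSE)
      }
      ivs[[st]] <- c(a, b)
    }
    qdb_record(lot_ids[i], feats, ivs)
  })
}

parse_iso8601 <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(as.POSIXct(NA))
  x <- trimws(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

format_iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Serialize quality-database records back to a delimited table
#'
#' Inverse of [parse_qdb_table()]. Feature values are written with 17
#' significant digits so that parse / serialize round-trips are exact on the
#' binary values.
#'
#' @param records List of [qdb_record()] objects.
#' @param path Output file path; when `NULL` the data frame is returned.
#' @param delimiter Field delimiter.
#' @return Invisibly, the data frame written.
#' @export
write_qdb_table <- function(records, path = NULL, delimiter = ",") {
  feat_names <- unique(unlist(lapply(records, function(r) names(r$features))))
  steps <- unique(unlist(lapply(records, function(r) names(r$step_intervals))))
  rows <- lapply(records, function(r) {
    row <- list(lot_id = r$lot_id)
    for (fn in feat_names) {
      v <- if (fn %in% names(r$features)) r$features[[fn]] else NA_real_
      row[[fn]] <- if (is.na(v)) "" else sprintf("%.17g", v)
    }
    for (st in steps) {
      iv <- r$step_intervals[[st]]
      row[[paste0(st, "_start")]] <- if (is.null(iv)) "" else format_iso8601(iv[1L])
      row[[paste0(st, "_end")]]   <- if (is.null(iv)) "" else format_iso8601(iv[2L])
    }
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(df)
}

#' Parse a table of sensor time series
#'
#' Accepts the two layouts sensor historians commonly export:
#' * `"long"` -- columns `timestamp`, `signal`, `value` and optionally
#'   `lot_id` and `unit`; rows for different series may be interleaved.
#' * `"wide"` -- a `timestamp` column plus one numeric column per signal.
#'
#' Timestamps may be numeric seconds or ISO-8601 datetimes. Each series'
#' times are rebased to seconds from its own first sample; when the input
#' carried absolute datetimes the origin is kept in the `"origin"` attribute
#' of each series so that unlabeled continuous streams can later be cut by
#' quality-database timestamps (see [segment_stream_by_intervals()]).
#' Rows with unparseable values are dropped; the total drop count is attached
#' to the result as attribute `"n_dropped"`.
#'
#' @param table_source Path to a delimited text file, or a `data.frame`.
#' @param layout `"long"` or `"wide"`.
#' @param delimiter Field delimiter when reading from a file.
#' @param unit Fallback unit when the table has no `unit` column.
#' @return A list of [fff_ts()] objects with attribute `n_dropped`.
#' @export
parse_timeseries_table <- function(table_source, layout = c("long", "wide"),
                                   delimiter = ",", unit = "") {
  layout <- match.arg(layout)
  df <- if (is.data.frame(table_source)) table_source else
    utils::read.table(table_source, header = TRUE, sep = delimiter,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      fileEncoding = "UTF-8")
  tcol <- intersect(c("timestamp", "t_seconds", "time"), names(df))[1L]
  if (is.na(tcol)) stop("no timestamp column found", call. = FALSE)
  tm <- parse_time_column(df[[tcol]])
  out <- list()
  n_dropped <- 0L
  if (layout == "long") {
    if (!all(c("signal", "value") %in% names(df))) {
      stop("long layout needs 'signal' and 'value' columns", call. = FALSE)
    }
    lot <- if ("lot_id" %in% names(df)) as.character(df[["lot_id"]]) else
      rep(NA_character_, nrow(df))
    un <- if ("unit" %in% names(df)) as.character(df[["unit"]]) else
      rep(unit, nrow(df))
    vals <- suppressWarnings(as.numeric(df[["value"]]))
    key <- paste(lot, df[["signal"]], sep = "\r")
    for (k in unique(key)) {
      sel <- which(key == k)
      keep <- sel[is.finite(vals[sel]) & is.finite(tm$seconds[sel])]
      n_dropped <- n_dropped + (length(sel) - length(keep))
      if (length(keep) < 2L) next
      out[[length(out) + 1L]] <- make_parsed_ts(
        signal = df[["signal"]][keep[1L]], secs = tm$seconds[keep],
        vals = vals[keep], unit = un[keep[1L]],
        lot = if (is.na(lot[keep[1L]])) NULL else lot[keep[1L]],
        origin = tm$origin)
    }
  } else {
    sigs <- setdiff(names(df), c(tcol, "lot_id", "unit"))
    for (sg in sigs) {
      vals <- suppressWarnings(as.numeric(df[[sg]]))
      keep <- which(is.finite(vals) & is.finite(tm$seconds))
      n_dropped <- n_dropped + (nrow(df) - length(keep))
      if (length(keep) < 2L) next
      out[[length(out) + 1L]] <- make_parsed_ts(
        signal = sg, secs = tm$seconds[keep], vals = vals[keep], unit = unit,
        lot = NULL, origin = tm$origin)
    }
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

parse_time_column <- function(x) {
  if (is.numeric(x)) return(list(seconds = as.numeric(x), origin = NULL))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(list(seconds = num, origin = NULL))
  dt <- parse_iso8601_vec(as.character(x))
  list(seconds = as.numeric(dt) - min(as.numeric(dt), na.rm = TRUE),
       origin = as.POSIXct(min(as.numeric(dt), na.rm = TRUE),
                           origin = "1970-01-01", tz = "UTC"))
}

parse_iso8601_vec <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  ok <- !is.na(x) & nzchar(trimws(x))
  if (any(ok)) out[ok] <- parse_iso8601_many(trimws(x[ok]))
  out
}

parse_iso8601_many <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"),
             optional = TRUE)
}

make_parsed_ts <- function(signal, secs, vals, unit, lot, origin) {
  if (any(diff(secs) <= 0)) {
    stop("non-monotone timestamps in series '", signal, "'",
         if (!is.null(lot)) paste0(" of lot ", lot) else "", call. = FALSE)
  }
  series_origin <- if (!is.null(origin)) origin + secs[1L] else NULL
  ts <- fff_ts(signal, secs - secs[1L], vals, unit = unit, lot_id = lot)
  gaps <- diff(ts$times)
  if (length(gaps) > 1L && max(gaps) / stats::median(gaps) > 10) {
    warning("signal '", signal, "': highly irregular sampling (max/median ",
            "inter-sample gap > 10)", call. = FALSE)
  }
  attr(ts, "origin") <- series_origin
  ts
}

#' Cut a continuous sensor stream into per-lot segments
#'
#' Sterile-filtration sensors record one continuous multi-month stream with
#' no lot labels. This function contextualizes the stream using the per-lot
#' step timestamps stored in the quality database: each lot receives the
#' samples with `start <= t < end` (half-open, so adjacent lots are
#' non-overlapping by construction) of its interval, rebased to seconds from
#' the interval start.
#'
#' @param stream List of [fff_ts()] objects carrying an `"origin"` attribute
#'   (absolute start time), as produced by [parse_timeseries_table()] on
#'   datetime input.
#' @param records List of [qdb_record()] objects supplying the intervals.
#' @param step_name Which step interval to use (default
#'   `"sterile_filtration"`).
#' @return A list with elements `segments` (named list: lot_id -> named list
#'   of per-signal [fff_ts()]), and `report`, a data frame with one row per
#'   lot and signal (samples assigned, coverage fraction of the interval)
#'   plus the attribute `"unassigned"` counting stream samples no lot claimed.
#' @export
segment_stream_by_intervals <- function(stream, records,
                                        step_name = "sterile_filtration") {
  ivs <- lapply(records, function(r) r$step_intervals[[step_name]])
  has_iv <- !vapply(ivs, is.null, logical(1))
  lots <- vapply(records, function(r) r$lot_id, character(1))
  iv_start <- vapply(ivs[has_iv], function(iv) as.numeric(iv[1L]), numeric(1))
  iv_end <- vapply(ivs[has_iv], function(iv) as.numeric(iv[2L]), numeric(1))
  iv_lots <- lots[has_iv]
  if (length(iv_start) > 1L) {
    o <- order(iv_start)
    overlap <- which(iv_end[o][-length(o)] > iv_start[o][-1L])
    if (length(overlap)) {
      stop("overlapping ", step_name, " intervals for lots: ",
           paste(paste(iv_lots[o][overlap], iv_lots[o][overlap + 1L],
                       sep = "/"), collapse = ", "), call. = FALSE)
    }
  }
  segments <- stats::setNames(vector("list", length(iv_lots)), iv_lots)
  rep_rows <- list()
  unassigned <- 0L
  for (ts in stream) {
    origin <- attr(ts, "origin")
    if (is.null(origin)) {
      stop("stream series '", ts$signal_name,
           "' has no absolute time origin", call. = FALSE)
    }
    abs_t <- as.numeric(origin) + ts$times
    assigned <- rep(FALSE, length(abs_t))
    for (j in seq_along(iv_lots)) {
      sel <- which(abs_t >= iv_start[j] & abs_t < iv_end[j] & !assigned)
      assigned[sel] <- TRUE
      cov <- if (length(sel) >= 2L) {
        (abs_t[sel[length(sel)]] - abs_t[sel[1L]]) / (iv_end[j] - iv_start[j])
      } else 0
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        lot_id = iv_lots[j], signal = ts$signal_name,
        samples = length(sel), coverage = cov, stringsAsFactors = FALSE)
      if (length(sel) < 2L) next
      seg <- fff_ts(ts$signal_name, abs_t[sel] - iv_start[j], ts$values[sel],
                    unit = ts$unit, lot_id = iv_lots[j])
      segments[[iv_lots[j]]][[ts$signal_name]] <- seg
    }
    unassigned <- unassigned + sum(!assigned)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(lot_id = character(), signal = character(),
               samples = integer(), coverage = numeric())
  attr(report, "unassigned") <- unassigned
  list(segments = segments, report = report)
}

#' Assemble aligned batch objects
#'
#' Joins the three data sources into one [fff_batch()] per quality-database
#' record: lyophilization series are joined on `lot_id`, filtration series
#' come from [segment_stream_by_intervals()]. Missing sources leave the
#' series map partially filled (with a warning); lyophilization series whose
#' lot is absent from the QDB are excluded with a warning.
#'
#' @param records List of [qdb_record()] objects.
#' @param lyo_series_by_lot Named list: lot_id -> list of [fff_ts()].
#' @param filtration_by_lot Named list: lot_id -> list of [fff_ts()]
#'   (typically the `segments` element of [segment_stream_by_intervals()]).
#' @return List of [fff_batch()] objects, one per record.
#' @export
assemble_batches <- function(records, lyo_series_by_lot = list(),
                             filtration_by_lot = list()) {
  lots <- vapply(records, function(r) r$lot_id, character(1))
  orphans <- setdiff(names(lyo_series_by_lot), lots)
  if (length(orphans)) {
    warning("lyophilization series for lots absent from the QDB, excluded: ",
            paste(orphans, collapse = ", "), call. = FALSE)
  }
  lapply(records, function(r) {
    series <- list()
    for (src in list(lyo_series_by_lot[[r$lot_id]],
                     filtration_by_lot[[r$lot_id]])) {
      for (s in src) {
        s$lot_id <- r$lot_id
        attr(s, "origin") <- NULL
        series[[s$signal_name]] <- s
      }
    }
    if (!length(series)) {
      warning("lot ", r$lot_id, ": no time-series source available",
              call. = FALSE)
    }
    fff_batch(r$lot_id, series, r)
  })
}

#' Write batches as canonical long-format CSV plus a JSON manifest
#'
#' @param batches List of [fff_batch()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_batches <- function(batches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(batches, function(b) {
    rows <- lapply(b$series, as.data.frame)
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(lot_id = character(), signal = character(),
                 t_seconds = numeric(), value = numeric(), unit = character())
    df$lot_id <- b$lot_id
    path <- file.path(dir, paste0("batch_", b$lot_id, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    list(lot_id = b$lot_id, file = basename(path),
         signals = as.list(names(b$series)),
         n_qdb_features = length(b$qdb$features))
  })
  jsonlite::write_json(manifest, file.path(dir, "batch_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
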