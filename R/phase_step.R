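#' Configuration for step-signal phase setting
#'
#' Step-shaped FFF signals (stepwise setpoint changes in pH, pressure or
#' temperature) consist of plateaus joined by sharp ramps. Detection compares
#' values `lookahead` samples apart against a threshold: a slope starts at
#' the first sample where `|y[t] - y[t+i]| > threshold` and ends at the first
#' subsequent sample where the difference falls back to or below the
#' threshold. When expert knowledge bounds the admissible phase durations,
#' the threshold is adapted: a detected phase shorter than its minimum
#' duration raises the threshold (multiplying by `threshold_step`), one
#' longer than its maximum lowers it, and the scan restarts globally, up to
#' `max_iterations` times.
#'
#' @param lookahead Sample offset `i` of the detector (default 1).
#' @param threshold0 Initial threshold in value units; `NULL` derives it as
#'   `3 * estimate_noise_sigma(ts)`, which keeps the false slope-start rate
#'   around 0.3\% per comparison under Gaussian noise.
#' @param duration_bounds Named list with elements `slope` and/or `plateau`,
#'   each `c(min_seconds, max_seconds)`. Defaults to unbounded.
#' @param threshold_step Multiplicative adjustment factor > 1 (default 1.5).
#' @param max_iterations Maximum adaptive restarts (default 20).
#' @return An object of class `step_config`.
#' @export
step_config <- function(lookahead = 1L, threshold0 = NULL,
                        duration_bounds = list(slope = c(0, Inf),
                                               plateau = c(0, Inf)),
                        threshold_step = 1.5, max_iterations = 20L) {
  if (lookahead < 1L) stop("lookahead must be >= 1", call. = FALSE)
  if (!is.null(threshold0) && threshold0 <= 0) {
    stop("threshold0 must be positive", call. = FALSE)
  }
  if (threshold_step <= 1) stop("threshold_step must be > 1", call. = FALSE)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  for (nm in names(duration_bounds)) {
    b <- duration_bounds[[nm]]
    if (length(b) != 2L || !(b[1L] < b[2L])) {
      stop("duration bound for '", nm, "' must be c(min, max) with min < max",
           call. = FALSE)
    }
  }
  if (is.null(duration_bounds$slope)) duration_bounds$slope <- c(0, Inf)
  if (is.null(duration_bounds$plateau)) duration_bounds$plateau <- c(0, Inf)
  structure(list(lookahead = as.integer(lookahead), threshold0 = threshold0,
                 duration_bounds = duration_bounds,
                 threshold_step = threshold_step,
                 max_iterations = as.integer(max_iterations)),
            class = "step_config")
}

# One forward scan at a fixed threshold. Returns phases as a data.frame with
# half-open sample-index intervals [start_index, end_index). The slope start
# is placed one sample after the detecting comparison (the compared pair
# brackets the first increment), so that on a noise-free step the slope phase
# covers exactly the ramp samples. A slope-end proposal arriving before the
# minimum slope duration is discarded and the scan searches for the next
# best end guess (a noise dip inside a ramp must not split it); afterwards
# every slope segment is re-classified by its median lookahead difference
# and spurious slopes (noise excursions on a plateau) are merged back into
# the surrounding plateau.
scan_step_phases <- function(ts, i, threshold, min_slope_seconds = 0) {
  y <- ts$values
  tms <- ts$times
  n <- length(y)
  d <- abs(y[seq_len(n - i)] - y[seq_len(n - i) + i])
  phases <- list()
  leading_slope <- FALSE
  pos <- 1L   # next uncovered sample index
  t <- 1L
  nd <- n - i
  end_time_of <- function(idx) if (idx <= n) tms[idx] else
    tms[n] + stats::median(diff(tms))
  add <- function(kind, start, end) {
    phases[[length(phases) + 1L]] <<- data.frame(
      kind = kind, start_index = start, end_index = end,
      stringsAsFactors = FALSE)
  }
  while (t <= nd) {
    if (d[t] > threshold) {
      slope_start <- if (t == 1L) 1L else t + 1L
      if (t == 1L) leading_slope <- TRUE
      if (slope_start > pos) add("plateau", pos, slope_start)
      t2 <- t + 1L
      repeat {
        while (t2 <= nd && d[t2] > threshold) t2 <- t2 + 1L
        slope_end <- if (t2 > nd) n + 1L else t2 + 1L
        if (t2 > nd ||
            end_time_of(slope_end) - tms[slope_start] >= min_slope_seconds) {
          break
        }
        t2 <- t2 + 1L   # end proposal too early: discard, next best guess
      }
      add("slope", slope_start, slope_end)
      pos <- slope_end
      t <- t2 + 1L
    } else {
      t <- t + 1L
    }
  }
  if (pos <= n) add("plateau", pos, n + 1L)
  ph <- do.call(rbind, phases)
  ph <- merge_spurious_slopes(ts, ph, threshold, i)
  attr(ph, "leading_slope") <- leading_slope && ph$kind[1L] == "slope"
  ph
}

# Re-classify each slope segment by the median of its lookahead differences
# (a real ramp keeps a high median; a forced-length noise excursion does
# not) and merge re-classified segments into their plateau neighbours.
merge_spurious_slopes <- function(ts, ph, threshold, i) {
  if (nrow(ph) < 2L) return(ph)
  is_real <- vapply(seq_len(nrow(ph)), function(r) {
    if (ph$kind[r] != "slope") return(TRUE)
    if (ph$end_index[r] - ph$start_index[r] < 2L) return(FALSE)
    classify_segment(ts, ph$start_index[r], ph$end_index[r], threshold,
                     i) == "slope"
  }, logical(1))
  if (all(is_real)) return(ph)
  ph$kind[!is_real] <- "plateau"
  # concatenate adjacent phases of equal kind
  out <- ph[1L, , drop = FALSE]
  for (r in 2L:nrow(ph)) {
    if (ph$kind[r] == out$kind[nrow(out)]) {
      out$end_index[nrow(out)] <- ph$end_index[r]
    } else {
      out <- rbind(out, ph[r, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

phase_duration <- function(ts, start, end) {
  n <- length(ts$times)
  t_end <- if (end <= n) ts$times[end] else
    ts$times[n] + stats::median(diff(ts$times))
  t_end - ts$times[start]
}

count_bound_violations <- function(ts, ph, bounds) {
  too_short <- 0L
  too_long <- 0L
  for (r in seq_len(nrow(ph))) {
    b <- bounds[[ph$kind[r]]]
    dur <- phase_duration(ts, ph$start_index[r], ph$end_index[r])
    if (dur < b[1L]) too_short <- too_short + 1L
    if (dur > b[2L]) too_long <- too_long + 1L
  }
  c(too_short = too_short, too_long = too_long)
}

#' Segment a step-shaped signal into plateau and slope phases
#'
#' Implements the adaptive step-signal phase-setting algorithm: forward scan
#' with a lookahead difference detector, duration validation against expert
#' bounds, and global threshold adaptation with restart (see
#' [step_config()]). Deterministic: identical input and configuration yield
#' an identical segmentation.
#'
#' @param ts An [fff_ts()] series; must be longer than `2 * lookahead`.
#' @param cfg A [step_config()].
#' @return An object of class `step_segmentation`: a list with `signal_name`,
#'   `phases` (data frame with `label`, `kind`, half-open `start_index` /
#'   `end_index`, `start_time`, `end_time`, `duration_seconds`),
#'   `final_threshold`, `iterations_used`, `converged` and `leading_slope`
#'   (flag: signal began mid-slope).
#' @examples
#' y <- c(rep(0, 50), seq(0.1, 1, by = 0.1), rep(1, 50))
#' ts <- fff_ts("LP2", seq_along(y) - 1, y)
#' seg <- detect_step_phases(ts, step_config(threshold0 = 0.05))
#' seg$phases[, c("label", "kind", "start_index", "end_index")]
#' @export
detect_step_phases <- function(ts, cfg = step_config()) {
  i <- cfg$lookahead
  n <- length(ts$values)
  if (n <= 2L * i) {
    stop("series shorter than 2 * lookahead (", 2L * i, " samples)",
         call. = FALSE)
  }
  thr <- cfg$threshold0
  if (is.null(thr)) {
    thr <- 3 * estimate_noise_sigma(ts)
    if (thr <= 0) thr <- .Machine$double.eps  # noise-free signal
  }
  best <- NULL
  best_viol <- Inf
  converged <- FALSE
  iter <- 0L
  # thresholds known to be too low (spurious short phases) / too high
  # (missed changes, over-long phases) bracket the viable window; once both
  # sides have been seen the multiplicative step switches to geometric
  # bisection, which cannot oscillate over a narrow window
  thr_lo <- NA_real_
  thr_hi <- NA_real_
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    ph <- scan_step_phases(ts, i, thr,
                           min_slope_seconds = cfg$duration_bounds$slope[1L])
    v <- count_bound_violations(ts, ph, cfg$duration_bounds)
    total <- sum(v)
    if (total < best_viol) {
      best <- ph
      best_viol <- total
      attr(best, "threshold") <- thr
    }
    if (total == 0L) {
      converged <- TRUE
      break
    }
    # a phase ending too early -> the detector is too jumpy -> raise;
    # a phase running too long -> the detector misses changes -> lower
    if (v["too_short"] > 0L) {
      thr_lo <- if (is.na(thr_lo)) thr else max(thr_lo, thr)
    } else {
      thr_hi <- if (is.na(thr_hi)) thr else min(thr_hi, thr)
    }
    if (!is.na(thr_lo) && !is.na(thr_hi)) {
      if (thr_hi / thr_lo < 1.001) break  # no viable threshold exists
      thr <- sqrt(thr_lo * thr_hi)
    } else if (v["too_short"] > 0L) {
      thr <- thr * cfg$threshold_step
    } else {
      thr <- thr / cfg$threshold_step
    }
  }
  ph <- best
  used_thr <- attr(best, "threshold")
  kinds <- ph$kind
  counters <- c(plateau = 0L, slope = 0L)
  labels <- character(nrow(ph))
  for (r in seq_len(nrow(ph))) {
    counters[kinds[r]] <- counters[kinds[r]] + 1L
    labels[r] <- paste0(kinds[r], "_", counters[kinds[r]])
  }
  t_end <- vapply(seq_len(nrow(ph)), function(r) {
    if (ph$end_index[r] <= n) ts$times[ph$end_index[r]] else
      ts$times[n] + stats::median(diff(ts$times))
  }, numeric(1))
  phases <- data.frame(
    label = labels, kind = kinds,
    start_index = ph$start_index, end_index = ph$end_index,
    start_time = ts$times[ph$start_index], end_time = t_end,
    duration_seconds = t_end - ts$times[ph$start_index],
    stringsAsFactors = FALSE)
  structure(list(signal_name = ts$signal_name, phases = phases,
                 final_threshold = used_thr, iterations_used = iter,
                 converged = converged,
                 leading_slope = isTRUE(attr(ph, "leading_slope"))),
            class = "step_segmentation")
}

#' @export
print.step_segmentation <- function(x, ...) {
  cat(sprintf(
    "<step_segmentation> %s: %d phases (%d slopes), threshold %.4g, %s\n",
    x$signal_name, nrow(x$phases), sum(x$phases$kind == "slope"),
    x$final_threshold,
    if (x$converged) sprintf("converged in %d iteration(s)", x$iterations_used)
    else "NOT converged"))
  print(x$phases[, c("label", "kind", "start_index", "end_index",
                     "duration_seconds")], row.names = FALSE)
  invisible(x)
}

#' Classify a segment of a step signal as slope or plateau
#'
#' A segment is a slope when the median lookahead difference
#' `|y[t] - y[t+i]|` over the segment exceeds the threshold, else a plateau.
#' The median makes the call robust to a minority of noisy comparisons.
#'
#' @param ts An [fff_ts()] series.
#' @param start,end Half-open sample-index interval `[start, end)` with
#'   `end - start >= 2`.
#' @param threshold Detection threshold in value units.
#' @param lookahead Sample offset `i` (default 1).
#' @return `"slope"` or `"plateau"`.
#' @export
classify_segment <- function(ts, start, end, threshold, lookahead = 1L) {
  if (end - start < 2L) stop("segment needs at least 2 samples", call. = FALSE)
  i <- as.integer(lookahead)
  y <- ts$values
  hi <- min(end - 1L, length(y)) # last sample in segment
  last_t <- min(hi - 1L, length(y) - i)
  if (last_t < start) {
    # segment too short for any lookahead comparison: endpoint difference
    return(if (abs(y[hi] - y[start]) > threshold) "slope" else "plateau")
  }
  tt <- start:last_t
  d <- abs(y[tt] - y[tt + i])
  if (stats::median(d) > threshold) "slope" else "plateau"
}
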