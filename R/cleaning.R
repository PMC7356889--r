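#' Estimate the noise standard deviation of a sensor signal
#'
#' The noise scale drives both the spike-removal slope threshold and the
#' default step-detection threshold. It is estimated from first differences:
#' for a signal that is locally constant plus i.i.d. noise of standard
#' deviation sigma, successive differences have standard deviation
#' sigma * sqrt(2). The robust estimator (default) takes
#' `1.4826 * median(|d - median(d)|) / sqrt(2)` of the differences `d`, which
#' ignores the small fraction of samples lying on ramps or spikes; the
#' classical estimator uses `sd(d) / sqrt(2)`.
#'
#' @param ts An [fff_ts()] time series (length >= 3).
#' @param estimator `"mad_of_differences"` (robust, default) or
#'   `"std_of_differences"`.
#' @return Non-negative noise sigma in the signal's units. A constant series
#'   yields 0.
#' @export
estimate_noise_sigma <- function(ts,
                                 estimator = c("mad_of_differences",
                                               "std_of_differences")) {
  estimator <- match.arg(estimator)
  if (length(ts$times) < 3L) {
    stop("need at least 3 samples to estimate noise", call. = FALSE)
  }
  d <- diff(ts$values)
  if (estimator == "mad_of_differences") {
    stats::mad(d, constant = 1.4826) / sqrt(2)
  } else {
    stats::sd(d) / sqrt(2)
  }
}

#' Cleaning configuration
#'
#' Thresholds for the two sensor-artifact cleaners. When
#' `spike_slope_threshold` is `NULL` it defaults, per series, to
#' `10 * estimate_noise_sigma(ts) / median(diff(times))` -- justified for
#' signals whose process slope is very low compared to artifact slopes (the
#' weight signal of a slow filtration).
#'
#' @param spike_slope_threshold Slope magnitude (value units per second)
#'   above which an excursion is treated as a spike; `NULL` for the
#'   noise-based default.
#' @param spike_max_duration Maximum spike duration in seconds (default 600).
#' @param terminal_slope_threshold Slope magnitude marking the terminal ramp
#'   of a pressure signal; `NULL` defaults to the same noise-based rule.
#' @param noise_sigma_estimator Passed to [estimate_noise_sigma()].
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(spike_slope_threshold = NULL,
                            spike_max_duration = 600,
                            terminal_slope_threshold = NULL,
                            noise_sigma_estimator = "mad_of_differences") {
  for (v in c(spike_slope_threshold, spike_max_duration,
              terminal_slope_threshold)) {
    if (!is.null(v) && (!is.finite(v) || v <= 0)) {
      stop("cleaning thresholds must be positive", call. = FALSE)
    }
  }
  structure(list(spike_slope_threshold = spike_slope_threshold,
                 spike_max_duration = spike_max_duration,
                 terminal_slope_threshold = terminal_slope_threshold,
                 noise_sigma_estimator = noise_sigma_estimator),
            class = "cleaning_config")
}

# Per-sample slope via centered difference over a 3-sample window (one-sided
# at the ends). A single noisy sample then perturbs two slope estimates only
# mildly, which avoids spurious triggers.
local_slope <- function(times, values) {
  n <- length(values)
  s <- numeric(n)
  if (n >= 3L) {
    idx <- 2:(n - 1L)
    s[idx] <- (values[idx + 1L] - values[idx - 1L]) /
      (times[idx + 1L] - times[idx - 1L])
  }
  s[1L] <- (values[2L] - values[1L]) / (times[2L] - times[1L])
  s[n] <- (values[n] - values[n - 1L]) / (times[n] - times[n - 1L])
  s
}

# Backward 3-sample window slope (one-sided at the start).
backward_slope <- function(times, values) {
  n <- length(values)
  s <- numeric(n)
  if (n >= 3L) {
    idx <- 3:n
    s[idx] <- (values[idx] - values[idx - 2L]) / (times[idx] - times[idx - 2L])
  }
  s[2L] <- (values[2L] - values[1L]) / (times[2L] - times[1L])
  s[1L] <- 0
  s
}

default_slope_threshold <- function(ts, cfg) {
  sig <- estimate_noise_sigma(ts, cfg$noise_sigma_estimator)
  dt <- stats::median(diff(ts$times))
  thr <- 10 * sig / dt
  if (thr <= 0) thr <- .Machine$double.eps
  thr
}

new_cleaning_report <- function(regions, samples_removed) {
  structure(list(samples_removed = samples_removed, regions = regions),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d samples removed in %d region(s)\n",
              x$samples_removed, nrow(x$regions)))
  invisible(x)
}

#' Remove the terminal ramp of a pressure signal
#'
#' At the end of sterile filtration the applied pressure rises sharply; the
#' resulting terminal peak is process-typical but irrelevant for monitoring
#' and would dominate downstream features. Scanning backward from the series
#' end (interior ramps are never touched), the last maximal contiguous suffix
#' whose local slope magnitude exceeds the threshold is truncated. A series
#' with no such suffix is returned unchanged.
#'
#' @param ts An [fff_ts()] series (typically SF2, applied pressure).
#' @param cfg A [cleaning_config()].
#' @return A list with elements `ts` (cleaned series) and `report`
#'   (a `cleaning_report`).
#' @export
remove_terminal_slope <- function(ts, cfg = cleaning_config()) {
  thr <- cfg$terminal_slope_threshold
  if (is.null(thr)) thr <- default_slope_threshold(ts, cfg)
  # backward-looking 3-sample slope: the scan runs from the end and must not
  # bleed across the ramp onset into the flat prefix
  s <- backward_slope(ts$times, ts$values)
  n <- length(s)
  m <- n
  while (m >= 1L && abs(s[m]) > thr) m <- m - 1L
  # suffix (m+1):n exceeds the threshold; m == n means nothing to remove
  if (m == n) {
    return(list(ts = ts, report = new_cleaning_report(
      data.frame(start_time = numeric(), end_time = numeric(),
                 reason = character()), 0L)))
  }
  if (m < 2L) {
    stop("terminal-slope truncation would leave fewer than 2 samples",
         call. = FALSE)
  }
  removed <- n - m
  regions <- data.frame(start_time = ts$times[m + 1L], end_time = ts$times[n],
                        reason = "terminal_slope", stringsAsFactors = FALSE)
  list(ts = ts_subset(ts, seq_len(m)),
       report = new_cleaning_report(regions, removed))
}

#' Remove operator-induced spikes from a signal
#'
#' The weight signal of a slow filtration should decrease slowly; personnel
#' stepping on the scale produces short excursions with slopes far above any
#' process slope. Samples whose local slope magnitude exceeds
#' `spike_slope_threshold` mark an excursion; each excursion is anchored at
#' the last sample before it (`base`), extended forward until the signal
#' returns within `3 * sigma` of `base` or `spike_max_duration` elapses, and
#' the enclosed samples are deleted (never interpolated -- no values are
#' invented). The cleaned series is a subsequence of the input.
#'
#' @param ts An [fff_ts()] series (typically SF3, product weight).
#' @param cfg A [cleaning_config()].
#' @return A list with elements `ts` and `report` as in
#'   [remove_terminal_slope()].
#' @export
remove_spikes <- function(ts, cfg = cleaning_config()) {
  thr <- cfg$spike_slope_threshold
  if (is.null(thr)) thr <- default_slope_threshold(ts, cfg)
  sigma <- estimate_noise_sigma(ts, cfg$noise_sigma_estimator)
  band <- 3 * sigma
  if (band <= 0) band <- .Machine$double.eps
  s <- local_slope(ts$times, ts$values)
  n <- length(s)
  keep <- rep(TRUE, n)
  regions <- list()
  t0 <- 2L
  while (t0 <= n) {
    if (!(abs(s[t0]) > thr) || !keep[t0]) {
      t0 <- t0 + 1L
      next
    }
    base_idx <- max(which(keep[seq_len(t0 - 1L)]))
    base <- ts$values[base_idx]
    # onset: first sample at/after the trigger that actually left the band
    st <- t0
    while (st <= n && abs(ts$values[st] - base) <= band) st <- st + 1L
    if (st > n) {
      t0 <- t0 + 1L
      next
    }
    en <- st
    while (en <= n && abs(ts$values[en] - base) > band &&
           (ts$times[en] - ts$times[st]) <= cfg$spike_max_duration) {
      en <- en + 1L
    }
    keep[st:(en - 1L)] <- FALSE
    regions[[length(regions) + 1L]] <- data.frame(
      start_time = ts$times[st], end_time = ts$times[en - 1L],
      reason = "spike", stringsAsFactors = FALSE)
    t0 <- en + 1L
  }
  removed <- sum(!keep)
  if (removed > 0.5 * n) {
    stop("spike removal would delete more than half of the samples; ",
         "spike_slope_threshold appears misconfigured", call. = FALSE)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(start_time = numeric(), end_time = numeric(),
               reason = character())
  out <- if (removed) ts_subset(ts, which(keep)) else ts
  list(ts = out, report = new_cleaning_report(regions, removed))
}
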