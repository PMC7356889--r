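#' Boundary predicates for rule-based phase setting
#'
#' Some process phases cannot be set from a single signal: their boundaries
#' are defined by conditions over several aligned signals (e.g. "first time
#' the relative difference between the two chamber-vacuum signals falls below
#' 20\%"). Each predicate, evaluated against a batch, yields one boundary
#' time in seconds. Signals compared pointwise are brought onto the union of
#' their time grids by linear interpolation of the coarser signal.
#'
#' Available predicates:
#' * `pred_signal_start(signal)` / `pred_signal_end(signal)` -- first / last
#'   sample time of a signal.
#' * `pred_rel_diff_below(signal_a, signal_b, fraction)` -- earliest time
#'   with `|a - b| / max(|a|, |b|) < fraction`. The symmetric denominator
#'   avoids division by near-zero on vacuum signals.
#' * `pred_slope_onset(signal, direction, threshold)` -- earliest slope start
#'   of the given sign (`"up"` or `"down"`) using the step-detector
#'   comparison `|y[t] - y[t+i]| > threshold`; `threshold = NULL` uses
#'   `sigma_mult * estimate_noise_sigma` (default 6, sized for a one-shot
#'   first-crossing detector).
#' * `pred_value_return(signal, ref_phase, ref_which, tolerance_fraction,
#'   window_fraction)` -- the time the signal *returns* to the value it had
#'   at a previously resolved phase boundary: the signal must first leave the
#'   tolerance band around the reference, and the earliest re-entry is
#'   accepted if, within a window of `window_fraction` of the signal span, it
#'   either stays in the band or crosses the reference (debouncing against
#'   transient noise excursions).
#' * `pred_phase_boundary(phase_name, which)` -- start or end of an already
#'   resolved phase (run-order discipline: only phases with smaller run
#'   order may be referenced).
#'
#' @param signal,signal_a,signal_b Signal names present in the batch.
#' @param fraction,tolerance_fraction Relative tolerance in (0, 1).
#' @param direction `"up"` or `"down"`.
#' @param threshold Detection threshold (value units) or `NULL`.
#' @param lookahead Sample offset of the slope detector.
#' @param ref_phase,phase_name Name of an already resolved phase.
#' @param ref_which,which `"start"` or `"end"`.
#' @param window_fraction Debounce window as a fraction of the signal span
#'   (default 0.1).
#' @return An object of class `phase_predicate`.
#' @name phase_predicates
NULL

new_predicate <- function(type, args) {
  structure(c(list(type = type), args), class = "phase_predicate")
}

#' @rdname phase_predicates
#' @export
pred_signal_start <- function(signal) new_predicate("signal_start",
                                                    list(signal = signal))

#' @rdname phase_predicates
#' @export
pred_signal_end <- function(signal) new_predicate("signal_end",
                                                  list(signal = signal))

#' @rdname phase_predicates
#' @export
pred_rel_diff_below <- function(signal_a, signal_b, fraction) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  new_predicate("rel_diff_below", list(signal_a = signal_a,
                                       signal_b = signal_b,
                                       fraction = fraction))
}

#' @rdname phase_predicates
#' @export
pred_slope_onset <- function(signal, direction = c("up", "down"),
                             threshold = NULL, lookahead = 3L,
                             sigma_mult = 6) {
  direction <- match.arg(direction)
  new_predicate("slope_onset", list(signal = signal, direction = direction,
                                    threshold = threshold,
                                    lookahead = as.integer(lookahead),
                                    sigma_mult = sigma_mult))
}

#' @rdname phase_predicates
#' @export
pred_value_return <- function(signal, ref_phase, ref_which = c("start", "end"),
                              tolerance_fraction = 0.05,
                              window_fraction = 0.1) {
  ref_which <- match.arg(ref_which)
  if (tolerance_fraction <= 0 || tolerance_fraction >= 1) {
    stop("tolerance_fraction must be in (0, 1)", call. = FALSE)
  }
  if (window_fraction <= 0) stop("window_fraction must be > 0", call. = FALSE)
  new_predicate("value_return", list(signal = signal, ref_phase = ref_phase,
                                     ref_which = ref_which,
                                     tolerance_fraction = tolerance_fraction,
                                     window_fraction = window_fraction))
}

#' @rdname phase_predicates
#' @export
pred_phase_boundary <- function(phase_name, which = c("start", "end")) {
  which <- match.arg(which)
  new_predicate("phase_boundary", list(phase_name = phase_name,
                                       which = which))
}

get_signal <- function(batch, name) {
  ts <- batch$series[[name]]
  if (is.null(ts)) {
    stop("signal '", name, "' not present in batch ", batch$lot_id,
         call. = FALSE)
  }
  ts
}

#' Evaluate a boundary predicate against a batch
#'
#' @param pred A predicate from [phase_predicates].
#' @param batch An [fff_batch()].
#' @param resolved_phases Named list of already resolved phases (each a list
#'   with `start_time`, `end_time`), for `phase_boundary` and `value_return`
#'   references.
#' @param t_from Earliest admissible boundary time (used when a rule's end
#'   must lie after its start); default `-Inf`.
#' @return The boundary time in seconds.
#' @export
evaluate_predicate <- function(pred, batch, resolved_phases = list(),
                               t_from = -Inf) {
  fail <- function(msg) {
    stop("predicate '", pred$type, "' not satisfied: ", msg, call. = FALSE)
  }
  switch(pred$type,
    signal_start = get_signal(batch, pred$signal)$times[1L],
    signal_end = {
      ts <- get_signal(batch, pred$signal)
      ts$times[length(ts$times)]
    },
    rel_diff_below = {
      a <- get_signal(batch, pred$signal_a)
      b <- get_signal(batch, pred$signal_b)
      grid <- sort(unique(c(a$times, b$times)))
      grid <- grid[grid >= max(a$times[1L], b$times[1L], t_from) &
                   grid <= min(max(a$times), max(b$times))]
      va <- ts_interp(a, grid)
      vb <- ts_interp(b, grid)
      rel <- abs(va - vb) / pmax(abs(va), abs(vb), .Machine$double.eps)
      hit <- which(rel < pred$fraction)
      if (!length(hit)) fail(paste0("|", pred$signal_a, " - ", pred$signal_b,
                                    "| never below ", pred$fraction,
                                    " relative"))
      grid[hit[1L]]
    },
    slope_onset = {
      ts <- get_signal(batch, pred$signal)
      i <- pred$lookahead
      thr <- pred$threshold
      if (is.null(thr)) {
        # a one-shot first-crossing detector needs a wider noise margin
        # than the segmentation scan: with sigma_mult = 6 a false onset
        # over a few hundred comparisons is a sub-percent event
        thr <- (pred$sigma_mult %||% 6) * estimate_noise_sigma(ts)
        if (thr <= 0) thr <- .Machine$double.eps
      }
      n <- length(ts$values)
      dlt <- ts$values[seq_len(n - i) + i] - ts$values[seq_len(n - i)]
      ok <- if (pred$direction == "up") dlt > thr else dlt < -thr
      ok <- ok & ts$times[seq_len(n - i)] >= t_from
      if (!any(ok)) fail(paste0("no ", pred$direction, "ward slope onset in ",
                                pred$signal))
      ts$times[which(ok)[1L]]
    },
    value_return = {
      ts <- get_signal(batch, pred$signal)
      ref_ph <- resolved_phases[[pred$ref_phase]]
      if (is.null(ref_ph)) fail(paste0("reference phase '", pred$ref_phase,
                                       "' not resolved"))
      t_ref <- ref_ph[[paste0(pred$ref_which, "_time")]]
      ref <- ts_interp(ts, t_ref)
      tolv <- pred$tolerance_fraction * max(abs(ref), .Machine$double.eps)
      span <- max(ts$times) - ts$times[1L]
      window <- pred$window_fraction * span
      idx <- which(ts$times >= max(t_ref, t_from))
      tt <- ts$times[idx]
      dev <- ts$values[idx] - ref
      dep <- which(abs(dev) > tolv)[1L]   # departure from the band
      if (is.na(dep)) fail("signal never leaves the reference band")
      dep_sign <- sign(dev[dep])
      # earliest re-entry into the band; the piecewise-linear signal is
      # interpolated so a steep ramp that skips the band between samples
      # still yields its crossing time
      j <- dep
      while (j < length(dev)) {
        j <- j + 1L
        if (abs(dev[j - 1L]) <= tolv) next
        entered <- abs(dev[j]) <= tolv
        crossed_band <- sign(dev[j]) != sign(dev[j - 1L])
        if (!entered && !crossed_band) next
        target <- sign(dev[j - 1L]) * tolv
        t_c <- if (entered && dev[j] == dev[j - 1L]) tt[j] else
          tt[j - 1L] + (tt[j] - tt[j - 1L]) *
            (dev[j - 1L] - target) / (dev[j - 1L] - dev[j])
        # debounce: within the window the signal must stay in the band or
        # cross the reference (transient blips are rejected)
        w <- which(tt >= t_c & tt <= t_c + window)
        ok <- crossed_band ||
          (length(w) && (abs(dev[w[length(w)]]) <= tolv ||
                         any(sign(dev[w]) == -dep_sign & dev[w] != 0)))
        if (ok) return(t_c)
      }
      fail("signal never returns to the reference value")
    },
    phase_boundary = {
      ph <- resolved_phases[[pred$phase_name]]
      if (is.null(ph)) fail(paste0("phase '", pred$phase_name,
                                   "' not resolved"))
      ph[[paste0(pred$which, "_time")]]
    },
    stop("unknown predicate type '", pred$type, "'", call. = FALSE)
  )
}

#' Construct a rule set for multi-signal phase setting
#'
#' @param rules List of rules, each created by [phase_rule()].
#' @return An object of class `phase_ruleset`.
#' @export
phase_ruleset <- function(rules) {
  orders <- vapply(rules, function(r) r$run_order, numeric(1))
  if (anyDuplicated(orders)) {
    stop("run_order must be unique within a rule set", call. = FALSE)
  }
  names(rules) <- vapply(rules, function(r) r$phase_name, character(1))
  structure(list(rules = rules), class = "phase_ruleset")
}

#' @param phase_name Name of the phase the rule sets.
#' @param run_order Positive integer; rules are evaluated in ascending run
#'   order, so a rule may reference boundaries of phases with smaller run
#'   order only.
#' @param start_predicate,end_predicate Predicates from [phase_predicates].
#' @param target_signal Signal whose index grid the resulting phase is
#'   expressed on.
#' @rdname phase_ruleset
#' @export
phase_rule <- function(phase_name, run_order, start_predicate, end_predicate,
                       target_signal) {
  if (run_order < 1) stop("run_order must be positive", call. = FALSE)
  structure(list(phase_name = phase_name, run_order = as.integer(run_order),
                 start_predicate = start_predicate,
                 end_predicate = end_predicate,
                 target_signal = target_signal),
            class = "phase_rule")
}

#' The bundled lyophilization phase rule set
#'
#' Encodes the four LP-Phases used to monitor the chamber-vacuum signal LP4
#' in detail, with their run order (2, 1, 3, 4):
#' * **LP-Phase 2** (run order 1): starts at the first time the relative
#'   difference between LP3 and LP4 falls below 20\%; ends at the increasing
#'   slope of LP1.
#' * **LP-Phase 1** (run order 2): from the start of LP4 to the start of
#'   LP-Phase 2.
#' * **LP-Phase 3** (run order 3): from the end of LP-Phase 2 until LP4
#'   returns to the value it had at the beginning of LP-Phase 2 (within a
#'   tolerance band, debounced over a time window).
#' * **LP-Phase 4** (run order 4): from the end of LP-Phase 3 to the end of
#'   LP4.
#'
#' @param rel_diff_fraction Trigger fraction for the LP3/LP4 relative
#'   difference (default 0.2).
#' @param tolerance_fraction,window_fraction Passed to
#'   [pred_value_return()] for the LP-Phase 3 end condition.
#' @return A [phase_ruleset()].
#' @export
lp_phase_ruleset <- function(rel_diff_fraction = 0.2,
                             tolerance_fraction = 0.05,
                             window_fraction = 0.1) {
  phase_ruleset(list(
    phase_rule("LP-Phase 2", run_order = 1L,
               start_predicate = pred_rel_diff_below("LP3", "LP4",
                                                     rel_diff_fraction),
               end_predicate = pred_slope_onset("LP1", "up"),
               target_signal = "LP4"),
    phase_rule("LP-Phase 1", run_order = 2L,
               start_predicate = pred_signal_start("LP4"),
               end_predicate = pred_phase_boundary("LP-Phase 2", "start"),
               target_signal = "LP4"),
    phase_rule("LP-Phase 3", run_order = 3L,
               start_predicate = pred_phase_boundary("LP-Phase 2", "end"),
               end_predicate = pred_value_return(
                 "LP4", "LP-Phase 2", "start",
                 tolerance_fraction = tolerance_fraction,
                 window_fraction = window_fraction),
               target_signal = "LP4"),
    phase_rule("LP-Phase 4", run_order = 4L,
               start_predicate = pred_phase_boundary("LP-Phase 3", "end"),
               end_predicate = pred_signal_end("LP4"),
               target_signal = "LP4")
  ))
}

#' Apply a rule set to a batch
#'
#' Rules are evaluated in ascending run order, each producing one phase on
#' its target signal; declaration order is irrelevant. Predicate failures
#' flag the batch and return the phases resolved so far together with a
#' failure report.
#'
#' @param ruleset A [phase_ruleset()].
#' @param batch An [fff_batch()].
#' @return A list with `phases` (data frame in chronological order with
#'   `label`, `kind = "rule"`, `start_time`, `end_time`, `start_index`,
#'   `end_index` on the target signal, `duration_seconds`, `target_signal`),
#'   `ok` (logical) and `failures` (character vector of failed rules).
#' @export
apply_ruleset <- function(ruleset, batch) {
  rules <- ruleset$rules[order(vapply(ruleset$rules,
                                      function(r) r$run_order, integer(1)))]
  resolved <- list()
  failures <- character()
  for (r in rules) {
    res <- tryCatch({
      t_start <- evaluate_predicate(r$start_predicate, batch, resolved)
      t_end <- evaluate_predicate(r$end_predicate, batch, resolved,
                                  t_from = t_start)
      if (!(t_start < t_end)) {
        stop("phase '", r$phase_name, "': start time ", t_start,
             " not before end time ", t_end, call. = FALSE)
      }
      list(start_time = t_start, end_time = t_end)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(r$phase_name, ": ",
                                     conditionMessage(res)))
      next
    }
    resolved[[r$phase_name]] <- res
  }
  rows <- lapply(names(resolved), function(nm) {
    r <- rules[[nm]]
    ph <- resolved[[nm]]
    ts <- batch$series[[r$target_signal]]
    si <- which(ts$times >= ph$start_time)[1L]
    ei <- which(ts$times >= ph$end_time)[1L]
    if (is.na(ei)) ei <- length(ts$times) + 1L
    data.frame(label = nm, kind = "rule",
               start_index = si, end_index = ei,
               start_time = ph$start_time, end_time = ph$end_time,
               duration_seconds = ph$end_time - ph$start_time,
               target_signal = r$target_signal, stringsAsFactors = FALSE)
  })
  phases <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), kind = character(),
               start_index = integer(), end_index = integer(),
               start_time = numeric(), end_time = numeric(),
               duration_seconds = numeric(), target_signal = character())
  phases <- phases[order(phases$start_time), , drop = FALSE]
  rownames(phases) <- NULL
  list(phases = phases, ok = length(failures) == 0L, failures = failures)
}
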