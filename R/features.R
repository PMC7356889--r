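#' Feature specifications
#'
#' A feature spec names one scalar to extract from one phase of one signal.
#' Statistics: `mean`, `min`, `max` on any phase; `plateau_std` (sample
#' standard deviation) on plateau phases only; `slope_residual_rmse`
#' (root-mean-square residual of an ordinary least-squares line of value on
#' time) on slope phases only; `duration_seconds` on any phase. Feature names
#' are canonical: `<signal>|<phase>|<statistic>`.
#'
#' @param signal_name Signal the phase lives on.
#' @param phase_label Label of the phase within that signal's segmentation.
#' @param statistic One of the statistics above.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(signal_name, phase_label,
                         statistic = c("mean", "min", "max", "plateau_std",
                                       "slope_residual_rmse",
                                       "duration_seconds")) {
  statistic <- match.arg(statistic)
  structure(list(signal_name = signal_name, phase_label = phase_label,
                 statistic = statistic), class = "feature_spec")
}

feature_name <- function(spec) {
  paste(spec$signal_name, spec$phase_label, spec$statistic, sep = "|")
}

compute_statistic <- function(ts, phase_row, statistic) {
  n <- length(ts$values)
  idx <- phase_row$start_index:min(phase_row$end_index - 1L, n)
  if (statistic == "duration_seconds") return(phase_row$duration_seconds)
  if (length(idx) < 2L) return(NA_real_)
  v <- ts$values[idx]
  switch(statistic,
    mean = mean(v),
    min = min(v),
    max = max(v),
    plateau_std = stats::sd(v),
    slope_residual_rmse = {
      tt <- ts$times[idx]
      fit <- stats::lm.fit(cbind(1, tt), v)
      sqrt(mean(fit$residuals^2))
    })
}

#' Extract per-phase features from one signal
#'
#' @param ts An [fff_ts()] series.
#' @param phases Data frame of phases for this signal (from
#'   [detect_step_phases()]`$phases` or [apply_ruleset()]`$phases`), with
#'   columns `label`, `kind`, `start_index`, `end_index`,
#'   `duration_seconds`.
#' @param specs List of [feature_spec()] objects for this signal. Statistic
#'   admissibility is enforced: `plateau_std` requires a plateau (or rule)
#'   phase, `slope_residual_rmse` a slope (or rule) phase.
#' @return Named numeric vector; a phase with fewer than 2 samples yields
#'   `NA` for its sample statistics.
#' @export
extract_phase_features <- function(ts, phases, specs) {
  out <- numeric(0)
  for (sp in specs) {
    nm <- feature_name(sp)
    row <- phases[phases$label == sp$phase_label, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("phase '", sp$phase_label, "' not found (or ambiguous) for signal ",
           ts$signal_name, call. = FALSE)
    }
    kind <- row$kind[1L]
    if (sp$statistic == "plateau_std" && kind == "slope") {
      stop("plateau_std requested on slope phase '", sp$phase_label, "'",
           call. = FALSE)
    }
    if (sp$statistic == "slope_residual_rmse" && kind == "plateau") {
      stop("slope_residual_rmse requested on plateau phase '",
           sp$phase_label, "'", call. = FALSE)
    }
    out[nm] <- compute_statistic(ts, row[1L, ], sp$statistic)
  }
  out
}

#' Build the lot-by-feature matrix
#'
#' Concatenates the features extracted from segmented time series with the
#' single-point quality-database features into one numeric matrix, one row
#' per batch. Column order is deterministic: extracted features sorted by
#' signal, phase, statistic, then QDB features in table order. Per-column
#' provenance (`extracted` vs `qdb`, signal, phase, statistic) is kept in the
#' `"provenance"` attribute.
#'
#' @param batches List of [fff_batch()] objects.
#' @param segmentations Named list: lot_id -> named list (signal ->
#'   [detect_step_phases()] result or bare phase data frame).
#' @param rule_phases Named list: lot_id -> [apply_ruleset()] result (or bare
#'   phase data frame) for rule-based phases.
#' @param specs List of [feature_spec()] objects applied to every lot.
#' @return A numeric matrix of class `feature_matrix` with lot row names and
#'   attributes `provenance` (data frame) and `units`.
#' @export
build_feature_matrix <- function(batches, segmentations = list(),
                                 rule_phases = list(), specs = list()) {
  specs <- specs[order(vapply(specs, feature_name, character(1)))]
  ext_names <- vapply(specs, feature_name, character(1))
  if (anyDuplicated(ext_names)) {
    stop("duplicate feature specs", call. = FALSE)
  }
  qdb_names <- unique(unlist(lapply(batches,
                                    function(b) names(b$qdb$features))))
  all_names <- c(ext_names, qdb_names)
  lots <- vapply(batches, function(b) b$lot_id, character(1))
  X <- matrix(NA_real_, nrow = length(batches), ncol = length(all_names),
              dimnames = list(lots, all_names))
  for (bi in seq_along(batches)) {
    b <- batches[[bi]]
    phase_tab <- collect_phases(b, segmentations[[b$lot_id]],
                                rule_phases[[b$lot_id]])
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      ts <- b$series[[sp$signal_name]]
      ph <- phase_tab[[sp$signal_name]]
      if (is.null(ts) || is.null(ph)) next  # missing source stays NA
      row <- ph[ph$label == sp$phase_label, , drop = FALSE]
      if (nrow(row) != 1L) next
      X[bi, ext_names[si]] <- compute_statistic(ts, row[1L, ], sp$statistic)
    }
    fv <- b$qdb$features
    if (length(fv)) X[bi, names(fv)] <- fv
  }
  prov <- data.frame(
    name = all_names,
    source = c(rep("extracted", length(ext_names)),
               rep("qdb", length(qdb_names))),
    signal = c(vapply(specs, function(s) s$signal_name, character(1)),
               rep(NA_character_, length(qdb_names))),
    phase = c(vapply(specs, function(s) s$phase_label, character(1)),
              rep(NA_character_, length(qdb_names))),
    statistic = c(vapply(specs, function(s) s$statistic, character(1)),
                  rep(NA_character_, length(qdb_names))),
    stringsAsFactors = FALSE)
  structure(X, provenance = prov, class = c("feature_matrix", "matrix",
                                            "array"))
}

# Merge step segmentations and rule phases of one batch into one
# signal -> phase-table map.
collect_phases <- function(batch, segs, rules) {
  out <- list()
  for (nm in names(segs)) {
    s <- segs[[nm]]
    out[[nm]] <- if (inherits(s, "step_segmentation")) s$phases else s
  }
  rp <- if (!is.null(rules) && !is.data.frame(rules)) rules$phases else rules
  if (!is.null(rp) && nrow(rp)) {
    for (sg in unique(rp$target_signal)) {
      add <- rp[rp$target_signal == sg, , drop = FALSE]
      out[[sg]] <- if (is.null(out[[sg]])) add else rbind(
        out[[sg]][, c("label", "kind", "start_index", "end_index",
                      "start_time", "end_time", "duration_seconds")],
        add[, c("label", "kind", "start_index", "end_index", "start_time",
                "end_time", "duration_seconds")])
    }
  }
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<feature_matrix> %d lots x %d features (%d extracted, %d qdb)",
              nrow(x), ncol(x), sum(prov$source == "extracted"),
              sum(prov$source == "qdb")))
  nmiss <- sum(is.na(x))
  if (nmiss) cat(sprintf(", %d missing entries", nmiss))
  cat("\n")
  invisible(x)
}

#' Drop zero-variance feature columns
#'
#' Features without variance within the lots carry no monitoring
#' information and break column scaling; exactly the columns whose
#' non-missing values are all equal are removed.
#'
#' @param fm A [build_feature_matrix()] result.
#' @return The reduced `feature_matrix` with attribute `removed_columns`
#'   naming the dropped columns. Idempotent. Errors when nothing would
#'   remain.
#' @export
drop_zero_variance <- function(fm) {
  const <- vapply(seq_len(ncol(fm)), function(j) {
    v <- fm[, j]
    v <- v[!is.na(v)]
    length(v) == 0L || all(v == v[1L])
  }, logical(1))
  if (all(const)) stop("all feature columns are constant", call. = FALSE)
  removed <- colnames(fm)[const]
  out <- fm[, !const, drop = FALSE]
  prov <- attr(fm, "provenance")
  attributes(out) <- c(attributes(out),
                       list(provenance = prov[!const, , drop = FALSE],
                            removed_columns = removed))
  class(out) <- class(fm)
  out
}

#' Scale feature columns to equal weight
#'
#' Brings every feature onto a common scale so the multivariate model weighs
#' all features equally. `"robust"` (default) centers by the median and
#' scales by the MAD, keeping the scaling itself outlier-resistant;
#' `"classical"` uses mean and standard deviation. Columns whose MAD is zero
#' fall back to classical scaling (logged in the `"fallback_columns"`
#' attribute). Run after [drop_zero_variance()].
#'
#' @param fm A `feature_matrix`.
#' @param method `"robust"` or `"classical"`.
#' @return The scaled `feature_matrix` with attributes `centers`, `scales`,
#'   `scaling_method`, `fallback_columns`.
#' @export
scale_features <- function(fm, method = c("robust", "classical")) {
  method <- match.arg(method)
  centers <- numeric(ncol(fm))
  scales <- numeric(ncol(fm))
  fallback <- character()
  for (j in seq_len(ncol(fm))) {
    v <- fm[, j]
    if (method == "robust") {
      ctr <- stats::median(v, na.rm = TRUE)
      scl <- stats::mad(v, constant = 1.4826, na.rm = TRUE)
      if (scl == 0) {
        fallback <- c(fallback, colnames(fm)[j])
        ctr <- mean(v, na.rm = TRUE)
        scl <- stats::sd(v, na.rm = TRUE)
      }
    } else {
      ctr <- mean(v, na.rm = TRUE)
      scl <- stats::sd(v, na.rm = TRUE)
    }
    if (!is.finite(scl) || scl == 0) {
      stop("column '", colnames(fm)[j], "' has zero scale; run ",
           "drop_zero_variance() first", call. = FALSE)
    }
    centers[j] <- ctr
    scales[j] <- scl
  }
  out <- sweep(sweep(fm, 2L, centers, "-"), 2L, scales, "/")
  attributes(out) <- c(attributes(out),
                       list(provenance = attr(fm, "provenance"),
                            centers = stats::setNames(centers, colnames(fm)),
                            scales = stats::setNames(scales, colnames(fm)),
                            scaling_method = method,
                            fallback_columns = fallback))
  class(out) <- class(fm)
  out
}

#' Undo feature scaling
#'
#' @param fm A matrix scaled by [scale_features()].
#' @return The matrix on the original scale.
#' @export
unscale_features <- function(fm) {
  centers <- attr(fm, "centers")
  scales <- attr(fm, "scales")
  if (is.null(centers)) stop("matrix carries no scaling info", call. = FALSE)
  out <- sweep(sweep(fm, 2L, scales, "*"), 2L, centers, "+")
  attr(out, "centers") <- NULL
  attr(out, "scales") <- NULL
  out
}

#' Prepare a feature matrix for multivariate modelling
#'
#' Convenience wrapper: drops columns with more than `max_missing_fraction`
#' missing entries (with a warning), imputes remaining missing entries by
#' the column median (the robust model requires complete data), drops
#' zero-variance columns and scales.
#'
#' @param fm A `feature_matrix`.
#' @param method Scaling method, see [scale_features()].
#' @param max_missing_fraction Columns with a larger missing fraction are
#'   dropped (default 0.2).
#' @return A complete, scaled `feature_matrix`.
#' @export
prepare_feature_matrix <- function(fm, method = "robust",
                                   max_missing_fraction = 0.2) {
  miss <- colMeans(is.na(fm))
  if (any(miss > max_missing_fraction)) {
    bad <- colnames(fm)[miss > max_missing_fraction]
    warning("dropping ", length(bad), " column(s) with > ",
            round(100 * max_missing_fraction), "% missing values: ",
            paste(utils::head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ..." else "", call. = FALSE)
    prov <- attr(fm, "provenance")
    keep <- miss <= max_missing_fraction
    fm2 <- fm[, keep, drop = FALSE]
    attr(fm2, "provenance") <- prov[keep, , drop = FALSE]
    class(fm2) <- class(fm)
    fm <- fm2
  }
  for (j in seq_len(ncol(fm))) {
    v <- fm[, j]
    if (anyNA(v)) fm[is.na(v), j] <- stats::median(v, na.rm = TRUE)
  }
  scale_features(drop_zero_variance(fm), method = method)
}
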