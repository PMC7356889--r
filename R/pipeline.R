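#' Pipeline configuration
#'
#' Assembles and validates the configuration of the five-step monitoring
#' pipeline (alignment, cleaning, phase setting, feature extraction,
#' multivariate analysis). Input is either a synthetic [campaign_spec()] or
#' the three source files. Unknown keys are rejected.
#'
#' @param synthetic A [campaign_spec()], or `NULL` to read from files.
#' @param qdb_path,lyo_path,sf_stream_path Source files (long-layout
#'   lyophilization table, absolutely-timestamped filtration stream), used
#'   when `synthetic` is `NULL`.
#' @param cleaning Named list mapping signal names to cleaners
#'   (`"terminal"` or `"spikes"`); default SF2 terminal, SF3 spikes.
#' @param step_signals Signals segmented with the step-phase detector.
#' @param step_cfg A [step_config()] applied to the step signals.
#' @param ruleset A [phase_ruleset()] (default the bundled lyophilization
#'   rule set) or `NULL` to skip rule phases.
#' @param feature_specs List of [feature_spec()]; `NULL` for the default
#'   roster (see [default_feature_specs()]).
#' @param scaling `"robust"` or `"classical"` column scaling.
#' @param k,variance_target,alpha,quantile Passed to [robpca()].
#' @param run_cpca Also fit the classical-PCA comparison (default TRUE).
#' @param seed Seed for every stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, qdb_path = NULL,
                            lyo_path = NULL, sf_stream_path = NULL,
                            cleaning = list(SF2 = "terminal", SF3 = "spikes"),
                            step_signals = c("LP2", "LP5", "LP6", "LP7"),
                            step_cfg = default_step_config(),
                            ruleset = lp_phase_ruleset(),
                            feature_specs = NULL,
                            scaling = "robust", k = NULL,
                            variance_target = 0.80, alpha = 0.75,
                            quantile = 0.975, run_cpca = TRUE, seed = 1L) {
  if (is.null(synthetic) &&
      (is.null(qdb_path) || is.null(lyo_path) || is.null(sf_stream_path))) {
    stop("either a synthetic campaign spec or all three source paths are ",
         "required", call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "campaign_spec")) {
    stop("`synthetic` must be a campaign_spec", call. = FALSE)
  }
  bad <- setdiff(unlist(cleaning), c("terminal", "spikes"))
  if (length(bad)) stop("unknown cleaner(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(synthetic = synthetic, qdb_path = qdb_path,
                 lyo_path = lyo_path, sf_stream_path = sf_stream_path,
                 cleaning = cleaning, step_signals = step_signals,
                 step_cfg = step_cfg, ruleset = ruleset,
                 feature_specs = feature_specs, scaling = scaling, k = k,
                 variance_target = variance_target, alpha = alpha,
                 quantile = quantile, run_cpca = run_cpca,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default feature roster
#'
#' Mirrors the study's extraction plan: per step-segmented signal, mean /
#' min / max on every phase plus the plateau standard deviation and the
#' slope residual RMSE (4 plateaus and 3 slopes yield 28 features per
#' signal); per rule phase on LP4, duration, mean, min, max; plus the
#' overall mean and maximum of the cleaned SF2 pressure. With the four
#' default step signals this yields 130 extracted features.
#'
#' @param step_signals Step-segmented signal names.
#' @param n_plateaus,n_slopes Expected phase counts per step signal.
#' @return List of [feature_spec()] objects.
#' @export
default_feature_specs <- function(step_signals = c("LP2", "LP5", "LP6",
                                                   "LP7"),
                                  n_plateaus = 4L, n_slopes = 3L) {
  specs <- list()
  for (sg in step_signals) {
    for (j in seq_len(n_plateaus)) {
      lbl <- paste0("plateau_", j)
      for (st in c("mean", "min", "max", "plateau_std")) {
        specs[[length(specs) + 1L]] <- feature_spec(sg, lbl, st)
      }
    }
    for (j in seq_len(n_slopes)) {
      lbl <- paste0("slope_", j)
      for (st in c("mean", "min", "max", "slope_residual_rmse")) {
        specs[[length(specs) + 1L]] <- feature_spec(sg, lbl, st)
      }
    }
  }
  for (ph in paste("LP-Phase", 1:4)) {
    for (st in c("duration_seconds", "mean", "min", "max")) {
      specs[[length(specs) + 1L]] <- feature_spec("LP4", ph, st)
    }
  }
  specs[[length(specs) + 1L]] <- feature_spec("SF2", "overall", "mean")
  specs[[length(specs) + 1L]] <- feature_spec("SF2", "overall", "max")
  specs
}

whole_signal_phase <- function(ts, label = "overall") {
  n <- length(ts$times)
  data.frame(label = label, kind = "rule", start_index = 1L,
             end_index = n + 1L, start_time = ts$times[1L],
             end_time = ts$times[n],
             duration_seconds = ts$times[n] - ts$times[1L],
             stringsAsFactors = FALSE)
}

#' Run the five-step monitoring pipeline
#'
#' Executes alignment, cleaning, phase setting, feature extraction and
#' robust multivariate analysis in order, writing every artifact (batch
#' manifest, cleaning reports, segmentations, feature matrix, outlier map,
#' contribution table, model JSON, run log) to `out_dir`. Deterministic
#' under a fixed configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created); `NULL` skips writing.
#' @return Invisibly, a list with `batches`, `cleaning_reports`,
#'   `segmentations`, `rule_phases`, `features_raw`, `features` (scaled),
#'   `fit` ([robpca()]), `map` ([outlier_map()]), `contributions`, `cpca`,
#'   and `log` (character vector narrating the steps).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[fffmon] ", msg)
  }

  # -- step 1: data alignment
  if (!is.null(config$synthetic)) {
    say("step 1/5 alignment: generating synthetic campaign (seed %d)",
        config$synthetic$seed)
    campaign <- generate_campaign(config$synthetic)
    batches <- campaign$batches
  } else {
    say("step 1/5 alignment: reading %s", config$qdb_path)
    records <- parse_qdb_table(config$qdb_path)
    lyo <- parse_timeseries_table(config$lyo_path, layout = "long")
    lyo_by_lot <- split(lyo, vapply(lyo, function(s) s$lot_id, character(1)))
    stream <- parse_timeseries_table(config$sf_stream_path, layout = "wide")
    segd <- segment_stream_by_intervals(stream, records)
    batches <- assemble_batches(records, lyo_by_lot, segd$segments)
  }
  say("aligned %d batches", length(batches))

  # -- step 2: data cleaning
  cleaning_reports <- list()
  for (bi in seq_along(batches)) {
    b <- batches[[bi]]
    for (sg in names(config$cleaning)) {
      if (is.null(b$series[[sg]])) next
      res <- switch(config$cleaning[[sg]],
                    terminal = remove_terminal_slope(b$series[[sg]]),
                    spikes = remove_spikes(b$series[[sg]]))
      b$series[[sg]] <- res$ts
      cleaning_reports[[b$lot_id]][[sg]] <- res$report
    }
    batches[[bi]] <- b
  }
  n_rm <- sum(unlist(lapply(cleaning_reports, function(l)
    vapply(l, function(r) r$samples_removed, numeric(1)))))
  say("step 2/5 cleaning: removed %d artifact samples", n_rm)

  # -- step 3: dynamic phase setting
  segmentations <- list()
  rule_phases <- list()
  n_nc <- 0L
  for (b in batches) {
    segs <- list()
    for (sg in intersect(config$step_signals, names(b$series))) {
      seg <- detect_step_phases(b$series[[sg]], config$step_cfg)
      if (!seg$converged) n_nc <- n_nc + 1L
      segs[[sg]] <- seg
    }
    for (sg in names(config$cleaning)) {
      if (!is.null(b$series[[sg]])) {
        segs[[sg]] <- whole_signal_phase(b$series[[sg]])
      }
    }
    segmentations[[b$lot_id]] <- segs
    if (!is.null(config$ruleset)) {
      rp <- apply_ruleset(config$ruleset, b)
      if (!rp$ok) say("lot %s: rule phases incomplete (%s)", b$lot_id,
                      paste(rp$failures, collapse = "; "))
      rule_phases[[b$lot_id]] <- rp
    }
  }
  say("step 3/5 phase setting: %d step segmentations (%d non-converged), %s",
      length(batches) * length(config$step_signals), n_nc,
      if (is.null(config$ruleset)) "no rule set" else "rule phases set")

  # -- step 4: feature extraction
  specs <- config$feature_specs
  if (is.null(specs)) specs <- default_feature_specs(config$step_signals)
  fm <- build_feature_matrix(batches, segmentations, rule_phases, specs)
  fm_red <- prepare_feature_matrix(fm, method = config$scaling)
  say("step 4/5 features: %d x %d matrix (%d extracted + %d qdb), %d after filtering/scaling",
      nrow(fm), ncol(fm), sum(attr(fm, "provenance")$source == "extracted"),
      sum(attr(fm, "provenance")$source == "qdb"), ncol(fm_red))

  # -- step 5: multivariate analysis
  fit <- robpca(fm_red, k = config$k,
                variance_target = config$variance_target,
                alpha = config$alpha, quantile = config$quantile,
                seed = config$seed)
  map <- outlier_map(fit, quantile = config$quantile)
  contrib <- score_contributions(fit, unclass(fm_red))
  cpca <- if (isTRUE(config$run_cpca))
    fit_cpca_diagnostics(unclass(fm_red), k = fit$k) else NULL
  say("step 5/5 robpca: k = %d (%.1f%% variance), %d lot(s) outside the regular quadrant",
      fit$k, 100 * fit$explained_variance_fraction,
      sum(map$quadrant != "regular"))

  result <- list(batches = batches, cleaning_reports = cleaning_reports,
                 segmentations = segmentations, rule_phases = rule_phases,
                 features_raw = fm, features = fm_red, fit = fit, map = map,
                 contributions = contrib, cpca = cpca, log = log)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, config, out_dir)
  invisible(result)
}

write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_batches(result$batches, file.path(out_dir, "batches"))
  rep_json <- lapply(result$cleaning_reports, function(l) {
    lapply(l, function(r) list(samples_removed = r$samples_removed,
                               regions = r$regions))
  })
  jsonlite::write_json(rep_json, file.path(out_dir, "cleaning_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  seg_rows <- list()
  for (lot in names(result$segmentations)) {
    for (sg in names(result$segmentations[[lot]])) {
      s <- result$segmentations[[lot]][[sg]]
      ph <- if (inherits(s, "step_segmentation")) s$phases else s
      ph <- cbind(lot_id = lot, signal = sg, ph)
      seg_rows[[length(seg_rows) + 1L]] <- ph
    }
    rp <- result$rule_phases[[lot]]
    if (!is.null(rp) && nrow(rp$phases)) {
      ph <- cbind(lot_id = lot, signal = rp$phases$target_signal,
                  rp$phases[, c("label", "kind", "start_index", "end_index",
                                "start_time", "end_time",
                                "duration_seconds")])
      seg_rows[[length(seg_rows) + 1L]] <- ph
    }
  }
  utils::write.csv(do.call(rbind, seg_rows),
                   file.path(out_dir, "segmentations.csv"),
                   row.names = FALSE, quote = FALSE)
  fm <- result$features_raw
  utils::write.csv(data.frame(lot_id = rownames(fm), unclass(fm)[,],
                              check.names = FALSE),
                   file.path(out_dir, "feature_matrix.csv"),
                   row.names = FALSE)
  jsonlite::write_json(attr(fm, "provenance"),
                       file.path(out_dir, "feature_provenance.json"),
                       pretty = TRUE)
  utils::write.csv(result$map, file.path(out_dir, "outlier_map.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(lot_id = rownames(result$contributions),
                              result$contributions, check.names = FALSE),
                   file.path(out_dir, "contributions.csv"),
                   row.names = FALSE)
  fit <- result$fit
  jsonlite::write_json(
    list(center = fit$center, loadings = fit$loadings,
         eigenvalues = fit$eigenvalues, k = fit$k, alpha = fit$alpha,
         h = fit$h, quantile = fit$quantile,
         explained_variance_fraction = fit$explained_variance_fraction,
         cutoffs = as.list(fit$cutoffs), seed = fit$seed),
    file.path(out_dir, "robpca_model.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$cpca)) {
    utils::write.csv(result$cpca, file.path(out_dir, "cpca_diagnostics.csv"),
                     row.names = FALSE)
  }
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("config_hash: %s", config_hash(config)),
               result$log),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

# A cheap, dependency-free digest: serialize the config and hash the bytes.
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2L)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 97L)) %%
            .Machine$integer.max)
}

#' Shorthand: simulate a campaign and run the full pipeline on it
#'
#' @param spec A [campaign_spec()].
#' @param out_dir Optional artifact directory.
#' @param ... Overrides passed to [pipeline_config()].
#' @return See [run_pipeline()].
#' @export
simulate_campaign <- function(spec = campaign_spec(), out_dir = NULL, ...) {
  run_pipeline(pipeline_config(synthetic = spec, seed = spec$seed, ...),
               out_dir = out_dir)
}
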