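#' Specification of a synthetic FFF campaign
#'
#' Describes a campaign of lots with known ground truth, emulating the data
#' shape of an industrial formulation/fill/finish process: step-profile
#' lyophilization signals (plateaus joined by sharp ramps) with Gaussian
#' sensor noise, the three-signal sterile-filtration stream (temperature,
#' pressure with an end-of-filtration peak, weight with operator-induced
#' spikes) recorded as one continuous absolutely-timestamped stream with
#' inter-lot gaps, correlated quality-database features, and optional
#' planted abnormal lots. The default campaign mirrors the shape of the
#' motivating 58-lot study: 58 lots, 122 QDB features (a handful constant)
#' and step/rule phases yielding 130 extracted features.
#'
#' Contamination mechanisms (`contamination$mechanism`):
#' * `"noise_inflation"` -- multiply the sensor noise of `target_signal`
#'   (default LP2) by `noise_factor` (default 1.3, the magnitude observed on
#'   abnormal lots in practice);
#' * `"plateau_shift"` -- shift all plateau levels of `target_signal` by
#'   `plateau_delta`;
#' * `"qdb_shift"` -- shift the lot's QDB features along the dominant
#'   direction of the true QDB covariance by `qdb_shift_sd` standard
#'   deviations of that component (an in-model shift, hence a score
#'   outlier).
#'
#' @param n_lots Number of lots (>= 4; default 58).
#' @param lp_dt,sf_dt Sampling periods in seconds of the lyophilization
#'   signals (default 10) and the filtration stream (default 30).
#' @param noise_scale Global multiplier on every sensor noise sigma
#'   (default 1; 0 yields noise-free series).
#' @param n_qdb_features Number of QDB feature columns (default 122).
#' @param n_constant_qdb How many of them are constant setpoint-like columns
#'   (default 5).
#' @param qdb_n_factors Latent factors behind the correlated QDB block
#'   (default 6).
#' @param spike List: `count`, `magnitude` (kg), `duration` (s) of the
#'   operator spikes on SF3.
#' @param terminal_peak List: `height` (bar), `duration` (s) of the terminal
#'   SF2 pressure ramp.
#' @param contamination List: `lots` (indices) or `fraction`, `mechanism`,
#'   `target_signal`, `noise_factor`, `plateau_delta`, `qdb_shift_sd`.
#' @param seed Master seed; everything derives from it.
#' @return An object of class `campaign_spec`.
#' @export
campaign_spec <- function(n_lots = 58L, lp_dt = 10, sf_dt = 30,
                          noise_scale = 1,
                          n_qdb_features = 122L, n_constant_qdb = 5L,
                          qdb_n_factors = 6L,
                          spike = list(count = 3L, magnitude = 80,
                                       duration = 60),
                          terminal_peak = list(height = 1.5, duration = 300),
                          contamination = list(lots = integer(),
                                               fraction = 0,
                                               mechanism = "noise_inflation",
                                               target_signal = "LP2",
                                               noise_factor = 1.3,
                                               plateau_delta = 2,
                                               qdb_shift_sd = 10),
                          seed = 1L) {
  if (n_lots < 4L) stop("n_lots must be >= 4", call. = FALSE)
  defaults <- list(lots = integer(), fraction = 0,
                   mechanism = "noise_inflation", target_signal = "LP2",
                   noise_factor = 1.3, plateau_delta = 2, qdb_shift_sd = 10)
  contamination <- utils::modifyList(defaults, contamination)
  if (contamination$fraction >= 0.5) {
    stop("contamination fraction must be < 0.5", call. = FALSE)
  }
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  structure(list(n_lots = as.integer(n_lots), lp_dt = lp_dt, sf_dt = sf_dt,
                 noise_scale = noise_scale,
                 n_qdb_features = as.integer(n_qdb_features),
                 n_constant_qdb = as.integer(n_constant_qdb),
                 qdb_n_factors = as.integer(qdb_n_factors),
                 spike = spike, terminal_peak = terminal_peak,
                 contamination = contamination, seed = as.integer(seed)),
            class = "campaign_spec")
}

# Step-profile templates of the lyophilization signals: 4 plateaus joined by
# 3 sharp ramps. Units per the usual sensor roster (temperatures in degC,
# vacuums/pressures in bar).
lp_step_templates <- function() {
  list(
    LP2 = list(levels = c(-45, -20, 0, 20), plateaus = c(1200, 1500, 1200, 900),
               ramps = c(200, 200, 200), sigma = 0.2, unit = "degC"),
    LP5 = list(levels = c(-190, -150, -185, -120),
               plateaus = c(900, 1500, 1200, 900),
               ramps = c(150, 200, 150), sigma = 0.3, unit = "degC"),
    LP6 = list(levels = c(1, 0.4, 0.1, 0.9), plateaus = c(900, 1200, 1500, 600),
               ramps = c(150, 150, 150), sigma = 0.004, unit = "bar"),
    LP7 = list(levels = c(1, 0.05, 0.35, 1), plateaus = c(600, 1800, 1200, 600),
               ramps = c(150, 150, 150), sigma = 0.004, unit = "bar")
  )
}

#' Default step-detection configuration matched to the campaign templates
#'
#' Duration bounds bracketing the template plateau (300-3500 s) and ramp
#' (50-500 s) durations, with a 3-sample lookahead: the detector then
#' compares values three ramp increments apart, which separates true ramps
#' from single-sample noise excursions at the sensor noise levels the
#' templates emulate, while the adaptive threshold loop still corrects any
#' residual false starts. Used by the full pipeline on the step-shaped
#' signals.
#'
#' @return A [step_config()].
#' @export
default_step_config <- function() {
  step_config(lookahead = 3L,
              duration_bounds = list(plateau = c(300, 3500),
                                     slope = c(50, 500)))
}

# Build one noise-free step profile. Ramp samples run linearly up to and
# including the next level (so a slope phase covers exactly the ramp
# samples). Returns values plus the true half-open phase boundaries.
make_step_profile <- function(levels, plateaus, ramps, dt) {
  npl <- pmax(2L, round(plateaus / dt))
  nrp <- pmax(2L, round(ramps / dt))
  vals <- numeric(0)
  boundaries <- integer(0)   # start index of every phase after the first
  kinds <- character(0)
  for (j in seq_along(levels)) {
    vals <- c(vals, rep(levels[j], npl[j]))
    if (j < length(levels)) {
      boundaries <- c(boundaries, length(vals) + 1L)
      kinds <- c(kinds, "slope")
      vals <- c(vals, levels[j] + seq_len(nrp[j]) / nrp[j] *
                  (levels[j + 1L] - levels[j]))
      boundaries <- c(boundaries, length(vals) + 1L)
      kinds <- c(kinds, "plateau")
    }
  }
  list(values = vals, boundaries = boundaries, kinds = kinds)
}

# Lyophilization profile of the three rule signals, with the closed-form
# ground-truth times of the four LP-Phase boundaries.
make_lyo_rule_profiles <- function(dt) {
  d1 <- 600; r1 <- 400; d2 <- 3000; r2 <- 400; d3 <- 600
  total <- d1 + r1 + d2 + r2 + d3
  tt <- seq(0, total - dt, by = dt)
  lp4 <- ifelse(tt < d1, 1,
         ifelse(tt < d1 + r1, 1 - 0.95 * (tt - d1) / r1,
         ifelse(tt < d1 + r1 + d2, 0.05,
         ifelse(tt < d1 + r1 + d2 + r2,
                0.05 + 0.95 * (tt - d1 - r1 - d2) / r2, 1))))
  lp3 <- rep(0.2, length(tt))       # second vacuum gauge, reads higher
  t_warm <- d1 + r1 + 1200          # shelf warm-up = end of LP-Phase 2
  lp1 <- ifelse(tt < t_warm, -40,
         ifelse(tt < t_warm + 600, -40 + 60 * (tt - t_warm) / 600, 20))
  # LP-Phase 2 starts when (lp4 - 0.2)/lp4 < 0.2, i.e. lp4 < 0.25, midway
  # down the descending ramp; ground truth = first grid time past the
  # crossing. The reference value there (~0.24) lies well above the 0.05
  # plateau, so the value-return condition closing LP-Phase 3 has a unique
  # crossing on the ascending ramp.
  t_cross <- d1 + r1 * (1 - 0.25) / 0.95
  t2_start <- tt[which(tt >= t_cross)[1L]]
  v_ref <- 1 - 0.95 * (t2_start - d1) / r1
  t3_end <- d1 + r1 + d2 + (v_ref - 0.05) / 0.95 * r2
  list(times = tt, LP4 = lp4, LP3 = lp3, LP1 = lp1,
       truth = list(phase1 = c(0, t2_start), phase2 = c(t2_start, t_warm),
                    phase3 = c(t_warm, t3_end),
                    phase4 = c(t3_end, tt[length(tt)])))
}

#' Generate a synthetic FFF campaign with ground truth
#'
#' Builds, per lot: step-profile signals LP2/LP5/LP6/LP7 with lot-to-lot
#' jitter on levels and durations, the rule signals LP1/LP3/LP4 constructed
#' so that every bundled rule-set condition has a known crossing time, and
#' the SF1-SF3 filtration segment with a terminal SF2 pressure ramp and
#' rectangular SF3 spikes. The filtration signals are additionally emitted
#' as one continuous absolutely-timestamped stream with inter-lot gap
#' samples, together with matching quality-database step intervals, so the
#' alignment stage can be exercised end to end. Fully deterministic from
#' `spec$seed`.
#'
#' @param spec A [campaign_spec()].
#' @return A list of class `fff_campaign`: `batches` (each with the 10
#'   signals SF1-SF3, LP1-LP7), `records` (QDB records), `stream` (list of 3
#'   continuous [fff_ts()] with `"origin"` attributes), and `truth` --
#'   per-lot step-phase boundaries, rule-phase boundary times, spike sample
#'   indices, SF2 peak-onset index, stream sample-to-lot assignment,
#'   contaminated lot indices and mechanism.
#' @export
generate_campaign <- function(spec = campaign_spec()) {
  restore <- local_rng(spec$seed)
  on.exit(restore(), add = TRUE)
  n <- spec$n_lots
  lot_ids <- sprintf("L%03d", seq_len(n))
  lot_seeds <- sample.int(.Machine$integer.max - 1L, n)
  qdb_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  contam <- spec$contamination
  bad_lots <- contam$lots
  if (!length(bad_lots) && contam$fraction > 0) {
    bad_lots <- sample.int(n, max(1L, round(contam$fraction * n)))
  }
  bad_lots <- sort(as.integer(bad_lots))

  templates <- lp_step_templates()
  scfg <- default_step_config()
  check_templates_solvable(templates, scfg, spec$lp_dt)

  # QDB block: latent-factor model + constant setpoint columns
  qdb <- make_qdb_block(spec, lot_ids, bad_lots, qdb_seed)

  sf_dur <- 7200
  gap <- 3600
  campaign_t0 <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  lyo_t0_offset <- 1800   # lyophilization starts after filtration ends

  batches <- vector("list", n)
  records <- vector("list", n)
  truth_lots <- vector("list", n)
  sf_stream_vals <- list(SF1 = numeric(), SF2 = numeric(), SF3 = numeric())
  sf_stream_abs <- numeric(0)
  sf_assign <- character(0)

  for (li in seq_len(n)) {
    set.seed(lot_seeds[li])
    is_bad <- li %in% bad_lots
    series <- list()
    lot_truth <- list(step_boundaries = list(), contaminated = is_bad)

    # --- step-profile LP signals
    for (sg in names(templates)) {
      tp <- templates[[sg]]
      levels <- tp$levels + stats::rnorm(length(tp$levels),
                                         sd = 0.01 * diff(range(tp$levels)))
      plateaus <- tp$plateaus * stats::runif(length(tp$plateaus), 0.97, 1.03)
      ramps <- tp$ramps * stats::runif(length(tp$ramps), 0.97, 1.03)
      sigma <- tp$sigma * spec$noise_scale
      if (is_bad && contam$mechanism == "noise_inflation" &&
          sg == contam$target_signal) {
        sigma <- sigma * contam$noise_factor
      }
      if (is_bad && contam$mechanism == "plateau_shift" &&
          sg == contam$target_signal) {
        levels <- levels + contam$plateau_delta
      }
      prof <- make_step_profile(levels, plateaus, ramps, spec$lp_dt)
      vals <- prof$values + stats::rnorm(length(prof$values), sd = sigma)
      tt <- (seq_along(vals) - 1L) * spec$lp_dt
      series[[sg]] <- fff_ts(sg, tt, vals, unit = tp$unit,
                             lot_id = lot_ids[li])
      lot_truth$step_boundaries[[sg]] <- list(index = prof$boundaries,
                                              sigma = sigma)
    }

    # --- rule signals LP1 / LP3 / LP4
    rp <- make_lyo_rule_profiles(spec$lp_dt)
    ns <- spec$noise_scale
    series$LP4 <- fff_ts("LP4", rp$times,
                         rp$LP4 + stats::rnorm(length(rp$times),
                                               sd = 0.002 * ns),
                         unit = "bar", lot_id = lot_ids[li])
    series$LP3 <- fff_ts("LP3", rp$times,
                         rp$LP3 + stats::rnorm(length(rp$times),
                                               sd = 0.002 * ns),
                         unit = "bar", lot_id = lot_ids[li])
    series$LP1 <- fff_ts("LP1", rp$times,
                         rp$LP1 + stats::rnorm(length(rp$times),
                                               sd = 0.1 * ns),
                         unit = "degC", lot_id = lot_ids[li])
    lot_truth$rule_boundaries <- rp$truth

    # --- filtration segment
    nsf <- floor(sf_dur / spec$sf_dt)
    tsf <- (seq_len(nsf) - 1L) * spec$sf_dt
    sf1 <- 5 + stats::rnorm(nsf, sd = 0.1 * ns)
    sf2 <- 0.5 + stats::rnorm(nsf, sd = 0.005 * ns)
    n_peak <- max(2L, round(spec$terminal_peak$duration / spec$sf_dt))
    peak_onset <- nsf - n_peak + 1L
    sf2[peak_onset:nsf] <- sf2[peak_onset:nsf] +
      spec$terminal_peak$height * seq_len(n_peak) / n_peak
    drain0 <- 100 + stats::rnorm(1L, sd = 0.5)
    sf3_clean <- drain0 - 5 * tsf / sf_dur
    sf3 <- sf3_clean + stats::rnorm(nsf, sd = 0.05 * ns)
    n_spk <- max(1L, round(spec$spike$duration / spec$sf_dt))
    spike_idx <- integer(0)
    if (spec$spike$count > 0L) {
      anchors <- sort(sample(seq(10L, nsf - n_peak - 10L - n_spk,
                                 by = 3L * n_spk), spec$spike$count))
      for (a in anchors) {
        spike_idx <- c(spike_idx, a:(a + n_spk - 1L))
      }
      sf3[spike_idx] <- sf3[spike_idx] + spec$spike$magnitude
    }
    series$SF1 <- fff_ts("SF1", tsf, sf1, unit = "degC", lot_id = lot_ids[li])
    series$SF2 <- fff_ts("SF2", tsf, sf2, unit = "bar", lot_id = lot_ids[li])
    series$SF3 <- fff_ts("SF3", tsf, sf3, unit = "kg", lot_id = lot_ids[li])
    lot_truth$spike_index <- spike_idx
    lot_truth$sf3_clean <- sf3_clean
    lot_truth$sf2_peak_onset <- peak_onset

    # --- continuous stream bookkeeping (lot samples + a gap chunk)
    lot_abs0 <- as.numeric(campaign_t0) + (li - 1L) * (sf_dur + gap)
    sf_stream_abs <- c(sf_stream_abs, lot_abs0 + tsf)
    sf_assign <- c(sf_assign, rep(lot_ids[li], nsf))
    sf_stream_vals$SF1 <- c(sf_stream_vals$SF1, sf1)
    sf_stream_vals$SF2 <- c(sf_stream_vals$SF2, sf2)
    sf_stream_vals$SF3 <- c(sf_stream_vals$SF3, sf3)
    if (li < n) {   # idle samples between lots, assigned to no lot
      gap_t <- lot_abs0 + sf_dur + seq(600, gap - 600, by = 600)
      sf_stream_abs <- c(sf_stream_abs, gap_t)
      sf_assign <- c(sf_assign, rep(NA_character_, length(gap_t)))
      sf_stream_vals$SF1 <- c(sf_stream_vals$SF1,
                              20 + stats::rnorm(length(gap_t), sd = 0.1))
      sf_stream_vals$SF2 <- c(sf_stream_vals$SF2,
                              stats::rnorm(length(gap_t), sd = 0.005))
      sf_stream_vals$SF3 <- c(sf_stream_vals$SF3,
                              stats::rnorm(length(gap_t), sd = 0.05))
    }

    sf_start <- as.POSIXct(lot_abs0, origin = "1970-01-01", tz = "UTC")
    sf_end <- sf_start + sf_dur
    lyo_start <- sf_end + lyo_t0_offset
    lyo_end <- lyo_start + max(rp$times) + spec$lp_dt
    records[[li]] <- qdb_record(
      lot_ids[li], qdb$features[li, ],
      list(sterile_filtration = c(sf_start, sf_end),
           lyophilization = c(lyo_start, lyo_end)))
    batches[[li]] <- fff_batch(lot_ids[li], series, records[[li]])
    truth_lots[[li]] <- lot_truth
  }
  names(truth_lots) <- lot_ids

  units <- c(SF1 = "degC", SF2 = "bar", SF3 = "kg")
  stream <- lapply(names(sf_stream_vals), function(sg) {
    ts <- fff_ts(sg, sf_stream_abs - sf_stream_abs[1L], sf_stream_vals[[sg]],
                 unit = units[[sg]])
    attr(ts, "origin") <- as.POSIXct(sf_stream_abs[1L], origin = "1970-01-01",
                                     tz = "UTC")
    ts
  })
  names(stream) <- names(sf_stream_vals)

  structure(list(
    batches = batches, records = records, stream = stream,
    truth = list(lots = truth_lots, stream_assignment = sf_assign,
                 contaminated = bad_lots,
                 mechanism = if (length(bad_lots)) contam$mechanism else NA,
                 qdb_truth = qdb$truth),
    spec = spec), class = "fff_campaign")
}

#' @export
print.fff_campaign <- function(x, ...) {
  cat(sprintf(paste0("<fff_campaign> %d lots, %d QDB features, ",
                     "%d contaminated lot(s)%s, seed %d\n"),
              length(x$batches), x$spec$n_qdb_features,
              length(x$truth$contaminated),
              if (length(x$truth$contaminated))
                paste0(" [", x$truth$mechanism, "]") else "",
              x$spec$seed))
  invisible(x)
}

# Correlated QDB block from a latent-factor model, plus constant columns.
# qdb_shift contamination moves a lot along the dominant factor direction.
make_qdb_block <- function(spec, lot_ids, bad_lots, qdb_seed) {
  set.seed(qdb_seed)
  n <- spec$n_lots
  p_var <- spec$n_qdb_features - spec$n_constant_qdb
  q <- spec$qdb_n_factors
  mu <- stats::runif(p_var, 1, 100)
  L <- matrix(stats::rnorm(p_var * q), p_var, q)
  # decaying factor strengths: process campaigns have a dominant covariance
  # direction, and the qdb_shift mechanism must land inside the retained
  # subspace to plant a score (not orthogonal) outlier
  fw <- 2^(-(seq_len(q) - 1) / 2)
  scl <- 0.02 * mu            # feature-specific scale, ~2% CV
  f <- matrix(stats::rnorm(n * q), n, q)
  eps <- matrix(stats::rnorm(n * p_var, sd = 0.3), n, p_var)
  x <- sweep((f %*% (fw * t(L)) / sqrt(q) + eps), 2L, scl, "*")
  x <- sweep(x, 2L, mu, "+")
  if (length(bad_lots) && spec$contamination$mechanism == "qdb_shift") {
    # shift along the dominant direction of the true covariance by
    # qdb_shift_sd standard deviations of that component: an in-model,
    # gross score outlier (the excursion-lot motif)
    sig <- (L %*% (fw^2 * t(L))) / q + diag(0.3^2, p_var)
    sig <- sig * tcrossprod(scl)
    eg <- eigen(sig, symmetric = TRUE)
    shift <- spec$contamination$qdb_shift_sd * sqrt(eg$values[1L]) *
      eg$vectors[, 1L]
    for (li in bad_lots) x[li, ] <- x[li, ] + shift
  }
  consts <- matrix(rep(round(stats::runif(spec$n_constant_qdb, 1, 10), 1),
                       each = n), nrow = n)
  out <- cbind(x, consts)
  colnames(out) <- paste0("QDB-", seq_len(spec$n_qdb_features))
  rownames(out) <- lot_ids
  list(features = out,
       truth = list(means = mu, scales = scl,
                    constant_columns = paste0("QDB-",
                                              (p_var + 1L):(p_var +
                                                 spec$n_constant_qdb))))
}

# Fixtures must be solvable: template durations have to respect the default
# step-config duration bounds.
check_templates_solvable <- function(templates, cfg, dt) {
  for (sg in names(templates)) {
    tp <- templates[[sg]]
    pb <- cfg$duration_bounds$plateau
    sb <- cfg$duration_bounds$slope
    if (any(tp$plateaus < pb[1L] | tp$plateaus > pb[2L])) {
      stop("template '", sg, "': plateau durations violate the default ",
           "step-config bounds", call. = FALSE)
    }
    if (any(tp$ramps < sb[1L] | tp$ramps > sb[2L])) {
      stop("template '", sg, "': ramp durations violate the default ",
           "step-config bounds", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a synthetic campaign in the CSV dialects the alignment stage reads
#'
#' Emits `qdb.csv` (features + step-interval timestamps), `lyo_long.csv`
#' (long-layout lyophilization series per lot), `sf_stream.csv` (the
#' continuous absolutely-timestamped filtration stream, no lot labels) and
#' `ground_truth.json`.
#'
#' @param campaign A [generate_campaign()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  qdb_path <- file.path(dir, "qdb.csv")
  write_qdb_table(campaign$records, qdb_path)
  lyo <- do.call(rbind, lapply(campaign$batches, function(b) {
    do.call(rbind, lapply(b$series[grep("^LP", names(b$series))],
                          as.data.frame))
  }))
  lyo_path <- file.path(dir, "lyo_long.csv")
  utils::write.csv(lyo, lyo_path, row.names = FALSE, quote = FALSE)
  origin <- attr(campaign$stream[[1L]], "origin")
  sfd <- data.frame(
    timestamp = format_iso8601(origin + campaign$stream[[1L]]$times),
    check.names = FALSE)
  for (sg in names(campaign$stream)) {
    sfd[[sg]] <- campaign$stream[[sg]]$values
  }
  sf_path <- file.path(dir, "sf_stream.csv")
  utils::write.csv(sfd, sf_path, row.names = FALSE, quote = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(contaminated = campaign$truth$contaminated,
         mechanism = campaign$truth$mechanism,
         stream_assignment = campaign$truth$stream_assignment),
    gt_path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(c(qdb_path, lyo_path, sf_path, gt_path))
}

#' Boundary-recovery study over a grid of signal-to-noise ratios
#'
#' For each SNR (ratio of the smallest template step height to the noise
#' sigma), generates `n_campaigns` seeded step signals from the LP2
#' template (with lot-to-lot jitter), segments them with the adaptive
#' detector and scores the fraction of true phase boundaries recovered
#' within `lookahead + 2` samples.
#'
#' @param snr Numeric vector of signal-to-noise ratios; `Inf` means
#'   noise-free.
#' @param n_campaigns Seeded replicates per SNR (default 50).
#' @param seed Master seed.
#' @param cfg Step configuration. The default uses a 7-sample lookahead:
#'   at low SNR a threshold separating ramps from noise excursions only
#'   exists when the detector spans several ramp increments per comparison,
#'   and the recovery tolerance scales with the lookahead accordingly.
#' @param dt Sampling period in seconds.
#' @return Data frame with columns `snr`, `recovery_rate`, `n_boundaries`.
#' @export
generate_noise_study <- function(snr, n_campaigns = 50L, seed = 1L,
                                 cfg = step_config(
                                   lookahead = 7L,
                                   duration_bounds = list(
                                     plateau = c(300, 3500),
                                     slope = c(50, 500))),
                                 dt = 10) {
  if (!length(snr)) stop("SNR grid must be non-empty", call. = FALSE)
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  tp <- lp_step_templates()$LP2
  min_step <- min(abs(diff(tp$levels)))
  rows <- lapply(snr, function(s) {
    hit <- 0L
    tot <- 0L
    for (r in seq_len(n_campaigns)) {
      levels <- tp$levels + stats::rnorm(length(tp$levels),
                                         sd = 0.01 * diff(range(tp$levels)))
      plateaus <- tp$plateaus * stats::runif(4L, 0.97, 1.03)
      ramps <- tp$ramps * stats::runif(3L, 0.97, 1.03)
      prof <- make_step_profile(levels, plateaus, ramps, dt)
      sigma <- if (is.finite(s)) min_step / s else 0
      vals <- prof$values + if (sigma > 0)
        stats::rnorm(length(prof$values), sd = sigma) else 0
      ts <- fff_ts("LP2", (seq_along(vals) - 1L) * dt, vals)
      seg <- detect_step_phases(ts, cfg)
      rec <- boundary_recovery(seg, prof$boundaries,
                               tol = cfg$lookahead + 2L)
      hit <- hit + rec$hits
      tot <- tot + rec$total
    }
    data.frame(snr = s, recovery_rate = hit / tot, n_boundaries = tot)
  })
  do.call(rbind, rows)
}

#' Score detected phase boundaries against ground truth
#'
#' @param seg A [detect_step_phases()] result (or bare phase data frame).
#' @param true_boundaries True interior boundary sample indices.
#' @param tol Tolerance in samples (default `lookahead + 2`).
#' @return List with `hits`, `total`, `rate`.
#' @export
boundary_recovery <- function(seg, true_boundaries, tol = 3L) {
  ph <- if (inherits(seg, "step_segmentation")) seg$phases else seg
  detected <- sort(unique(c(ph$start_index, ph$end_index)))
  hits <- sum(vapply(true_boundaries, function(b) {
    min(abs(detected - b)) <= tol
  }, logical(1)))
  list(hits = hits, total = length(true_boundaries),
       rate = hits / length(true_boundaries))
}
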