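test_that("noise sigma estimation recovers the true scale", {
  expect_identical(estimate_noise_sigma(mk_ts(rep(2, 50))), 0)

  set.seed(11)
  ts <- mk_ts(rnorm(10000))
  expect_gt(estimate_noise_sigma(ts), 0.95)
  expect_lt(estimate_noise_sigma(ts), 1.05)

  # robust estimator ignores a small fraction of ramp samples
  set.seed(12)
  y <- c(rep(0, 490), seq(0.4, 8, by = 0.4), rep(8, 490)) + rnorm(1000, sd = 0.5)
  est <- estimate_noise_sigma(mk_ts(y), "mad_of_differences")
  expect_gt(est, 0.4)
  expect_lt(est, 0.6)
})

test_that("terminal-slope removal truncates exactly the trailing ramp", {
  flat <- mk_ts(rep(1, 100))
  cfg <- cleaning_config(terminal_slope_threshold = 0.1)
  out <- remove_terminal_slope(flat, cfg)
  expect_identical(out$ts$values, flat$values)
  expect_identical(out$report$samples_removed, 0L)

  ramp <- mk_ts(c(rep(1, 100), 1 + cumsum(rep(1, 20))))   # slope 10x threshold
  out <- remove_terminal_slope(ramp, cleaning_config(terminal_slope_threshold = 0.1))
  expect_identical(out$ts$values, rep(1, 100))
  expect_identical(out$report$samples_removed, 20L)
  expect_identical(out$report$regions$reason, "terminal_slope")

  # interior ramps are never touched
  interior <- mk_ts(c(rep(0, 50), seq(1, 20), rep(20, 50)))
  out <- remove_terminal_slope(interior, cleaning_config(terminal_slope_threshold = 0.1))
  expect_identical(out$ts$values, interior$values)
})

test_that("terminal-slope removal finds the generator SF2 peak onset", {
  cmp <- generate_campaign(mk_small_campaign_spec(seed = 21, n_lots = 4))
  for (li in 1:4) {
    b <- cmp$batches[[li]]
    out <- remove_terminal_slope(b$series$SF2)
    onset <- cmp$truth$lots[[li]]$sf2_peak_onset
    expect_lte(abs(length(out$ts$values) + 1L - onset), 3)
    # idempotent
    again <- remove_terminal_slope(out$ts)
    expect_identical(again$ts$values, out$ts$values)
  }
})

test_that("spike removal deletes exactly the injected spikes", {
  set.seed(31)
  n <- 400
  drain <- 100 - 5 * (0:(n - 1)) / n + rnorm(n, sd = 0.05)
  spikes <- sort(sample(seq(20, n - 20, by = 12), 5))
  idx <- as.integer(outer(0:1, spikes, "+"))
  y <- drain
  y[idx] <- y[idx] + 80
  ts <- mk_ts(y, dt = 30, signal = "SF3", unit = "kg")
  out <- remove_spikes(ts)
  expect_identical(out$report$samples_removed, length(idx))
  kept <- setdiff(seq_len(n), idx)
  expect_identical(out$ts$values, drain[kept])

  # no sample above threshold: identity
  quiet <- mk_ts(drain, dt = 30)
  out2 <- remove_spikes(quiet)
  expect_identical(out2$ts$values, quiet$values)
  expect_identical(out2$report$samples_removed, 0L)

  # idempotence: cleaning a cleaned series removes nothing
  again <- remove_spikes(out$ts)
  expect_identical(again$report$samples_removed, 0L)
})

test_that("spike removal reduces RMSE to ground truth by at least 90%", {
  cmp <- generate_campaign(mk_small_campaign_spec(seed = 41, n_lots = 4))
  for (li in 1:4) {
    b <- cmp$batches[[li]]
    tr <- cmp$truth$lots[[li]]
    out <- remove_spikes(b$series$SF3)
    rmse_raw <- sqrt(mean((b$series$SF3$values - tr$sf3_clean)^2))
    kept <- match(out$ts$times, b$series$SF3$times)
    rmse_cln <- sqrt(mean((out$ts$values - tr$sf3_clean[kept])^2))
    expect_lt(rmse_cln, 0.1 * rmse_raw)
  }
})

test_that("cleaners never invent values and misconfiguration is caught", {
  set.seed(51)
  y <- cumsum(rnorm(200))
  ts <- mk_ts(y)
  out <- remove_spikes(ts, cleaning_config(spike_slope_threshold = 100))
  expect_true(all(out$ts$values %in% y))   # subsequence of the input
  expect_error(
    remove_spikes(mk_ts(rep(c(rep(0, 15), rep(45, 45)), 3), dt = 1),
                  cleaning_config(spike_slope_threshold = 1,
                                  spike_max_duration = 1e6)),
    "half")
})
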