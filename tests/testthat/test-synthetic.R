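test_that("campaigns are fully deterministic from the master seed", {
  s <- mk_small_campaign_spec(seed = 81, n_lots = 4)
  c1 <- generate_campaign(s)
  c2 <- generate_campaign(s)
  expect_identical(c1$batches[[3]]$series$LP2$values,
                   c2$batches[[3]]$series$LP2$values)
  expect_identical(c1$batches[[2]]$qdb$features, c2$batches[[2]]$qdb$features)
  expect_identical(c1$stream$SF3$values, c2$stream$SF3$values)
  c3 <- generate_campaign(mk_small_campaign_spec(seed = 82, n_lots = 4))
  expect_false(identical(c1$batches[[3]]$series$LP2$values,
                         c3$batches[[3]]$series$LP2$values))
})

test_that("noise-free campaigns are segmented exactly", {
  cmp <- generate_campaign(mk_small_campaign_spec(seed = 83, n_lots = 4,
                                                  noise_scale = 0))
  for (b in cmp$batches) {
    for (sg in c("LP2", "LP5", "LP6", "LP7")) {
      seg <- detect_step_phases(b$series[[sg]], default_step_config())
      tb <- cmp$truth$lots[[b$lot_id]]$step_boundaries[[sg]]$index
      expect_identical(
        boundary_recovery(seg, tb, tol = default_step_config()$lookahead)$rate,
        1)
    }
  }
})

test_that("noise inflation lifts the target signal's plateau spread as planted", {
  cmp <- generate_campaign(campaign_spec(
    n_lots = 10, n_qdb_features = 8, n_constant_qdb = 1,
    contamination = list(lots = 4L, mechanism = "noise_inflation"),
    seed = 84))
  stds <- vapply(cmp$batches, function(b) {
    seg <- detect_step_phases(b$series$LP2, default_step_config())
    ph <- seg$phases[seg$phases$kind == "plateau", ][1, ]
    sd(b$series$LP2$values[ph$start_index:(ph$end_index - 1)])
  }, numeric(1))
  expect_gt(stds[4] / median(stds), 1.25)
})

test_that("emitted CSVs round-trip through the alignment stage", {
  cmp <- generate_campaign(mk_small_campaign_spec(seed = 85, n_lots = 4))
  dir <- tempfile()
  write_campaign(cmp, dir)
  recs <- parse_qdb_table(file.path(dir, "qdb.csv"))
  expect_length(recs, 4)
  expect_identical(recs[[2]]$features, cmp$records[[2]]$features)
  lyo <- parse_timeseries_table(file.path(dir, "lyo_long.csv"), "long")
  expect_identical(attr(lyo, "n_dropped"), 0L)
  # the continuous stream legitimately has large inter-lot gaps
  stream <- suppressWarnings(
    parse_timeseries_table(file.path(dir, "sf_stream.csv"), "wide"))
  seg <- segment_stream_by_intervals(stream, recs)
  truth <- cmp$truth$stream_assignment
  for (lot in names(seg$segments)) {
    got <- seg$segments[[lot]]$SF3$values
    want <- cmp$stream$SF3$values[!is.na(truth) & truth == lot]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the noise study is monotone and complete over its grid", {
  st <- generate_noise_study(c(Inf, 50, 20, 5), n_campaigns = 8, seed = 86)
  expect_identical(nrow(st), 4L)
  expect_identical(st$recovery_rate[1], 1)
  # non-increasing in noise, allowing 2% Monte-Carlo slack
  expect_true(all(diff(st$recovery_rate) <= 0.02))
})

test_that("unsolvable templates are rejected", {
  expect_error(
    fffmon:::check_templates_solvable(
      list(X = list(levels = c(0, 1), plateaus = c(10, 10), ramps = 5,
                    sigma = 0, unit = "")),
      default_step_config(), 10),
    "bounds")
})
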