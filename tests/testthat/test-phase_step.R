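test_that("a constant series is one plateau", {
  seg <- detect_step_phases(mk_ts(rep(3.2, 60)), step_config(threshold0 = 0.5))
  expect_identical(nrow(seg$phases), 1L)
  expect_identical(seg$phases$kind, "plateau")
  expect_identical(seg$phases$start_index, 1L)
  expect_identical(seg$phases$end_index, 61L)
  expect_true(seg$converged)
})

test_that("a noise-free two-level step segments exactly at the ramp", {
  ts <- mk_two_level_step()
  seg <- detect_step_phases(ts, step_config(lookahead = 1L, threshold0 = 0.05))
  expect_identical(seg$phases$kind, c("plateau", "slope", "plateau"))
  expect_identical(seg$phases$start_index, c(1L, 101L, 111L))
  expect_identical(seg$phases$end_index, c(101L, 111L, 211L))
  expect_true(seg$converged)
})

test_that("segmentation is deterministic, covering, disjoint and alternating", {
  for (sd in 1:10) {
    set.seed(sd)
    y <- c(rep(0, 80), seq(0.5, 10, by = 0.5), rep(10, 60),
           seq(9.75, 5, by = -0.25), rep(5, 70)) + rnorm(250, sd = 0.05)
    ts <- mk_ts(y)
    cfg <- step_config(lookahead = 2L,
                       duration_bounds = list(plateau = c(20, 200),
                                              slope = c(5, 60)))
    s1 <- detect_step_phases(ts, cfg)
    s2 <- detect_step_phases(ts, cfg)
    expect_identical(s1$phases, s2$phases)
    ph <- s1$phases
    expect_identical(ph$start_index[1], 1L)
    expect_identical(ph$end_index[nrow(ph)], length(y) + 1L)
    expect_identical(ph$start_index[-1], ph$end_index[-nrow(ph)])  # no gaps
    expect_true(all(ph$kind[-1] != ph$kind[-nrow(ph)]))  # alternation
  }
})

test_that("boundaries are scale-equivariant", {
  set.seed(5)
  y <- c(rep(0, 70), seq(1, 20), rep(20, 70)) + rnorm(160, sd = 0.1)
  s1 <- detect_step_phases(mk_ts(y), step_config(threshold0 = 0.5))
  s2 <- detect_step_phases(mk_ts(y * 37), step_config(threshold0 = 0.5 * 37))
  expect_identical(s1$phases$start_index, s2$phases$start_index)
  expect_identical(s1$phases$end_index, s2$phases$end_index)
  expect_identical(s1$phases$kind, s2$phases$kind)
})

test_that("noise-free piecewise constructions are recovered within the lookahead", {
  set.seed(8)
  for (rep in 1:5) {
    levels <- cumsum(c(0, runif(3, 2, 6) * sample(c(-1, 1), 3, TRUE)))
    prof <- fffmon:::make_step_profile(levels, plateaus = runif(4, 400, 900),
                                       ramps = runif(3, 100, 300), dt = 10)
    ts <- mk_ts(prof$values, dt = 10)
    for (i in c(1L, 3L)) {
      cfg <- step_config(lookahead = i,
                         duration_bounds = list(plateau = c(300, 1000),
                                                slope = c(50, 400)))
      seg <- detect_step_phases(ts, cfg)
      rec <- boundary_recovery(seg, prof$boundaries, tol = i)
      expect_identical(rec$rate, 1)
      expect_true(seg$converged)
    }
  }
})

test_that("the adaptive threshold loop recovers from a misconfigured start", {
  set.seed(13)
  y <- c(rep(0, 100), seq(0.5, 10, by = 0.5), rep(10, 100)) +
    rnorm(220, sd = 0.12)
  ts <- mk_ts(y, dt = 10)
  # threshold0 far too low: every noise excursion a slope at first
  cfg <- step_config(lookahead = 3L, threshold0 = 0.01,
                     duration_bounds = list(plateau = c(300, 1500),
                                            slope = c(50, 500)))
  seg <- detect_step_phases(ts, cfg)
  expect_true(seg$converged)
  expect_gt(seg$iterations_used, 1L)
  expect_gt(seg$final_threshold, 0.01)
  expect_identical(sum(seg$phases$kind == "slope"), 1L)
  expect_identical(boundary_recovery(seg, c(101L, 121L), tol = 5)$rate, 1)
})

test_that("a signal beginning mid-slope is flagged", {
  y <- c(seq(1, 10), rep(10, 80))
  seg <- detect_step_phases(mk_ts(y), step_config(threshold0 = 0.5))
  expect_true(seg$leading_slope)
  expect_identical(seg$phases$kind[1], "slope")
})

test_that("series shorter than twice the lookahead are rejected", {
  expect_error(detect_step_phases(mk_ts(rnorm(6)),
                                  step_config(lookahead = 3L)), "lookahead")
})

test_that("segment classification separates ramps from noise", {
  flat <- mk_ts(rep(1, 50))
  expect_identical(classify_segment(flat, 1, 51, threshold = 0.1), "plateau")

  ramp <- mk_ts(seq(0, by = 0.4, length.out = 50))   # 4x threshold per step
  expect_identical(classify_segment(ramp, 1, 51, threshold = 0.1), "slope")

  hits <- 0L
  for (sd in 1:100) {
    set.seed(sd)
    noisy <- mk_ts(rnorm(60, sd = 0.1))   # sigma = threshold / 5
    hits <- hits + (classify_segment(noisy, 1, 61, threshold = 0.5) == "plateau")
  }
  expect_gte(hits, 99L)
})
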