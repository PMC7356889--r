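mk_rule_batch <- function() {
  tt <- 0:100
  fff_batch("B1", list(
    fff_ts("A", tt, rep(100, 101), lot_id = "B1"),
    fff_ts("B", tt, pmin(tt, 100), lot_id = "B1")   # ramp 0 -> 100
  ))
}

test_that("signal_start and signal_end predicates return the grid ends", {
  b <- mk_rule_batch()
  expect_identical(evaluate_predicate(pred_signal_start("B"), b), 0)
  expect_identical(evaluate_predicate(pred_signal_end("B"), b), 100)
})

test_that("relative-difference predicate fires at the closed-form crossing", {
  b <- mk_rule_batch()
  # |100 - b| / max(100, b) < 0.2  <=>  b > 80: earliest grid time is 81
  t <- evaluate_predicate(pred_rel_diff_below("A", "B", 0.2), b)
  expect_identical(t, 81)
  expect_error(evaluate_predicate(pred_rel_diff_below("A", "B", 0.001),
                                  fff_batch("B1", list(
                                    fff_ts("A", 0:10, rep(1, 11), lot_id = "B1"),
                                    fff_ts("B", 0:10, rep(2, 11), lot_id = "B1")))),
               "never")
})

test_that("value_return finds the mirrored time on a symmetric triangle", {
  tt <- 0:20
  tri <- fff_batch("B1", list(
    fff_ts("V", tt, c(seq(0, 10, by = 1), seq(9, 1, by = -1), 0.5),
           lot_id = "B1")))
  resolved <- list(rise = list(start_time = 2, end_time = 10))
  pred <- pred_value_return("V", "rise", "start", tolerance_fraction = 0.05,
                            window_fraction = 0.5)
  t <- evaluate_predicate(pred, tri, resolved)
  expect_lt(abs(t - 18), 1)   # value 2 is reattained at t = 18
})

test_that("slope onset locates the first rising ramp", {
  set.seed(3)
  y <- c(rep(-40, 200), -40 + seq(1, 60), rep(20, 100)) + rnorm(360, sd = 0.1)
  b <- fff_batch("B1", list(fff_ts("LP1", (0:359) * 10, y, lot_id = "B1")))
  t <- evaluate_predicate(pred_slope_onset("LP1", "up"), b)
  expect_lt(abs(t - 2000), 40)   # within lookahead + 1 samples of onset
})

test_that("the bundled rule set matches generator ground truth within 2 samples", {
  cmp <- generate_campaign(mk_small_campaign_spec(seed = 14, n_lots = 5))
  dt <- cmp$spec$lp_dt
  for (b in cmp$batches) {
    rp <- apply_ruleset(lp_phase_ruleset(), b)
    expect_true(rp$ok)
    expect_identical(nrow(rp$phases), 4L)
    tr <- cmp$truth$lots[[b$lot_id]]$rule_boundaries
    for (k in 1:4) {
      det <- rp$phases[rp$phases$label == paste("LP-Phase", k), ]
      expect_lte(abs(det$start_time - tr[[k]][1]) / dt, 2)
      expect_lte(abs(det$end_time - tr[[k]][2]) / dt, 2)
    }
    # the four phases partition LP4's support: contiguous, no gaps
    ph <- rp$phases[order(rp$phases$start_time), ]
    expect_identical(ph$start_time[1], b$series$LP4$times[1])
    expect_equal(ph$end_time[4],
                 b$series$LP4$times[length(b$series$LP4$times)])
    expect_equal(ph$start_time[-1], ph$end_time[-4])
    expect_true(all(ph$start_time < ph$end_time))
  }
})

test_that("rule evaluation is driven by run order, not declaration order", {
  cmp <- generate_campaign(mk_small_campaign_spec(seed = 15, n_lots = 4))
  b <- cmp$batches[[1]]
  rs <- lp_phase_ruleset()
  shuffled <- phase_ruleset(rs$rules[c(3, 1, 4, 2)])
  p1 <- apply_ruleset(rs, b)$phases
  p2 <- apply_ruleset(shuffled, b)$phases
  expect_identical(p1, p2)
})

test_that("a single start-to-end rule spans the whole signal", {
  b <- mk_rule_batch()
  rs <- phase_ruleset(list(
    phase_rule("all", 1L, pred_signal_start("B"), pred_signal_end("B"), "B")))
  out <- apply_ruleset(rs, b)
  expect_true(out$ok)
  expect_identical(out$phases$start_time, 0)
  expect_identical(out$phases$end_time, 100)
})

test_that("predicate failures flag the batch and return partial phases", {
  b <- mk_rule_batch()
  rs <- phase_ruleset(list(
    phase_rule("ok", 1L, pred_signal_start("B"), pred_signal_end("B"), "B"),
    phase_rule("bad", 2L, pred_rel_diff_below("A", "B", 0.0001),
               pred_signal_end("B"), "B")))
  out <- apply_ruleset(rs, b)
  expect_false(out$ok)
  expect_match(out$failures, "bad")
  expect_identical(out$phases$label, "ok")
})

test_that("duplicate run orders are rejected", {
  expect_error(phase_ruleset(list(
    phase_rule("a", 1L, pred_signal_start("X"), pred_signal_end("X"), "X"),
    phase_rule("b", 1L, pred_signal_start("X"), pred_signal_end("X"), "X"))),
    "unique")
})
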