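mk_phases <- function(label, kind, start, end, ts) {
  data.frame(label = label, kind = kind, start_index = start,
             end_index = end, start_time = ts$times[start],
             end_time = ts$times[pmin(end, length(ts$times))],
             duration_seconds = ts$times[pmin(end, length(ts$times))] -
               ts$times[start], stringsAsFactors = FALSE)
}

test_that("phase statistics have their closed-form values", {
  ts <- mk_ts(c(rep(5, 50), seq(5.2, 15, by = 0.2)), signal = "X")
  ph <- rbind(mk_phases("p1", "plateau", 1L, 51L, ts),
              mk_phases("s1", "slope", 51L, 101L, ts))
  out <- extract_phase_features(ts, ph, list(
    feature_spec("X", "p1", "mean"), feature_spec("X", "p1", "min"),
    feature_spec("X", "p1", "max"), feature_spec("X", "p1", "plateau_std"),
    feature_spec("X", "s1", "slope_residual_rmse"),
    feature_spec("X", "s1", "duration_seconds")))
  expect_identical(unname(out[c("X|p1|mean", "X|p1|min", "X|p1|max")]),
                   c(5, 5, 5))
  expect_identical(unname(out["X|p1|plateau_std"]), 0)
  expect_lt(unname(out["X|s1|slope_residual_rmse"]), 1e-10)  # perfect line
  expect_identical(unname(out["X|s1|duration_seconds"]), 49)
})

test_that("plateau_std estimates the plateau noise", {
  set.seed(6)
  ts <- mk_ts(4 + rnorm(200, sd = 0.3), signal = "X")
  ph <- mk_phases("p1", "plateau", 1L, 201L, ts)
  out <- extract_phase_features(ts, ph,
                                list(feature_spec("X", "p1", "plateau_std")))
  expect_gt(out, 0.25)
  expect_lt(out, 0.35)
})

test_that("statistic admissibility by phase kind is enforced", {
  ts <- mk_ts(rnorm(30), signal = "X")
  ph <- mk_phases("s1", "slope", 1L, 31L, ts)
  expect_error(extract_phase_features(ts, ph,
                                      list(feature_spec("X", "s1", "plateau_std"))),
               "plateau_std")
  ph2 <- mk_phases("p1", "plateau", 1L, 31L, ts)
  expect_error(extract_phase_features(
    ts, ph2, list(feature_spec("X", "p1", "slope_residual_rmse"))),
    "slope_residual_rmse")
})

test_that("the default roster yields 130 extracted features and the matrix adds QDB", {
  specs <- default_feature_specs()
  expect_length(specs, 130L)

  cmp <- generate_campaign(mk_small_campaign_spec(seed = 61, n_lots = 4))
  segs <- lapply(cmp$batches, function(b) {
    out <- lapply(c("LP2", "LP5", "LP6", "LP7"), function(sg)
      detect_step_phases(b$series[[sg]], default_step_config()))
    names(out) <- c("LP2", "LP5", "LP6", "LP7")
    out$SF2 <- fffmon:::whole_signal_phase(b$series$SF2)
    out
  })
  names(segs) <- vapply(cmp$batches, function(b) b$lot_id, character(1))
  rules <- lapply(cmp$batches, function(b) apply_ruleset(lp_phase_ruleset(), b))
  names(rules) <- names(segs)
  fm <- build_feature_matrix(cmp$batches, segs, rules, specs)
  expect_identical(dim(fm), c(4L, 130L + 12L))
  prov <- attr(fm, "provenance")
  expect_identical(sum(prov$source == "extracted"), 130L)
  expect_identical(sum(prov$source == "qdb"), 12L)

  # batch order permutes rows only, never values
  fm2 <- build_feature_matrix(cmp$batches[c(3, 1, 4, 2)], segs, rules, specs)
  expect_identical(fm2[rownames(fm), , drop = FALSE][, colnames(fm)],
                   fm[, ])

  # empty specs: QDB columns only
  fm3 <- build_feature_matrix(cmp$batches[1], specs = list())
  expect_identical(dim(fm3), c(1L, 12L))
})

test_that("zero-variance filtering removes exactly the constant columns", {
  x <- cbind(a = rnorm(10), b = rep(1, 10), c = rnorm(10), d = rnorm(10),
             e = rnorm(10))
  fm <- structure(x, provenance = data.frame(name = colnames(x),
                                             source = "qdb"),
                  class = c("feature_matrix", "matrix", "array"))
  out <- drop_zero_variance(fm)
  expect_identical(colnames(out), c("a", "c", "d", "e"))
  expect_identical(attr(out, "removed_columns"), "b")
  # idempotent, and identity without constants
  out2 <- drop_zero_variance(out)
  expect_identical(out2[, ], out[, ])
  expect_identical(attr(out2, "removed_columns"), character(0))
  expect_error(drop_zero_variance(out[, 0, drop = FALSE]), "constant")
})

test_that("generator campaigns lose exactly the planted constant QDB columns", {
  cmp <- generate_campaign(mk_small_campaign_spec(seed = 62, n_lots = 6))
  fm <- build_feature_matrix(cmp$batches, specs = list())
  out <- drop_zero_variance(fm)
  expect_setequal(attr(out, "removed_columns"),
                  cmp$truth$qdb_truth$constant_columns)
  expect_identical(ncol(out), ncol(fm) - cmp$spec$n_constant_qdb)
})

test_that("robust scaling centers at median 0 / MAD 1 and inverts exactly", {
  set.seed(63)
  x <- cbind(a = rnorm(30, 100, 5), b = rexp(30), c = runif(30))
  fm <- structure(x, provenance = data.frame(name = colnames(x),
                                             source = "qdb"),
                  class = c("feature_matrix", "matrix", "array"))
  sc <- scale_features(fm, "robust")
  expect_equal(unname(apply(sc, 2, median)), rep(0, 3))
  expect_equal(unname(apply(sc, 2, mad)), rep(1, 3))
  back <- unscale_features(sc)
  expect_equal(back[, ], x, tolerance = 1e-12)

  # one gross outlier: robust and classical scale differ by > 2x
  y <- cbind(v = c(rnorm(29), 50))
  fmy <- structure(y, provenance = data.frame(name = "v", source = "qdb"),
                   class = c("feature_matrix", "matrix", "array"))
  s_rob <- attr(scale_features(fmy, "robust"), "scales")
  s_cls <- attr(scale_features(fmy, "classical"), "scales")
  expect_gt(unname(s_cls / s_rob), 2)
})

test_that("feature-count bookkeeping is consistent through the pipeline steps", {
  cmp <- generate_campaign(mk_small_campaign_spec(seed = 64, n_lots = 6))
  fm <- build_feature_matrix(cmp$batches, specs = list())
  out <- drop_zero_variance(fm)
  expect_identical(ncol(out) + length(attr(out, "removed_columns")),
                   ncol(fm))
})
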