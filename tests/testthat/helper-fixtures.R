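# Small fixture builders shared across the suite. Everything is generated
# in code; no data files.

mk_ts <- function(values, dt = 1, signal = "S1", unit = "", lot = NULL) {
  fff_ts(signal, (seq_along(values) - 1) * dt, values, unit = unit,
         lot_id = lot)
}

# The two-level noise-free step of the canonical segmentation example:
# 100 samples at 0, a 10-sample ramp 0.1..1, 100 samples at 1.
mk_two_level_step <- function() {
  mk_ts(c(rep(0, 100), seq(0.1, 1, by = 0.1), rep(1, 100)))
}

# A tiny QDB table as a data frame (parse_qdb_table accepts both).
mk_qdb_df <- function(n = 3) {
  data.frame(
    lot_id = sprintf("L%02d", seq_len(n)),
    f_a = seq_len(n) + 0.5,
    f_b = seq_len(n) * 2,
    sterile_filtration_start = sprintf("2019-01-0%dT00:00:00", seq_len(n)),
    sterile_filtration_end = sprintf("2019-01-0%dT02:00:00", seq_len(n)),
    lyophilization_start = sprintf("2019-01-0%dT03:00:00", seq_len(n)),
    lyophilization_end = sprintf("2019-01-0%dT09:00:00", seq_len(n)),
    stringsAsFactors = FALSE)
}

# A tiny campaign for pipeline-level tests (full 10-signal batches).
mk_small_campaign_spec <- function(seed = 1, n_lots = 8, ...) {
  campaign_spec(n_lots = n_lots, n_qdb_features = 12, n_constant_qdb = 2,
                seed = seed, ...)
}

# First principal angle (degrees) between the column spans of two
# orthonormal bases.
principal_angle <- function(a, b) {
  s <- svd(crossprod(a, b))$d
  acos(min(1, min(s))) * 180 / pi
}
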