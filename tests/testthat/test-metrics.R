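test_that("exceedance classifies by absolute below and relative above 100", {
  cfg <- metric_config()
  p1 <- make_pairs(90, 104)       # |delta| = 14 mg/dL at ref < 100
  ex1 <- exceedance_table(p1, cfg)
  expect_equal(ex1$n_exceed, c(0L, 0L, 0L, 0L))
  p2 <- make_pairs(200, 262)      # |rel| = 31 % at ref >= 100
  ex2 <- exceedance_table(p2, cfg)
  expect_equal(ex2$n_exceed, c(1L, 1L, 1L, 0L))
  # exactly-100 reference falls in the relative stratum
  p3 <- make_pairs(100, 118)      # 18 %: exceeds 15, not 20
  expect_equal(exceedance_table(p3, cfg)$n_exceed, c(1L, 0L, 0L, 0L))
  # strictness: 15 % exactly does not exceed 15
  p4 <- make_pairs(100, 115)
  expect_equal(exceedance_table(p4, cfg)$n_exceed[1], 0L)
  # empty input gives a defined zero-count result
  ex0 <- exceedance_table(make_pairs(numeric(0), numeric(0)), cfg)
  expect_equal(ex0$n_total, rep(0L, 4L))
})

test_that("exceedance percentage is monotone non-increasing in threshold and
           below/above shares partition the exceeding pairs", {
  set.seed(12)
  for (rep in 1:5) {
    ref <- stats::runif(300, 50, 350)
    cgm <- ref * (1 + stats::rnorm(300, 0, 0.2))
    ex <- exceedance_table(make_pairs(ref, cgm, minutes = 1:300))
    expect_true(all(diff(ex$pct_exceed) <= 0))
    has <- ex$n_exceed > 0
    expect_equal(ex$pct_cgm_below[has] + ex$pct_cgm_above[has],
                 rep(100, sum(has)))
  }
  # within-limits is the exact complement
  ref <- stats::runif(200, 50, 350)
  cgm <- ref * (1 + stats::rnorm(200, 0, 0.15))
  pp <- make_pairs(ref, cgm, minutes = 1:200)
  expect_equal(within_limits_table(pp)$pct_within,
               100 - exceedance_table(pp)$pct_exceed)
})

test_that("mad_mard strata, units and degenerate cases", {
  cfg <- metric_config()
  same <- make_pairs(c(80, 150), c(80, 150))
  mm <- mad_mard(same, cfg)
  expect_equal(mm$mad_mean, 0); expect_equal(mm$mard_mean, 0)

  single <- mad_mard(make_pairs(80, 90), cfg)
  expect_equal(single$mad_mean, 10); expect_equal(single$mad_n, 1L)
  expect_true(is.na(single$mard_mean)); expect_equal(single$mard_n, 0L)

  both <- mad_mard(make_pairs(c(80, 200), c(90, 250)), cfg)
  expect_equal(both$mad_mean, 10)
  expect_equal(both$mard_mean, 25)
  expect_equal(both$combined_mean, (10 + 25) / 2)
  expect_equal(both$whole_range_mard_mean, (100 * 10 / 80 + 25) / 2)
})

test_that("thin_hourly keeps the earliest pair per sensor-hour", {
  p <- make_pairs(rep(120, 4), c(121, 130, 140, 150), minutes = c(60, 75, 90, 105))
  th <- thin_hourly(p)
  expect_equal(nrow(th), 1L)
  expect_equal(th$cgm_value, 121)

  hourly <- make_pairs(rep(120, 3), 121:123, minutes = c(60, 120, 180))
  expect_equal(nrow(thin_hourly(hourly)), 3L)

  two_sensors <- rbind(make_pairs(120, 121, minutes = 65, site = "left"),
                       make_pairs(120, 122, minutes = 70, site = "right"))
  expect_equal(nrow(thin_hourly(two_sensors)), 2L)
})

test_that("pad_pard: identity, symmetry, and mismatch guard", {
  a <- make_sensor_tab(seq(0, 600, by = 5), 150 + sin((0:120) / 10) * 30)
  expect_equal(pad_pard(a, a)$pard_mean, 0)
  expect_equal(pad_pard(a, a)$pad_n + 0L, pad_pard(a, a)$pad_n)

  b <- make_sensor_tab(seq(0, 600, by = 5), 150 + cos((0:120) / 10) * 30,
                       site = "right")
  ab <- pad_pard(a, b); ba <- pad_pard(b, a)
  expect_equal(ab, ba)
  expect_equal(ab$n_minutes, 601L)

  other <- make_sensor_tab(seq(0, 600, by = 15), 150, system = "FL-like",
                           site = "right")
  expect_error(pad_pard(a, other), "same system")
  # disjoint wear: undefined with n = 0
  far <- make_sensor_tab(seq(2000, 2600, by = 5), 150, site = "right")
  expect_equal(pad_pard(a, far)$pad_n, 0L)
})

test_that("stratify partitions the pairs under every key", {
  st <- generate_study(zero_cfg(seed = 41L),
                       models = list("DG5-like" = sensor_error_model(),
                                     "FL-like" = sensor_error_model()))
  pairs <- build_pairs(st)
  for (key in c("phase", "wear_day", "glucose_range", "trend",
                "therapeutic_decision", "reference_method")) {
    groups <- stratify(pairs, key)
    expect_equal(sum(vapply(groups, nrow, integer(1))), nrow(pairs),
                 info = key)
  }
  expect_error(stratify(pairs, "nope"))
  # wear_day: a pair 10 h into wear is day 0
  p <- make_pairs(120, 125, minutes = 600)
  expect_named(stratify(p, "wear_day"), "day0")
})

test_that("trend stratification classifies known rising/falling sequences", {
  # dynamic references every 15 min climbing 30 mg/dL per step: +2 mg/dL/min
  up <- make_pairs(seq(100, 220, by = 30), seq(100, 220, by = 30) + 1,
                   minutes = seq(480, 540, by = 15), phase = "dynamic")
  lab_up <- stratify(up, "trend")
  expect_true("rising" %in% names(lab_up))
  expect_equal(nrow(lab_up$rising), 3L)  # interior points
  down <- make_pairs(seq(220, 100, by = -30), seq(220, 100, by = -30) - 1,
                     minutes = seq(480, 540, by = 15), phase = "dynamic")
  expect_equal(nrow(stratify(down, "trend")$falling), 3L)
  flat <- make_pairs(rep(120, 5), rep(121, 5),
                     minutes = seq(480, 540, by = 15), phase = "dynamic")
  expect_equal(nrow(stratify(flat, "trend")$stable), 3L)
})

test_that("unit aggregation is consistent: n adds up, means n-weight", {
  set.seed(99)
  ref <- stats::runif(400, 110, 300)
  cgm <- ref * (1 + stats::rnorm(400, 0, 0.1))
  pairs <- make_pairs(ref, cgm, minutes = 1:400)
  pairs$site <- rep(c("left", "right"), 200)
  pairs$sensor_seq <- rep(c(1L, 1L, 2L, 2L), 100)
  per_sensor <- summarize_units(pairs, "sensor")
  agg <- summarize_units(pairs, "aggregated")
  expect_equal(sum(per_sensor$mard_n), agg$mard_n)
  expect_equal(sum(per_sensor$mard_mean * per_sensor$mard_n) /
                 sum(per_sensor$mard_n),
               agg$mard_mean, tolerance = 1e-9)
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(c(0.05, 0.15, 0.25), 1), c(0.1, 0.2, 0.3))
  expect_equal(round_half_up(-0.15, 1), -0.2)
  expect_equal(round_half_up(24.25, 1), 24.3)
})
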