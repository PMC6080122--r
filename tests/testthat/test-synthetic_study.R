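test_that("profile generation is deterministic in the seed", {
  cfg <- study_config(n_participants = 1L, n_days = 2L,
                      visit_windows = list(c(0L, 2L)), dynamic_days = 1L,
                      seed = 5L)
  p1 <- simulate_profile(cfg, "P01", 123L)
  p2 <- simulate_profile(cfg, "P01", 123L)
  p3 <- simulate_profile(cfg, "P01", 124L)
  expect_identical(p1$value, p2$value)
  expect_false(identical(p1$value, p3$value))
})

test_that("all variance terms off and no meals gives a constant baseline", {
  cfg <- study_config(n_participants = 1L, n_days = 1L,
                      visit_windows = list(c(0L, 1L)),
                      dynamic_days = integer(0), circadian_amp_mgdl = 0,
                      ou_sd_mgdl = 0, meal_amps_mgdl = c(0, 0, 0),
                      seed = 1L)
  p <- simulate_profile(cfg, "P01", 1L)
  expect_true(all(p$value == cfg$baseline_mgdl))
})

test_that("dynamic days reach hyper- and hypoglycemia inside the window", {
  cfg <- study_config(seed = 9L)
  p <- simulate_profile(cfg, "P01", 42L)
  mins <- as.numeric(p$t - cfg$start_date, units = "mins")
  for (day in cfg$dynamic_days) {
    lo <- day * 1440 + cfg$breakfast_minute - cfg$dynamic_span_before
    hi <- day * 1440 + cfg$breakfast_minute + cfg$dynamic_span_after
    win <- p$value[mins >= lo & mins <= hi]
    expect_gt(max(win), 250)
    expect_lt(min(win), 70)
  }
  expect_true(all(p$value >= 40 & p$value <= 450))
})

test_that("lag filter matches the closed form on a linear ramp", {
  tau <- 8; r <- 1.5
  g <- 100 + r * (0:300)
  f <- lag_filter(g, tau)
  # analytic solution with T(0) = G(0):
  # T(t) = G(t) - r*tau + r*tau*exp(-t/tau)
  expected <- g - r * tau + r * tau * exp(-(0:300) / tau)
  expect_equal(f, expected, tolerance = 1e-9)
  expect_equal(f[301] - g[301], -r * tau, tolerance = 1e-9)
  expect_identical(lag_filter(g, 0), g)
})

test_that("the identity sensor reproduces the profile at sample times", {
  cfg <- zero_cfg()
  p <- simulate_profile(cfg, "P01", 3L)
  sim <- simulate_sensor(p, zero_error_model(), "DG5-like", "left", 1L,
                         cfg$start_date, cfg$start_date + 86400 * 3,
                         seed = 4L)
  tr <- sim$continuous
  idx <- match(as.numeric(tr$t), as.numeric(p$t))
  expect_false(anyNA(idx))
  expect_equal(tr$value, p$value[idx])
  # 5-min cadence and warm-up omission
  expect_true(all(diff(as.numeric(tr$t)) == 300))
  expect_equal(min(as.numeric(tr$t)), as.numeric(cfg$start_date) + 120 * 60)
})

test_that("dropout_prob 1 yields an empty trace; wear outside profile errors", {
  cfg <- zero_cfg()
  p <- simulate_profile(cfg, "P01", 3L)
  m <- sensor_error_model(dropout_prob = 1, lag_tau_minutes = 0)
  sim <- simulate_sensor(p, m, "DG5-like", "left", 1L, cfg$start_date,
                         cfg$start_date + 86400, seed = 4L)
  expect_equal(nrow(sim$continuous), 0L)
  expect_error(simulate_sensor(p, m, "DG5-like", "left", 1L, cfg$start_date,
                               cfg$start_date + 86400 * 10, seed = 4L),
               "outside the simulated profile")
})

test_that("meter duplicates follow the 10 mg/dL / 10 % concordance rule", {
  cfg0 <- zero_cfg()
  p <- simulate_profile(cfg0, "P01", 3L)
  refs <- simulate_reference(p, cfg0, "P01", 5L)
  bg <- refs[refs$method == "BGMS_capillary"]
  sizes <- table(bg$replicate_group)
  expect_true(all(sizes == 2L))  # zero meter error: rule never fires

  # gross meter error forces third measurements
  cfg_bad <- study_config(n_participants = 1L, n_days = 2L,
                          visit_windows = list(c(0L, 2L)), dynamic_days = 1L,
                          bgms_proportional_sd = 0.2, ou_sd_mgdl = 0,
                          seed = 8L)
  refs_bad <- simulate_reference(simulate_profile(cfg_bad, "P01", 3L),
                                 cfg_bad, "P01", 6L)
  bg_bad <- refs_bad[refs_bad$method == "BGMS_capillary"]
  expect_true(any(table(bg_bad$replicate_group) == 3L))
  expect_true(all(table(bg_bad$replicate_group) %in% 2:3))
  # the final replicate is always the last index of its group
  finals <- select_final_replicates(refs_bad)
  maxidx <- tapply(refs_bad$replicate_index, refs_bad$replicate_group, max)
  expect_equal(finals$replicate_index,
               as.integer(maxidx[finals$replicate_group]))
})

test_that("reference schedule matches the closed-form design counts", {
  cfg <- study_config(seed = 2L)
  sched <- reference_schedule(cfg)
  # plain in-house day: 18 hourly daytime slots + 1 nightly
  plain <- setdiff(inhouse_days(cfg), cfg$dynamic_days)
  for (d in plain)
    expect_equal(sum(sched$day == d), 19L)
  # dynamic day: 23-point 15-min grid (BGMS + venous) + slots outside the
  # window (06:00, 07:00, 14:00..23:00) + nightly
  for (d in cfg$dynamic_days) {
    expect_equal(sum(sched$day == d & sched$method == "HK_venous"), 23L)
    expect_equal(sum(sched$day == d & sched$phase == "dynamic" &
                       sched$method == "BGMS_capillary"), 23L)
    expect_equal(sum(sched$day == d & sched$phase == "in_house"), 13L)
  }
  for (d in home_days(cfg))
    expect_equal(sum(sched$day == d), cfg$home_bgm_per_day)
  # generated replicate groups conserve the schedule exactly
  p <- simulate_profile(cfg, "P01", 3L)
  refs <- simulate_reference(p, cfg, "P01", 4L)
  expect_equal(length(unique(refs$replicate_group)), nrow(sched))
})

test_that("tiny study has the right trace inventory and is deterministic", {
  cfg <- study_config(n_participants = 1L, n_days = 1L,
                      visit_windows = list(c(0L, 1L)),
                      dynamic_days = integer(0), seed = 3L)
  st <- generate_study(cfg)
  tr <- trace_table(st)
  expect_equal(sum(tr$system == "FL-like"), 2L)
  expect_equal(sum(tr$system == "DG5-like"), 2L)  # no replacement in 1 day
  expect_true(all(tr$sensor_seq == 1L))

  st2 <- generate_study(cfg)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_study(st, dir1); write_study(st2, dir2)
  for (f in c("continuous.csv", "scans.csv", "reference.csv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
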