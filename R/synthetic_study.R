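# Synthetic CGM wear-study generator.
#
# Emulates the structure of a 14-day head-to-head study: 20 participants,
# three clinic visits (48 h each) with one induced-excursion ("dynamic")
# morning per visit, home-use phases in between, duplicate meter (BGMS)
# measurements on a fixed schedule, venous laboratory samples during
# dynamic phases, two flash-type sensors worn 14 days and two pairs of
# 7-day CGM sensors with replacement at mid-study.
#
# The glucose process is phenomenological: baseline + circadian sinusoid +
# gamma-shaped meal responses + an Ornstein-Uhlenbeck fluctuation, at 1-min
# resolution. Sensors see a first-order lag-filtered ("tissue") version of
# it with proportional + additive Gaussian noise, bias, display clamping
# and i.i.d. dropout.

#' Study design configuration
#'
#' All schedule parameters of the synthetic study. Defaults encode the
#' emulated design: 20 participants, 14 days, visits on days `[0,2)`,
#' `[5,7)` and `[12,14)` (half-open day-index windows, i.e. 3 x 48 h
#' in-house with 72 h and 120 h home-use phases between), dynamic mornings
#' on days 1, 6 and 13, CGM sensor replacement at day 7, duplicate meter
#' measurements hourly 06:00-24:00 plus one nightly while in-house, every
#' 15 min from 30 min before breakfast to 5 h after on dynamic mornings,
#' and five per day at home.
#'
#' @param n_participants,n_days cohort size and study length in days.
#' @param visit_windows list of `c(first_day, end_day)` half-open day-index
#'   intervals spent in-house.
#' @param dynamic_days day indices with an induced rapid excursion.
#' @param dg5_replacement_day day at which the 7-day sensors are replaced.
#' @param home_bgm_per_day meter measurements per home-use day.
#' @param inhouse_bgm_interval_minutes in-house daytime measurement spacing.
#' @param dynamic_bgm_interval_minutes measurement spacing in the dynamic
#'   window.
#' @param dynamic_span_before,dynamic_span_after dynamic window extent in
#'   minutes around breakfast.
#' @param breakfast_minute,lunch_minute,dinner_minute,wake_minute,bed_minute,night_minute
#'   clock minutes (from midnight) anchoring the daily schedule.
#' @param start_date POSIXct study start (midnight, day 0).
#' @param baseline_mgdl,circadian_amp_mgdl,ou_sd_mgdl,ou_tau_minutes glucose
#'   process parameters: baseline level, circadian amplitude, stationary SD
#'   and mean-reversion time of the fluctuation term.
#' @param meal_amps_mgdl peak heights of the breakfast/lunch/dinner
#'   responses; `meal_peak_minutes` the time-to-peak.
#' @param dynamic_meal_amp_mgdl,dynamic_dip_amp_mgdl,dynamic_dip_peak_minutes
#'   enlarged breakfast response and delayed insulin-response dip used on
#'   dynamic days (sized so the excursion passes 250 mg/dL and later falls
#'   below 70 mg/dL inside the dynamic window).
#' @param bgms_proportional_sd,hk_proportional_sd,hk_bias_mgdl reference
#'   method error models (meter; venous laboratory method).
#' @param dup_limit_mgdl,dup_limit_pct duplicate concordance rule: meter
#'   duplicates may differ by at most 10 mg/dL (mean < 100 mg/dL) or 10 %
#'   (mean >= 100 mg/dL), otherwise a third measurement is taken.
#' @param seed master seed; all per-participant and per-sensor streams are
#'   derived from it.
#' @return A validated `study_config` list.
#' @export
study_config <- function(n_participants = 20L, n_days = 14L,
                         visit_windows = list(c(0L, 2L), c(5L, 7L), c(12L, 14L)),
                         dynamic_days = c(1L, 6L, 13L),
                         dg5_replacement_day = 7L,
                         home_bgm_per_day = 5L,
                         inhouse_bgm_interval_minutes = 60L,
                         dynamic_bgm_interval_minutes = 15L,
                         dynamic_span_before = 30L,
                         dynamic_span_after = 300L,
                         breakfast_minute = 480L, lunch_minute = 780L,
                         dinner_minute = 1140L, wake_minute = 420L,
                         bed_minute = 1380L, night_minute = 180L,
                         start_date = as.POSIXct("2016-03-01 00:00:00",
                                                 tz = "UTC"),
                         baseline_mgdl = 120, circadian_amp_mgdl = 10,
                         ou_sd_mgdl = 6, ou_tau_minutes = 30,
                         meal_amps_mgdl = c(80, 60, 70),
                         meal_peak_minutes = 45,
                         dynamic_meal_amp_mgdl = 170,
                         dynamic_dip_amp_mgdl = 120,
                         dynamic_dip_peak_minutes = 210,
                         bgms_proportional_sd = 0.025,
                         hk_proportional_sd = 0.02, hk_bias_mgdl = 0,
                         dup_limit_mgdl = 10, dup_limit_pct = 10,
                         seed = 20160301L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_days = as.integer(n_days),
              visit_windows = lapply(visit_windows, as.integer),
              dynamic_days = as.integer(dynamic_days),
              dg5_replacement_day = as.integer(dg5_replacement_day),
              home_bgm_per_day = as.integer(home_bgm_per_day),
              inhouse_bgm_interval_minutes = as.integer(inhouse_bgm_interval_minutes),
              dynamic_bgm_interval_minutes = as.integer(dynamic_bgm_interval_minutes),
              dynamic_span_before = as.integer(dynamic_span_before),
              dynamic_span_after = as.integer(dynamic_span_after),
              breakfast_minute = as.integer(breakfast_minute),
              lunch_minute = as.integer(lunch_minute),
              dinner_minute = as.integer(dinner_minute),
              wake_minute = as.integer(wake_minute),
              bed_minute = as.integer(bed_minute),
              night_minute = as.integer(night_minute),
              start_date = parse_utc(start_date),
              baseline_mgdl = baseline_mgdl,
              circadian_amp_mgdl = circadian_amp_mgdl,
              ou_sd_mgdl = ou_sd_mgdl, ou_tau_minutes = ou_tau_minutes,
              meal_amps_mgdl = meal_amps_mgdl,
              meal_peak_minutes = meal_peak_minutes,
              dynamic_meal_amp_mgdl = dynamic_meal_amp_mgdl,
              dynamic_dip_amp_mgdl = dynamic_dip_amp_mgdl,
              dynamic_dip_peak_minutes = dynamic_dip_peak_minutes,
              bgms_proportional_sd = bgms_proportional_sd,
              hk_proportional_sd = hk_proportional_sd,
              hk_bias_mgdl = hk_bias_mgdl,
              dup_limit_mgdl = dup_limit_mgdl,
              dup_limit_pct = dup_limit_pct,
              seed = as.integer(seed))
  if (cfg$n_participants < 1L || cfg$n_days < 1L)
    stop("need at least one participant and one day", call. = FALSE)
  for (w in cfg$visit_windows) {
    if (length(w) != 2L || w[1L] >= w[2L] || w[1L] < 0L || w[2L] > cfg$n_days)
      stop("visit windows must be half-open day intervals within [0, n_days]",
           call. = FALSE)
  }
  if (cfg$inhouse_bgm_interval_minutes <= 0L ||
      cfg$dynamic_bgm_interval_minutes <= 0L)
    stop("measurement intervals must be positive", call. = FALSE)
  if (!all(cfg$dynamic_days %in% inhouse_days(cfg)))
    stop("dynamic days must lie within visit windows", call. = FALSE)
  class(cfg) <- "study_config"
  cfg
}

#' Day-index helpers for a study configuration
#'
#' @param config a `study_config`.
#' @return Integer day indices spent in-house / at home.
#' @export
inhouse_days <- function(config) {
  sort(unique(unlist(lapply(config$visit_windows,
                            function(w) seq(w[1L], w[2L] - 1L)))))
}

#' @rdname inhouse_days
#' @export
home_days <- function(config) {
  setdiff(seq_len(config$n_days) - 1L, inhouse_days(config))
}

#' Sensor error model
#'
#' First-order tissue lag plus Gaussian proportional and additive noise,
#' additive bias, display clamping, i.i.d. sample dropout, and (for flash
#' systems) uniform jitter of scan times around the reference measurement
#' they accompany. Defaults are illustrative, chosen to land aggregated
#' MARD in the ~10 % range typical of the emulated devices; they are not
#' estimates of any real sensor.
#'
#' @param lag_tau_minutes time constant of the blood-to-tissue first-order
#'   lag (>= 0; 0 disables it).
#' @param bias_mgdl additive bias.
#' @param proportional_sd relative noise SD (dimensionless).
#' @param additive_sd_mgdl absolute noise SD.
#' @param dropout_prob per-sample missingness probability in `[0, 1]`
#'   (stored stream only; scans are deliberate user actions).
#' @param scan_jitter_seconds half-width of the uniform scan-time jitter
#'   around reference times (flash systems; default 120 s so the +/-3 min
#'   scan matcher is exercised near its edges).
#' @return A `sensor_error_model` list.
#' @export
sensor_error_model <- function(lag_tau_minutes = 8, bias_mgdl = 0,
                               proportional_sd = 0.09,
                               additive_sd_mgdl = 3, dropout_prob = 0.01,
                               scan_jitter_seconds = 120) {
  if (lag_tau_minutes < 0 || proportional_sd < 0 || additive_sd_mgdl < 0 ||
      scan_jitter_seconds < 0)
    stop("lag, noise SDs and jitter must be >= 0", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must be in [0, 1]", call. = FALSE)
  structure(list(lag_tau_minutes = lag_tau_minutes, bias_mgdl = bias_mgdl,
                 proportional_sd = proportional_sd,
                 additive_sd_mgdl = additive_sd_mgdl,
                 dropout_prob = dropout_prob,
                 scan_jitter_seconds = scan_jitter_seconds),
            class = "sensor_error_model")
}

#' An error-free sensor model (identity sensor)
#' @return `sensor_error_model` with every parameter zero.
#' @export
zero_error_model <- function() {
  sensor_error_model(lag_tau_minutes = 0, bias_mgdl = 0, proportional_sd = 0,
                     additive_sd_mgdl = 0, dropout_prob = 0,
                     scan_jitter_seconds = 0)
}

# deterministic seed stream: master and derived seeds stay below 2^31
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 2147483647 * 1000003 + k) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# unit-peak meal response: (u/tp)^2 exp(2 (1 - u/tp)), peak 1 at u = tp
.meal_shape <- function(u, tp) {
  out <- numeric(length(u))
  pos <- u > 0
  r <- u[pos] / tp
  out[pos] <- r^2 * exp(2 * (1 - r))
  out
}

#' Simulate a participant's true glucose profile
#'
#' Minute-resolution series over the whole study span:
#' baseline + circadian sinusoid + meal responses (enlarged breakfast and a
#' delayed insulin-response dip on dynamic days) + stationary
#' Ornstein-Uhlenbeck fluctuation, clamped to `[40, 450]` mg/dL.
#' Deterministic given `seed`.
#'
#' @param config a [study_config()].
#' @param participant_id identifier stored as an attribute.
#' @param seed integer seed for the fluctuation term.
#' @return data.table `(t, value)` with one row per minute, attributes
#'   `participant_id` and `start`.
#' @export
simulate_profile <- function(config, participant_id, seed) {
  n_min <- config$n_days * 1440L
  mins <- 0:n_min
  mod <- mins %% 1440L
  value <- rep(config$baseline_mgdl, length(mins)) +
    config$circadian_amp_mgdl * sin(2 * pi * (mod - 360) / 1440)

  meal_minutes <- c(config$breakfast_minute, config$lunch_minute,
                    config$dinner_minute)
  for (day in seq_len(config$n_days) - 1L) {
    dynamic <- day %in% config$dynamic_days
    amps <- config$meal_amps_mgdl
    if (dynamic) amps[1L] <- config$dynamic_meal_amp_mgdl
    for (m in seq_along(meal_minutes)) {
      u <- mins - (day * 1440L + meal_minutes[m])
      value <- value + amps[m] * .meal_shape(u, config$meal_peak_minutes)
    }
    if (dynamic) {
      u <- mins - (day * 1440L + config$breakfast_minute)
      value <- value - config$dynamic_dip_amp_mgdl *
        .meal_shape(u, config$dynamic_dip_peak_minutes)
    }
  }

  if (config$ou_sd_mgdl > 0) {
    value <- value + with_seed(seed, {
      a <- exp(-1 / config$ou_tau_minutes)
      z <- stats::rnorm(length(mins))
      x0 <- config$ou_sd_mgdl * z[1L]
      innov_sd <- config$ou_sd_mgdl * sqrt(1 - a^2)
      c(x0, as.numeric(stats::filter(innov_sd * z[-1L], a,
                                     method = "recursive", init = x0)))
    })
  }
  value <- pmin(pmax(value, 40), 450)
  out <- data.table::data.table(t = config$start_date + 60 * mins,
                                value = value)
  data.table::setattr(out, "participant_id", participant_id)
  data.table::setattr(out, "start", config$start_date)
  out
}

#' First-order lag filter (blood-to-tissue kinetics)
#'
#' Exact exponential integrator for `tau * dT/dt = G(t) - T(t)` assuming the
#' input is piecewise linear between samples. On a linear ramp of slope `r`
#' the steady-state output lags the input by exactly `r * tau`.
#'
#' @param values input series, sampled every `dt_minutes`.
#' @param tau_minutes time constant; 0 returns the input unchanged.
#' @param dt_minutes sample spacing.
#' @param init initial state (default: first input value).
#' @return Filtered series, same length.
#' @export
lag_filter <- function(values, tau_minutes, dt_minutes = 1,
                       init = values[1L]) {
  n <- length(values)
  if (tau_minutes <= 0 || n == 0L) return(values)
  a <- exp(-dt_minutes / tau_minutes)
  # exact response to a linear segment:
  #   T[i] = G[i] - s*tau + (T[i-1] - G[i-1] + s*tau) * a,  s = slope
  # rewritten as the linear recursion T[i] = a*T[i-1] + b[i]
  s <- diff(values) / dt_minutes
  b <- (values[-1L] - s * tau_minutes) - a * (values[-n] - s * tau_minutes)
  c(init, as.numeric(stats::filter(b, a, method = "recursive",
                                   init = init)))
}

#' Simulate one worn sensor
#'
#' Applies the error model to a true glucose profile: first-order lag,
#' sampling at the system cadence (5 min for DG5-like, 15 min for FL-like,
#' anchored at `wear_start`), proportional/additive Gaussian noise, bias,
#' display clamping, i.i.d. dropout, and warm-up omission. For FL-like
#' systems, scan events are generated at `scan_times` (typically the
#' reference measurement times) plus uniform jitter.
#'
#' @param profile output of [simulate_profile()].
#' @param model a [sensor_error_model()].
#' @param system `"DG5-like"` or `"FL-like"`.
#' @param site `"left"` or `"right"`.
#' @param sensor_seq replacement index (1-based).
#' @param wear_start,wear_end POSIXct wear interval (within the profile).
#' @param warmup_minutes default 120 (DG5-like) / 60 (FL-like).
#' @param scan_times POSIXct times at which the sensor is scanned
#'   (FL-like only; ignored otherwise).
#' @param seed integer seed.
#' @return list with elements `continuous` and `scans`, each a data.table in
#'   the study sensor-table layout.
#' @export
simulate_sensor <- function(profile, model, system, site, sensor_seq,
                            wear_start, wear_end, warmup_minutes = NULL,
                            scan_times = NULL, seed = 1L) {
  stopifnot(system %in% SYSTEMS, site %in% SITES,
            inherits(model, "sensor_error_model"))
  wear_start <- parse_utc(wear_start); wear_end <- parse_utc(wear_end)
  pt <- as.numeric(profile$t)
  if (as.numeric(wear_start) < pt[1L] || as.numeric(wear_end) > pt[length(pt)])
    stop("wear interval outside the simulated profile span", call. = FALSE)
  if (is.null(warmup_minutes))
    warmup_minutes <- if (system == "DG5-like") 120L else 60L
  cadence <- if (system == "DG5-like") 5L else 15L
  body_location <- if (system == "DG5-like") "abdomen" else "upper_arm"
  rng <- display_ranges()[[system]]

  tissue <- lag_filter(profile$value, model$lag_tau_minutes)
  tissue_at <- function(tt) stats::approx(pt, tissue, xout = tt)$y
  participant_id <- attr(profile, "participant_id")

  with_seed(seed, {
    st <- seq(as.numeric(wear_start), as.numeric(wear_end), by = 60 * cadence)
    st <- st[st >= as.numeric(wear_start) + 60 * warmup_minutes]
    noisy <- function(tt) {
      base <- tissue_at(tt)
      v <- base * (1 + stats::rnorm(length(tt), 0, model$proportional_sd)) +
        stats::rnorm(length(tt), 0, model$additive_sd_mgdl) + model$bias_mgdl
      pmin(pmax(v, rng[1L]), rng[2L])
    }
    cont_v <- noisy(st)
    keep <- stats::runif(length(st)) >= model$dropout_prob
    make_tab <- function(tt, vv) {
      data.table::data.table(
        system = system, participant_id = participant_id, site = site,
        body_location = body_location, sensor_seq = as.integer(sensor_seq),
        wear_start = wear_start, wear_end = wear_end,
        warmup_minutes = as.integer(warmup_minutes),
        t = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"), value = vv)
    }
    continuous <- make_tab(st[keep], cont_v[keep])
    scans <- make_tab(numeric(0), numeric(0))
    if (system == "FL-like" && length(scan_times)) {
      sc <- as.numeric(parse_utc(scan_times))
      jit <- if (model$scan_jitter_seconds > 0)
        round(stats::runif(length(sc), -model$scan_jitter_seconds,
                           model$scan_jitter_seconds)) else 0
      sc <- sc + jit
      ok <- sc >= as.numeric(wear_start) + 60 * warmup_minutes &
        sc <= as.numeric(wear_end)
      sc <- sort(unique(sc[ok]))
      if (length(sc)) scans <- make_tab(sc, noisy(sc))
    }
    list(continuous = continuous, scans = scans)
  })
}

#' The reference measurement schedule implied by a configuration
#'
#' Deterministic expansion of the design into measurement events (one row
#' per replicate group), independent of any participant: in-house days get
#' hourly daytime slots plus one nightly; dynamic days replace the slots
#' inside the dynamic window by a 15-min grid measured by both the meter
#' and the venous laboratory method; home days get `home_bgm_per_day`
#' events. Used both by the generator and as the closed-form count oracle.
#'
#' @param config a [study_config()].
#' @return data.table with columns `day`, `minute_of_day`, `minute`
#'   (since study start), `method`, `phase`, `therapeutic_decision`.
#' @export
reference_schedule <- function(config) {
  meal_mins <- c(config$breakfast_minute, config$lunch_minute,
                 config$dinner_minute)
  rows <- list()
  add <- function(day, mod, method, phase, td) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      day = day, minute_of_day = as.integer(mod),
      minute = as.integer(day * 1440L + mod), method = method, phase = phase,
      therapeutic_decision = td)
  }
  ih <- inhouse_days(config)
  dyn_lo <- config$breakfast_minute - config$dynamic_span_before
  dyn_hi <- config$breakfast_minute + config$dynamic_span_after
  for (day in seq_len(config$n_days) - 1L) {
    if (day %in% ih) {
      slots <- seq(360L, 1380L, by = config$inhouse_bgm_interval_minutes)
      dynamic <- day %in% config$dynamic_days
      if (dynamic) {
        grid <- seq(dyn_lo, dyn_hi, by = config$dynamic_bgm_interval_minutes)
        slots <- slots[slots < dyn_lo | slots > dyn_hi]
        add(day, grid, "BGMS_capillary", "dynamic", grid %in% meal_mins)
        add(day, grid, "HK_venous", "dynamic", FALSE)
      }
      add(day, slots, "BGMS_capillary", "in_house", slots %in% meal_mins)
      add(day, config$night_minute, "BGMS_capillary", "in_house", FALSE)
    } else {
      pool <- c(config$wake_minute, config$breakfast_minute,
                config$lunch_minute, config$dinner_minute, config$bed_minute,
                540L, 660L, 900L, 1020L, 1260L)
      mods <- sort(utils::head(unique(pool), config$home_bgm_per_day))
      add(day, mods, "BGMS_capillary", "home_use", mods %in% meal_mins)
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setorderv(out, c("minute", "method"))
  out[]
}

#' Simulate the reference measurements for one participant
#'
#' Meter (BGMS) events are measured in duplicate; when the two replicates
#' differ by more than the 10 mg/dL / 10 % concordance rule (below/above a
#' 100 mg/dL mean) a third replicate is drawn. The last replicate of each
#' group is flagged `is_final_replicate`. Venous laboratory (HK) events are
#' single measurements during dynamic windows only.
#'
#' @param profile output of [simulate_profile()].
#' @param config a [study_config()].
#' @param participant_id identifier.
#' @param seed integer seed.
#' @return data.table in the study reference-table layout.
#' @export
simulate_reference <- function(profile, config, participant_id, seed) {
  sched <- reference_schedule(config)
  truth <- profile$value[sched$minute + 1L]
  with_seed(seed, {
    rows <- vector("list", nrow(sched))
    for (i in seq_len(nrow(sched))) {
      tv <- truth[i]
      tm <- config$start_date + 60 * sched$minute[i]
      grp <- sprintf("%s-d%02d-m%04d-%s", participant_id, sched$day[i],
                     sched$minute_of_day[i],
                     if (sched$method[i] == "HK_venous") "HK" else "BGMS")
      if (sched$method[i] == "HK_venous") {
        v <- tv * (1 + stats::rnorm(1L, 0, config$hk_proportional_sd)) +
          config$hk_bias_mgdl
        vals <- v
      } else {
        vals <- tv * (1 + stats::rnorm(2L, 0, config$bgms_proportional_sd))
        if (.duplicates_discordant(vals[1L], vals[2L], config))
          vals <- c(vals, tv * (1 + stats::rnorm(1L, 0,
                                                 config$bgms_proportional_sd)))
      }
      k <- length(vals)
      rows[[i]] <- data.table::data.table(
        participant_id = participant_id, t = rep(tm, k), value = vals,
        method = sched$method[i], replicate_group = grp,
        replicate_index = seq_len(k),
        is_final_replicate = seq_len(k) == k,
        therapeutic_decision = sched$therapeutic_decision[i],
        phase = sched$phase[i])
    }
    out <- data.table::rbindlist(rows)
    data.table::setorderv(out, c("participant_id", "t", "replicate_index"))
    out[]
  })
}

.duplicates_discordant <- function(a, b, config) {
  m <- (a + b) / 2
  if (m < 100) abs(a - b) > config$dup_limit_mgdl
  else abs(a - b) > config$dup_limit_pct / 100 * m
}

#' Generate a complete synthetic study
#'
#' Per participant: two FL-like sensors (left/right upper arm, worn the full
#' study) and two pairs of DG5-like sensors (left/right abdomen, replaced at
#' `dg5_replacement_day`), plus the scheduled reference measurements. All
#' randomness is derived from `config$seed` by a counter scheme, so
#' regeneration is byte-identical.
#'
#' @param config a [study_config()].
#' @param models named list of [sensor_error_model()]s per system class.
#' @return A validated `cgm_study`.
#' @export
generate_study <- function(config = study_config(),
                           models = list("DG5-like" = sensor_error_model(),
                                         "FL-like" = sensor_error_model())) {
  stopifnot(inherits(config, "study_config"),
            all(SYSTEMS %in% names(models)))
  t0 <- config$start_date
  t_end <- t0 + 86400 * config$n_days
  repl <- min(config$dg5_replacement_day, config$n_days)
  conts <- list(); scans <- list(); refs <- list()
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    profile <- simulate_profile(config, pid, derive_seed(config$seed, i * 1000L))
    refs[[i]] <- simulate_reference(profile, config, pid,
                                    derive_seed(config$seed, i * 1000L + 1L))
    bgms_times <- unique(refs[[i]]$t[refs[[i]]$method == "BGMS_capillary"])
    counter <- 10L
    add_sensor <- function(system, site, seq_no, ws, we) {
      counter <<- counter + 1L
      sim <- simulate_sensor(
        profile, models[[system]], system, site, seq_no, ws, we,
        scan_times = if (system == "FL-like") bgms_times else NULL,
        seed = derive_seed(config$seed, i * 1000L + counter))
      conts[[length(conts) + 1L]] <<- sim$continuous
      scans[[length(scans) + 1L]] <<- sim$scans
    }
    for (site in SITES) {
      add_sensor("FL-like", site, 1L, t0, t_end)
      if (repl < config$n_days) {
        add_sensor("DG5-like", site, 1L, t0, t0 + 86400 * repl)
        add_sensor("DG5-like", site, 2L, t0 + 86400 * repl, t_end)
      } else {
        add_sensor("DG5-like", site, 1L, t0, t_end)
      }
    }
  }
  study <- cgm_study(data.table::rbindlist(conts),
                     data.table::rbindlist(scans),
                     data.table::rbindlist(refs))
  validate_study(study)
  study
}
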