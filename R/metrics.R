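# Deviation and precision statistics.
#
# Field convention implemented throughout: below 100 mg/dL (reference, or
# sensor-pair mean for precision) differences are absolute in mg/dL, at or
# above 100 mg/dL they are relative. "Exceeding" a threshold is strict
# (> not >=); the ISO-15197-style "within limits" analysis is the exact
# complement (<=). Summaries are mean +/- population SD of the per-pair
# quantities. Percent rounding (half-up, one decimal) happens only at
# reporting, never inside intermediate computation.

#' Metric configuration
#'
#' @param split_mgdl cutoff separating absolute from relative statistics;
#'   references exactly at the cutoff fall in the relative stratum
#'   (default 100).
#' @param thresholds_mgdl_or_pct exceedance thresholds, read as mg/dL below
#'   the split and as percent at/above it (default 15, 20, 30, 50).
#' @param glucose_bins interior cut points of the glucose-range
#'   stratification (default 70 and 180, i.e. <70 / 70-180 / >180).
#' @param trend_threshold_mgdl_min rate of change beyond which the
#'   reference is classified rising/falling (default 1 mg/dL/min).
#' @return A `metric_config` list.
#' @export
metric_config <- function(split_mgdl = 100,
                          thresholds_mgdl_or_pct = c(15, 20, 30, 50),
                          glucose_bins = c(70, 180),
                          trend_threshold_mgdl_min = 1) {
  if (split_mgdl <= 0) stop("split must be positive", call. = FALSE)
  th <- thresholds_mgdl_or_pct
  if (any(th <= 0) || is.unsorted(th))
    stop("thresholds must be positive and sorted", call. = FALSE)
  structure(list(split_mgdl = split_mgdl, thresholds_mgdl_or_pct = th,
                 glucose_bins = sort(glucose_bins),
                 trend_threshold_mgdl_min = trend_threshold_mgdl_min),
            class = "metric_config")
}

#' Round half-up
#'
#' Decimal rounding with ties away from zero (the convention used for
#' reported percentages), unlike `round()`'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pop_sd <- function(x) {
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

.exceeds <- function(pairs, h, cfg) {
  below <- pairs$ref_value < cfg$split_mgdl
  (below & abs(pairs$delta) > h) | (!below & abs(pairs$rel_delta) > h / 100)
}

#' Threshold-exceedance table
#'
#' For each threshold `h`, the share of pairs whose deviation exceeds
#' `h` mg/dL (reference below the split) or `h` % (at/above the split),
#' strictly, together with how the exceeding pairs divide into sensor
#' reading below vs above the reference.
#'
#' @param pairs paired observations ([build_pairs()] layout).
#' @param cfg a [metric_config()].
#' @return data.table with one row per threshold: `threshold`, `n_exceed`,
#'   `pct_exceed`, `pct_cgm_below`, `pct_cgm_above` (shares of the
#'   exceeding pairs), `n_total`. Percentages are unrounded.
#' @export
exceedance_table <- function(pairs, cfg = metric_config()) {
  n <- nrow(pairs)
  rows <- lapply(cfg$thresholds_mgdl_or_pct, function(h) {
    if (n == 0L)
      return(data.table::data.table(threshold = h, n_exceed = 0L,
                                    pct_exceed = NA_real_,
                                    pct_cgm_below = NA_real_,
                                    pct_cgm_above = NA_real_, n_total = 0L))
    ex <- .exceeds(pairs, h, cfg)
    ne <- sum(ex)
    data.table::data.table(
      threshold = h, n_exceed = ne, pct_exceed = 100 * ne / n,
      pct_cgm_below = if (ne) 100 * sum(pairs$delta[ex] < 0) / ne else NA_real_,
      pct_cgm_above = if (ne) 100 * sum(pairs$delta[ex] > 0) / ne else NA_real_,
      n_total = n)
  })
  data.table::rbindlist(rows)
}

#' ISO-15197-style "within limits" table
#'
#' The exact complement of [exceedance_table()]: the share of pairs whose
#' deviation is at most the threshold (`<=`).
#'
#' @inheritParams exceedance_table
#' @return data.table `threshold`, `n_within`, `pct_within`, `n_total`.
#' @export
within_limits_table <- function(pairs, cfg = metric_config()) {
  ex <- exceedance_table(pairs, cfg)
  data.table::data.table(threshold = ex$threshold,
                         n_within = ex$n_total - ex$n_exceed,
                         pct_within = 100 - ex$pct_exceed,
                         n_total = ex$n_total)
}

#' MAD / MARD deviation summary
#'
#' Mean absolute difference (mg/dL) over pairs with reference below the
#' split, mean absolute relative difference (%) over pairs at/above it,
#' each with population SD and n; plus the combined per-pair statistic
#' (|delta| mg/dL below the split, 100 |rel_delta| at/above it) and the
#' whole-range MARD over all pairs regardless of level.
#'
#' @inheritParams exceedance_table
#' @return One-row data.table: `n_pairs`, `mad_mean`, `mad_sd`, `mad_n`,
#'   `mard_mean`, `mard_sd`, `mard_n` (percent scale), `combined_mean`,
#'   `whole_range_mard_mean`, `whole_range_mard_sd`. Empty strata give
#'   `NA` with n = 0.
#' @export
mad_mard <- function(pairs, cfg = metric_config()) {
  below <- pairs$ref_value < cfg$split_mgdl
  ad <- abs(pairs$delta)[below]
  ard <- 100 * abs(pairs$rel_delta)[!below]
  combined <- ifelse(below, abs(pairs$delta), 100 * abs(pairs$rel_delta))
  wr <- 100 * abs(pairs$rel_delta)
  data.table::data.table(
    n_pairs = nrow(pairs),
    mad_mean = if (length(ad)) mean(ad) else NA_real_,
    mad_sd = pop_sd(ad), mad_n = length(ad),
    mard_mean = if (length(ard)) mean(ard) else NA_real_,
    mard_sd = pop_sd(ard), mard_n = length(ard),
    combined_mean = if (nrow(pairs)) mean(combined) else NA_real_,
    whole_range_mard_mean = if (nrow(pairs)) mean(wr) else NA_real_,
    whole_range_mard_sd = pop_sd(wr))
}

#' Thin pairs to at most one per sensor and clock hour
#'
#' Keeps the earliest pair within each (participant, system, site,
#' sensor_seq, pairing mode, clock hour) cell, so densely sampled phases
#' (one reference every 15 min) do not dominate hour-scale summaries.
#'
#' @param pairs paired observations.
#' @return The retained subset, original order within the kept rows.
#' @export
thin_hourly <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  x <- data.table::as.data.table(pairs)
  hour <- floor(as.numeric(x$ref_time) / 3600)
  x[, .hour := hour]
  data.table::setorderv(x, c("participant_id", "system", "site", "sensor_seq",
                             "pairing_mode", "ref_time"))
  out <- x[, .SD[1L], by = c("participant_id", "system", "site", "sensor_seq",
                             "pairing_mode", ".hour")]
  out[, .hour := NULL]
  out[]
}

#' Sensor-to-sensor precision (PAD / PARD)
#'
#' Both traces are linearly interpolated to one value per minute; on common
#' minutes the absolute between-sensor difference is classified by the pair
#' mean against the split: PAD (mg/dL, mean below the split) and PARD
#' (percent of the pair mean, at/above the split). Symmetric in the two
#' traces by construction.
#'
#' @param traceA,traceB continuous readings of two sensors of the same
#'   system worn by the same participant (study layout).
#' @param cfg a [metric_config()].
#' @param pcfg a [pairing_config()] (interpolation gap rule).
#' @return One-row data.table: `pad_mean`, `pad_sd`, `pad_n`, `pard_mean`,
#'   `pard_sd`, `pard_n`, `n_minutes`. No overlap gives `NA`s with n = 0.
#' @export
pad_pard <- function(traceA, traceB, cfg = metric_config(),
                     pcfg = pairing_config()) {
  if (nrow(traceA) && nrow(traceB)) {
    if (traceA$system[1L] != traceB$system[1L] ||
        traceA$participant_id[1L] != traceB$participant_id[1L])
      stop("pad_pard: traces must be same system and participant",
           call. = FALSE)
  }
  empty <- data.table::data.table(pad_mean = NA_real_, pad_sd = NA_real_,
                                  pad_n = 0L, pard_mean = NA_real_,
                                  pard_sd = NA_real_, pard_n = 0L,
                                  n_minutes = 0L)
  if (nrow(traceA) < 2L || nrow(traceB) < 2L) return(empty)
  ia <- interpolate_minutely(traceA, pcfg)
  ib <- interpolate_minutely(traceB, pcfg)
  ia <- ia[as.numeric(ia$t) %% 60 == 0]
  ib <- ib[as.numeric(ib$t) %% 60 == 0]
  common <- merge(ia, ib, by = "t")
  if (nrow(common) == 0L) return(empty)
  d <- abs(common$value.x - common$value.y)
  m <- (common$value.x + common$value.y) / 2
  below <- m < cfg$split_mgdl
  pad <- d[below]
  pard <- 100 * d[!below] / m[!below]
  data.table::data.table(
    pad_mean = if (length(pad)) mean(pad) else NA_real_,
    pad_sd = pop_sd(pad), pad_n = length(pad),
    pard_mean = if (length(pard)) mean(pard) else NA_real_,
    pard_sd = pop_sd(pard), pard_n = length(pard),
    n_minutes = nrow(common))
}

#' Stratify pairs by a study dimension
#'
#' Splits the pair set into groups that partition it. Keys:
#' `phase` (in-house / home-use / dynamic), `wear_day` (whole days since
#' the sensor's wear start), `glucose_range` (reference level bins),
#' `trend` (reference rate of change by centered difference over adjacent
#' final-replicate meter values within the dynamic phase: rising above
#' +1 mg/dL/min, falling below -1, stable otherwise; pairs without a
#' computable dynamic-phase rate are grouped as `unclassified`),
#' `therapeutic_decision`, and `reference_method`.
#'
#' @param pairs paired observations.
#' @param key one of the strings above.
#' @param cfg a [metric_config()].
#' @return Named list of disjoint data.tables covering the input.
#' @export
stratify <- function(pairs, key = c("phase", "wear_day", "glucose_range",
                                    "trend", "therapeutic_decision",
                                    "reference_method"),
                     cfg = metric_config()) {
  key <- match.arg(key)
  x <- data.table::as.data.table(pairs)
  lab <- switch(key,
    phase = x$phase,
    wear_day = sprintf("day%d", floor(as.numeric(x$ref_time) -
                                        as.numeric(x$wear_start)) %/% 86400),
    glucose_range = {
      cuts <- cfg$glucose_bins
      labs <- c(sprintf("<%g", cuts[1L]),
                if (length(cuts) > 1L)
                  sprintf("%g-%g", cuts[-length(cuts)], cuts[-1L]),
                sprintf(">%g", cuts[length(cuts)]))
      as.character(cut(x$ref_value, c(-Inf, cuts, Inf), labels = labs,
                       right = TRUE))
    },
    trend = .trend_labels(x, cfg),
    therapeutic_decision = ifelse(x$therapeutic_decision, "decision",
                                  "no_decision"),
    reference_method = x$method)
  split(x, lab)
}

# reference rate of change around each dynamic-phase measurement, centered
# difference over the participant's adjacent final-replicate meter values
.trend_labels <- function(x, cfg) {
  lab <- rep("unclassified", nrow(x))
  dyn <- x$phase == "dynamic" & x$method == "BGMS_capillary"
  if (!any(dyn)) return(lab)
  refs <- unique(x[dyn, c("participant_id", "ref_time", "ref_value")])
  data.table::setorderv(refs, c("participant_id", "ref_time"))
  refs[, rate := {
    n <- .N
    if (n < 3L) rep(NA_real_, n)
    else c(NA_real_,
           (ref_value[3:n] - ref_value[1:(n - 2L)]) /
             ((as.numeric(ref_time[3:n]) - as.numeric(ref_time[1:(n - 2L)])) / 60),
           NA_real_)
  }, by = "participant_id"]
  idx <- match(paste(x$participant_id, as.numeric(x$ref_time)),
               paste(refs$participant_id, as.numeric(refs$ref_time)))
  rate <- refs$rate[idx]
  th <- cfg$trend_threshold_mgdl_min
  lab[!is.na(rate) & rate > th] <- "rising"
  lab[!is.na(rate) & rate < -th] <- "falling"
  lab[!is.na(rate) & abs(rate) <= th] <- "stable"
  lab
}
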