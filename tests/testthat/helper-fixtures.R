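# Shared fixture builders: everything is constructed in code, no files.

T0 <- as.POSIXct("2016-03-01 00:00:00", tz = "UTC")

# one sensor's readings in the study table layout, times in minutes from T0
make_sensor_tab <- function(minutes, values, system = "DG5-like",
                            pid = "P01", site = "left", sensor_seq = 1L,
                            wear_start = T0, wear_days = 14,
                            warmup_minutes = 0L) {
  data.table::data.table(
    system = system, participant_id = pid, site = site,
    body_location = if (system == "DG5-like") "abdomen" else "upper_arm",
    sensor_seq = as.integer(sensor_seq), wear_start = wear_start,
    wear_end = wear_start + 86400 * wear_days,
    warmup_minutes = as.integer(warmup_minutes),
    t = wear_start + 60 * minutes, value = as.numeric(values))
}

# reference rows; `final` defaults to one-replicate groups
make_ref_tab <- function(minutes, values, pid = "P01",
                         method = "BGMS_capillary", phase = "in_house",
                         td = FALSE, group = NULL, replicate_index = 1L,
                         final = TRUE) {
  n <- length(minutes)
  if (is.null(group)) group <- sprintf("%s-g%03d", pid, seq_len(n))
  data.table::data.table(
    participant_id = pid, t = T0 + 60 * minutes, value = as.numeric(values),
    method = method, replicate_group = group,
    replicate_index = as.integer(replicate_index),
    is_final_replicate = final, therapeutic_decision = td, phase = phase)
}

# minimal pair rows for metric tests (only the columns metrics consume)
make_pairs <- function(ref, cgm, minutes = seq_along(ref) * 60,
                       pid = "P01", system = "DG5-like", site = "left",
                       sensor_seq = 1L, mode = "LOCF", phase = "in_house",
                       method = "BGMS_capillary", td = FALSE,
                       wear_start = T0) {
  data.table::data.table(
    participant_id = pid, system = system, site = site,
    body_location = "abdomen", sensor_seq = as.integer(sensor_seq),
    wear_start = wear_start, pairing_mode = mode,
    ref_time = T0 + 60 * minutes, ref_value = as.numeric(ref),
    method = method, phase = phase, therapeutic_decision = td,
    replicate_group = sprintf("%s-g%03d", pid, seq_along(ref)),
    cgm_time = T0 + 60 * minutes, cgm_value = as.numeric(cgm),
    delta = cgm - ref, rel_delta = (cgm - ref) / ref)
}

# a small error-free study: 2 participants, 3 days, one 48-h visit with a
# dynamic morning on day 1
zero_cfg <- function(seed = 11L, ...) {
  study_config(n_participants = 2L, n_days = 3L,
               visit_windows = list(c(0L, 2L)), dynamic_days = 1L,
               bgms_proportional_sd = 0, hk_proportional_sd = 0,
               ou_sd_mgdl = 0, seed = seed, ...)
}

zero_models <- function() {
  list("DG5-like" = zero_error_model(), "FL-like" = zero_error_model())
}

# brute-force LOCF oracle: linear scan over every trace point
locf_oracle <- function(trace, ref_time, window_minutes = 5) {
  tn <- as.numeric(trace$t)
  rt <- as.numeric(ref_time)
  ok <- tn >= rt - 60 * window_minutes & tn <= rt
  if (!any(ok)) return(NULL)
  i <- max(which(ok))
  data.table::data.table(t = trace$t[i], value = trace$value[i])
}
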