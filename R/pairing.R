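# Pairing rules: turn sensor traces + reference measurements into paired
# observations. Three modes, reflecting what a user would have seen:
#   LOCF         - last stored value within 5 min before the reference
#                  (closed interval: a reading exactly 5 min old qualifies)
#   SCAN         - scanned value within +/-3 min of the reference; among
#                  several candidates the closest wins, ties break toward
#                  the earlier scan (the value the user saw first)
#   INTERPOLATED - continuous records linearly interpolated; evaluated at
#                  the exact reference time from the bracketing records
#                  (never snapped to the minute grid), with a configurable
#                  maximum bridgeable gap

#' Pairing configuration
#'
#' @param locf_window_minutes LOCF look-back window, closed on both ends
#'   (default 5).
#' @param scan_window_minutes scan matching half-window (default 3).
#' @param max_interpolation_gap_minutes largest record spacing across which
#'   linear interpolation is allowed (default 30, i.e. 2-6x the nominal
#'   cadences; unlimited interpolation across outages would fabricate data).
#' @param warmup_excluded exclude references falling in a sensor's warm-up
#'   (default `TRUE`; the devices report nothing then).
#' @return A `pairing_config` list. The interpolation step is fixed at
#'   one minute.
#' @export
pairing_config <- function(locf_window_minutes = 5, scan_window_minutes = 3,
                           max_interpolation_gap_minutes = 30,
                           warmup_excluded = TRUE) {
  if (locf_window_minutes <= 0 || scan_window_minutes <= 0 ||
      max_interpolation_gap_minutes <= 0)
    stop("pairing windows must be positive", call. = FALSE)
  structure(list(locf_window_minutes = locf_window_minutes,
                 scan_window_minutes = scan_window_minutes,
                 interpolation_step_minutes = 1,
                 max_interpolation_gap_minutes = max_interpolation_gap_minutes,
                 warmup_excluded = isTRUE(warmup_excluded)),
            class = "pairing_config")
}

#' Reduce reference replicates to the final measurement of each group
#'
#' Duplicate (or, after a discordant pair, triplicate) meter measurements
#' are collapsed to the last obtained result, which is the value used for
#' calibration and therapeutic decisions.
#'
#' @param refs reference table (study layout).
#' @return The rows flagged `is_final_replicate`, one per replicate group.
#' @export
select_final_replicates <- function(refs) {
  refs <- data.table::as.data.table(refs)
  if (nrow(refs) == 0L) return(refs)
  nfinal <- tapply(refs$is_final_replicate, refs$replicate_group, sum)
  bad <- names(nfinal)[nfinal != 1L]
  if (length(bad))
    stop("replicate group(s) without exactly one final replicate: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  refs[refs$is_final_replicate]
}

#' Match a reference time to the last stored sensor value (LOCF)
#'
#' Returns the latest continuous reading `p` with
#' `ref_time - window <= p$t <= ref_time`, or `NULL` when none exists.
#' Both bounds are closed.
#'
#' @param trace continuous readings of one sensor (study layout), sorted in
#'   time, warm-up already excluded.
#' @param ref_time POSIXct reference time.
#' @param cfg a [pairing_config()].
#' @return One-row data.table (`t`, `value`) or `NULL`.
#' @export
match_locf <- function(trace, ref_time, cfg = pairing_config()) {
  tn <- as.numeric(trace$t)
  rt <- as.numeric(parse_utc(ref_time))
  idx <- findInterval(rt, tn)
  if (idx < 1L || tn[idx] < rt - 60 * cfg$locf_window_minutes) return(NULL)
  data.table::data.table(t = trace$t[idx], value = trace$value[idx])
}

#' Match a reference time to the nearest scan
#'
#' Among scans within `+/- scan_window_minutes` of the reference, returns
#' the one with the smallest absolute time offset; an exact tie breaks
#' toward the earlier scan. `NULL` when no scan qualifies.
#'
#' @param trace scanned readings of one FL-like sensor (study layout),
#'   sorted in time.
#' @inheritParams match_locf
#' @return One-row data.table (`t`, `value`) or `NULL`.
#' @export
match_scan <- function(trace, ref_time, cfg = pairing_config()) {
  if (nrow(trace) && any(trace$system == "DG5-like"))
    stop("match_scan: DG5-like systems have no scanned stream",
         call. = FALSE)
  tn <- as.numeric(trace$t)
  rt <- as.numeric(parse_utc(ref_time))
  if (!length(tn)) return(NULL)
  win <- 60 * cfg$scan_window_minutes
  idx <- findInterval(rt, tn)
  cand <- unique(pmin(pmax(c(idx, idx + 1L), 1L), length(tn)))
  d <- abs(tn[cand] - rt)
  cand <- cand[d <= win]
  if (!length(cand)) return(NULL)
  d <- abs(tn[cand] - rt)
  best <- cand[d == min(d)]
  best <- min(best)  # tie -> earlier scan
  data.table::data.table(t = trace$t[best], value = trace$value[best])
}

#' Linearly interpolate a trace to one value per minute
#'
#' Produces values on every whole minute strictly between consecutive
#' recorded points whose spacing does not exceed the configured gap, plus
#' the recorded points themselves (preserved exactly). No extrapolation
#' beyond the first or last record.
#'
#' @param trace continuous readings of one sensor, sorted in time, at least
#'   two points.
#' @param cfg a [pairing_config()].
#' @return data.table (`t`, `value`) sorted in time.
#' @export
interpolate_minutely <- function(trace, cfg = pairing_config()) {
  if (nrow(trace) < 2L)
    stop("interpolate_minutely: need at least two recorded points",
         call. = FALSE)
  tn <- as.numeric(trace$t)
  v <- trace$value
  gap <- 60 * cfg$max_interpolation_gap_minutes
  out_t <- list(tn)
  out_v <- list(v)
  for (i in seq_len(length(tn) - 1L)) {
    if (tn[i + 1L] - tn[i] > gap) next
    mins <- seq(ceiling(tn[i] / 60) * 60, floor(tn[i + 1L] / 60) * 60, by = 60)
    mins <- mins[mins > tn[i] & mins < tn[i + 1L]]
    if (!length(mins)) next
    out_t[[length(out_t) + 1L]] <- mins
    out_v[[length(out_v) + 1L]] <-
      v[i] + (mins - tn[i]) / (tn[i + 1L] - tn[i]) * (v[i + 1L] - v[i])
  }
  tt <- unlist(out_t); vv <- unlist(out_v)
  o <- order(tt)
  data.table::data.table(t = as.POSIXct(tt[o], origin = "1970-01-01",
                                        tz = "UTC"),
                         value = vv[o])
}

# interpolated value at exact times (no grid snapping); NA where a time is
# outside the record span or falls in a larger-than-gap segment
interpolate_at <- function(trace, times, cfg = pairing_config()) {
  tn <- as.numeric(trace$t)
  v <- trace$value
  tt <- as.numeric(parse_utc(times))
  out <- rep(NA_real_, length(tt))
  if (length(tn) < 2L) {
    if (length(tn) == 1L) out[tt == tn] <- v[1L]
    return(out)
  }
  gap <- 60 * cfg$max_interpolation_gap_minutes
  idx <- findInterval(tt, tn)
  exact <- idx >= 1L & tt == tn[pmax(idx, 1L)]
  out[exact] <- v[idx[exact]]
  inner <- which(!exact & idx >= 1L & idx < length(tn))
  if (length(inner)) {
    i <- idx[inner]
    ok <- (tn[i + 1L] - tn[i]) <= gap
    j <- inner[ok]; i <- i[ok]
    out[j] <- v[i] + (tt[j] - tn[i]) / (tn[i + 1L] - tn[i]) * (v[i + 1L] - v[i])
  }
  out
}

#' Build paired observations from a study
#'
#' For every final-replicate reference measurement and every sensor of the
#' same participant worn at that time (post warm-up), emits at most one
#' pair per (sensor, mode): `LOCF` (DG5-like by default, optionally
#' FL-like), `SCAN` (FL-like only), and `INTERPOLATED` (continuous records
#' only, both systems). `delta = cgm - ref` and `rel_delta = delta / ref`
#' are populated.
#'
#' @param study a validated `cgm_study`.
#' @param cfg a [pairing_config()].
#' @param modes subset of `c("LOCF", "SCAN", "INTERPOLATED")`.
#' @param locf_systems systems the LOCF mode applies to (default DG5-like
#'   only, matching how flash data are usually reported).
#' @return data.table of paired observations, one row per pair, with the
#'   reference annotations, the sensor key, `pairing_mode`, `cgm_time`,
#'   `cgm_value`, `delta` and `rel_delta`.
#' @export
build_pairs <- function(study, cfg = pairing_config(),
                        modes = c("LOCF", "SCAN", "INTERPOLATED"),
                        locf_systems = "DG5-like") {
  modes <- match.arg(modes, PAIRING_MODES, several.ok = TRUE)
  finals <- select_final_replicates(study$reference)
  traces <- trace_table(study)
  out <- list()
  for (k in seq_len(nrow(traces))) {
    tr <- traces[k]
    cont <- get_trace(study, tr$system, tr$participant_id, tr$site,
                      tr$sensor_seq, "continuous")
    scn <- get_trace(study, tr$system, tr$participant_id, tr$site,
                     tr$sensor_seq, "scans")
    lo <- as.numeric(tr$wear_start) +
      if (cfg$warmup_excluded) 60 * tr$warmup_minutes else 0
    hi <- as.numeric(tr$wear_end)
    refs <- finals[finals$participant_id == tr$participant_id &
                     as.numeric(finals$t) >= lo & as.numeric(finals$t) <= hi]
    if (nrow(refs) == 0L) next
    emit <- function(mode, cgm_t, cgm_v) {
      ok <- !is.na(cgm_v)
      if (!any(ok)) return()
      r <- refs[ok]
      out[[length(out) + 1L]] <<- data.table::data.table(
        participant_id = tr$participant_id, system = tr$system,
        site = tr$site, body_location = tr$body_location,
        sensor_seq = tr$sensor_seq, wear_start = tr$wear_start,
        pairing_mode = mode, ref_time = r$t, ref_value = r$value,
        method = r$method, phase = r$phase,
        therapeutic_decision = r$therapeutic_decision,
        replicate_group = r$replicate_group,
        cgm_time = as.POSIXct(cgm_t[ok], origin = "1970-01-01", tz = "UTC"),
        cgm_value = cgm_v[ok], delta = cgm_v[ok] - r$value,
        rel_delta = (cgm_v[ok] - r$value) / r$value)
    }
    if ("LOCF" %in% modes && tr$system %in% locf_systems && nrow(cont)) {
      tn <- as.numeric(cont$t)
      rt <- as.numeric(refs$t)
      idx <- findInterval(rt, tn)
      good <- idx >= 1L & tn[pmax(idx, 1L)] >= rt - 60 * cfg$locf_window_minutes
      cgm_t <- ifelse(good, tn[pmax(idx, 1L)], NA_real_)
      cgm_v <- ifelse(good, cont$value[pmax(idx, 1L)], NA_real_)
      emit("LOCF", cgm_t, cgm_v)
    }
    if ("SCAN" %in% modes && tr$system == "FL-like" && nrow(scn)) {
      tn <- as.numeric(scn$t)
      rt <- as.numeric(refs$t)
      idx <- findInterval(rt, tn)
      win <- 60 * cfg$scan_window_minutes
      pick <- function(j) {
        cand <- unique(pmin(pmax(c(idx[j], idx[j] + 1L), 1L), length(tn)))
        d <- abs(tn[cand] - rt[j])
        cand <- cand[d <= win]
        if (!length(cand)) return(NA_integer_)
        d <- abs(tn[cand] - rt[j])
        min(cand[d == min(d)])
      }
      sel <- vapply(seq_along(rt), pick, integer(1L))
      cgm_t <- ifelse(is.na(sel), NA_real_, tn[ifelse(is.na(sel), 1L, sel)])
      cgm_v <- ifelse(is.na(sel), NA_real_,
                      scn$value[ifelse(is.na(sel), 1L, sel)])
      emit("SCAN", cgm_t, cgm_v)
    }
    if ("INTERPOLATED" %in% modes && nrow(cont) >= 2L) {
      cgm_v <- interpolate_at(cont, refs$t, cfg)
      emit("INTERPOLATED", as.numeric(refs$t), cgm_v)
    }
  }
  if (!length(out)) return(.empty_pairs())
  res <- data.table::rbindlist(out)
  data.table::setorderv(res, c("participant_id", "system", "site",
                               "sensor_seq", "pairing_mode", "ref_time"))
  res[]
}

.empty_pairs <- function() {
  data.table::data.table(
    participant_id = character(), system = character(), site = character(),
    body_location = character(), sensor_seq = integer(),
    wear_start = as.POSIXct(character(), tz = "UTC"),
    pairing_mode = character(),
    ref_time = as.POSIXct(character(), tz = "UTC"), ref_value = numeric(),
    method = character(), phase = character(),
    therapeutic_decision = logical(), replicate_group = character(),
    cgm_time = as.POSIXct(character(), tz = "UTC"), cgm_value = numeric(),
    delta = numeric(), rel_delta = numeric())
}
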