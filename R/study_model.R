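# Core containers and CSV interchange for CGM performance studies.
#
# A study is a list of three tables:
#   continuous : stored sensor readings, one row per reading, with the
#                sensor's wear metadata repeated on every row
#   scans      : scanned readings (flash systems only), same layout
#   reference  : blood-glucose comparison measurements with replicate,
#                phase and therapeutic-decision annotations
#
# Conventions (single source of truth):
#   * time is POSIXct UTC, second resolution; serialized as
#     "YYYY-MM-DDTHH:MM:SSZ"; all window arithmetic is in seconds
#   * glucose is mg/dL everywhere (mmol/L offered as a reader option only)
#   * a sensor trace is keyed by (system, participant_id, site, sensor_seq)

SYSTEMS <- c("DG5-like", "FL-like")
SITES <- c("left", "right")
BODY_LOCATIONS <- c("abdomen", "upper_arm")
REF_METHODS <- c("BGMS_capillary", "HK_venous")
PHASES <- c("in_house", "home_use", "dynamic")
PAIRING_MODES <- c("LOCF", "SCAN", "INTERPOLATED")

#' Display ranges of supported system classes
#'
#' Default display clamp ranges in mg/dL, used by the synthetic generator
#' (values are clamped on simulation, never on reading) and by validation.
#'
#' @return Named list of length-2 numeric vectors `c(lo, hi)`.
#' @export
display_ranges <- function() {
  list("DG5-like" = c(40, 400), "FL-like" = c(40, 500))
}

MMOL_PER_MGDL_FACTOR <- 18.016

.trace_cols <- c("system", "participant_id", "site", "body_location",
                 "sensor_seq", "wear_start", "wear_end", "warmup_minutes")
.cont_cols <- c(.trace_cols, "t", "value")
.ref_cols <- c("participant_id", "t", "value", "method", "replicate_group",
               "replicate_index", "is_final_replicate", "therapeutic_decision",
               "phase")

#' Parse / format UTC timestamps
#'
#' @param x character vector `"YYYY-MM-DDTHH:MM:SSZ"` (or anything
#'   `as.POSIXct` accepts as fallback) / POSIXct vector.
#' @return POSIXct (UTC) / character vector.
#' @export
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate_free_utc(x))
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) out[bad] <- as.POSIXct(x[bad], tz = "UTC")
  out
}

lubridate_free_utc <- function(x) {
  attr(x, "tzone") <- "UTC"
  x
}

#' @rdname parse_utc
#' @export
format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Construct a CGM study object
#'
#' Bundles the three study tables into a `cgm_study` object. Columns are
#' coerced to canonical types; rows are ordered by trace key and time.
#' Use [validate_study()] to check invariants.
#'
#' @param continuous data.frame of stored sensor readings (see
#'   `cgmperf:::.cont_cols` for required columns).
#' @param scans data.frame of scanned readings, same columns; may be `NULL`
#'   or empty (always empty for DG5-like systems).
#' @param reference data.frame of reference measurements (see
#'   `cgmperf:::.ref_cols`).
#' @return An object of class `cgm_study`.
#' @export
cgm_study <- function(continuous, scans = NULL, reference) {
  continuous <- .coerce_sensor_table(continuous, "continuous")
  scans <- .coerce_sensor_table(scans, "scans")
  reference <- .coerce_reference_table(reference)
  structure(list(continuous = continuous, scans = scans,
                 reference = reference),
            class = "cgm_study")
}

.empty_sensor_table <- function() {
  data.table::data.table(
    system = character(), participant_id = character(), site = character(),
    body_location = character(), sensor_seq = integer(),
    wear_start = as.POSIXct(character(), tz = "UTC"),
    wear_end = as.POSIXct(character(), tz = "UTC"),
    warmup_minutes = integer(),
    t = as.POSIXct(character(), tz = "UTC"), value = numeric())
}

.empty_reference_table <- function() {
  data.table::data.table(
    participant_id = character(), t = as.POSIXct(character(), tz = "UTC"),
    value = numeric(), method = character(), replicate_group = character(),
    replicate_index = integer(), is_final_replicate = logical(),
    therapeutic_decision = logical(), phase = character())
}

.coerce_sensor_table <- function(x, what) {
  if (is.null(x) || nrow(x) == 0L) return(.empty_sensor_table())
  missing <- setdiff(.cont_cols, names(x))
  if (length(missing))
    stop(sprintf("%s.csv: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  x <- data.table::as.data.table(x)[, .cont_cols, with = FALSE]
  for (col in c("wear_start", "wear_end", "t"))
    data.table::set(x, j = col, value = parse_utc(x[[col]]))
  for (col in c("system", "participant_id", "site", "body_location"))
    data.table::set(x, j = col, value = as.character(x[[col]]))
  data.table::set(x, j = "sensor_seq", value = as.integer(x[["sensor_seq"]]))
  data.table::set(x, j = "warmup_minutes",
                  value = as.integer(x[["warmup_minutes"]]))
  data.table::set(x, j = "value", value = as.numeric(x[["value"]]))
  data.table::setorderv(x, c("system", "participant_id", "site", "sensor_seq",
                             "t"))
  x[]
}

.coerce_reference_table <- function(x) {
  if (is.null(x) || nrow(x) == 0L) return(.empty_reference_table())
  missing <- setdiff(.ref_cols, names(x))
  if (length(missing))
    stop(sprintf("reference.csv: missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  x <- data.table::as.data.table(x)[, .ref_cols, with = FALSE]
  data.table::set(x, j = "t", value = parse_utc(x[["t"]]))
  for (col in c("participant_id", "method", "replicate_group", "phase"))
    data.table::set(x, j = col, value = as.character(x[[col]]))
  data.table::set(x, j = "replicate_index",
                  value = as.integer(x[["replicate_index"]]))
  for (col in c("is_final_replicate", "therapeutic_decision"))
    data.table::set(x, j = col, value = as.logical(x[[col]]))
  data.table::set(x, j = "value", value = as.numeric(x[["value"]]))
  data.table::setorderv(x, c("participant_id", "t", "replicate_index"))
  x[]
}

#' @export
print.cgm_study <- function(x, ...) {
  tr <- trace_table(x)
  cat(sprintf(
    "<cgm_study> %d trace(s), %d continuous, %d scanned, %d reference rows\n",
    nrow(tr), nrow(x$continuous), nrow(x$scans), nrow(x$reference)))
  if (nrow(tr)) {
    counts <- table(tr$system)
    cat("  traces by system:",
        paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Unique sensor traces of a study
#'
#' @param study a `cgm_study`.
#' @return data.table with one row per (system, participant_id, site,
#'   sensor_seq) and the wear metadata.
#' @export
trace_table <- function(study) {
  both <- data.table::rbindlist(list(study$continuous, study$scans))
  if (nrow(both) == 0L) return(.empty_sensor_table()[, .trace_cols, with = FALSE])
  unique(both[, .trace_cols, with = FALSE],
         by = c("system", "participant_id", "site", "sensor_seq"))
}

#' Extract a single trace's readings
#'
#' @inheritParams trace_table
#' @param system,participant_id,site,sensor_seq trace key.
#' @param stream `"continuous"` or `"scans"`.
#' @return data.table of readings for the one trace (possibly empty).
#' @export
get_trace <- function(study, system, participant_id, site, sensor_seq,
                      stream = c("continuous", "scans")) {
  stream <- match.arg(stream)
  x <- study[[stream]]
  keep <- x$system == system & x$participant_id == participant_id &
    x$site == site & x$sensor_seq == sensor_seq
  x[which(keep)]
}

#' Validate a CGM study
#'
#' Checks every type invariant: enum membership, strictly increasing
#' timestamps within a trace, readings inside the post-warm-up wear
#' interval, per-trace wear-metadata consistency, display-range membership,
#' exactly one final replicate per reference group, and phase labelling.
#' All violations are collected (with trace keys and row numbers) and
#' reported together.
#'
#' @param study a `cgm_study`.
#' @param ranges display ranges, as [display_ranges()].
#' @param stop_on_error if `TRUE` (default) violations raise one error
#'   listing everything found; otherwise they are returned.
#' @return (invisibly) character vector of violation messages, empty when
#'   the study is valid.
#' @export
validate_study <- function(study, ranges = display_ranges(),
                           stop_on_error = TRUE) {
  stopifnot(inherits(study, "cgm_study"))
  problems <- character()
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  check_sensor <- function(tab, what) {
    if (nrow(tab) == 0L) return()
    bad_sys <- !tab$system %in% SYSTEMS
    if (any(bad_sys))
      note("%s: unknown system %s (rows %s)", what,
           paste(unique(tab$system[bad_sys]), collapse = ","),
           .rowlist(which(bad_sys)))
    bad_site <- !tab$site %in% SITES
    if (any(bad_site))
      note("%s: unknown site (rows %s)", what, .rowlist(which(bad_site)))
    bad_loc <- !tab$body_location %in% BODY_LOCATIONS
    if (any(bad_loc))
      note("%s: unknown body_location (rows %s)", what,
           .rowlist(which(bad_loc)))
    if (identical(what, "scans") && any(tab$system == "DG5-like"))
      note("scans: DG5-like systems have no scanned stream (rows %s)",
           .rowlist(which(tab$system == "DG5-like")))
    key <- paste(tab$system, tab$participant_id, tab$site, tab$sensor_seq,
                 sep = "/")
    for (k in unique(key)) {
      idx <- which(key == k)
      tt <- tab$t[idx]
      if (is.unsorted(tt, strictly = TRUE))
        note("%s: trace %s has non-increasing timestamps (rows %s)",
             what, k, .rowlist(idx[which(diff(as.numeric(tt)) <= 0) + 1L]))
      ws <- tab$wear_start[idx]; we <- tab$wear_end[idx]
      wu <- tab$warmup_minutes[idx]
      if (length(unique(as.numeric(ws))) > 1L ||
          length(unique(as.numeric(we))) > 1L || length(unique(wu)) > 1L)
        note("%s: trace %s has inconsistent wear metadata", what, k)
      lo <- as.numeric(ws[1L]) + 60 * wu[1L]
      hi <- as.numeric(we[1L])
      out <- as.numeric(tt) < lo | as.numeric(tt) > hi
      if (any(out))
        note("%s: trace %s has readings outside [wear_start+warmup, wear_end] (rows %s)",
             what, k, .rowlist(idx[out]))
      rng <- ranges[[tab$system[idx[1L]]]]
      if (!is.null(rng)) {
        outside <- tab$value[idx] < rng[1L] | tab$value[idx] > rng[2L]
        if (any(outside))
          note("%s: trace %s has values outside display range [%g, %g] (rows %s)",
               what, k, rng[1L], rng[2L], .rowlist(idx[outside]))
      }
    }
  }
  check_sensor(study$continuous, "continuous")
  check_sensor(study$scans, "scans")

  ref <- study$reference
  if (nrow(ref)) {
    bad_m <- !ref$method %in% REF_METHODS
    if (any(bad_m))
      note("reference: unknown method (rows %s)", .rowlist(which(bad_m)))
    bad_p <- !ref$phase %in% PHASES
    if (any(bad_p))
      note("reference: unknown phase (rows %s)", .rowlist(which(bad_p)))
    if (any(ref$value <= 0))
      note("reference: non-positive glucose value (rows %s)",
           .rowlist(which(ref$value <= 0)))
    if (any(ref$replicate_index < 1L))
      note("reference: replicate_index < 1 (rows %s)",
           .rowlist(which(ref$replicate_index < 1L)))
    nfinal <- tapply(ref$is_final_replicate, ref$replicate_group, sum)
    off <- nfinal != 1L
    if (any(off))
      note("reference: replicate group(s) without exactly one final replicate: %s",
           paste(utils::head(names(nfinal)[off], 5L), collapse = ", "))
  }

  if (length(problems) && stop_on_error)
    stop("study validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(problems)
}

.rowlist <- function(idx, max = 5L) {
  shown <- utils::head(idx, max)
  extra <- if (length(idx) > max) sprintf(", ... (%d total)", length(idx)) else ""
  paste0(paste(shown, collapse = ","), extra)
}

#' Read a study from its CSV interchange files
#'
#' Expects `continuous.csv`, `reference.csv` and (optionally) `scans.csv`
#' in `path`, UTF-8, comma-separated, `"."` decimal separator, with the
#' canonical header row. Timestamps are ISO 8601 UTC. Values may optionally
#' be converted from mmol/L on input.
#'
#' @param path directory containing the files.
#' @param units `"mgdl"` (default) or `"mmol"`; with `"mmol"` glucose values
#'   are multiplied by 18.016 on input so the in-memory unit is always mg/dL.
#' @param validate run [validate_study()] after reading (default `TRUE`).
#' @return A `cgm_study`.
#' @export
read_study <- function(path, units = c("mgdl", "mmol"), validate = TRUE) {
  units <- match.arg(units)
  fp <- function(f) file.path(path, f)
  if (!file.exists(fp("continuous.csv")))
    stop("not a study directory (no continuous.csv): ", path, call. = FALSE)
  read1 <- function(f) {
    if (!file.exists(fp(f))) return(NULL)
    data.table::fread(fp(f), sep = ",", dec = ".", tz = "UTC")
  }
  cont <- read1("continuous.csv")
  scans <- read1("scans.csv")
  ref <- read1("reference.csv")
  if (is.null(ref))
    stop("not a study directory (no reference.csv): ", path, call. = FALSE)
  if (units == "mmol") {
    if (nrow(cont)) cont$value <- cont$value * MMOL_PER_MGDL_FACTOR
    if (!is.null(scans) && nrow(scans))
      scans$value <- scans$value * MMOL_PER_MGDL_FACTOR
    if (nrow(ref)) ref$value <- ref$value * MMOL_PER_MGDL_FACTOR
  }
  study <- cgm_study(cont, scans, ref)
  if (validate) validate_study(study)
  study
}

#' Write a study to its CSV interchange files
#'
#' Deterministic output: fixed column order, rows sorted by trace key and
#' time, ISO 8601 UTC timestamps, `%.6g` numeric formatting. Writing then
#' reading a valid study reproduces it field-for-field.
#'
#' @param study a `cgm_study` (validated before writing).
#' @param path output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_study <- function(study, path) {
  validate_study(study)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt_num <- function(v) sub("^(-?\\d+)\\.?0*$", "\\1", sprintf("%.6f", v))
  sensor_out <- function(tab) {
    out <- data.table::copy(tab)
    for (col in c("wear_start", "wear_end", "t"))
      data.table::set(out, j = col, value = format_utc(out[[col]]))
    data.table::set(out, j = "value", value = fmt_num(out[["value"]]))
    out
  }
  ref_out <- data.table::copy(study$reference)
  data.table::set(ref_out, j = "t", value = format_utc(ref_out[["t"]]))
  data.table::set(ref_out, j = "value", value = fmt_num(ref_out[["value"]]))
  files <- c(continuous = file.path(path, "continuous.csv"),
             scans = file.path(path, "scans.csv"),
             reference = file.path(path, "reference.csv"))
  data.table::fwrite(sensor_out(study$continuous), files[["continuous"]])
  data.table::fwrite(sensor_out(study$scans), files[["scans"]])
  data.table::fwrite(ref_out, files[["reference"]])
  invisible(files)
}
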