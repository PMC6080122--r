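# Consensus (Parkes) error grid, type 1 diabetes variant.
#
# Zone boundaries are piecewise-linear transition curves between
# consecutive risk zones (A|B, B|C, C|D upper and lower of the identity
# line; D|E upper only -- the type 1 grid has no lower E region). The
# vertex table ships as inst/extdata/ceg_type1_boundaries.csv, taken from
# the published technical description of the consensus grid so it is
# auditable and swappable. Points exactly on a boundary belong to the
# lower-risk zone. The domain is [0, 550] mg/dL on both axes; out-of-range
# input is rejected, never clamped.

CEG_DOMAIN <- c(0, 550)

#' Load consensus error grid boundaries
#'
#' @param path CSV of boundary vertices with columns `transition`
#'   (`"A-B_upper"`, `"A-B_lower"`, ..., `"D-E_upper"`), `vertex` (order),
#'   `reference_mgdl`, `cgm_mgdl`. Defaults to the packaged type 1 grid.
#' @return A `ceg_boundaries` object: lists of upper/lower transition
#'   polylines in increasing risk order.
#' @export
ceg_boundaries <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ceg_type1_boundaries.csv",
                        package = "cgmperf", mustWork = TRUE)
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transition", "vertex", "reference_mgdl", "cgm_mgdl") %in%
                  names(v)))
  v <- v[order(v$transition, v$vertex), ]
  get_poly <- function(tr) {
    p <- v[v$transition == tr, ]
    if (nrow(p) == 0L) return(NULL)
    list(x = p$reference_mgdl, y = p$cgm_mgdl)
  }
  upper <- Filter(Negate(is.null),
                  lapply(c("A-B_upper", "B-C_upper", "C-D_upper", "D-E_upper"),
                         get_poly))
  lower <- Filter(Negate(is.null),
                  lapply(c("A-B_lower", "B-C_lower", "C-D_lower", "D-E_lower"),
                         get_poly))
  for (p in c(upper, lower))
    if (is.unsorted(p$x)) stop("boundary polyline not monotone in reference",
                               call. = FALSE)
  structure(list(upper = upper, lower = lower), class = "ceg_boundaries")
}

# boundary height at reference x; outside the polyline's x-range the
# boundary is never crossed (`Inf` above, `-Inf` below). Duplicated x
# values (vertical segments) keep the outermost vertex for interpolation
# beyond them; points lying ON a vertical segment are handled separately
# so they stay in the lower-risk zone.
.boundary_at <- function(poly, x, side) {
  yl <- if (side == "upper") Inf else -Inf
  stats::approx(poly$x, poly$y, xout = x, ties = max, yleft = yl,
                yright = yl)$y
}

# TRUE where (x, y) lies on a vertical segment of the polyline
.on_vertical <- function(poly, x, y) {
  out <- rep(FALSE, length(x))
  dup <- which(diff(poly$x) == 0)
  for (i in dup) {
    ylo <- min(poly$y[i], poly$y[i + 1L])
    yhi <- max(poly$y[i], poly$y[i + 1L])
    out <- out | (x == poly$x[i] & y >= ylo & y <= yhi)
  }
  out
}

#' Assign consensus error grid zones
#'
#' Vectorized zone lookup: the risk zone of each (reference, sensor) pair.
#' Boundary points are assigned the lower-risk zone. Inputs outside
#' `[0, 550]` mg/dL raise an error.
#'
#' @param ref,cgm numeric vectors, mg/dL.
#' @param boundaries a [ceg_boundaries()] object.
#' @return factor with levels `A` to `E`.
#' @export
ceg_zone <- function(ref, cgm, boundaries = ceg_boundaries()) {
  stopifnot(inherits(boundaries, "ceg_boundaries"),
            length(ref) == length(cgm))
  if (any(is.na(ref)) || any(is.na(cgm)) ||
      any(ref < CEG_DOMAIN[1L] | ref > CEG_DOMAIN[2L]) ||
      any(cgm < CEG_DOMAIN[1L] | cgm > CEG_DOMAIN[2L]))
    stop("ceg_zone: values must be within [0, 550] mg/dL", call. = FALSE)
  up <- integer(length(ref))
  for (p in boundaries$upper)
    up <- up + as.integer(cgm > .boundary_at(p, ref, "upper"))
  lo <- integer(length(ref))
  for (p in boundaries$lower)
    lo <- lo + as.integer(cgm < .boundary_at(p, ref, "lower") &
                            !.on_vertical(p, ref, cgm))
  factor(LETTERS[1L + pmax(up, lo)], levels = c("A", "B", "C", "D", "E"))
}

#' Consensus error grid zone summary
#'
#' @param pairs paired observations ([build_pairs()] layout) or any table
#'   with `ref_value` and `cgm_value` columns.
#' @param boundaries a [ceg_boundaries()] object.
#' @return data.table with one row per zone: `zone`, `n`, `pct`
#'   (unrounded; `NA` when there are no pairs) and the common denominator
#'   `n_total`.
#' @export
ceg_summary <- function(pairs, boundaries = ceg_boundaries()) {
  n <- nrow(pairs)
  if (n == 0L)
    return(data.table::data.table(zone = c("A", "B", "C", "D", "E"), n = 0L,
                                  pct = NA_real_, n_total = 0L))
  z <- ceg_zone(pairs$ref_value, pairs$cgm_value, boundaries)
  counts <- table(z)
  data.table::data.table(zone = names(counts), n = as.integer(counts),
                         pct = 100 * as.integer(counts) / n, n_total = n)
}
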