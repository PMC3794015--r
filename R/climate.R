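# Temporally continuous paleoclimate: per-cell, per-variable linear blend of
# glacial and interglacial end-members, indexed by the isotope-proxy global
# mean annual temperature.

#' Blend weight for a time slice
#'
#' The interpolation weight `alpha = (MAT(t) - mat_glacial) /
#' (mat_modern - mat_glacial)`: 1 reproduces the modern end-member, 0 the
#' glacial end-member.  `alpha` may exceed 1 (linear extrapolation for
#' interglacials warmer than present).
#'
#' @param isotope an [isotope_series()].
#' @param t slice age, ka BP; must be one of the series' slice times.
#' @return Numeric scalar.
#' @export
blend_alpha <- function(isotope, t) {
  i <- match_slice(isotope, t)
  (isotope$mat_c[i] - attr(isotope, "mat_glacial")) /
    (attr(isotope, "mat_modern") - attr(isotope, "mat_glacial"))
}

match_slice <- function(isotope, t) {
  i <- which(abs(isotope$time_ka - t) < 1e-9)
  if (!length(i))
    stop("no such slice: t = ", t,
         " ka is not in the series (no nearest-slice snapping; ",
         "use slices_in_window() to map ages to slices)")
  i[1]
}

#' Slices overlapping an age window
#'
#' Maps an arbitrary age window to the modeled slice times it contains.
#'
#' @param isotope an [isotope_series()].
#' @param age_min,age_max window bounds, ka BP (`age_min <= age_max`).
#' @return Numeric vector of slice times inside the window (possibly after
#'   widening a between-slice window to its bracketing pair).
#' @export
slices_in_window <- function(isotope, age_min, age_max) {
  if (age_min > age_max) stop("`age_min` must not exceed `age_max`")
  times <- slice_times(isotope)
  if (age_max < min(times) || age_min > max(times))
    stop("age window [", age_min, ", ", age_max,
         "] ka lies outside the modeled slices")
  hit <- times[times >= age_min - 1e-9 & times <= age_max + 1e-9]
  if (length(hit)) return(hit)
  # window falls strictly between two slices: return the bracketing pair
  lo <- max(times[times < age_min]); hi <- min(times[times > age_max])
  c(lo, hi)
}

#' Interpolate a paleoclimate slice between end-members
#'
#' Every cell/variable value at time `t` is the linear blend
#' `X_t = alpha * X_modern + (1 - alpha) * X_glacial` with `alpha` from
#' [blend_alpha()].  At `alpha = 1` the result is identical to the modern
#' grid, at `alpha = 0` to the glacial grid; `alpha > 1` extrapolates
#' linearly for interglacials warmer than present.
#'
#' @param modern,glacial end-member [climate_grid()]s on the same lattice.
#' @param isotope an [isotope_series()].
#' @param t slice age, ka BP; must be one of the series' slice times.
#' @return A [climate_grid()] at time `t`.
#' @export
interpolate_slice <- function(modern, glacial, isotope, t) {
  if (!same_lattice(modern, glacial))
    stop("incompatible grids: modern and glacial must share the lattice")
  vars <- intersect(colnames(modern$values), colnames(glacial$values))
  if (!length(vars)) stop("incompatible grids: no shared variables")
  a <- blend_alpha(isotope, t)
  vals <- a * modern$values[, vars, drop = FALSE] +
    (1 - a) * glacial$values[, vars, drop = FALSE]
  climate_grid(modern$cells, vals, modern$cell_area, time_ka = t)
}

#' Interpolate the full series of paleoclimate slices
#'
#' @inheritParams interpolate_slice
#' @param times slice ages to interpolate (default: all series slices).
#' @return Named list of [climate_grid()]s, names the slice ages.
#' @export
interpolate_series <- function(modern, glacial, isotope,
                               times = slice_times(isotope)) {
  out <- lapply(times, function(t)
    interpolate_slice(modern, glacial, isotope, t))
  names(out) <- as.character(times)
  out
}

#' Per-variable climate bounds over a cell set
#'
#' Min--max bounds of the available climate over a reference cell set, in
#' the same bounds form as a niche envelope.  Used as the reference for
#' available-climate MESS maps and non-analogue detection.
#'
#' @param grid a [climate_grid()].
#' @param cell_ids reference cells (default: all cells).
#' @param variables variables to bound (default: all in the grid).
#' @return A [niche_envelope()] with provenance `"available-climate"`.
#' @export
climate_bounds <- function(grid, cell_ids = NULL, variables = NULL) {
  v <- grid_values(grid, cell_ids, variables)
  if (!nrow(v)) stop("empty reference cell set")
  niche_envelope(apply(v, 2, min), apply(v, 2, max),
                 provenance = "available-climate")
}

#' Non-analogue climate map
#'
#' Combined MESS score of every cell of a paleoclimate grid against the
#' per-variable min--max bounds of a reference grid.  Cells with negative
#' scores hold climate combinations outside the reference period's climate
#' space on at least one variable (non-analogue climate).
#'
#' @param paleo grid to score.
#' @param reference grid providing the reference bounds.
#' @param variables variables to use (default: variables shared by both).
#' @return data.frame with `cell_id`, `mess` (combined score) and
#'   `limiting` (name of the score-limiting variable).
#' @export
nonanalogue_map <- function(paleo, reference,
                            variables = intersect(colnames(paleo$values),
                                                  colnames(reference$values))) {
  bounds <- climate_bounds(reference, variables = variables)
  m <- mess_grid(bounds, paleo, mode = "combined")
  m
}
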