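#' Bioclimatic variable names
#'
#' The 19 standard bioclimatic variables.  `BIO1`--`BIO11` are temperature
#' variables in degrees Celsius, `BIO12`--`BIO19` precipitation variables in
#' millimetres.
#'
#' @format Character vectors of variable names.
#' @name bioclim_vars
NULL

#' @rdname bioclim_vars
#' @export
BIOCLIM_VARS <- paste0("BIO", 1:19)

#' @rdname bioclim_vars
#' @export
BIOCLIM_TEMP_VARS <- paste0("BIO", 1:11)

#' @rdname bioclim_vars
#' @export
BIOCLIM_PRECIP_VARS <- paste0("BIO", 12:19)

#' Default modeling variable subset
#'
#' Eight moderately correlated bioclimatic variables used by default to fit
#' niche envelopes: mean diurnal range (BIO2), maximum temperature of the
#' warmest month (BIO5), mean temperature of the wettest quarter (BIO8),
#' mean temperature of the warmest quarter (BIO10) and precipitation of the
#' wettest, driest, warmest and coldest quarters (BIO16--BIO19).
#'
#' Published variable lists for this subset sometimes label the warm-month
#' maximum "BIO6"; conventionally BIO6 is the minimum temperature of the
#' coldest month and BIO5 the warm-month maximum.  The conventional BIO5
#' definition is used here, and every fitting function accepts a
#' `variables` argument so the subset can be overridden.
#'
#' @export
MODELING_VARS <- c("BIO2", "BIO5", "BIO8", "BIO10",
                   "BIO16", "BIO17", "BIO18", "BIO19")

# temperature *level* variables: shifted by a uniform cooling, unlike the
# range/variability variables (BIO2, BIO3, BIO4, BIO7), which are
# differences of temperatures and invariant under a uniform offset
TEMP_LEVEL_VARS <- c("BIO1", "BIO5", "BIO6", "BIO8", "BIO9", "BIO10", "BIO11")

# order used to break ties "by canonical BIO ordering"
bio_order <- function(vars) {
  idx <- suppressWarnings(as.integer(sub("^BIO", "", vars)))
  idx[is.na(idx)] <- .Machine$integer.max
  order(idx, vars)
}

#' Construct an equal-area climate grid
#'
#' A climate grid is a regular equal-area lattice of cells, each carrying a
#' vector of bioclimatic values for one time slice.  Cell centres are in a
#' projected coordinate system in kilometres; every cell has the same area.
#'
#' @param cells data.frame with columns `cell_id` (unique integer), `x`, `y`
#'   (cell-centre coordinates, km).
#' @param values numeric matrix, one row per cell, columns named after
#'   bioclimatic variables (e.g. `"BIO1"`).  No missing values are allowed.
#' @param cell_area cell area in km^2 (all cells share it; default 50).
#' @param time_ka age of the slice in thousand years before present.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(cells, values, cell_area = 50, time_ka = 0) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "x", "y") %in% names(cells)))
  values <- as.matrix(values)
  if (nrow(values) != nrow(cells))
    stop("`values` must have one row per cell")
  if (anyDuplicated(cells$cell_id))
    stop("cell ids must be unique")
  if (anyNA(values))
    stop("missing values inside the modeled domain are not allowed")
  if (is.null(colnames(values)))
    stop("`values` columns must be named after bioclimatic variables")
  if (all(c("BIO5", "BIO6") %in% colnames(values)) &&
      any(values[, "BIO5"] < values[, "BIO6"]))
    stop("BIO5 must be >= BIO6 in every cell")
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0)
    stop("`cell_area` must be a positive scalar")
  structure(
    list(cells = cells[, c("cell_id", "x", "y")],
         values = values,
         cell_area = cell_area,
         time_ka = time_ka),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d cells x %d variables, %.0f km^2/cell, t = %g ka BP\n",
              nrow(x$values), ncol(x$values), x$cell_area, x$time_ka))
  invisible(x)
}

#' Number of cells in a climate grid
#' @param grid a `climate_grid`.
#' @export
n_cells <- function(grid) nrow(grid$cells)

# do two grids share the identical lattice?
same_lattice <- function(a, b) {
  isTRUE(all.equal(a$cells, b$cells)) && a$cell_area == b$cell_area
}

#' Extract climate values for a set of cells
#'
#' @param grid a `climate_grid`.
#' @param cell_ids cells to extract (default: all).
#' @param variables variables to extract (default: all in the grid).
#' @return Numeric matrix of values, rows named by cell id.
#' @export
grid_values <- function(grid, cell_ids = NULL, variables = NULL) {
  idx <- if (is.null(cell_ids)) seq_len(nrow(grid$cells))
         else match(cell_ids, grid$cells$cell_id)
  if (anyNA(idx)) stop("unknown cell ids: ",
                       paste(cell_ids[is.na(idx)], collapse = ", "))
  vars <- if (is.null(variables)) colnames(grid$values) else variables
  miss <- setdiff(vars, colnames(grid$values))
  if (length(miss)) stop("variables absent from grid: ",
                         paste(miss, collapse = ", "))
  out <- grid$values[idx, vars, drop = FALSE]
  rownames(out) <- grid$cells$cell_id[idx]
  out
}

#' Construct a watershed membership map
#'
#' Assigns every cell of a lattice to a nested pair of drainage-basin
#' labels, analogous to Pfafstetter Level-1 (major basin) and Level-2
#' (sub-basin) coding.  Every Level-2 basin must lie inside exactly one
#' Level-1 basin.
#'
#' @param cell_id integer cell ids.
#' @param level1,level2 basin labels per cell.
#' @return Object of class `watershed_map` (a data.frame).
#' @export
watershed_map <- function(cell_id, level1, level2) {
  df <- data.frame(cell_id = cell_id, level1 = level1, level2 = level2)
  nest <- unique(df[, c("level1", "level2")])
  if (anyDuplicated(nest$level2))
    stop("every Level-2 basin must nest within exactly one Level-1 basin")
  class(df) <- c("watershed_map", "data.frame")
  df
}

#' Construct an isotope-proxy temperature series
#'
#' A uniformly spaced series of global mean annual temperature (MAT)
#' estimates, typically derived from deep-sea oxygen isotope records, used
#' to index the interpolation between glacial and interglacial climate
#' end-members.
#'
#' @param time_ka strictly increasing, uniformly spaced slice ages (ka BP).
#' @param mat_c proxy global MAT per slice (degrees C).
#' @param mat_modern,mat_glacial end-member anchor temperatures (degrees C);
#'   `mat_modern` must exceed `mat_glacial`.
#' @return Object of class `isotope_series` (a data.frame with attributes).
#' @export
isotope_series <- function(time_ka, mat_c, mat_modern, mat_glacial) {
  if (length(time_ka) != length(mat_c))
    stop("`time_ka` and `mat_c` must have equal length")
  if (length(time_ka) < 2L) stop("need at least two slices")
  d <- diff(time_ka)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-8 * max(abs(d)))
    stop("slice times must be strictly increasing with a uniform step")
  if (!(mat_modern > mat_glacial))
    stop("`mat_modern` must exceed `mat_glacial`")
  structure(
    data.frame(time_ka = time_ka, mat_c = mat_c),
    mat_modern = mat_modern, mat_glacial = mat_glacial,
    class = c("isotope_series", "data.frame"))
}

#' @export
print.isotope_series <- function(x, ...) {
  cat(sprintf("<isotope_series> %d slices, %g..%g ka BP, MAT %.2f..%.2f C (anchors %.2f / %.2f)\n",
              nrow(x), min(x$time_ka), max(x$time_ka),
              min(x$mat_c), max(x$mat_c),
              attr(x, "mat_modern"), attr(x, "mat_glacial")))
  invisible(x)
}

#' Slice times of an isotope series
#' @param isotope an `isotope_series`.
#' @export
slice_times <- function(isotope) isotope$time_ka

#' Construct a rectilinear niche envelope
#'
#' Per-variable `[lower, upper]` bounds in climate space: the rectilinear
#' (BIOCLIM) potential-niche description.  A vector is inside the envelope
#' iff it is within bounds on every variable.
#'
#' @param lower,upper named numeric vectors of per-variable bounds
#'   (`lower <= upper` everywhere).
#' @param trim_fraction fraction of outlying points excluded when the
#'   envelope was fitted (0 or 0.10).
#' @param provenance free-text origin tag, e.g. `"modern-tip"`,
#'   `"time-adjusted at 20 ka"`, `"ancestral-node"`.
#' @return Object of class `niche_envelope`.
#' @export
niche_envelope <- function(lower, upper, trim_fraction = 0,
                           provenance = "modern-tip") {
  if (is.null(names(lower)) || is.null(names(upper)))
    stop("bounds must be named by variable")
  upper <- upper[names(lower)]
  if (anyNA(upper)) stop("`lower` and `upper` must cover the same variables")
  if (any(lower > upper)) stop("lower bound exceeds upper bound on: ",
                               paste(names(lower)[lower > upper], collapse = ", "))
  structure(list(variables = names(lower),
                 lower = lower, upper = upper,
                 trim_fraction = trim_fraction,
                 provenance = provenance),
            class = "niche_envelope")
}

#' @export
print.niche_envelope <- function(x, ...) {
  cat(sprintf("<niche_envelope> %d variables, trim = %g, provenance: %s\n",
              length(x$variables), x$trim_fraction, x$provenance))
  print(data.frame(variable = x$variables,
                   lower = unname(x$lower), upper = unname(x$upper)))
  invisible(x)
}

#' Envelope membership test
#'
#' Tests whether climate vectors fall inside a rectilinear niche envelope:
#' inside iff within `[lower, upper]` (bounds inclusive) on every envelope
#' variable.
#'
#' @param envelope a `niche_envelope`.
#' @param x numeric matrix or data.frame whose columns include the
#'   envelope's variables; or a single named numeric vector.
#' @return Logical vector, one element per row of `x`.
#' @export
envelope_contains <- function(envelope, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  miss <- setdiff(envelope$variables, colnames(x))
  if (length(miss)) stop("vectors are missing envelope variables: ",
                         paste(miss, collapse = ", "))
  v <- x[, envelope$variables, drop = FALSE]
  lo <- matrix(envelope$lower, nrow(v), ncol(v), byrow = TRUE)
  hi <- matrix(envelope$upper, nrow(v), ncol(v), byrow = TRUE)
  rowSums(v < lo | v > hi) == 0
}

# run expr with a temporary RNG state seeded by `seed` (NULL = use current)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
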