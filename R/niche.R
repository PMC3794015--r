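# Occurrence preparation and niche estimation: grid thinning, point-to-cell
# climate extraction, rectilinear (BIOCLIM) envelope fitting at trim 0 and
# 0.10, and convex-hull realized-niche membership.

#' Thin occurrences to one point per grid cell
#'
#' Resamples point occurrences on a regular thinning grid of spacing
#' `resolution`, retaining exactly one point per occupied thinning cell.
#' Retention is deterministic: the first point, in input order, of each
#' cell is kept.  This removes the effects of uneven sampling density.
#'
#' @param points data.frame with columns `x`, `y` (projected km);
#'   additional columns (e.g. `species`) are carried through.
#' @param resolution thinning-grid spacing, km (> 0).  The default 18.5 km
#'   is the equatorial equivalent of a ten arc-minute grid.
#' @return The retained rows of `points`, with attributes `resolution` and
#'   `n_input`.
#' @export
thin_occurrences <- function(points, resolution = 18.5) {
  if (resolution <= 0) stop("`resolution` must be positive")
  if (!nrow(points)) {
    warning("no occurrence points to thin; returning empty set")
    return(structure(points, resolution = resolution, n_input = 0L))
  }
  key <- paste(floor(points$x / resolution), floor(points$y / resolution))
  keep <- !duplicated(key)
  structure(points[keep, , drop = FALSE],
            resolution = resolution, n_input = nrow(points))
}

# lattice geometry implied by a climate_grid built on the package's
# row-major equal-area lattice (origin 0,0; spacing sqrt(cell_area))
lattice_geometry <- function(grid) {
  h <- sqrt(grid$cell_area)
  n_cols <- round(max(grid$cells$x) / h + 0.5)
  n_rows <- round(max(grid$cells$y) / h + 0.5)
  list(h = h, n_rows = n_rows, n_cols = n_cols)
}

#' Look up the grid cell containing each point
#'
#' Cells are half-open in both axes (left/bottom edge inclusive, right/top
#' exclusive), so a point on a shared edge belongs to the cell on its
#' right/top side's left/bottom -- i.e. the cell whose lower-left corner it
#' touches.
#'
#' @param points data.frame with `x`, `y` (km).
#' @param grid a [climate_grid()].
#' @return Integer vector of cell ids; errors listing any points outside
#'   the grid's bounding region.
#' @export
cell_at <- function(points, grid) {
  g <- lattice_geometry(grid)
  col <- floor(points$x / g$h) + 1L
  row <- floor(points$y / g$h) + 1L
  bad <- col < 1L | col > g$n_cols | row < 1L | row > g$n_rows
  if (any(bad))
    stop("points outside the modeled domain at rows: ",
         paste(which(bad), collapse = ", "))
  id <- (row - 1L) * g$n_cols + col
  if (!all(id %in% grid$cells$cell_id))
    stop("lattice lookup failed; grid is not a full row-major lattice")
  id
}

#' Extract climate vectors at occurrence points
#'
#' Each point receives the bioclimatic vector of its containing cell (see
#' [cell_at()] for the edge convention).  Points outside the domain raise
#' an error listing the offending rows rather than being silently dropped.
#'
#' @param points data.frame with `x`, `y` (km).
#' @param grid a [climate_grid()].
#' @param variables variables to extract (default: all in the grid).
#' @return data.frame: `cell_id` followed by one column per variable.
#' @export
extract_climate <- function(points, grid, variables = NULL) {
  ids <- cell_at(points, grid)
  v <- grid_values(grid, ids, variables)
  out <- data.frame(cell_id = ids, v, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit a rectilinear (BIOCLIM) niche envelope
#'
#' Per-variable bounds around a set of climate vectors.  With
#' `trim_fraction = 0` the bounds are the data min/max, so the envelope
#' contains every training vector.  With `trim_fraction = 0.10` the bounds
#' are the per-variable 5th and 95th percentiles (linear-interpolation
#' convention, `stats::quantile` type 7), excluding the outlying 10% of
#' points on each axis; this envelope is nested inside the 100% envelope
#' fitted on the same data.
#'
#' @param vectors matrix or data.frame of climate vectors (rows = points).
#' @param variables variables to bound (default: all columns).
#' @param trim_fraction 0 or 0.10.
#' @param provenance origin tag for the envelope.
#' @return A [niche_envelope()].
#' @export
fit_envelope <- function(vectors, variables = NULL, trim_fraction = 0,
                         provenance = "modern-tip") {
  vectors <- as.matrix(vectors)
  if (!nrow(vectors)) stop("cannot fit an envelope to zero vectors")
  if (!trim_fraction %in% c(0, 0.10))
    stop("`trim_fraction` must be 0 or 0.10")
  if (is.null(variables)) variables <- colnames(vectors)
  v <- vectors[, variables, drop = FALSE]
  if (anyNA(v)) stop("climate vectors contain missing values")
  if (trim_fraction > 0 && nrow(v) < 10) {
    warning("fewer than 10 vectors: 10% trim poorly defined, ",
            "falling back to min/max bounds")
    trim_fraction <- 0
    provenance <- paste0(provenance, " (trim fallback: n < 10)")
  }
  if (trim_fraction == 0) {
    lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  } else {
    p <- trim_fraction / 2
    q <- apply(v, 2, stats::quantile, probs = c(p, 1 - p),
               names = FALSE, type = 7)
    lo <- q[1, ]; hi <- q[2, ]
    names(lo) <- names(hi) <- variables
  }
  niche_envelope(lo, hi, trim_fraction = trim_fraction,
                 provenance = provenance)
}

#' Realized-niche membership (convex hull in E-space)
#'
#' Tests whether a query climate vector lies in the convex hull of the
#' reference vectors -- i.e. whether it is expressible as a convex
#' combination of observed climates.  This is strictly tighter than the
#' rectilinear envelope on the same points, so realized membership implies
#' potential (trim 0) membership.
#'
#' The test solves the nearest-point-in-hull quadratic program in
#' range-standardized coordinates and accepts the query when the residual
#' distance is below `tol`.  With fewer than `d + 1` reference points (or
#' a rank-deficient reference cloud) the hull is degenerate and the test
#' falls back to bounding-box membership with a warning.
#'
#' @param reference_vectors matrix/data.frame of reference climate vectors.
#' @param query named numeric vector, or matrix with one query per row.
#' @param variables variables defining the E-space (default: all columns of
#'   `reference_vectors`).
#' @param tol residual tolerance in standardized coordinates.
#' @return Logical vector, one element per query.
#' @export
realized_membership <- function(reference_vectors, query, variables = NULL,
                                tol = 1e-4) {
  R <- as.matrix(reference_vectors)
  if (is.null(variables)) variables <- colnames(R)
  R <- R[, variables, drop = FALSE]
  if (is.null(dim(query)))
    query <- matrix(query[variables], nrow = 1,
                    dimnames = list(NULL, variables))
  Q <- as.matrix(query)[, variables, drop = FALSE]
  n <- nrow(R); d <- ncol(R)

  lo <- apply(R, 2, min); hi <- apply(R, 2, max)
  scale <- pmax(hi - lo, 1e-12)
  Z <- sweep(sweep(R, 2, lo), 2, scale, "/")
  Zq <- sweep(sweep(Q, 2, lo), 2, scale, "/")

  degenerate <- n < d + 1 || qr(sweep(Z, 2, colMeans(Z)))$rank < d
  if (degenerate) {
    warning("degenerate reference set (need > d affinely independent ",
            "points); falling back to bounding-box membership")
    return(envelope_contains(niche_envelope(lo, hi), Q))
  }

  inbox <- envelope_contains(niche_envelope(lo, hi), Q)
  out <- logical(nrow(Q))
  D <- tcrossprod(Z) + diag(1e-10, n)
  A <- cbind(rep(1, n), diag(n))
  for (i in which(inbox)) {
    sol <- quadprog::solve.QP(Dmat = D, dvec = Z %*% Zq[i, ],
                              Amat = A, bvec = c(1, rep(0, n)), meq = 1)
    resid <- sqrt(sum((crossprod(Z, sol$solution) - Zq[i, ])^2))
    out[i] <- resid <= tol
  }
  out
}
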