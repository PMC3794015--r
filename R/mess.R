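# Rectilinear multivariate environmental similarity (MESS) scores:
# width-normalized distance of a point to a per-variable reference interval,
# positive inside (100 at the centre, 0 on a boundary), negative outside
# (-100 one full interval width beyond a boundary), combined across
# variables as the minimum.

#' Univariate MESS score
#'
#' For a reference interval `[ref_lower, ref_upper]` of width `w`:
#' inside, the score is `100 * (1 - 2 * |value - mid| / w)` (100 at the
#' centre, 0 on a boundary); outside, it is `-100 * d / w` where `d` is the
#' distance to the nearest boundary, so a point one full width beyond a
#' boundary scores exactly -100.
#'
#' @param ref_lower,ref_upper reference interval bounds
#'   (`ref_lower <= ref_upper`).
#' @param value value(s) to score (vectorised).
#' @return Numeric score(s), at most 100, unbounded below.
#' @export
mess_univariate <- function(ref_lower, ref_upper, value) {
  if (ref_lower > ref_upper) stop("`ref_lower` must not exceed `ref_upper`")
  w <- ref_upper - ref_lower
  if (w == 0) {
    if (any(value != ref_lower))
      stop("degenerate reference: zero-width interval with value off the bound")
    return(rep(0, length(value)))
  }
  inside <- value >= ref_lower & value <= ref_upper
  out <- numeric(length(value))
  # inside: 200 * distance-to-nearest-boundary / width, the same map as
  # 100 * (1 - 2|x - mid|/w) but exactly 0 on a boundary
  out[inside] <- 200 * pmin(value[inside] - ref_lower,
                            ref_upper - value[inside]) / w
  d <- pmax(ref_lower - value, value - ref_upper)
  out[!inside] <- -100 * d[!inside] / w
  out
}

#' Combined MESS score of a climate vector
#'
#' Scores every variable with [mess_univariate()] against its reference
#' interval and combines them as the minimum: a point is outside the
#' reference space as soon as it is outside on one variable.  Ties for the
#' limiting (arg-min) variable are broken by canonical BIO ordering.
#'
#' @param bounds a [niche_envelope()] (or any list with `variables`,
#'   `lower`, `upper`) giving per-variable reference intervals.
#' @param vector named numeric climate vector covering all bound variables.
#' @return List of class `mess_result`: `per_variable` (named scores),
#'   `combined`, `limiting`, `reference` (provenance of the bounds).
#' @export
mess_combined <- function(bounds, vector) {
  miss <- setdiff(bounds$variables, names(vector))
  if (length(miss)) stop("missing reference/vector variables: ",
                         paste(miss, collapse = ", "))
  vars <- bounds$variables[bio_order(bounds$variables)]
  s <- vapply(vars, function(v)
    mess_univariate(bounds$lower[[v]], bounds$upper[[v]], vector[[v]]),
    numeric(1))
  structure(list(per_variable = s,
                 combined = min(s),
                 limiting = vars[which.min(s)],
                 reference = if (!is.null(bounds$provenance))
                   bounds$provenance else "bounds"),
            class = "mess_result")
}

#' @export
print.mess_result <- function(x, ...) {
  cat(sprintf("<mess_result> combined %.2f (limiting %s; reference %s)\n",
              x$combined, x$limiting, x$reference))
  invisible(x)
}

#' MESS scores over a climate grid
#'
#' Scores every cell of a grid against reference bounds, which may be (a) a
#' species' potential-niche envelope or (b) available-climate bounds over a
#' reference cell set (see [climate_bounds()]).
#'
#' @param reference a [niche_envelope()] or bounds from [climate_bounds()].
#' @param grid a [climate_grid()] to score.
#' @param mode `"combined"` (one score per cell, the minimum across
#'   variables, plus the limiting variable) or `"per-variable"` (one score
#'   column per variable).
#' @return data.frame with `cell_id` and either `mess` + `limiting`
#'   (combined) or one column per variable.
#' @export
mess_grid <- function(reference, grid, mode = c("combined", "per-variable")) {
  mode <- match.arg(mode)
  vars <- reference$variables[bio_order(reference$variables)]
  v <- grid_values(grid, variables = vars)
  if (!nrow(v)) stop("empty grid")
  scores <- vapply(vars, function(nm)
    mess_univariate(reference$lower[[nm]], reference$upper[[nm]], v[, nm]),
    numeric(nrow(v)))
  if (!is.matrix(scores))
    scores <- matrix(scores, nrow = nrow(v), dimnames = list(NULL, vars))
  if (mode == "per-variable")
    return(data.frame(cell_id = grid$cells$cell_id, scores,
                      check.names = FALSE))
  comb <- do.call(pmin, as.data.frame(scores))
  lim <- vars[max.col(-scores, ties.method = "first")]
  data.frame(cell_id = grid$cells$cell_id, mess = comb, limiting = lim)
}

#' Minimal refugium: the k least-negative cells (SIM5)
#'
#' When a projected range is empty, the `k` accessible cells whose combined
#' potential-niche MESS scores are least negative stand in as the most
#' parsimonious hypothesized refugium.  Ties at the selection boundary are
#' broken by ascending cell id, making the result deterministic.
#'
#' @param scores data.frame with `cell_id` and `mess` (combined score) over
#'   the accessible cells.
#' @param k number of cells to select (default 5).
#' @return Integer vector of `k` cell ids (fewer, with a warning, if fewer
#'   accessible cells exist), with attribute `sim5_substituted = TRUE`.
#' @export
sim5 <- function(scores, k = 5) {
  if (!nrow(scores)) stop("no accessible cells to select from")
  if (nrow(scores) < k) {
    warning("fewer than ", k, " accessible cells; returning all ",
            nrow(scores))
    k <- nrow(scores)
  }
  ord <- order(-scores$mess, scores$cell_id)
  structure(scores$cell_id[ord[seq_len(k)]], sim5_substituted = TRUE)
}
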