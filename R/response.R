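# Pairwise changes in temperature, range size and range centroid; response
# regressions; partitioning into climate-tracking and phylogenetic
# (adaptive) components.

#' Per-slice mean annual temperature for a species
#'
#' Range-local MAT series: mean BIO1 over the species' accessibility mask,
#' per slice.  Falls back to the global isotope-proxy MAT when the grids
#' do not carry BIO1.
#'
#' @param fit a fitted [ppgm()] or a list with `modern`, `glacial`,
#'   `isotope`.
#' @param mask accessible cell ids (NULL: global proxy MAT).
#' @return data.frame `time_ka`, `mat_c`.
#' @export
mat_series <- function(fit, mask = NULL) {
  iso <- fit$isotope
  if (is.null(mask) || !"BIO1" %in% colnames(fit$modern$values))
    return(data.frame(time_ka = iso$time_ka, mat_c = iso$mat_c))
  mo <- mean(grid_values(fit$modern, mask, "BIO1"))
  gl <- mean(grid_values(fit$glacial, mask, "BIO1"))
  a <- vapply(iso$time_ka, function(t) blend_alpha(iso, t), numeric(1))
  data.frame(time_ka = iso$time_ka, mat_c = a * mo + (1 - a) * gl)
}

#' Pairwise changes in MAT, range size and range centroid
#'
#' For each slice pair of a projected range series, the change record
#' holds `pc_mat` (change in mean annual temperature, degC), `pc_rs`
#' (change in range area, km^2) and `pc_gc` (displacement of the range
#' centroid, km, always >= 0).  `"consecutive"` mode emits one record per
#' adjacent slice pair; `"all-pairs"` one per unordered pair.  Pairs in
#' which either slice has no centroid (empty range) get `pc_gc = NA` and
#' are flagged for exclusion from centroid regressions; empty slices
#' contribute area 0 to `pc_rs`.
#'
#' @param series a `ppgm_series` table (or a fitted [ppgm()]); rows for one
#'   provenance are selected with `provenance`.
#' @param mat data.frame `time_ka`, `mat_c` aligned on the slices (e.g.
#'   [mat_series()]); per-species MAT may be supplied via a `species`
#'   column.
#' @param mode `"consecutive"` or `"all-pairs"`.
#' @param provenance `"corrected"` or `"uncorrected"`.
#' @return data.frame of change records: `species`, `t1`, `t2`, `pc_mat`,
#'   `pc_rs`, `pc_gc`, `gc_defined`, `provenance`.
#' @export
pairwise_changes <- function(series, mat, mode = c("consecutive", "all-pairs"),
                             provenance = "corrected") {
  mode <- match.arg(mode)
  tab <- if (inherits(series, "ppgm")) series$series$table
         else if (inherits(series, "ppgm_series")) series$table
         else series
  tab <- tab[tab$provenance == provenance, , drop = FALSE]
  out <- list()
  for (sp in unique(tab$species)) {
    st <- tab[tab$species == sp, ]
    st <- st[order(st$time_ka), ]
    m <- if ("species" %in% names(mat)) mat[mat$species == sp, ] else mat
    mv <- m$mat_c[match(st$time_ka, m$time_ka)]
    if (anyNA(mv)) stop("MAT series and range series slices do not align")
    n <- nrow(st)
    pairs <- if (mode == "consecutive")
      cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
    else t(utils::combn(n, 2L))
    gc <- sqrt((st$centroid_x[pairs[, 2]] - st$centroid_x[pairs[, 1]])^2 +
               (st$centroid_y[pairs[, 2]] - st$centroid_y[pairs[, 1]])^2)
    # SIM5-substituted slices carry stand-in centroids; treat as undefined
    undef <- st$empty[pairs[, 1]] | st$empty[pairs[, 2]]
    gc[undef] <- NA_real_
    out[[sp]] <- data.frame(
      species = sp,
      t1 = st$time_ka[pairs[, 1]], t2 = st$time_ka[pairs[, 2]],
      pc_mat = mv[pairs[, 2]] - mv[pairs[, 1]],
      pc_rs = ifelse(st$empty[pairs[, 2]], 0, st$area_km2[pairs[, 2]]) -
              ifelse(st$empty[pairs[, 1]], 0, st$area_km2[pairs[, 1]]),
      pc_gc = gc,
      gc_defined = !is.na(gc),
      provenance = provenance)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regress range response on temperature change
#'
#' Ordinary least squares of the response magnitude on the magnitude of
#' the MAT change (`|response| ~ |pc_mat|`), the form in which range
#' responses per degree are reported; `signed = TRUE` regresses the signed
#' changes instead.  Records with undefined centroids are excluded from
#' `pc_gc` fits.
#'
#' @param records change records from [pairwise_changes()] or
#'   [partition_response()].
#' @param response `"pc_rs"` (range size) or `"pc_gc"` (centroid shift).
#' @param signed use signed changes instead of magnitudes?
#' @return Object of class `response_fit`: `slope`, `intercept`, `r2`,
#'   `p`, `n`, `response`, `signed`.
#' @export
fit_response <- function(records, response = c("pc_rs", "pc_gc"),
                         signed = FALSE) {
  response <- match.arg(response)
  use <- if (response == "pc_gc") records[records$gc_defined, ] else records
  use <- use[stats::complete.cases(use[, c("pc_mat", response)]), ]
  if (nrow(use) < 3) stop("need at least 3 usable records")
  x <- if (signed) use$pc_mat else abs(use$pc_mat)
  y <- if (signed) use[[response]] else abs(use[[response]])
  if (stats::var(x) == 0)
    stop("undefined fit: no variance in pc_mat")
  if (stats::var(y) == 0)
    # constant response (e.g. an identically-zero adaptive component):
    # nothing to explain, so slope 0 and R^2 0 rather than 0/0
    return(structure(list(slope = 0, intercept = mean(y), r2 = 0, p = 1,
                          n = nrow(use), response = response,
                          signed = signed),
                     class = "response_fit"))
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = s$r.squared,
                 p = unname(s$coefficients[2, 4]),
                 n = nrow(use),
                 response = response, signed = signed),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("%s = %.2f + %.2f * %spc_mat   (R^2 = %.3f, p = %.3g, n = %d)\n",
              toupper(x$response), x$intercept, x$slope,
              if (x$signed) "" else "|", x$r2, x$p, x$n))
  invisible(x)
}

#' Partition range responses into tracking and adaptive components
#'
#' Subtracts uncorrected (fixed modern envelope, pure climate tracking)
#' change records from phylogenetically corrected ones, field-wise per
#' species and slice pair.  The difference is the phylogenetic (adaptive)
#' component of the response; `pc_mat` is shared.  By construction,
#' corrected = uncorrected + component on `pc_rs` and `pc_gc` exactly;
#' with zero niche evolution the component vanishes identically.
#'
#' @param corrected,uncorrected change records from [pairwise_changes()].
#' @return Change records with `provenance = "phylogenetic"`; `gc_defined`
#'   is TRUE only where both inputs had defined centroids.
#' @export
partition_response <- function(corrected, uncorrected) {
  key <- function(d) paste(d$species, d$t1, d$t2)
  kc <- key(corrected); ku <- key(uncorrected)
  miss <- c(setdiff(kc, ku), setdiff(ku, kc))
  if (length(miss))
    stop("records misaligned on species/slice pairs: ",
         paste(utils::head(miss, 5), collapse = "; "))
  u <- uncorrected[match(kc, ku), ]
  data.frame(species = corrected$species,
             t1 = corrected$t1, t2 = corrected$t2,
             pc_mat = corrected$pc_mat,
             pc_rs = corrected$pc_rs - u$pc_rs,
             pc_gc = corrected$pc_gc - u$pc_gc,
             gc_defined = corrected$gc_defined & u$gc_defined,
             provenance = "phylogenetic")
}
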