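# Range hindcasting: watershed accessibility masks, envelope projection on
# interpolated slices, SIM5 substitution for empty slices, empty-slice
# census, richness maps, and the ppgm() model front end.

#' Watershed accessibility mask
#'
#' The union of cells belonging to drainage basins (at the requested
#' Pfafstetter level) that contain at least one occurrence point.  Level-1
#' basins mask projected ranges (dispersal accessibility); Level-2 basins
#' define the available climate space.
#'
#' @param occurrences data.frame with `x`, `y` (km) or a `cell_id` column.
#' @param watersheds a [watershed_map()].
#' @param grid a [climate_grid()] (for point-to-cell lookup).
#' @param level 1 or 2.
#' @return Sorted integer vector of accessible cell ids.
#' @export
accessible_mask <- function(occurrences, watersheds, grid, level = 1) {
  if (!nrow(occurrences)) stop("occurrences must be non-empty")
  if (!level %in% c(1, 2)) stop("`level` must be 1 or 2")
  ids <- if ("cell_id" %in% names(occurrences)) occurrences$cell_id
         else cell_at(occurrences, grid)
  lab <- if (level == 1) watersheds$level1 else watersheds$level2
  at <- lab[match(ids, watersheds$cell_id)]
  if (anyNA(at))
    stop("occurrence outside every basin (cells ",
         paste(ids[is.na(at)], collapse = ", "), ")")
  sort(watersheds$cell_id[lab %in% unique(at)])
}

#' Project a niche envelope onto a climate slice
#'
#' The projected range is the set of accessible cells whose climate vector
#' lies inside the envelope.  Area is exactly `|presence| * cell_area`;
#' the centroid is the unweighted mean of presence-cell centres (equal-area
#' lattice, hence area-weighted).
#'
#' @param envelope a [niche_envelope()].
#' @param climate a [climate_grid()].
#' @param mask accessible cell ids (non-empty).
#' @param species optional species id carried into the result.
#' @return Object of class `range_projection`: list with `species`,
#'   `time_ka`, `cells`, `area`, `centroid`, `empty`, `sim5_substituted`,
#'   `provenance`.
#' @export
project_slice <- function(envelope, climate, mask, species = NA_character_) {
  if (!length(mask)) stop("invalid mask: empty accessibility mask")
  v <- grid_values(climate, mask, envelope$variables)
  inside <- envelope_contains(envelope, v)
  cells <- mask[inside]
  idx <- match(cells, climate$cells$cell_id)
  centroid <- if (length(cells))
    c(x = mean(climate$cells$x[idx]), y = mean(climate$cells$y[idx]))
  else c(x = NA_real_, y = NA_real_)
  structure(list(species = species,
                 time_ka = climate$time_ka,
                 cells = cells,
                 area = length(cells) * climate$cell_area,
                 centroid = centroid,
                 empty = length(cells) == 0L,
                 sim5_substituted = FALSE,
                 provenance = envelope$provenance),
            class = "range_projection")
}

#' @export
print.range_projection <- function(x, ...) {
  cat(sprintf("<range_projection> %s at %g ka: %d cells (%.0f km^2)%s%s\n",
              x$species, x$time_ka, length(x$cells), x$area,
              if (x$empty) " [empty]" else "",
              if (x$sim5_substituted) " [SIM5]" else ""))
  invisible(x)
}

# count 4-connected fragments among presence cells on the lattice
count_fragments <- function(cells, grid) {
  if (!length(cells)) return(0L)
  g <- lattice_geometry(grid)
  col <- (cells - 1L) %% g$n_cols + 1L
  row <- (cells - 1L) %/% g$n_cols + 1L
  key <- row * (g$n_cols + 2L) + col
  present <- new.env(parent = emptyenv(), size = length(cells))
  for (i in seq_along(cells)) assign(as.character(key[i]), i, envir = present)
  seen <- logical(length(cells))
  nfrag <- 0L
  for (i in seq_along(cells)) {
    if (seen[i]) next
    nfrag <- nfrag + 1L
    stack <- i
    seen[i] <- TRUE
    while (length(stack)) {
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (dk in c(-1L, 1L, -(g$n_cols + 2L), g$n_cols + 2L)) {
        nb <- get0(as.character(key[j] + dk), envir = present)
        if (!is.null(nb) && !seen[nb]) {
          seen[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
  }
  nfrag
}

#' Hindcast range series for a set of species
#'
#' For every species and every slice of the interpolated climate series,
#' projects both the phylogenetically corrected envelope (time-adjusted
#' along the species' terminal branch, [envelope_at_time()]) and the
#' uncorrected envelope (the modern envelope held constant), masked by
#' Level-1 watershed accessibility.  Corrected slices whose projection is
#' empty are assigned a SIM5 minimal refugium (the 5 accessible cells with
#' least-negative potential-niche MESS) when `sim5 = TRUE`; the empty flag
#' records the pre-substitution state.  A failure for one species is
#' recorded and the run continues (partial-results contract).
#'
#' @param envelopes named list of modern [niche_envelope()]s per species.
#' @param tree validated `phylo` tree containing the species as tips.
#' @param occurrences data.frame (`species`, `x`, `y`) of modern points.
#' @param modern,glacial end-member [climate_grid()]s.
#' @param isotope an [isotope_series()].
#' @param watersheds a [watershed_map()].
#' @param sim5 substitute SIM5 refugia for empty corrected slices?
#' @param keep_masks keep per-slice presence cell sets (needed for
#'   [richness()])?
#' @return List of class `ppgm_series`: `table` (data.frame: species,
#'   time_ka, provenance, n_cells, area_km2, centroid_x, centroid_y,
#'   n_fragments, empty, sim5), `masks` (nested list or NULL), `census`
#'   (per-species empty-slice counts), `errors` (named list).
#' @export
run_series <- function(envelopes, tree, occurrences, modern, glacial,
                       isotope, watersheds, sim5 = TRUE, keep_masks = TRUE) {
  tree <- validate_tree(tree)
  species <- names(envelopes)
  if (!all(species %in% tree$tip.label))
    stop("species missing from tree: ",
         paste(setdiff(species, tree$tip.label), collapse = ", "))
  traits <- tip_trait_matrix(envelopes)
  anc <- ancestral_trait_table(tree, traits)
  times <- slice_times(isotope)
  slices <- interpolate_series(modern, glacial, isotope, times)

  rows <- list(); masks <- list(); errors <- list()
  for (sp in species) {
    res <- tryCatch({
      occ <- occurrences[occurrences$species == sp, , drop = FALSE]
      mask <- accessible_mask(occ, watersheds, modern, level = 1)
      tipv <- traits[sp, ]
      nodev <- anc$estimates[as.character(anc$parent[[sp]]), ]
      page <- anc$parent_age[[sp]]
      sp_rows <- vector("list", 2L * length(times))
      sp_masks <- list(corrected = vector("list", length(times)),
                       uncorrected = vector("list", length(times)))
      for (k in seq_along(times)) {
        t <- times[k]
        frac <- (t / KA_PER_MY) / page
        env_t <- suppressWarnings(bounds_to_envelope(
          tipv + frac * (nodev - tipv),
          provenance = sprintf("time-adjusted at %g ka", t)))
        for (prov in c("corrected", "uncorrected")) {
          e <- if (prov == "corrected") env_t else envelopes[[sp]]
          pr <- project_slice(e, slices[[k]], mask, species = sp)
          was_empty <- pr$empty
          if (prov == "corrected" && was_empty && sim5) {
            sc <- mess_grid_subset(e, slices[[k]], mask)
            pr$cells <- sim5(sc, 5)
            pr$sim5_substituted <- TRUE
            pr$area <- length(pr$cells) * slices[[k]]$cell_area
            idx <- match(pr$cells, slices[[k]]$cells$cell_id)
            pr$centroid <- c(x = mean(slices[[k]]$cells$x[idx]),
                             y = mean(slices[[k]]$cells$y[idx]))
          }
          sp_rows[[2L * (k - 1L) + (prov == "uncorrected") + 1L]] <-
            data.frame(species = sp, time_ka = t, provenance = prov,
                       n_cells = length(pr$cells), area_km2 = pr$area,
                       centroid_x = unname(pr$centroid["x"]),
                       centroid_y = unname(pr$centroid["y"]),
                       n_fragments = count_fragments(pr$cells, modern),
                       empty = was_empty, sim5 = pr$sim5_substituted)
          sp_masks[[prov]][[k]] <- pr$cells
        }
      }
      names(sp_masks$corrected) <- names(sp_masks$uncorrected) <-
        as.character(times)
      list(rows = do.call(rbind, sp_rows), masks = sp_masks, mask = mask)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sp]] <- conditionMessage(res)
      warning("species ", sp, " failed: ", conditionMessage(res))
    } else {
      rows[[sp]] <- res$rows
      if (keep_masks) masks[[sp]] <- res$masks
      attr(masks, "accessible")[[sp]] <- res$mask
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  corr <- table[table$provenance == "corrected", ]
  census <- stats::aggregate(empty ~ species, data = corr, FUN = sum)
  names(census)[2] <- "n_empty"
  structure(list(table = table,
                 masks = if (keep_masks) masks else NULL,
                 census = census,
                 errors = errors,
                 times = times),
            class = "ppgm_series")
}

# combined MESS of mask cells against an envelope (helper for SIM5)
mess_grid_subset <- function(envelope, climate, mask) {
  v <- grid_values(climate, mask, envelope$variables)
  vars <- envelope$variables[bio_order(envelope$variables)]
  scores <- vapply(vars, function(nm)
    mess_univariate(envelope$lower[[nm]], envelope$upper[[nm]], v[, nm]),
    numeric(length(mask)))
  if (!is.matrix(scores))
    scores <- matrix(scores, nrow = length(mask))
  data.frame(cell_id = mask, mess = do.call(pmin, as.data.frame(scores)))
}

#' Empty-slice census summary
#'
#' Counts, per species, the corrected-projection slices with no suitable
#' climate (before SIM5 substitution), and summarizes species with two or
#' more empty slices (min / median / max), the form used to report
#' glacial range collapses.
#'
#' @param series a `ppgm_series` from [run_series()].
#' @return List with `per_species` and `summary`.
#' @export
census_empty <- function(series) {
  cen <- series$census
  hit <- cen[cen$n_empty >= 2, ]
  list(per_species = cen,
       summary = data.frame(
         n_species_with_empty = nrow(hit),
         min_empty = if (nrow(hit)) min(hit$n_empty) else NA_integer_,
         median_empty = if (nrow(hit)) stats::median(hit$n_empty) else NA_real_,
         max_empty = if (nrow(hit)) max(hit$n_empty) else NA_integer_))
}

#' Species richness at one slice
#'
#' Per-cell count of species present at a slice.  SIM5-substituted ranges
#' are excluded by default (they are hypothesized refugia, not projected
#' presence).
#'
#' @param series a `ppgm_series` with kept masks.
#' @param t slice age, ka BP.
#' @param provenance `"corrected"` or `"uncorrected"`.
#' @param include_sim5 count SIM5-substituted cells?
#' @param grid the lattice [climate_grid()].
#' @return data.frame `cell_id`, `richness`.
#' @export
richness <- function(series, t, provenance = "corrected",
                     include_sim5 = FALSE, grid) {
  if (is.null(series$masks)) stop("run_series() was called with keep_masks = FALSE")
  key <- as.character(t)
  counts <- integer(nrow(grid$cells))
  tab <- series$table
  for (sp in names(series$masks)) {
    row <- tab[tab$species == sp & tab$time_ka == t &
                 tab$provenance == provenance, ]
    if (!nrow(row)) stop("no such slice: ", t, " ka")
    if (row$sim5 && !include_sim5) next
    cells <- series$masks[[sp]][[provenance]][[key]]
    counts[match(cells, grid$cells$cell_id)] <-
      counts[match(cells, grid$cells$cell_id)] + 1L
  }
  data.frame(cell_id = grid$cells$cell_id, richness = counts)
}

#' Fit a paleophylogeographic model (PPGM)
#'
#' The front end of the package: estimates each species' rectilinear
#' climate-niche envelope from its modern occurrences, reconstructs
#' ancestral envelope bounds on the phylogeny under Brownian motion,
#' projects corrected (time-adjusted) and uncorrected envelopes onto the
#' interpolated paleoclimate series masked by watershed accessibility, and
#' returns the per-slice range series with an empty-slice census.
#'
#' @param occurrences data.frame of modern points: `species`, `x`, `y` (km).
#' @param tree time-calibrated `phylo` tree (branch lengths My) whose tips
#'   include the occurrence species.
#' @param modern,glacial end-member [climate_grid()]s on one lattice.
#' @param isotope an [isotope_series()].
#' @param watersheds a [watershed_map()].
#' @param variables modeling variables (default [MODELING_VARS] present in
#'   the grids).
#' @param trim_fraction envelope trim, 0 (100% envelope) or 0.10 (90%).
#' @param thin_resolution occurrence thinning-grid spacing in km, or NULL
#'   to skip thinning.
#' @param sim5 substitute SIM5 refugia for empty corrected slices?
#' @param keep_masks keep per-slice presence cell sets?
#' @return Object of class `ppgm`: list with `envelopes`, `traits`, `anc`,
#'   `series` (a `ppgm_series`), `occ_climate` (per-species climate at
#'   occurrences), `masks_accessible`, the inputs, and `call`.
#' @seealso [predict.ppgm()], [pairwise_changes()], [partition_response()]
#' @export
ppgm <- function(occurrences, tree, modern, glacial, isotope, watersheds,
                 variables = intersect(MODELING_VARS, colnames(modern$values)),
                 trim_fraction = 0, thin_resolution = NULL,
                 sim5 = TRUE, keep_masks = TRUE) {
  stopifnot(is.data.frame(occurrences),
            all(c("species", "x", "y") %in% names(occurrences)))
  tree <- validate_tree(tree)
  if (!is.null(thin_resolution)) {
    occurrences <- do.call(rbind, lapply(
      split(occurrences, occurrences$species),
      thin_occurrences, resolution = thin_resolution))
    rownames(occurrences) <- NULL
  }
  species <- intersect(tree$tip.label, unique(occurrences$species))
  if (!length(species)) stop("no occurrence species found among tree tips")

  envelopes <- list(); occ_climate <- list()
  for (sp in species) {
    occ <- occurrences[occurrences$species == sp, ]
    cl <- extract_climate(occ, modern, variables)
    occ_climate[[sp]] <- cl
    envelopes[[sp]] <- fit_envelope(cl[, variables, drop = FALSE],
                                    variables, trim_fraction,
                                    provenance = paste0("modern-tip ", sp))
  }
  series <- run_series(envelopes, tree, occurrences, modern, glacial,
                       isotope, watersheds, sim5 = sim5,
                       keep_masks = keep_masks)
  structure(list(envelopes = envelopes,
                 traits = tip_trait_matrix(envelopes),
                 anc = ancestral_trait_table(tree, tip_trait_matrix(envelopes)),
                 series = series,
                 occ_climate = occ_climate,
                 occurrences = occurrences,
                 tree = tree, modern = modern, glacial = glacial,
                 isotope = isotope, watersheds = watersheds,
                 variables = variables, trim_fraction = trim_fraction,
                 call = match.call()),
            class = "ppgm")
}

#' @export
print.ppgm <- function(x, ...) {
  cat("Paleophylogeographic model (PPGM)\n")
  cat(sprintf("  %d species, %d slices (%g..%g ka BP), %d modeling variables, trim = %g\n",
              length(x$envelopes), length(x$series$times),
              min(x$series$times), max(x$series$times),
              length(x$variables), x$trim_fraction))
  nerr <- length(x$series$errors)
  if (nerr) cat(sprintf("  %d species failed (see $series$errors)\n", nerr))
  cat(sprintf("  species with >= 2 empty corrected slices: %d\n",
              sum(x$series$census$n_empty >= 2)))
  invisible(x)
}

#' @export
summary.ppgm <- function(object, ...) {
  tab <- object$series$table
  corr <- tab[tab$provenance == "corrected", ]
  area <- stats::aggregate(area_km2 ~ species, data = corr,
                           FUN = function(a) c(min = min(a), mean = mean(a),
                                               max = max(a)))
  area <- data.frame(species = area$species, area$area_km2)
  out <- list(n_species = length(object$envelopes),
              times = object$series$times,
              census = census_empty(object$series),
              area = area,
              trim_fraction = object$trim_fraction)
  class(out) <- "summary.ppgm"
  out
}

#' @export
print.summary.ppgm <- function(x, ...) {
  cat(sprintf("PPGM summary: %d species, %d slices (%g..%g ka BP), trim = %g\n",
              x$n_species, length(x$times), min(x$times), max(x$times),
              x$trim_fraction))
  cat("\nRange area per species (km^2, corrected projections):\n")
  print(x$area, row.names = FALSE)
  s <- x$census$summary
  cat(sprintf("\nSpecies with >= 2 empty slices: %d", s$n_species_with_empty))
  if (s$n_species_with_empty > 0)
    cat(sprintf(" (empty-slice count min %d / median %g / max %d)",
                s$min_empty, s$median_empty, s$max_empty))
  cat("\n")
  invisible(x)
}

#' @export
coef.ppgm <- function(object, ...) object$traits

#' Project a fitted PPGM at a time slice
#'
#' @param object a fitted [ppgm()].
#' @param t slice age, ka BP (one of the modeled slices).
#' @param species tip labels (default: all fitted species).
#' @param corrected use the time-adjusted envelope (TRUE) or the fixed
#'   modern envelope (FALSE)?
#' @param ... unused.
#' @return Named list of [project_slice()] results.
#' @export
predict.ppgm <- function(object, t = 0, species = names(object$envelopes),
                         corrected = TRUE, ...) {
  slice <- interpolate_slice(object$modern, object$glacial, object$isotope, t)
  out <- lapply(species, function(sp) {
    mask <- accessible_mask(
      object$occurrences[object$occurrences$species == sp, ],
      object$watersheds, object$modern, level = 1)
    e <- if (corrected)
      envelope_at_time(object$tree, object$traits, sp, t, anc = object$anc)
    else object$envelopes[[sp]]
    project_slice(e, slice, mask, species = sp)
  })
  names(out) <- species
  out
}

#' Plot range-area trajectories of a fitted PPGM
#'
#' Corrected projected range area against slice age for every species,
#' with the proxy MAT curve drawn beneath for orientation.
#'
#' @param x a fitted [ppgm()].
#' @param provenance `"corrected"` or `"uncorrected"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ppgm <- function(x, provenance = "corrected", ...) {
  tab <- x$series$table
  tab <- tab[tab$provenance == provenance, ]
  wide <- stats::reshape(tab[, c("species", "time_ka", "area_km2")],
                         idvar = "time_ka", timevar = "species",
                         direction = "wide")
  wide <- wide[order(wide$time_ka), ]
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(wide$time_ka, as.matrix(wide[, -1]), type = "l",
                    lty = 1, xlab = "", ylab = "range area (km^2)",
                    main = sprintf("PPGM range areas (%s)", provenance),
                    xlim = rev(range(wide$time_ka)), ...)
  graphics::par(mar = c(4, 4, 0, 1))
  graphics::plot(x$isotope$time_ka, x$isotope$mat_c, type = "l",
                 xlab = "age (ka BP)", ylab = "proxy MAT (degC)",
                 xlim = rev(range(wide$time_ka)))
  invisible(x)
}
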