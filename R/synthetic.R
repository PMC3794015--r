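# Synthetic inputs with the statistical structure the pipeline assumes:
# smooth autocorrelated climate fields with glacial/interglacial end-members,
# a quasi-periodic isotope MAT curve, a Yule clade with Brownian-evolving
# niche envelopes, occurrences sampled inside tip envelopes, fossils planted
# with ground-truth labels, and blocky nested watershed partitions.

# sum of low-frequency cosine modes on the unit square; ~O(1) amplitude
smooth_field <- function(n_rows, n_cols, n_modes = 3L) {
  rr <- matrix((seq_len(n_rows) - 0.5) / n_rows, n_rows, n_cols)
  cc <- matrix((seq_len(n_cols) - 0.5) / n_cols, n_rows, n_cols, byrow = TRUE)
  f <- matrix(0, n_rows, n_cols)
  for (k in seq_len(n_modes)) {
    a <- stats::rnorm(2)
    ph <- stats::runif(2, 0, 2 * pi)
    th <- stats::runif(1, 0, 2 * pi)
    u <- cos(th) * rr + sin(th) * cc
    v <- -sin(th) * rr + cos(th) * cc
    f <- f + (a[1] * cos(2 * pi * k * u + ph[1]) +
              a[2] * cos(2 * pi * k * v + ph[2])) / k
  }
  f / sqrt(n_modes)
}

# row-major lattice: id = (row-1)*n_cols + col, x east, y north, h = sqrt(area)
lattice_cells <- function(n_rows, n_cols, cell_area) {
  h <- sqrt(cell_area)
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  data.frame(cell_id = seq_len(n_rows * n_cols),
             x = (col - 0.5) * h,
             y = (row - 0.5) * h)
}

#' Generate glacial and interglacial end-member climate grids
#'
#' Builds two bioclimatic grids on an identical equal-area lattice: a modern
#' (interglacial) end-member with a meridional temperature gradient plus
#' smooth spatially autocorrelated structure, and a glacial end-member in
#' which every temperature variable is colder by `glacial_offset` plus a
#' shared smooth anomaly scaled by `roughness`.  A blocky nested watershed
#' partition (Level-1 bands subdivided into Level-2 blocks) is generated on
#' the same lattice.
#'
#' With `roughness = 0` the fields are purely deterministic gradients and
#' the glacial grid equals the modern grid minus `glacial_offset` on every
#' temperature variable (precipitation unchanged).
#'
#' @param n_rows,n_cols lattice dimensions (>= 2).
#' @param cell_area cell area, km^2.
#' @param n_vars 8 (modeling subset) or 19 (all bioclimatic variables).
#' @param roughness amplitude of the random smooth structure (>= 0).
#' @param glacial_offset uniform glacial cooling of temperature variables,
#'   degrees C.
#' @param n_level1 number of Level-1 watershed bands.
#' @param n_level2 number of Level-2 sub-blocks per Level-1 band.
#' @param seed integer seed (NULL: use the current RNG state).
#' @return List with elements `modern`, `glacial` (both `climate_grid`) and
#'   `watersheds` (`watershed_map`).
#' @export
make_endmember_grids <- function(n_rows, n_cols, cell_area = 50,
                                 n_vars = 19, roughness = 0.5,
                                 glacial_offset = 6,
                                 n_level1 = 3, n_level2 = 2,
                                 seed = NULL) {
  if (n_rows < 2 || n_cols < 2) stop("grid dimensions must be at least 2 x 2")
  if (!n_vars %in% c(8, 19)) stop("`n_vars` must be 8 or 19")
  if (roughness < 0) stop("`roughness` must be non-negative")
  with_seed(seed, {
    cells <- lattice_cells(n_rows, n_cols, cell_area)
    lat <- matrix(rep((seq_len(n_rows) - 0.5) / n_rows, each = n_cols),
                  n_rows, n_cols, byrow = TRUE)
    lon <- matrix(rep((seq_len(n_cols) - 0.5) / n_cols, times = n_rows),
                  n_rows, n_cols, byrow = TRUE)
    rf <- function() roughness * smooth_field(n_rows, n_cols)

    # temperature: warm south (low y), cold north; units degrees C
    t0 <- 25 - 18 * lat + 2 * rf()
    amp <- 9 + 1.5 * rf()                    # seasonal half-amplitude
    diurnal <- 9 + 1.5 * rf()
    p0 <- pmax(80, 800 + 500 * (lon - 0.5) * 2 + 150 * rf())  # annual precip, mm

    fields <- list(
      BIO1  = t0,
      BIO2  = diurnal,
      BIO3  = 40 + 4 * rf(),
      BIO4  = 600 + 60 * rf(),
      BIO5  = t0 + amp + diurnal / 2,
      BIO6  = t0 - amp - diurnal / 2,
      BIO8  = t0 + 2 + rf(),
      BIO9  = t0 - 2 + rf(),
      BIO10 = t0 + 0.7 * amp,
      BIO11 = t0 - 0.7 * amp,
      BIO12 = p0,
      BIO13 = p0 * (0.16 + 0.01 * rf()),
      BIO14 = p0 * pmax(0.005, 0.03 + 0.01 * rf()),
      BIO15 = 35 + 6 * rf(),
      BIO16 = p0 * (0.38 + 0.02 * rf()),
      BIO17 = p0 * pmax(0.01, 0.10 + 0.02 * rf()),
      BIO18 = p0 * (0.30 + 0.02 * rf()),
      BIO19 = p0 * (0.20 + 0.02 * rf()))
    fields$BIO7 <- fields$BIO5 - fields$BIO6

    vars <- if (n_vars == 19) BIOCLIM_VARS else MODELING_VARS
    # matrix rows in cell-id (row-major) order; t(field) flattens that way
    modern <- sapply(vars, function(v) as.vector(t(fields[[v]])))

    anom <- roughness * 0.5 * as.vector(t(smooth_field(n_rows, n_cols)))
    panom <- roughness * 0.1 * as.vector(t(smooth_field(n_rows, n_cols)))
    glacial <- modern
    # uniform cooling shifts temperature levels; range-type temperature
    # variables (BIO2/3/4/7) are differences and stay put
    tv <- intersect(vars, TEMP_LEVEL_VARS)
    pv <- intersect(vars, BIOCLIM_PRECIP_VARS)
    glacial[, tv] <- glacial[, tv] - glacial_offset + anom
    if (length(pv))
      glacial[, pv] <- glacial[, pv] * pmax(0.05, 1 + panom)

    # blocky Level-1 basins (column bands x north/south halves), each split
    # into Level-2 row sub-blocks
    col <- (cells$cell_id - 1L) %% n_cols + 1L
    row <- (cells$cell_id - 1L) %/% n_cols + 1L
    band <- pmin(n_level1, ceiling(col / (n_cols / n_level1)))
    half <- ifelse(row <= n_rows / 2, 1L, 2L)
    l1 <- (band - 1L) * 2L + half
    l2sub <- pmin(2L * n_level2, ceiling(row / (n_rows / (2 * n_level2))))
    ws <- watershed_map(cells$cell_id, l1, paste(l1, l2sub, sep = "."))

    list(modern  = climate_grid(cells, modern, cell_area, time_ka = 0),
         glacial = climate_grid(cells, glacial, cell_area, time_ka = 21),
         watersheds = ws)
  })
}

#' Generate a quasi-periodic isotope-proxy temperature series
#'
#' Emulates a deep-sea-core oxygen-isotope proxy for global mean annual
#' temperature over repeated glacial-interglacial cycles.  The curve equals
#' `mat_modern` at t = 0, dips to `mat_glacial` at glacial maxima (when
#' `amplitude` is left at its default), and optionally overshoots
#' `mat_modern` by `overshoot` degrees at interglacial peaks (one cycle
#' period before present), emulating a last interglacial warmer than today.
#'
#' @param n_slices number of slices (>= 2).
#' @param step_ky slice spacing, ky.
#' @param period_ky glacial cycle period, ky.
#' @param mat_modern,mat_glacial end-member MAT anchors, degrees C.
#' @param amplitude peak-to-trough amplitude of the cycle, degrees C
#'   (default `mat_modern - mat_glacial`; 0 gives a constant series).
#' @param overshoot interglacial overshoot above `mat_modern`, degrees C.
#' @param wiggle amplitude of an extra seeded harmonic wiggle (default 0,
#'   keeping the min/max anchors exact).
#' @param seed integer seed (only used when `wiggle > 0`).
#' @return An [isotope_series()].
#' @export
make_isotope_series <- function(n_slices = 80, step_ky = 4, period_ky = 100,
                                mat_modern = 15, mat_glacial = 9,
                                amplitude = mat_modern - mat_glacial,
                                overshoot = 0, wiggle = 0, seed = NULL) {
  if (n_slices < 2) stop("`n_slices` must be at least 2")
  if (!(mat_modern > mat_glacial))
    stop("`mat_modern` must exceed `mat_glacial`")
  with_seed(seed, {
    t <- (seq_len(n_slices) - 1) * step_ky
    mat <- mat_modern - amplitude * (1 - cos(2 * pi * t / period_ky)) / 2 +
      overshoot * sin(pi * t / (2 * period_ky))^4
    if (wiggle > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      mat <- mat + wiggle * sin(6 * pi * t / period_ky + ph) *
        sin(2 * pi * t / period_ky)^2
    }
    isotope_series(t, mat, mat_modern, mat_glacial)
  })
}

# Brownian motion along the tree; returns (Ntip+Nnode) x p matrix of node
# values, tips first, in ape numbering.  rate = variance per unit length.
sim_bm_tree <- function(tree, x0, rate) {
  tree <- stats::reorder(tree, "cladewise")   # parents precede children
  nt <- ape::Ntip(tree)
  p <- length(x0)
  X <- matrix(NA_real_, nt + tree$Nnode, p)
  X[nt + 1L, ] <- x0
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    X[ch, ] <- X[par, ] + stats::rnorm(p, 0, sqrt(rate * tree$edge.length[i]))
  }
  X
}

#' Simulate a clade with Brownian-evolving niche envelopes
#'
#' Simulates an ultrametric Yule tree conditioned on `n_species` extant
#' tips (branch lengths in My) and evolves each niche-envelope bound pair
#' along it: the envelope midpoint follows Brownian motion with variance
#' `bm_rate` per My, the envelope log-width follows Brownian motion with
#' variance `log_width_rate` per My (keeping widths positive).  Tip
#' envelopes are reconstructed from midpoint and width.  With
#' `bm_rate = 0` and `log_width_rate = 0` every tip envelope equals the
#' root envelope.
#'
#' If the shortest terminal branch is shorter than `min_tip_branch` My the
#' whole tree is rescaled so the modeled time window fits inside every
#' terminal branch (topology and relative branch lengths preserved).
#'
#' @param n_species number of extant tips (>= 2).
#' @param birth_rate Yule speciation rate per My.
#' @param bm_rate Brownian variance of envelope midpoints per My (>= 0).
#' @param root_envelope a [niche_envelope()]: the ancestral envelope.
#' @param log_width_rate Brownian variance of log envelope widths per My.
#' @param min_tip_branch minimum terminal branch length, My (default 0.32,
#'   the 320-ky hindcast window).
#' @param seed integer seed (NULL: current RNG state).
#' @return List with `tree` (ape `phylo`), `traits` (tip x bound matrix,
#'   columns `<VAR>_lower`, `<VAR>_upper`) and `tip_envelopes` (named list
#'   of [niche_envelope()]).
#' @export
simulate_clade <- function(n_species, birth_rate = 0.25, bm_rate = 0.05,
                           root_envelope, log_width_rate = 0.02,
                           min_tip_branch = 0.32, seed = NULL) {
  if (n_species < 2) stop("`n_species` must be at least 2")
  if (bm_rate < 0) stop("`bm_rate` must be non-negative")
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
    tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
    term <- tree$edge[, 2L] <= n_species
    shortest <- min(tree$edge.length[term])
    if (shortest < min_tip_branch)
      tree$edge.length <- tree$edge.length * (min_tip_branch / shortest)

    vars <- root_envelope$variables
    lo0 <- root_envelope$lower
    hi0 <- root_envelope$upper
    w0 <- hi0 - lo0
    if (any(w0 <= 0)) stop("root envelope must have positive width")
    p <- length(vars)
    # midpoint and log-width displacements from the root (both 0 there), so
    # zero rates reproduce the root bounds bit-exactly
    dmid <- sim_bm_tree(tree, rep(0, p), bm_rate)
    dlw <- sim_bm_tree(tree, rep(0, p), log_width_rate)
    nt <- ape::Ntip(tree)
    dm <- dmid[seq_len(nt), , drop = FALSE]
    dw <- dlw[seq_len(nt), , drop = FALSE]
    w0m <- matrix(w0, nt, p, byrow = TRUE)
    lower <- matrix(lo0, nt, p, byrow = TRUE) + dm +
      (w0m / 2) * (1 - exp(dw))
    upper <- matrix(hi0, nt, p, byrow = TRUE) + dm +
      (w0m / 2) * (exp(dw) - 1)
    colnames(lower) <- colnames(upper) <- vars
    traits <- cbind(lower, upper)
    colnames(traits) <- c(paste0(vars, "_lower"), paste0(vars, "_upper"))
    # interleave to canonical order lower,upper per variable
    traits <- traits[, as.vector(rbind(paste0(vars, "_lower"),
                                       paste0(vars, "_upper"))), drop = FALSE]
    rownames(traits) <- tree$tip.label
    tip_envelopes <- lapply(seq_len(nt), function(i)
      niche_envelope(lower[i, ], upper[i, ], trim_fraction = 0,
                     provenance = "synthetic-truth"))
    names(tip_envelopes) <- tree$tip.label
    list(tree = tree, traits = traits, tip_envelopes = tip_envelopes)
  })
}

#' Sample occurrences and plant fossils in a synthetic world
#'
#' Occurrences are drawn, per species, from grid cells whose modern climate
#' lies inside the species' ground-truth envelope: each suitable cell is
#' retained with probability `occupancy` and at most `n_occ` of the
#' retained cells are sampled (points at cell centres).  Fossils are
#' planted at past slices: each fossil gets a true slice, a location inside
#' the species' Level-1 accessibility mask, an age window of the true slice
#' +/- `age_blur` ky, and a ground-truth label recording whether its
#' paleoclimate at the true slice lies inside the species' envelope.
#' Truth labels are a test-only channel; analysis functions never read
#' them.
#'
#' @param world list with components `modern`, `glacial`, `isotope`,
#'   `watersheds`, `tree`, `tip_envelopes` (as built by [synthetic_world()]).
#' @param n_occ target occurrences per species.
#' @param n_fossils total fossils to plant across species.
#' @param occupancy probability that a suitable cell is occupied (0, 1].
#' @param age_blur half-width of the reported fossil age window, ky.
#' @param plant_inside fraction of fossils planted at climates inside the
#'   species' envelope.
#' @param home_basins number of Level-1 basins a species' realized range is
#'   restricted to (sampled with probability proportional to suitable-cell
#'   count), emulating dispersal-limited realized ranges nested inside the
#'   potential range; NULL (default) places no geographic restriction.
#' @param seed integer seed (NULL: current RNG state).
#' @return List with `occurrences` (data.frame: species, x, y, cell_id) and
#'   `fossils` (data.frame: species, x, y, cell_id, age_min_ka, age_max_ka,
#'   true_slice_ka, true_inside).
#' @export
sample_occurrences_and_fossils <- function(world, n_occ = 60, n_fossils = 40,
                                           occupancy = 0.8, age_blur = 8,
                                           plant_inside = 0.87,
                                           home_basins = NULL, seed = NULL) {
  if (!(occupancy > 0 && occupancy <= 1))
    stop("`occupancy` must be in (0, 1]")
  with_seed(seed, {
    modern <- world$modern
    ws <- world$watersheds
    vars <- intersect(MODELING_VARS, colnames(modern$values))
    vals <- grid_values(modern, variables = vars)
    occ <- list(); skipped <- character()
    for (sp in names(world$tip_envelopes)) {
      env <- world$tip_envelopes[[sp]]
      suitable <- modern$cells$cell_id[envelope_contains(env, vals)]
      if (length(suitable) && !is.null(home_basins)) {
        # confine the realized range to a few Level-1 basins, chosen with
        # probability proportional to their suitable area
        bas <- ws$level1[match(suitable, ws$cell_id)]
        tab <- table(bas)
        k <- min(home_basins, length(tab))
        home <- sample(names(tab), k, prob = as.numeric(tab))
        suitable <- suitable[bas %in% home]
      }
      if (!length(suitable)) {
        warning("species ", sp, " has no suitable cells; no points emitted")
        skipped <- c(skipped, sp)
        next
      }
      pool <- suitable[stats::runif(length(suitable)) <= occupancy]
      if (!length(pool)) pool <- sample(suitable, 1L)
      take <- sample(pool, min(n_occ, length(pool)))
      occ[[sp]] <- data.frame(species = sp,
                              x = modern$cells$x[match(take, modern$cells$cell_id)],
                              y = modern$cells$y[match(take, modern$cells$cell_id)],
                              cell_id = take)
    }
    occurrences <- do.call(rbind, occ)
    rownames(occurrences) <- NULL

    times <- slice_times(world$isotope)
    past <- times[times > 0]
    have <- setdiff(names(world$tip_envelopes), skipped)
    grids <- new.env(parent = emptyenv())
    paleo_vals <- function(t) {
      key <- as.character(t)
      if (is.null(grids[[key]]))
        grids[[key]] <- grid_values(
          interpolate_slice(world$modern, world$glacial, world$isotope, t),
          variables = vars)
      grids[[key]]
    }
    # "inside" fossils are planted inside the envelope the pipeline will fit
    # from the sampled occurrences (nested in the truth envelope), so the
    # zero-blur round trip classifies them within the potential niche;
    # "outside" fossils are planted outside the truth envelope.  The margin
    # between the two is left unplanted.  Truth labels are recomputed
    # against the truth envelope either way.
    fit_envs <- lapply(occ, function(d)
      fit_envelope(vals[match(d$cell_id, modern$cells$cell_id), , drop = FALSE],
                   vars, trim_fraction = 0, provenance = "sampler-fit"))
    fos <- vector("list", n_fossils)
    for (i in seq_len(n_fossils)) {
      sp <- sample(have, 1L)
      env <- world$tip_envelopes[[sp]]
      mask <- accessible_mask(occurrences[occurrences$species == sp, ],
                              world$watersheds, world$modern, level = 1)
      want_inside <- stats::runif(1) <= plant_inside
      rec <- NULL
      for (try in seq_len(25L)) {
        t_true <- sample(past, 1L)
        pv <- paleo_vals(t_true)[as.character(mask), , drop = FALSE]
        in_fit <- envelope_contains(fit_envs[[sp]], pv)
        in_truth <- envelope_contains(env, pv)
        cand <- if (want_inside) mask[in_fit] else mask[!in_truth]
        if (!length(cand) && try > 15L)
          cand <- if (want_inside) mask[!in_truth] else mask[in_fit]
        if (length(cand)) {
          cell <- if (length(cand) == 1L) cand else sample(cand, 1L)
          truth <- envelope_contains(env, paleo_vals(t_true)[as.character(cell), ])
          rec <- data.frame(
            species = sp,
            x = world$modern$cells$x[match(cell, world$modern$cells$cell_id)],
            y = world$modern$cells$y[match(cell, world$modern$cells$cell_id)],
            cell_id = cell,
            age_min_ka = max(min(times), t_true - age_blur),
            age_max_ka = min(max(times), t_true + age_blur),
            true_slice_ka = t_true,
            true_inside = as.logical(truth))
          break
        }
      }
      fos[[i]] <- rec
    }
    fossils <- do.call(rbind, fos)
    rownames(fossils) <- NULL
    list(occurrences = occurrences, fossils = fossils)
  })
}

#' Generate a complete synthetic study system
#'
#' Assembles every input the pipeline needs: glacial/interglacial climate
#' end-members with nested watersheds, a quasi-periodic isotope MAT curve,
#' a Yule clade with Brownian-evolving ground-truth niche envelopes,
#' occurrences sampled inside the tip envelopes, and fossils planted at
#' past slices with known truth labels.  The same seed reproduces every
#' component exactly.
#'
#' The ancestral (root) envelope defaults to the central band of the modern
#' climate (per-variable 30th--70th percentiles), so that glacial cooling
#' plausibly contracts ranges.
#'
#' @param n_species,n_rows,n_cols,n_slices,step_ky,cell_area,roughness,
#'   glacial_offset,bm_rate,log_width_rate,birth_rate,n_occ,n_fossils,
#'   occupancy,age_blur,plant_inside,home_basins see the component
#'   generators.
#' @param mat_modern,mat_glacial isotope anchors, degrees C.
#' @param root_quantiles envelope quantiles of modern climate for the root
#'   (default the central 70% band per variable).
#' @param seed integer seed controlling all randomness.
#' @return Object of class `synthetic_world`: list with `modern`, `glacial`,
#'   `watersheds`, `isotope`, `tree`, `traits`, `tip_envelopes`,
#'   `occurrences`, `fossils`, `seed`.
#' @export
synthetic_world <- function(n_species = 10, n_rows = 50, n_cols = 50,
                            n_slices = 80, step_ky = 4, cell_area = 50,
                            roughness = 0.5, glacial_offset = 6,
                            mat_modern = 15, mat_glacial = 9,
                            bm_rate = 0.05, log_width_rate = 0.02,
                            birth_rate = 0.25,
                            n_occ = 60, n_fossils = 40, occupancy = 0.8,
                            age_blur = 8, plant_inside = 0.87,
                            home_basins = 2,
                            root_quantiles = c(0.15, 0.85), seed = 1) {
  with_seed(seed, {
    em <- make_endmember_grids(n_rows, n_cols, cell_area = cell_area,
                               n_vars = 19, roughness = roughness,
                               glacial_offset = glacial_offset)
    iso <- make_isotope_series(n_slices, step_ky,
                               mat_modern = mat_modern,
                               mat_glacial = mat_glacial)
    vars <- MODELING_VARS
    q <- apply(grid_values(em$modern, variables = vars), 2, stats::quantile,
               probs = root_quantiles, names = FALSE)
    root <- niche_envelope(stats::setNames(q[1, ], vars),
                           stats::setNames(q[2, ], vars),
                           provenance = "synthetic-root")
    clade <- simulate_clade(n_species, birth_rate = birth_rate,
                            bm_rate = bm_rate, root_envelope = root,
                            log_width_rate = log_width_rate,
                            min_tip_branch = n_slices * step_ky / 1000)
    world <- list(modern = em$modern, glacial = em$glacial,
                  watersheds = em$watersheds, isotope = iso,
                  tree = clade$tree, traits = clade$traits,
                  tip_envelopes = clade$tip_envelopes,
                  root_envelope = root)
    sampled <- sample_occurrences_and_fossils(world, n_occ = n_occ,
                                              n_fossils = n_fossils,
                                              occupancy = occupancy,
                                              age_blur = age_blur,
                                              plant_inside = plant_inside,
                                              home_basins = home_basins)
    world$occurrences <- sampled$occurrences
    world$fossils <- sampled$fossils
    world$seed <- seed
    class(world) <- "synthetic_world"
    world
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d species, %d cells, %d slices ",
                     "(%g..%g ka), %d occurrences, %d fossils, seed %s\n"),
              ape::Ntip(x$tree), n_cells(x$modern), nrow(x$isotope),
              min(slice_times(x$isotope)), max(slice_times(x$isotope)),
              nrow(x$occurrences),
              if (is.null(x$fossils)) 0L else nrow(x$fossils),
              format(x$seed)))
  invisible(x)
}
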