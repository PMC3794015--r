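# Synthetic-data generator: determinism, lattice identity, zero-noise and
# zero-evolution limits, occurrence/fossil planting invariants.

test_that("zero roughness gives glacial = modern minus the offset on temperature levels", {
  em <- make_endmember_grids(6, 8, roughness = 0, glacial_offset = 5, seed = 1)
  tv <- intersect(colnames(em$modern$values), TEMP_LEVEL_VARS)
  rv <- c("BIO2", "BIO3", "BIO4", "BIO7")   # temperature differences
  pv <- intersect(colnames(em$modern$values), BIOCLIM_PRECIP_VARS)
  expect_equal(em$glacial$values[, tv], em$modern$values[, tv] - 5)
  expect_equal(em$glacial$values[, rv], em$modern$values[, rv])
  expect_equal(em$glacial$values[, pv], em$modern$values[, pv])
})

test_that("end-member grids share cell ids, coordinates and cell area", {
  em <- make_endmember_grids(7, 5, cell_area = 50, roughness = 0.8, seed = 2)
  expect_identical(em$modern$cells, em$glacial$cells)
  expect_identical(em$modern$cell_area, em$glacial$cell_area)
  expect_equal(nrow(em$modern$values), 35)
  # watershed nesting: each level2 inside exactly one level1
  nest <- unique(em$watersheds[, c("level1", "level2")])
  expect_false(anyDuplicated(nest$level2) > 0)
})

test_that("generators are reproducible under a fixed seed and vary across seeds", {
  a <- make_endmember_grids(6, 6, seed = 7)
  b <- make_endmember_grids(6, 6, seed = 7)
  expect_identical(a, b)
  w1 <- synthetic_world(n_species = 3, n_rows = 10, n_cols = 10,
                        n_slices = 10, n_occ = 15, n_fossils = 5, seed = 5)
  w2 <- synthetic_world(n_species = 3, n_rows = 10, n_cols = 10,
                        n_slices = 10, n_occ = 15, n_fossils = 5, seed = 5)
  w3 <- synthetic_world(n_species = 3, n_rows = 10, n_cols = 10,
                        n_slices = 10, n_occ = 15, n_fossils = 5, seed = 6)
  expect_identical(w1, w2)
  expect_false(identical(w1$occurrences, w3$occurrences))
})

test_that("generator arguments are validated", {
  expect_error(make_endmember_grids(1, 5), "at least 2")
  expect_error(make_endmember_grids(5, 5, n_vars = 12), "8 or 19")
  expect_error(make_isotope_series(mat_modern = 9, mat_glacial = 15),
               "must exceed")
  root <- niche_envelope(c(BIO1 = 0), c(BIO1 = 1))
  expect_error(simulate_clade(1, root_envelope = root), "at least 2")
  expect_error(simulate_clade(4, bm_rate = -1, root_envelope = root),
               "non-negative")
})

test_that("isotope series spans the requested window with exact anchors", {
  iso <- make_isotope_series(80, 4, period_ky = 100,
                             mat_modern = 15, mat_glacial = 9)
  expect_equal(nrow(iso), 80)
  expect_equal(unique(diff(iso$time_ka)), 4)
  expect_equal(iso$time_ka[1], 0)
  expect_equal(iso$mat_c[1], 15)            # modern at t = 0
  expect_gte(min(iso$mat_c), 9)             # never below the glacial anchor
  expect_lt(min(iso$mat_c), 9.05)           # ... and approaches it closely

  flat <- make_isotope_series(20, 4, amplitude = 0)
  expect_equal(flat$mat_c, rep(15, 20))

  over <- make_isotope_series(80, 4, period_ky = 100, overshoot = 1)
  expect_equal(max(over$mat_c), 16, tolerance = 1e-9)
})

test_that("simulated clades are ultrametric with envelope traits at the tips", {
  root <- niche_envelope(c(BIO1 = 5, BIO12 = 400), c(BIO1 = 15, BIO12 = 900))
  two <- simulate_clade(2, root_envelope = root, seed = 3)
  expect_equal(two$tree$Nnode, 1)
  depth <- ape::node.depth.edgelength(two$tree)[1:2]
  expect_equal(depth[1], depth[2])

  frozen <- simulate_clade(6, bm_rate = 0, log_width_rate = 0,
                           root_envelope = root, seed = 4)
  for (e in frozen$tip_envelopes) {
    expect_equal(unname(e$lower), unname(root$lower))
    expect_equal(unname(e$upper), unname(root$upper))
  }
})

test_that("Brownian tip variance scales with tree depth", {
  # fixed two-tip tree of depth 3 My, rate 1: tip values ~ N(x0, 3)
  tree <- ape::read.tree(text = "(a:3,b:3);")
  set.seed(99)
  tips <- replicate(500, sim_bm_tree(tree, c(mid = 0), 1)[1, 1])
  expect_equal(var(tips), 3, tolerance = 0.2)   # 3 MC sd ~ 0.57
})

test_that("occupancy 1 with an all-covering envelope samples min(n_occ, n_cells) cells", {
  em <- make_endmember_grids(8, 8, roughness = 0.3, seed = 10)
  iso <- make_isotope_series(10, 4)
  root <- climate_bounds(em$modern, variables = MODELING_VARS)
  clade <- simulate_clade(3, bm_rate = 0, log_width_rate = 0,
                          root_envelope = niche_envelope(
                            root$lower, root$upper), seed = 10)
  world <- list(modern = em$modern, glacial = em$glacial,
                watersheds = em$watersheds, isotope = iso,
                tree = clade$tree, tip_envelopes = clade$tip_envelopes)
  s <- sample_occurrences_and_fossils(world, n_occ = 1000, n_fossils = 0,
                                      occupancy = 1, seed = 1)
  counts <- table(s$occurrences$species)
  expect_true(all(counts == 64))
  s2 <- sample_occurrences_and_fossils(world, n_occ = 10, n_fossils = 0,
                                       occupancy = 1, seed = 1)
  expect_true(all(table(s2$occurrences$species) == 10))
})

test_that("every sampled occurrence climate lies inside its truth envelope", {
  w <- small_world()
  vals <- grid_values(w$modern, variables = MODELING_VARS)
  for (sp in unique(w$occurrences$species)) {
    cells <- w$occurrences$cell_id[w$occurrences$species == sp]
    inside <- envelope_contains(w$tip_envelopes[[sp]],
                                vals[match(cells, w$modern$cells$cell_id), ,
                                     drop = FALSE])
    expect_true(all(inside))
  }
})

test_that("fossil truth labels match an independent membership recomputation", {
  w <- small_world()
  for (i in seq_len(nrow(w$fossils))) {
    f <- w$fossils[i, ]
    g <- interpolate_slice(w$modern, w$glacial, w$isotope, f$true_slice_ka)
    v <- grid_values(g, f$cell_id, MODELING_VARS)
    expect_identical(unname(envelope_contains(w$tip_envelopes[[f$species]], v)),
                     f$true_inside)
  }
})
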