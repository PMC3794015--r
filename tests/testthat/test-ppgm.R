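# Range projection: accessibility masks, slice projection, the corrected /
# uncorrected series, empty-slice censuses, richness.

test_that("accessibility masks are basin unions over occupied basins", {
  em <- make_endmember_grids(10, 9, n_level1 = 3, n_level2 = 2, seed = 61)
  g <- em$modern; ws <- em$watersheds
  one <- data.frame(x = g$cells$x[5], y = g$cells$y[5])
  m1 <- accessible_mask(one, ws, g, level = 1)
  b <- ws$level1[ws$cell_id == cell_at(one, g)]
  expect_equal(m1, sort(ws$cell_id[ws$level1 == b]))

  # occurrences in two Level-1 basins: union of both
  left <- which(ws$level1 == 1)[1]; right <- which(ws$level1 == 3)[1]
  two <- data.frame(x = g$cells$x[c(left, right)],
                    y = g$cells$y[c(left, right)])
  m2 <- accessible_mask(two, ws, g, level = 1)
  expect_equal(m2, sort(ws$cell_id[ws$level1 %in% c(1, 3)]))

  # brute force: every mask cell's basin holds an occurrence, no other does
  set.seed(61)
  pts <- g$cells[sample(nrow(g$cells), 6), ]
  m <- accessible_mask(pts, ws, g, level = 2)
  occupied <- unique(ws$level2[match(cell_at(pts, g), ws$cell_id)])
  expect_equal(m, sort(ws$cell_id[ws$level2 %in% occupied]))
})

test_that("slice projection equals the brute-force membership test", {
  em <- make_endmember_grids(10, 10, roughness = 0.5, seed = 62)
  g <- em$modern
  mask <- g$cells$cell_id[1:60]
  all_env <- climate_bounds(g, variables = MODELING_VARS)
  pr <- project_slice(niche_envelope(all_env$lower, all_env$upper), g, mask)
  expect_equal(pr$cells, mask)              # envelope spans all climates
  expect_equal(pr$area, 60 * g$cell_area)
  expect_false(pr$empty)

  off <- niche_envelope(all_env$upper + 1, all_env$upper + 2)
  pr0 <- project_slice(off, g, mask)
  expect_true(pr0$empty)
  expect_equal(pr0$area, 0)

  mid <- niche_envelope(
    (all_env$lower + all_env$upper) / 2 - (all_env$upper - all_env$lower) / 4,
    (all_env$lower + all_env$upper) / 2 + (all_env$upper - all_env$lower) / 4)
  pr1 <- project_slice(mid, g, mask)
  v <- grid_values(g, mask, mid$variables)
  want <- mask[apply(v, 1, function(row)
    all(row >= mid$lower & row <= mid$upper))]
  expect_equal(pr1$cells, want)
  expect_equal(unname(pr1$centroid["x"]),
               mean(g$cells$x[match(want, g$cells$cell_id)]))
  expect_error(project_slice(mid, g, integer(0)), "invalid mask")
})

test_that("fragment counting uses 4-connectivity", {
  em <- make_endmember_grids(5, 5, seed = 63)
  # cells 1,2 adjacent; 13 isolated; 21,22 adjacent; 25 isolated
  expect_equal(count_fragments(c(1L, 2L, 13L, 21L, 22L, 25L), em$modern), 4L)
  expect_equal(count_fragments(integer(0), em$modern), 0L)
  # diagonal neighbours are separate fragments
  expect_equal(count_fragments(c(1L, 7L), em$modern), 2L)
})

test_that("zero niche evolution makes corrected and uncorrected series identical", {
  # identical up to SIM5 substitution, which by design only fills empty
  # corrected slices; the pre-substitution state is the empty flag
  fit <- zero_bm_fit()
  tab <- fit$series$table
  cols <- c("species", "time_ka", "n_cells", "area_km2",
            "centroid_x", "centroid_y", "empty")
  corr <- tab[tab$provenance == "corrected", ]
  unc <- tab[tab$provenance == "uncorrected", cols]
  expect_equal(corr$empty,
               unc$empty[match(paste(corr$species, corr$time_ka),
                               paste(unc$species, unc$time_ka))])
  keep <- !corr$sim5
  corr <- corr[keep, cols]
  unc <- unc[keep, ]
  rownames(corr) <- rownames(unc) <- NULL
  expect_equal(corr, unc)
})

test_that("corrected and uncorrected projections coincide at the modern slice", {
  fit <- small_fit()
  tab <- fit$series$table[fit$series$table$time_ka == 0, ]
  corr <- tab[tab$provenance == "corrected", "area_km2"]
  unc <- tab[tab$provenance == "uncorrected", "area_km2"]
  expect_equal(corr, unc)
})

test_that("empty flags match the analytic blend-threshold oracle", {
  fit <- zero_bm_fit()
  tab <- fit$series$table
  for (sp in names(fit$envelopes)) {
    want <- empty_slices_oracle(fit, sp)
    got <- tab$empty[tab$species == sp & tab$provenance == "uncorrected"]
    expect_equal(got, unname(want))
  }
})

test_that("SIM5 substitution fills empty corrected slices and is flagged", {
  fit <- small_fit()
  tab <- fit$series$table
  subd <- tab[tab$sim5, ]
  if (nrow(subd)) {
    expect_true(all(subd$provenance == "corrected"))
    expect_true(all(subd$empty))
    expect_true(all(subd$n_cells == 5))
  }
  # empty flag reflects the pre-substitution state everywhere
  expect_true(all(tab$n_cells[tab$empty & !tab$sim5] == 0))
})

test_that("richness equals the per-cell sum over species masks", {
  fit <- small_fit()
  r <- richness(fit$series, 0, grid = fit$modern)
  manual <- integer(n_cells(fit$modern))
  for (sp in names(fit$series$masks)) {
    cells <- fit$series$masks[[sp]]$corrected[["0"]]
    row <- fit$series$table[fit$series$table$species == sp &
                              fit$series$table$time_ka == 0 &
                              fit$series$table$provenance == "corrected", ]
    if (row$sim5) next
    manual[match(cells, fit$modern$cells$cell_id)] <-
      manual[match(cells, fit$modern$cells$cell_id)] + 1L
  }
  expect_equal(r$richness, manual)
  expect_lte(max(r$richness), length(fit$envelopes))
})

test_that("the fitted model object behaves like a classic R model", {
  fit <- small_fit()
  expect_s3_class(fit, "ppgm")
  expect_output(print(fit), "Paleophylogeographic")
  s <- summary(fit)
  expect_s3_class(s, "summary.ppgm")
  expect_output(print(s), "PPGM summary")
  cf <- coef(fit)
  expect_true(is.matrix(cf))
  expect_equal(nrow(cf), length(fit$envelopes))
  pr <- predict(fit, t = 0)
  expect_equal(length(pr), length(fit$envelopes))
  # modern corrected prediction matches the stored series
  sp <- names(pr)[1]
  row <- fit$series$table[fit$series$table$species == sp &
                            fit$series$table$time_ka == 0 &
                            fit$series$table$provenance == "corrected", ]
  expect_equal(pr[[sp]]$area, row$area_km2)
})

test_that("projection series are bit-reproducible for a fixed world", {
  w <- small_world()
  f1 <- ppgm(w$occurrences, w$tree, w$modern, w$glacial, w$isotope,
             w$watersheds)
  expect_identical(f1$series$table, small_fit()$series$table)
})
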