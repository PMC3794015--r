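# Fossil evaluation: age resolution, classification against realized and
# potential niches, summary tables, physiological congruence.

test_that("age resolution picks the most climate-compatible slice, keeping exact ties", {
  w <- zero_bm_world()
  slices <- interpolate_series(w$modern, w$glacial, w$isotope)
  env <- w$tip_envelopes[[1]]
  f <- data.frame(x = w$modern$cells$x[200], y = w$modern$cells$y[200],
                  age_min_ka = 8, age_max_ka = 8)
  r <- resolve_age(f, env, slices, w$isotope)
  expect_equal(r$slices, 8)                  # single-slice window

  f3 <- data.frame(x = f$x, y = f$y, age_min_ka = 4, age_max_ka = 12)
  r3 <- resolve_age(f3, env, slices, w$isotope)
  expect_equal(r3$slices, as.numeric(names(which.max(r3$scores))))
  expect_equal(r3$scores,
               vapply(c(4, 8, 12), function(t) {
                 v <- grid_values(slices[[as.character(t)]], r3$cell_id,
                                  env$variables)
                 mess_combined(env, setNames(as.numeric(v),
                                             colnames(v)))$combined
               }, numeric(1), USE.NAMES = FALSE),
               ignore_attr = TRUE)

  # exact ties are both retained: two slices with identical proxy MAT
  # produce bit-identical paleoclimates, hence identical scores
  iso2 <- isotope_series(c(0, 4, 8, 12), c(15, 12, 12, 10), 15, 9)
  slices2 <- interpolate_series(w$modern, w$glacial, iso2)
  ftie <- data.frame(x = f$x, y = f$y, age_min_ka = 4, age_max_ka = 8)
  rt <- resolve_age(ftie, env, slices2, iso2)
  expect_equal(rt$slices, c(4, 8))

  fout <- data.frame(x = f$x, y = f$y, age_min_ka = 500, age_max_ka = 600)
  expect_error(resolve_age(fout, env, slices, w$isotope), "outside")
})

test_that("a fossil at a modern occurrence cell with a modern window is within the realized niche", {
  fit <- zero_bm_fit()
  sp <- names(fit$envelopes)[1]
  occ <- fit$occurrences[fit$occurrences$species == sp, ][1, ]
  slices <- interpolate_series(fit$modern, fit$glacial, fit$isotope)
  f <- data.frame(x = occ$x, y = occ$y, age_min_ka = 0, age_max_ka = 0)
  cl <- classify_fossil(f, fit$occ_climate[[sp]][, fit$variables],
                        fit$envelopes[[sp]], slices, fit$isotope)
  expect_equal(cl$classification, "within-realized")
  expect_true(cl$within_potential)
})

test_that("a fossil a known fraction outside the envelope gets that per-variable MESS", {
  # envelope width 10 on BIO6; value 1.6% of the width below the lower
  # bound scores exactly -1.6 on BIO6
  env <- niche_envelope(c(BIO6 = -10, BIO10 = 20), c(BIO6 = 0, BIO10 = 30))
  v <- c(BIO6 = -10 - 0.16, BIO10 = 25)
  m <- mess_combined(env, v)
  expect_equal(unname(m$per_variable["BIO6"]), -1.6)
  expect_equal(m$limiting, "BIO6")
})

test_that("planted fossils classify according to their truth labels at zero age blur", {
  w <- zero_bm_world()
  fit <- zero_bm_fit()
  ev <- evaluate_fossils(fit, w$fossils)
  expect_equal(ev$within_potential, w$fossils$true_inside)
  # all planted-inside fossils fall within the potential niche
  expect_true(all(ev$within_potential[w$fossils$true_inside]))
})

test_that("summary tables pool correctly and respect the nesting invariant", {
  w <- zero_bm_world()
  fit <- zero_bm_fit()
  ev <- evaluate_fossils(fit, w$fossils)
  s <- summarize_fossils(ev)
  per <- s$per_species
  tot <- per[per$species == "Total", ]
  body <- per[per$species != "Total", ]
  expect_equal(tot$n_fossils, nrow(ev))
  # count-weighted pooling equals the pooled raw percentage
  expect_equal(tot$pct_potential,
               round(100 * mean(ev$within_potential), 1))
  expect_equal(tot$pct_realized,
               round(100 * mean(ev$within_realized), 1))
  # nesting: within-realized implies within-potential, per species and total
  expect_true(all(per$pct_potential >= per$pct_realized))
  # per-species Ns sum to the total
  expect_equal(sum(body$n_fossils), tot$n_fossils)

  # deviation rows only list variables with negative scores
  if (!is.null(s$deviations)) {
    expect_true(all(s$deviations$mean_mess < 0))
    expect_true(all(s$deviations$max_mess <= s$deviations$mean_mess))
  }
})

test_that("resolve_age is idempotent and order-independent", {
  w <- zero_bm_world()
  slices <- interpolate_series(w$modern, w$glacial, w$isotope)
  env <- w$tip_envelopes[[2]]
  f <- data.frame(x = w$modern$cells$x[44], y = w$modern$cells$y[44],
                  age_min_ka = 0, age_max_ka = 40)
  r1 <- resolve_age(f, env, slices, w$isotope)
  r2 <- resolve_age(f, env, slices, w$isotope)
  expect_identical(r1, r2)
})

test_that("physiological congruence flags follow the documented comparisons", {
  mk <- function(b5u, b6l, b10) niche_envelope(
    c(BIO5 = b5u - 10, BIO6 = b6l, BIO10 = b10[1]),
    c(BIO5 = b5u, BIO6 = b6l + 10, BIO10 = b10[2]))
  envs <- list(mk(38, -12, c(20, 26)), mk(40, -8, c(22, 28)))

  phys <- data.frame(ct_max_c = 41, ct_min_c = -14,
                     inc_low_c = 24, inc_high_c = 30)
  rep1 <- compare_physiology(envs, phys)
  expect_equal(rep1$congruent[rep1$parameter == "CT_max"], TRUE)
  expect_equal(rep1$congruent[rep1$parameter == "CT_min"], TRUE)
  expect_equal(rep1$congruent[rep1$parameter == "incubation"], TRUE)

  # CT_max below one slice's BIO5 upper bound: incongruent
  hot <- data.frame(ct_max_c = 39)
  expect_false(compare_physiology(envs, hot)$congruent)
  # CT_min above a slice's BIO6 lower bound: incongruent
  cold <- data.frame(ct_min_c = -10)
  expect_false(compare_physiology(envs, cold)$congruent)
  # incubation interval exactly equal to the BIO10 interval: congruent
  exact <- data.frame(inc_low_c = 20, inc_high_c = 26)
  expect_true(compare_physiology(envs[1], exact)$congruent)
  # missing fields are skipped
  expect_equal(nrow(compare_physiology(envs, data.frame(note = "x"))), 0)
})
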