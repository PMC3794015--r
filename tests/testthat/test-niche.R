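# Occurrence thinning, climate extraction, envelope fitting and
# convex-hull realized-niche membership.

test_that("thinning keeps exactly one point per occupied thinning cell, first in input order", {
  pts <- data.frame(x = c(1, 2, 30, 31, 60), y = c(1, 2, 5, 6, 50))
  th <- thin_occurrences(pts, resolution = 10)
  expect_equal(nrow(th), 3)
  expect_equal(th$x, c(1, 30, 60))          # first of each cell retained

  apart <- data.frame(x = seq(5, 95, by = 10), y = seq(5, 95, by = 10))
  expect_equal(nrow(thin_occurrences(apart, 10)), nrow(apart))

  set.seed(31)
  rnd <- data.frame(x = runif(100, 0, 80), y = runif(100, 0, 80))
  th <- thin_occurrences(rnd, resolution = 12)
  key <- paste(floor(rnd$x / 12), floor(rnd$y / 12))
  expect_equal(nrow(th), length(unique(key)))

  expect_warning(thin_occurrences(rnd[0, ]), "no occurrence points")
})

test_that("climate extraction uses the half-open containing-cell convention", {
  em <- make_endmember_grids(6, 6, seed = 32)
  g <- em$modern
  h <- sqrt(g$cell_area)
  centre <- data.frame(x = 2.5 * h, y = 3.5 * h)   # centre of col 3, row 4
  ex <- extract_climate(centre, g)
  expect_equal(ex$cell_id, 3 * 6 + 3)
  expect_equal(unname(ex$BIO1), unname(g$values[3 * 6 + 3, "BIO1"]))

  # point on a shared edge: left/bottom inclusive -> higher column's cell
  edge <- data.frame(x = 2 * h, y = 0.5 * h)
  expect_equal(extract_climate(edge, g)$cell_id, 3)

  expect_error(extract_climate(data.frame(x = -1, y = 1), g),
               "outside the modeled domain")

  # random in-domain points match brute-force nearest-centre lookup
  set.seed(32)
  pts <- data.frame(x = runif(50, 0, 6 * h), y = runif(50, 0, 6 * h))
  ids <- extract_climate(pts, g)$cell_id
  for (i in seq_len(50)) {
    d2 <- (g$cells$x - pts$x[i])^2 + (g$cells$y - pts$y[i])^2
    expect_equal(ids[i], g$cells$cell_id[which.min(d2)])
  }
})

test_that("envelope fitting reproduces min/max and percentile bounds", {
  v <- rbind(c(1, 10), c(3, 30))
  colnames(v) <- c("BIO1", "BIO12")
  e <- fit_envelope(v, trim_fraction = 0)
  expect_equal(unname(e$lower), c(1, 10))
  expect_equal(unname(e$upper), c(3, 30))
  expect_true(all(envelope_contains(e, v)))

  single <- fit_envelope(v[1, , drop = FALSE], trim_fraction = 0)
  expect_equal(single$lower, single$upper)
  expect_true(envelope_contains(single, v[1, ]))
  expect_false(envelope_contains(single, v[2, ]))

  set.seed(33)
  u <- matrix(runif(300), ncol = 3,
              dimnames = list(NULL, c("BIO2", "BIO5", "BIO16")))
  e90 <- fit_envelope(u, trim_fraction = 0.10)
  for (j in colnames(u)) {
    expect_equal(e90$lower[[j]], percentile_type7(u[, j], 0.05))
    expect_equal(e90$upper[[j]], percentile_type7(u[, j], 0.95))
  }
  # nesting inside the 100% envelope on the same data
  e100 <- fit_envelope(u, trim_fraction = 0)
  expect_true(all(e90$lower >= e100$lower & e90$upper <= e100$upper))

  expect_warning(small <- fit_envelope(u[1:5, ], trim_fraction = 0.10),
                 "fewer than 10")
  expect_equal(small$lower, apply(u[1:5, ], 2, min))
  expect_error(fit_envelope(u[0, ]), "zero vectors")
})

test_that("envelope fitting is permutation-invariant", {
  set.seed(34)
  u <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("BIO1", "BIO12")))
  a <- fit_envelope(u, trim_fraction = 0.10)
  b <- fit_envelope(u[sample(nrow(u)), ], trim_fraction = 0.10)
  expect_equal(a$lower, b$lower)
  expect_equal(a$upper, b$upper)
})

test_that("hull membership agrees with a 2-D triangulation oracle", {
  set.seed(35)
  ref <- matrix(runif(40), ncol = 2, dimnames = list(NULL, c("BIO1", "BIO12")))
  qry <- matrix(runif(60), ncol = 2, dimnames = list(NULL, c("BIO1", "BIO12")))
  got <- realized_membership(ref, qry)
  want <- vapply(seq_len(nrow(qry)), function(i)
    in_hull_2d_oracle(ref, qry[i, ]), logical(1))
  expect_identical(got, want)
})

test_that("hull membership basic contracts hold", {
  set.seed(36)
  ref <- matrix(rnorm(45), ncol = 3,
                dimnames = list(NULL, c("BIO2", "BIO5", "BIO16")))
  # a reference vertex is a member
  expect_true(realized_membership(ref, ref[4, ]))
  # outside the bounding box cannot be in the hull
  far <- apply(ref, 2, max) + 1
  expect_false(realized_membership(ref, far))
  # degenerate reference set falls back to the bounding box with a warning
  flat <- ref; flat[, 3] <- 0
  expect_warning(deg <- realized_membership(flat, flat[2, ]), "degenerate")
  expect_true(deg)
})

test_that("realized membership is nested inside the 100% envelope", {
  set.seed(37)
  ref <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("BIO1", "BIO12")))
  env <- fit_envelope(ref, trim_fraction = 0)
  qry <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("BIO1", "BIO12")))
  inhull <- realized_membership(ref, qry)
  inbox <- envelope_contains(env, qry)
  expect_true(all(!inhull | inbox))         # hull subset of box
})
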