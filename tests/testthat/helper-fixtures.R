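# Shared fixtures (built once per run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# small drifting-niche world for module tests
small_world <- function() cached("small", function()
  synthetic_world(n_species = 4, n_rows = 15, n_cols = 15, n_slices = 20,
                  n_occ = 40, n_fossils = 12, seed = 42))

# no niche evolution, exhaustive occupancy, exact fossil ages: the
# round-trip regime in which every tip envelope (truth and fitted) is
# identical across species
zero_bm_world <- function() cached("zerobm", function()
  synthetic_world(n_species = 5, n_rows = 20, n_cols = 20, n_slices = 20,
                  bm_rate = 0, log_width_rate = 0, occupancy = 1,
                  n_occ = 400, n_fossils = 15, age_blur = 0,
                  home_basins = NULL, seed = 11))

# full-scale deterministic end-to-end system: 10 species, 80 slices at
# 4 ky, 50 x 50 equal-area grid, no niche evolution, exact fossil ages
e2e_world <- function() cached("e2e", function()
  synthetic_world(n_species = 10, n_rows = 50, n_cols = 50, n_slices = 80,
                  bm_rate = 0, log_width_rate = 0, age_blur = 0,
                  seed = 2026))

e2e_fit <- function() cached("e2e_fit", function() {
  w <- e2e_world()
  ppgm(w$occurrences, w$tree, w$modern, w$glacial, w$isotope, w$watersheds)
})

small_fit <- function() cached("small_fit", function() {
  w <- small_world()
  ppgm(w$occurrences, w$tree, w$modern, w$glacial, w$isotope, w$watersheds)
})

zero_bm_fit <- function() cached("zerobm_fit", function() {
  w <- zero_bm_world()
  ppgm(w$occurrences, w$tree, w$modern, w$glacial, w$isotope, w$watersheds)
})

# --- independent oracles -------------------------------------------------

# joint ML ancestral states: minimize sum over edges (x_child - x_parent)^2
# / length, i.e. solve the branch-weighted tree-Laplacian normal equations
# with tips clamped at the data.  Independent of the package's BLUP path.
anc_laplacian_oracle <- function(tree, x) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  x <- x[tree$tip.label]
  A <- matrix(0, nn, nn)
  b <- rep(0, nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - nt
    ch <- tree$edge[e, 2]
    w <- 1 / tree$edge.length[e]
    A[p, p] <- A[p, p] + w
    if (ch <= nt) {
      b[p] <- b[p] + w * x[ch]
    } else {
      ci <- ch - nt
      A[p, ci] <- A[p, ci] - w
      A[ci, p] <- A[ci, p] - w
      A[ci, ci] <- A[ci, ci] + w
    }
  }
  as.numeric(solve(A, b))       # internal nodes in order nt+1 .. nt+nn
}

# 2-D point-in-convex-hull by exhaustive triangulation: a point is in the
# hull iff it is inside (or on) some triangle of reference points.
in_hull_2d_oracle <- function(ref, q) {
  sgn <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  n <- nrow(ref)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- ref[i, ]; b <- ref[j, ]; c <- ref[k, ]
    d1 <- sgn(a, b, q); d2 <- sgn(b, c, q); d3 <- sgn(c, a, q)
    tol <- 1e-12 * max(1, abs(d1), abs(d2), abs(d3))
    if ((d1 >= -tol && d2 >= -tol && d3 >= -tol) ||
        (d1 <= tol && d2 <= tol && d3 <= tol)) return(TRUE)
  }
  FALSE
}

# per-cell alpha-interval oracle for empty projection slices: each
# cell/variable value is linear in the blend weight, so cell suitability
# is an alpha interval; a slice is empty iff alpha(t) misses every cell's
# interval.  Independent of the projection code path.
empty_slices_oracle <- function(fit, sp) {
  env <- fit$envelopes[[sp]]
  mask <- accessible_mask(fit$occurrences[fit$occurrences$species == sp, ],
                          fit$watersheds, fit$modern, level = 1)
  m <- grid_values(fit$modern, mask, env$variables)
  g <- grid_values(fit$glacial, mask, env$variables)
  n <- nrow(m)
  alo <- rep(-Inf, n); ahi <- rep(Inf, n); feas <- rep(TRUE, n)
  for (j in seq_along(env$variables)) {
    d <- m[, j] - g[, j]
    L <- env$lower[[j]]; U <- env$upper[[j]]
    pos <- d > 0; neg <- d < 0; zer <- d == 0
    alo[pos] <- pmax(alo[pos], (L - g[pos, j]) / d[pos])
    ahi[pos] <- pmin(ahi[pos], (U - g[pos, j]) / d[pos])
    alo[neg] <- pmax(alo[neg], (U - g[neg, j]) / d[neg])
    ahi[neg] <- pmin(ahi[neg], (L - g[neg, j]) / d[neg])
    feas[zer] <- feas[zer] & g[zer, j] >= L & g[zer, j] <= U
  }
  vapply(slice_times(fit$isotope), function(t) {
    a <- blend_alpha(fit$isotope, t)
    !any(feas & alo <= a & a <= ahi)
  }, logical(1))
}

# manual type-7 (linear interpolation) percentile
percentile_type7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
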