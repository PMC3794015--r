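# Ancestral niche-bound estimation under Brownian motion (phylogenetic GLS)
# and time-adjusted envelopes along terminal branches.  Each envelope bound
# (lower and upper per variable) is treated as an independent continuous
# trait; time units are My on the tree and ka in the climate series, with
# the 1 My = 1000 ky conversion owned by this module.

KA_PER_MY <- 1000

#' Validate a time-calibrated tree
#'
#' Checks that branch lengths are present and positive (zero-length
#' branches are collapsed into polytomies with a warning) and that extant
#' tips are contemporaneous (ultrametric within tolerance).
#'
#' @param tree an `ape` `phylo` tree, branch lengths in My.
#' @param tol relative ultrametricity tolerance.
#' @param require_ultrametric enforce contemporaneous tips?  Range
#'   hindcasting needs an ultrametric tree; plain GLS ancestral estimation
#'   does not.
#' @return The (possibly collapsed) tree.
#' @export
validate_tree <- function(tree, tol = 1e-6, require_ultrametric = TRUE) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (any(tree$edge.length == 0)) {
    warning("zero-length branches collapsed into polytomies")
    tree <- ape::di2multi(tree, tol = 0)
  }
  if (require_ultrametric && !ape::is.ultrametric(tree, tol = tol))
    stop("extant tips must be contemporaneous (ultrametric tree)")
  tree
}

# depth (distance from root) of every node, and age = treeheight - depth
node_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  list(depth = d, height = max(d[seq_len(ape::Ntip(tree))]))
}

#' Ancestral state estimation under Brownian motion (phylogenetic GLS)
#'
#' Estimates the trait value at every internal node as the generalized
#' least squares / best linear unbiased predictor under the Brownian
#' covariance implied by shared path lengths: with tip covariance `C` and
#' GLS grand mean `mu` (the root estimate), the estimate at node `v` is
#' `mu + c_v' C^{-1} (x - mu)` where `c_v` holds the root-to-MRCA path
#' lengths between `v` and each tip.  Standard errors account for the
#' estimated mean and use the maximum-likelihood Brownian rate.
#'
#' @param tree a validated ultrametric `phylo` tree (branch lengths My).
#' @param trait named numeric vector, one value per tip.
#' @return data.frame with `node` (ape node number), `age` (My before
#'   present), `estimate`, `se`.  The root row equals the GLS grand mean.
#' @export
ancestral_estimate <- function(tree, trait) {
  tree <- validate_tree(tree, require_ultrametric = FALSE)
  nt <- ape::Ntip(tree)
  if (is.null(names(trait)))
    stop("`trait` must be named by tip label")
  x <- trait[tree$tip.label]
  if (anyNA(x))
    stop("tips missing trait values: ",
         paste(setdiff(tree$tip.label, names(trait)), collapse = ", "))

  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  Ci <- solve(C)
  one <- rep(1, nt)
  denom <- sum(Ci)
  mu <- sum(Ci %*% x) / denom

  M <- ape::mrca(tree, full = TRUE)          # (nt+nnode)^2 MRCA matrix
  dep <- node_depths(tree)
  nodes <- nt + seq_len(tree$Nnode)
  tip_idx <- match(tree$tip.label, c(tree$tip.label, rep(NA, tree$Nnode)))
  sig2 <- bm_rate_ml_(C, Ci, x, mu, nt)

  res <- x - mu
  est <- se <- numeric(length(nodes))
  for (k in seq_along(nodes)) {
    v <- nodes[k]
    cv <- dep$depth[M[v, tip_idx]]           # shared path length node-tip
    w <- Ci %*% cv
    est[k] <- mu + sum(w * res)
    condvar <- dep$depth[v] - sum(cv * w) + (1 - sum(w))^2 / denom
    se[k] <- sqrt(max(0, sig2 * condvar))
  }
  data.frame(node = nodes, age = dep$height - dep$depth[nodes],
             estimate = est, se = se)
}

bm_rate_ml_ <- function(C, Ci, x, mu, n) {
  r <- x - mu
  as.numeric(crossprod(r, Ci %*% r)) / n
}

#' Maximum-likelihood Brownian rate
#'
#' ML estimate of the Brownian variance per My given the tree:
#' `sigma^2 = (x - mu)' C^{-1} (x - mu) / n` with `mu` the GLS mean.
#' Doubling all branch lengths halves the estimate; a constant trait gives
#' rate 0 with a warning.
#'
#' @inheritParams ancestral_estimate
#' @return Non-negative rate (trait variance per My).
#' @export
bm_rate_ml <- function(tree, trait) {
  tree <- validate_tree(tree, require_ultrametric = FALSE)
  nt <- ape::Ntip(tree)
  if (nt < 3) stop("need at least 3 tips to estimate a rate")
  x <- trait[tree$tip.label]
  if (anyNA(x)) stop("tips missing trait values")
  if (stats::var(x) == 0) {
    warning("constant trait: Brownian rate is 0")
    return(0)
  }
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  Ci <- solve(C)
  mu <- sum(Ci %*% x) / sum(Ci)
  bm_rate_ml_(C, Ci, x, mu, nt)
}

#' Ancestral estimates for every envelope-bound trait
#'
#' Runs [ancestral_estimate()] independently on each column of a trait
#' matrix of envelope bounds (one reconstruction run per bound).
#'
#' @param tree a validated `phylo` tree.
#' @param traits matrix, rows = tips (rownames = tip labels), columns =
#'   envelope bounds (`<VAR>_lower`, `<VAR>_upper`).
#' @return List with `estimates` (internal nodes x traits matrix), `se`
#'   (same shape), `node_age` (named by node number), `parent` (tip label
#'   -> parent node number), `parent_age` (tip label -> parent age, My).
#' @export
ancestral_trait_table <- function(tree, traits) {
  tree <- validate_tree(tree)
  nt <- ape::Ntip(tree)
  est <- se <- NULL
  for (j in seq_len(ncol(traits))) {
    a <- ancestral_estimate(tree, traits[, j])
    if (is.null(est)) {
      est <- matrix(NA_real_, nrow(a), ncol(traits),
                    dimnames = list(a$node, colnames(traits)))
      se <- est
      node_age <- stats::setNames(a$age, a$node)
    }
    est[, j] <- a$estimate
    se[, j] <- a$se
  }
  parent <- tree$edge[match(seq_len(nt), tree$edge[, 2]), 1]
  names(parent) <- tree$tip.label
  list(estimates = est, se = se, node_age = node_age,
       parent = parent,
       parent_age = stats::setNames(node_age[as.character(parent)],
                                    tree$tip.label))
}

#' Time-adjusted niche envelope along a terminal branch
#'
#' Each envelope bound at age `t` ka is linearly interpolated between the
#' tip's observed value (at t = 0) and the Brownian GLS estimate at the
#' parent node (at the node's age):
#' `x(t) = x_tip + (t/1000 / age_parent) * (x_node - x_tip)`.
#' If interpolation makes a lower bound exceed its upper bound, both are
#' collapsed to their midpoint and a warning is recorded.
#'
#' @param tree a validated `phylo` tree (branch lengths My).
#' @param traits tip x bound trait matrix (see [ancestral_trait_table()]).
#' @param species tip label.
#' @param t age, ka BP; must not exceed the parent node's age.
#' @param anc optional precomputed [ancestral_trait_table()] result.
#' @return A [niche_envelope()] with provenance `"time-adjusted at <t> ka"`.
#' @export
envelope_at_time <- function(tree, traits, species, t, anc = NULL) {
  if (t < 0) stop("`t` must be non-negative")
  if (is.null(anc)) anc <- ancestral_trait_table(tree, traits)
  if (!species %in% rownames(traits)) stop("unknown species: ", species)
  page <- anc$parent_age[[species]]
  if (t / KA_PER_MY > page + 1e-9)
    stop("beyond-branch: t = ", t, " ka exceeds the parent-node age (",
         page * KA_PER_MY, " ka) for ", species)
  frac <- (t / KA_PER_MY) / page
  tipv <- traits[species, ]
  nodev <- anc$estimates[as.character(anc$parent[[species]]), ]
  bv <- tipv + frac * (nodev - tipv)
  bounds_to_envelope(bv, provenance = sprintf("time-adjusted at %g ka", t))
}

# turn a named bound vector (<VAR>_lower / <VAR>_upper) into an envelope,
# collapsing crossed bounds to their midpoint with a warning
bounds_to_envelope <- function(bv, trim_fraction = 0, provenance) {
  nm <- names(bv)
  vars <- unique(sub("_(lower|upper)$", "", nm))
  lo <- bv[paste0(vars, "_lower")]
  hi <- bv[paste0(vars, "_upper")]
  crossed <- lo > hi
  if (any(crossed)) {
    mid <- (lo[crossed] + hi[crossed]) / 2
    lo[crossed] <- hi[crossed] <- mid
    warning("bound crossing repaired by midpoint collapse on: ",
            paste(vars[crossed], collapse = ", "))
  }
  names(lo) <- names(hi) <- vars
  niche_envelope(lo, hi, trim_fraction = trim_fraction,
                 provenance = provenance)
}

#' Envelope bounds as a trait matrix
#'
#' Flattens per-species niche envelopes into the tip x bound trait matrix
#' used for Brownian reconstruction (columns `<VAR>_lower`, `<VAR>_upper`).
#'
#' @param envelopes named list of [niche_envelope()]s (names = tip labels).
#' @return Numeric matrix, one row per species.
#' @export
tip_trait_matrix <- function(envelopes) {
  vars <- envelopes[[1]]$variables
  out <- t(vapply(envelopes, function(e) {
    stopifnot(identical(e$variables, vars))
    as.vector(rbind(e$lower, e$upper))
  }, numeric(2 * length(vars))))
  colnames(out) <- as.vector(rbind(paste0(vars, "_lower"),
                                   paste0(vars, "_upper")))
  rownames(out) <- names(envelopes)
  out
}
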