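# Fossil evaluation: age resolution by climate compatibility, classification
# against realized and potential niches, summary tables, and physiological
# congruence checks.

#' Resolve a fossil's age to its most climate-compatible slice(s)
#'
#' Among the modeled slices inside the fossil's reported age window, the
#' best age estimate is the slice whose paleoclimate at the fossil's cell
#' is most compatible with the species' potential niche -- the slice
#' maximizing the combined MESS score.  Exact ties are all retained as
#' equally likely.
#'
#' @param fossil one-row data.frame with `x`, `y` (km), `age_min_ka`,
#'   `age_max_ka`.
#' @param envelope the species' modern potential [niche_envelope()].
#' @param slices named list of interpolated [climate_grid()]s (names =
#'   slice ages, as from [interpolate_series()]).
#' @param isotope an [isotope_series()] (for the window-to-slice mapping).
#' @return List with `slices` (resolved ages, ka), `scores` (combined MESS
#'   per candidate slice, named by age) and `cell_id`.
#' @export
resolve_age <- function(fossil, envelope, slices, isotope) {
  if (fossil$age_min_ka > fossil$age_max_ka)
    stop("`age_min_ka` must not exceed `age_max_ka`")
  cand <- slices_in_window(isotope, fossil$age_min_ka, fossil$age_max_ka)
  cell <- cell_at(fossil, slices[[1]])
  scores <- vapply(cand, function(t) {
    v <- grid_values(slices[[as.character(t)]], cell, envelope$variables)
    mess_combined(envelope, stats::setNames(as.numeric(v), colnames(v)))$combined
  }, numeric(1))
  names(scores) <- cand
  best <- scores == max(scores)          # exact ties all retained
  list(slices = cand[best], scores = scores, cell_id = cell)
}

#' Classify a fossil against realized and potential niches
#'
#' At each resolved slice the fossil's paleoclimate (read from the single
#' grid cell containing it) is tested for potential-niche membership
#' (envelope containment) and realized-niche membership (convex hull of
#' the species' modern occurrence climates), and scored with per-variable
#' and combined MESS against the potential niche.  When resolved slices
#' disagree, the most favorable slice (highest combined MESS) provides the
#' headline classification and all slices are retained.
#'
#' Classifications: `"within-realized"` (realized and potential),
#' `"within-potential-only"`, `"outside-potential"`.
#'
#' @param fossil one-row data.frame (`x`, `y`, `age_min_ka`, `age_max_ka`).
#' @param reference_vectors the species' modern occurrence climate matrix.
#' @param envelope the species' modern potential [niche_envelope()].
#' @param slices named list of interpolated slices.
#' @param isotope an [isotope_series()].
#' @return List of class `fossil_classification`: `classification`,
#'   `within_potential`, `within_realized`, `mess` (headline
#'   [mess_combined()] result), `resolved` ([resolve_age()] output),
#'   `slice_ka` (headline slice), `per_slice` (data.frame over resolved
#'   slices).
#' @export
classify_fossil <- function(fossil, reference_vectors, envelope,
                            slices, isotope) {
  res <- resolve_age(fossil, envelope, slices, isotope)
  per <- lapply(res$slices, function(t) {
    v <- grid_values(slices[[as.character(t)]], res$cell_id,
                     envelope$variables)
    if (anyNA(v)) stop("data gap: no paleoclimate at the fossil cell")
    vec <- stats::setNames(as.numeric(v), colnames(v))
    m <- mess_combined(envelope, vec)
    pot <- unname(envelope_contains(envelope, vec))
    rea <- pot && suppressWarnings(
      realized_membership(reference_vectors, vec,
                          variables = envelope$variables))
    list(t = t, mess = m, potential = pot, realized = rea)
  })
  comb <- vapply(per, function(p) p$mess$combined, numeric(1))
  head <- per[[which.max(comb)]]
  cls <- if (head$realized) "within-realized"
         else if (head$potential) "within-potential-only"
         else "outside-potential"
  structure(list(classification = cls,
                 within_potential = head$potential,
                 within_realized = head$realized,
                 mess = head$mess,
                 resolved = res,
                 slice_ka = head$t,
                 per_slice = data.frame(
                   time_ka = vapply(per, `[[`, numeric(1), "t"),
                   combined_mess = comb,
                   within_potential = vapply(per, `[[`, logical(1), "potential"),
                   within_realized = vapply(per, `[[`, logical(1), "realized"))),
            class = "fossil_classification")
}

#' @export
print.fossil_classification <- function(x, ...) {
  cat(sprintf("<fossil_classification> %s at %g ka (combined MESS %.1f, limiting %s)\n",
              x$classification, x$slice_ka, x$mess$combined, x$mess$limiting))
  invisible(x)
}

#' Evaluate every fossil against a fitted PPGM
#'
#' Runs [classify_fossil()] for each fossil record using the fitted modern
#' envelopes and occurrence climates of a [ppgm()] object.
#'
#' @param fit a fitted [ppgm()].
#' @param fossils data.frame: `species`, `x`, `y`, `age_min_ka`,
#'   `age_max_ka`.
#' @return data.frame with one row per fossil: the input columns plus
#'   `slice_ka`, `combined_mess`, `limiting`, `within_potential`,
#'   `within_realized`, `classification`, `n_resolved`, and one
#'   `mess_<VAR>` column per modeling variable.
#' @export
evaluate_fossils <- function(fit, fossils) {
  slices <- interpolate_series(fit$modern, fit$glacial, fit$isotope)
  rows <- vector("list", nrow(fossils))
  for (i in seq_len(nrow(fossils))) {
    f <- fossils[i, , drop = FALSE]
    sp <- f$species
    if (!sp %in% names(fit$envelopes)) {
      warning("fossil ", i, ": species ", sp, " not fitted; skipped")
      next
    }
    cl <- classify_fossil(f, fit$occ_climate[[sp]][, fit$variables,
                                                   drop = FALSE],
                          fit$envelopes[[sp]], slices, fit$isotope)
    mv <- as.list(cl$mess$per_variable)
    names(mv) <- paste0("mess_", names(mv))
    rows[[i]] <- cbind(f,
                       data.frame(slice_ka = cl$slice_ka,
                                  combined_mess = cl$mess$combined,
                                  limiting = cl$mess$limiting,
                                  within_potential = cl$within_potential,
                                  within_realized = cl$within_realized,
                                  classification = cl$classification,
                                  n_resolved = length(cl$resolved$slices)),
                       mv)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count-weighted pooling of per-group percentages or means
#'
#' Pools per-group summary values into a total as the count-weighted mean
#' `sum(n * value) / sum(n)` -- the aggregation used for the totals rows
#' of the fossil summary tables.
#'
#' @param n per-group counts.
#' @param value per-group percentages or means.
#' @return The pooled value (unrounded).
#' @export
pool_weighted <- function(n, value) {
  if (length(n) != length(value)) stop("`n` and `value` lengths differ")
  sum(n * value) / sum(n)
}

#' Summary tables for classified fossils
#'
#' Produces (i) a per-species table of fossil counts and the percentage
#' falling within the realized and potential niches, with a count-weighted
#' totals row, and (ii) a per-variable deviation table of MESS scores for
#' fossils that fall outside the reference bounds on that variable (N,
#' mean score, most negative score), partitioned by whether the fossil is
#' overall within or outside the potential niche.  Percentages are pooled
#' unrounded and rounded once, to one decimal, for output.
#'
#' @param evaluated data.frame from [evaluate_fossils()].
#' @return List with `per_species` (incl. `"Total"` row) and `deviations`.
#' @export
summarize_fossils <- function(evaluated) {
  if (!nrow(evaluated)) stop("need at least one evaluated fossil")
  sp <- split(evaluated, evaluated$species)
  per <- do.call(rbind, lapply(names(sp), function(s) {
    d <- sp[[s]]
    data.frame(species = s, n_fossils = nrow(d),
               pct_realized = 100 * mean(d$within_realized),
               pct_potential = 100 * mean(d$within_potential))
  }))
  total <- data.frame(species = "Total", n_fossils = sum(per$n_fossils),
                      pct_realized = pool_weighted(per$n_fossils,
                                                   per$pct_realized),
                      pct_potential = pool_weighted(per$n_fossils,
                                                    per$pct_potential))
  per <- rbind(per, total)
  per$pct_realized <- round(per$pct_realized, 1)
  per$pct_potential <- round(per$pct_potential, 1)

  mess_cols <- grep("^mess_", names(evaluated), value = TRUE)
  dev <- list()
  for (subset in c("all", "outside", "within")) {
    d <- switch(subset,
                all = evaluated,
                outside = evaluated[!evaluated$within_potential, ],
                within = evaluated[evaluated$within_potential, ])
    for (col in mess_cols) {
      s <- d[[col]][!is.na(d[[col]]) & d[[col]] < 0]
      if (!length(s)) next
      dev[[length(dev) + 1L]] <- data.frame(
        subset = c(all = "total",
                   outside = "outside modern potential niche",
                   within = "within modern potential niche")[[subset]],
        variable = sub("^mess_", "", col),
        n = length(s), mean_mess = round(mean(s), 1),
        max_mess = round(min(s), 1))     # "max" deviation = most negative
    }
  }
  deviations <- do.call(rbind, dev)
  if (!is.null(deviations))
    deviations <- deviations[order(deviations$subset, -deviations$n), ]
  rownames(per) <- NULL
  if (!is.null(deviations)) rownames(deviations) <- NULL
  list(per_species = per, deviations = deviations)
}

#' Physiological congruence of a species' envelope history
#'
#' Compares thermal physiology with the species' per-slice potential
#' niche: the critical thermal maximum is congruent iff it is at or above
#' the warmest warm-month bound (BIO5 upper) over all slices; the critical
#' thermal minimum is congruent iff it is at or below the coldest
#' cold-month bound (BIO6 lower) over all slices; the incubation interval
#' is congruent iff it overlaps the envelope's warmest-quarter (BIO10)
#' interval in every slice.  Missing physiology fields are skipped with a
#' note.
#'
#' @param envelopes list of per-slice [niche_envelope()]s for one species
#'   (e.g. [envelope_at_time()] at each slice).
#' @param physiology one-row data.frame with any of `ct_max_c`, `ct_min_c`,
#'   `inc_low_c`, `inc_high_c`.
#' @return data.frame with one row per available comparison: `parameter`,
#'   `congruent`, `note`.
#' @export
compare_physiology <- function(envelopes, physiology) {
  bound <- function(var, side) {
    b <- vapply(envelopes, function(e)
      if (var %in% e$variables) e[[side]][[var]] else NA_real_, numeric(1))
    if (anyNA(b)) NULL else b
  }
  rows <- list()
  has <- function(f) f %in% names(physiology) && !is.na(physiology[[f]])

  if (has("ct_max_c") && !is.null(b <- bound("BIO5", "upper"))) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "CT_max", congruent = physiology$ct_max_c >= max(b),
      note = sprintf("CT_max %.1f vs max BIO5 upper %.1f",
                     physiology$ct_max_c, max(b)))
  }
  if (has("ct_min_c") && !is.null(b <- bound("BIO6", "lower"))) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "CT_min", congruent = physiology$ct_min_c <= min(b),
      note = sprintf("CT_min %.1f vs min BIO6 lower %.1f",
                     physiology$ct_min_c, min(b)))
  }
  if (has("inc_low_c") && has("inc_high_c") &&
      !is.null(lo <- bound("BIO10", "lower")) &&
      !is.null(hi <- bound("BIO10", "upper"))) {
    ok <- all(physiology$inc_low_c <= hi & physiology$inc_high_c >= lo)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "incubation", congruent = ok,
      note = sprintf("incubation [%.1f, %.1f] vs BIO10 intervals",
                     physiology$inc_low_c, physiology$inc_high_c))
  }
  if (!length(rows))
    return(data.frame(parameter = character(), congruent = logical(),
                      note = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
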