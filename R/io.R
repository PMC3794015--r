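# Plain-text readers and writers for the pipeline's inputs and outputs.
# Grids, watershed maps, occurrences, fossils, envelopes and isotope series
# travel as CSV; trees as Newick via ape.

#' Read an occurrence table
#'
#' CSV with columns `species`, `x`, `y` (projected km).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y")
  if (!all(need %in% names(d)))
    stop("occurrence file must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read a fossil record table
#'
#' CSV with columns `species`, `x`, `y`, `age_min_ka`, `age_max_ka` (and
#' optionally `source`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_fossils <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "age_min_ka", "age_max_ka")
  if (!all(need %in% names(d)))
    stop("fossil file must have columns: ", paste(need, collapse = ", "))
  if (any(d$age_min_ka > d$age_max_ka))
    stop("age_min_ka must not exceed age_max_ka")
  d
}

#' Read an isotope-proxy MAT series
#'
#' CSV with columns `time_ka`, `mat_c`.  The end-member anchors default to
#' the series' value at t = 0 (modern) and its minimum (glacial) unless
#' given.
#'
#' @param path file path.
#' @param mat_modern,mat_glacial anchor temperatures (degC); defaults
#'   derived from the series.
#' @return An [isotope_series()].
#' @export
read_isotope_series <- function(path, mat_modern = NULL, mat_glacial = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_ka", "mat_c") %in% names(d)))
    stop("isotope file must have columns: time_ka, mat_c")
  d <- d[order(d$time_ka), ]
  if (is.null(mat_modern)) mat_modern <- d$mat_c[d$time_ka == min(d$time_ka)]
  if (is.null(mat_glacial)) mat_glacial <- min(d$mat_c)
  isotope_series(d$time_ka, d$mat_c, mat_modern, mat_glacial)
}

#' Read a time-calibrated Newick tree
#'
#' Branch lengths are interpreted as My; zero-length branches are
#' collapsed with a warning and ultrametricity of extant tips is checked.
#'
#' @param path Newick file path.
#' @return A validated `phylo` tree.
#' @export
read_ppgm_tree <- function(path) {
  validate_tree(ape::read.tree(path))
}

#' Write / read a climate grid as CSV
#'
#' Wide layout: `cell_id`, `x`, `y`, then one column per variable.  Cell
#' area and slice age travel in `#`-prefixed header lines.
#'
#' @param grid a [climate_grid()].
#' @param path file path.
#' @export
write_grid_csv <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_area_km2: %.10g", grid$cell_area),
               sprintf("# time_ka: %.10g", grid$time_ka)), con)
  utils::write.csv(data.frame(grid$cells, grid$values, check.names = FALSE),
                   con, row.names = FALSE)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  num <- function(x) as.numeric(sub("^#.*: ", "", x))
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  climate_grid(d[, c("cell_id", "x", "y")],
               as.matrix(d[, setdiff(names(d), c("cell_id", "x", "y"))]),
               cell_area = num(hdr[1]), time_ka = num(hdr[2]))
}

#' Write / read a niche envelope as CSV
#'
#' Columns `variable`, `lower`, `upper`; trim fraction and provenance
#' travel in `#`-prefixed header lines.
#'
#' @param envelope a [niche_envelope()].
#' @param path file path.
#' @export
write_envelope_csv <- function(envelope, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# trim_fraction: %g", envelope$trim_fraction),
               sprintf("# provenance: %s", envelope$provenance)), con)
  utils::write.csv(data.frame(variable = envelope$variables,
                              lower = unname(envelope$lower),
                              upper = unname(envelope$upper)),
                   con, row.names = FALSE)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  d <- utils::read.csv(path, comment.char = "#")
  niche_envelope(stats::setNames(d$lower, d$variable),
                 stats::setNames(d$upper, d$variable),
                 trim_fraction = as.numeric(sub("^#.*: ", "", hdr[1])),
                 provenance = sub("^# provenance: ", "", hdr[2]))
}

#' Read a watershed map from CSV
#'
#' Columns `cell_id`, `level1`, `level2`.
#'
#' @param path file path.
#' @return A [watershed_map()].
#' @export
read_watersheds_csv <- function(path) {
  d <- utils::read.csv(path)
  watershed_map(d$cell_id, d$level1, d$level2)
}

#' Read a physiology table
#'
#' CSV with columns `species` and any of `ct_max_c`, `ct_min_c`,
#' `inc_low_c`, `inc_high_c` (degC); empty fields are allowed.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_physiology <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(d)) stop("physiology file must have a species column")
  ok <- with(d, !(ifelse(is.na(d$ct_max_c), FALSE,
                         ifelse(is.na(d$ct_min_c), FALSE,
                                d$ct_min_c >= d$ct_max_c))))
  if (!all(ok)) stop("ct_min_c must be below ct_max_c")
  d
}

#' Bundled published fossil-niche summary tables
#'
#' Two small tables compiled from a published analysis of the Quaternary
#' fossil record of Nearctic turtles (18 species with fossils, 141
#' records): per-species fossil counts with the percentage of records
#' falling within the species' realized and potential niches, and
#' per-variable MESS deviation summaries for records that fell outside
#' reference bounds.  They serve as worked inputs for the count-weighted
#' pooling arithmetic of [pool_weighted()] and as schema references for
#' [summarize_fossils()].
#'
#' @param which `"niche_summary"` or `"mess_deviations"`.
#' @return data.frame.
#' @export
published_fossil_tables <- function(which = c("niche_summary",
                                              "mess_deviations")) {
  which <- match.arg(which)
  f <- switch(which,
              niche_summary = "chelonian_fossil_niche_summary.csv",
              mess_deviations = "chelonian_fossil_mess_deviations.csv")
  utils::read.csv(system.file("extdata", f, package = "paleoniche",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
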