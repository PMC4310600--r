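# Cohort definition: the mature-tree domain of a species is the set of plots
# holding a stem at least as large as a percentile (default 75th) of the
# species' diameter distribution in the study area; the seedling domain is
# the set of plots with any seedling tally.  Stems between 2.54 cm and the
# cutoff belong to neither cohort, guaranteeing temporal separation between
# recruitment represented by seedlings and by mature trees.

#' Weighted empirical quantile (left-continuous inverse CDF)
#'
#' Returns the smallest observed value `y` whose weighted empirical CDF
#' reaches `p`, i.e. the inverse of the weighted empirical distribution
#' function.  With equal weights this is the classical type-1 sample
#' quantile.  The convention is deterministic and used consistently for
#' diameter cutoffs and for range-extreme (5th/95th percentile) estimation.
#'
#' @param x numeric values.
#' @param w positive weights, recycled length-1 allowed; `NULL` for equal.
#' @param p probabilities in (0, 1); may be a vector.
#' @return numeric vector, one quantile per element of `p`.
#' @export
weighted_quantile <- function(x, w = NULL, p) {
  if (length(x) == 0L) stop("weighted_quantile: no data")
  if (is.null(w)) w <- rep.int(1, length(x))
  if (length(w) == 1L) w <- rep.int(w, length(x))
  if (length(w) != length(x)) stop("x and w lengths differ")
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) stop("weighted_quantile: all values missing")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  .wq(x, w, p)
}

# no-check kernel shared with the bootstrap hot loop
.wq <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o])
  total <- cw[length(cw)]
  xs <- x[o]
  vapply(p, function(pp) xs[which.max(cw >= pp * total)], numeric(1))
}

# per-row expansion weight: plot design weight * count / subplot area
.tally_expansion <- function(tally, plots, areas) {
  w_plot <- plots$weight[match(tally$plot_id, plots$plot_id)]
  w_plot * tally$count / .area_for_class(tally$size_class, areas)
}

#' Estimate a species' diameter cutoff
#'
#' Estimates the `percentile` (default 75th) of the species' stem-diameter
#' distribution over the study area from all measured stems (>= 2.54 cm) on
#' forested plots.  Each stem contributes its design-consistent expansion
#' weight, plot weight x count / subplot area, so that a stem tallied on the
#' small 54 m^2 subplot represents proportionally more stems per unit area
#' than one tallied on the 672.5 m^2 subplot.
#'
#' @param tally tally table.
#' @param plots plot table with weights.
#' @param species species code.
#' @param percentile fraction in (0, 1), default 0.75.
#' @param areas a [subplot_areas()] object.
#' @return one-row data.frame: `species`, `percentile`, `cutoff_cm`.
#' @export
estimate_diameter_cutoff <- function(tally, plots, species, percentile = 0.75,
                                     areas = subplot_areas()) {
  out <- estimate_cutoffs(tally, plots, percentile = percentile, areas = areas,
                          species = species)
  if (nrow(out) == 0L)
    stop("no measured stems (diameter >= 2.54 cm) for species ", species)
  out
}

#' Estimate diameter cutoffs for many species at once
#'
#' @inheritParams estimate_diameter_cutoff
#' @param species optional character vector restricting the species set;
#'   default all species with measured stems.
#' @return data.frame: `species`, `percentile`, `cutoff_cm`, one row per
#'   species with at least one measured stem on a forested plot.
#' @export
estimate_cutoffs <- function(tally, plots, percentile = 0.75,
                             areas = subplot_areas(), species = NULL) {
  if (percentile <= 0 || percentile >= 1)
    stop("percentile must lie strictly inside (0, 1)")
  if (!"weight" %in% names(plots) || anyNA(plots$weight))
    stop("plots must carry design weights; see assign_weights()")
  keep <- tally$size_class %in% c("small_tree", "large_tree") &
    !is.na(tally$diameter_cm)
  if (!is.null(species)) keep <- keep & tally$species %in% species
  forested_ids <- plots$plot_id[plots$forested]
  keep <- keep & tally$plot_id %in% forested_ids
  t2 <- tally[keep, , drop = FALSE]
  if (nrow(t2) == 0L)
    return(data.frame(species = character(), percentile = numeric(),
                      cutoff_cm = numeric()))
  t2$.w <- .tally_expansion(t2, plots, areas)
  dt <- data.table::as.data.table(t2)
  res <- as.data.frame(dt[, list(cutoff_cm = .wq(diameter_cm, .w, percentile)),
                          by = "species"])
  res <- res[order(res$species), , drop = FALSE]
  data.frame(species = res$species, percentile = percentile,
             cutoff_cm = res$cutoff_cm, row.names = NULL)
}

#' Assign plots to seedling and mature-tree domains
#'
#' For each species with a cutoff, flags every forested plot that holds any
#' seedling tally (`has_seedling`) and any measured stem with diameter at or
#' above the species' cutoff (`has_mature`).  Stems between 2.54 cm and the
#' cutoff place the plot in neither domain; a plot can be in both.
#'
#' @param tally tally table.
#' @param plots plot table.
#' @param cutoffs data.frame `species`, `percentile`, `cutoff_cm` as from
#'   [estimate_cutoffs()] (or read from file to inject published cutoffs).
#' @return data.frame `species`, `plot_id`, `has_seedling`, `has_mature`,
#'   one row per (species, forested plot) with membership in at least one
#'   domain.
#' @export
assign_domains <- function(tally, plots, cutoffs) {
  .require_columns(cutoffs, c("species", "cutoff_cm"), "cutoff table")
  forested_ids <- plots$plot_id[plots$forested]
  dt <- data.table::as.data.table(
    tally[tally$species %in% cutoffs$species &
            tally$plot_id %in% forested_ids, , drop = FALSE])
  if (nrow(dt) == 0L)
    return(data.frame(species = character(), plot_id = character(),
                      has_seedling = logical(), has_mature = logical()))
  cut_dt <- data.table::as.data.table(cutoffs[, c("species", "cutoff_cm")])
  dt <- merge(dt, cut_dt, by = "species")
  memb <- dt[, list(
    has_seedling = any(size_class == "seedling"),
    has_mature = any(size_class != "seedling" & !is.na(diameter_cm) &
                       diameter_cm >= cutoff_cm)),
    by = c("species", "plot_id")]
  memb <- memb[memb$has_seedling | memb$has_mature, ]
  out <- as.data.frame(memb)
  out <- out[order(out$species, out$plot_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Filter species by per-domain plot counts
#'
#' A species is retained when it occupies at least `min_plots_each` plots as
#' seedlings AND at least `min_plots_each` plots as mature trees (25 for mean
#' shifts; 100 for range-extreme percentile analysis).  An explicit exclusion
#' list (non-native species, taxa the inventory cannot discriminate) is
#' honored first.
#'
#' @param domains domain membership table from [assign_domains()].
#' @param min_plots_each minimum plots per domain.
#' @param exclude character vector of species codes dropped regardless of
#'   counts.
#' @return data.frame `species`, `n_seedling_plots`, `n_mature_plots`,
#'   `retained`, `reason` ("" when retained).
#' @export
filter_species <- function(domains, min_plots_each = 25, exclude = character()) {
  dt <- data.table::as.data.table(domains)
  if (nrow(dt) == 0L)
    return(data.frame(species = character(), n_seedling_plots = integer(),
                      n_mature_plots = integer(), retained = logical(),
                      reason = character()))
  counts <- dt[, list(n_seedling_plots = sum(has_seedling),
                      n_mature_plots = sum(has_mature)),
               by = "species"]
  counts <- as.data.frame(counts)
  counts <- counts[order(counts$species), , drop = FALSE]
  reason <- character(nrow(counts))
  reason[counts$n_seedling_plots < min_plots_each] <- "too-few-seedling-plots"
  reason[counts$n_mature_plots < min_plots_each] <-
    ifelse(nzchar(reason[counts$n_mature_plots < min_plots_each]),
           "too-few-plots-both-domains", "too-few-mature-plots")
  reason[counts$species %in% exclude] <- "excluded-by-config"
  counts$retained <- !nzchar(reason)
  counts$reason <- reason
  row.names(counts) <- NULL
  counts
}

#' Write/read a cutoff table
#'
#' Cutoffs round-trip through a three-column CSV so that externally published
#' cutoff tables can be injected verbatim instead of re-estimated.
#'
#' @param cutoffs data.frame `species`, `percentile`, `cutoff_cm`.
#' @param path CSV path.
#' @return `write_cutoffs`: the path, invisibly; `read_cutoffs`: the
#'   data.frame.
#' @export
write_cutoffs <- function(cutoffs, path) {
  data.table::fwrite(cutoffs[, c("species", "percentile", "cutoff_cm")], path)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  .require_columns(out, c("species", "percentile", "cutoff_cm"), "cutoff table")
  out
}
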