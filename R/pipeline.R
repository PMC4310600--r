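# Orchestration: cutoffs -> domains -> filters -> per-species shifts for
# every attribute -> GLS combination (overall and by taxonomic group) ->
# joint latitude/elevation quadrant summary -> range-extreme percentile
# shifts -> cohort-percentile sensitivity -> tabular outputs + run log.

#' Analysis configuration
#'
#' @param attributes plot attributes analyzed; any of `"mat"`, `"tmin"`,
#'   `"tmax"`, `"elevation"`, `"latitude"`.
#' @param percentile cohort diameter percentile defining mature trees.
#' @param sensitivity_percentiles additional cohort percentiles re-run for
#'   the sensitivity table.
#' @param min_plots_means minimum plots per domain for mean-shift analysis.
#' @param min_plots_percentiles minimum plots per domain for range-extreme
#'   percentile analysis.
#' @param tail_probs quantile levels of the range extremes.
#' @param n_boot bootstrap resamples for percentile confidence intervals.
#' @param seed master seed for every random sub-stream.
#' @param exclude species codes excluded regardless of sample size.
#' @param groups named character vector species code -> group label (for the
#'   angiosperm/gymnosperm contrast); `NULL` for overall estimates only.
#' @param stratum_density named vector of km^2 per plot by stratum; `NULL`
#'   when the plot table already carries weights.
#' @param areas a [subplot_areas()] object.
#' @param run_percentiles,run_sensitivity toggle the two optional stages.
#' @param stratified_var use the stratified variance form in
#'   [diff_estimate()].
#' @param cond_max condition-number ceiling for covariance shrinkage.
#' @param significance_level per-species significance level used in the
#'   quadrant classification (no multiple-testing correction is applied; the
#'   per-species intervals are reported as-is).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(attributes = c("mat", "elevation", "latitude"),
                            percentile = 0.75,
                            sensitivity_percentiles = c(0.60, 0.85),
                            min_plots_means = 25, min_plots_percentiles = 100,
                            tail_probs = c(0.05, 0.95), n_boot = 2000,
                            seed = 1, exclude = character(), groups = NULL,
                            stratum_density = NULL, areas = subplot_areas(),
                            run_percentiles = TRUE, run_sensitivity = TRUE,
                            stratified_var = FALSE, cond_max = 1e8,
                            significance_level = 0.05) {
  if (length(attributes) == 0L) stop("at least one attribute is required")
  bad <- setdiff(attributes, names(ATTRIBUTE_COLUMNS))
  if (length(bad)) stop("unknown attribute(s): ", paste(bad, collapse = ", "))
  if (min_plots_means <= 0 || min_plots_percentiles <= 0)
    stop("plot-count thresholds must be positive")
  structure(list(attributes = attributes, percentile = percentile,
                 sensitivity_percentiles = sensitivity_percentiles,
                 min_plots_means = min_plots_means,
                 min_plots_percentiles = min_plots_percentiles,
                 tail_probs = tail_probs, n_boot = n_boot, seed = seed,
                 exclude = exclude, groups = groups,
                 stratum_density = stratum_density, areas = areas,
                 run_percentiles = run_percentiles,
                 run_sensitivity = run_sensitivity,
                 stratified_var = stratified_var, cond_max = cond_max,
                 significance_level = significance_level),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Flat key-value YAML mirroring the [analysis_config()] arguments;
#' `stratum_density` and `groups` are given as mappings, `areas` as a
#' mapping of the three subplot areas.
#'
#' @param path YAML file.
#' @return list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        setdiff(names(formals(analysis_config)),
                                c("stratum_density", "groups", "areas")))]
  if (!is.null(raw$stratum_density))
    args$stratum_density <- unlist(raw$stratum_density)
  if (!is.null(raw$groups)) {
    g <- unlist(raw$groups)
    args$groups <- stats::setNames(as.character(g), names(g))
  }
  if (!is.null(raw$areas)) args$areas <- do.call(subplot_areas, raw$areas)
  do.call(analysis_config, args)
}

# per-species membership lists from a domain table
.membership_lists <- function(domains) {
  list(seedling = split(domains$plot_id[domains$has_seedling],
                        domains$species[domains$has_seedling]),
       mature = split(domains$plot_id[domains$has_mature],
                      domains$species[domains$has_mature]))
}

# cutoffs -> domains -> filter -> per-species mat shifts -> combined "all";
# shared by the sensitivity stage
.combined_at_percentile <- function(plots, tally, config, percentile) {
  cutoffs <- estimate_cutoffs(tally, plots, percentile = percentile,
                              areas = config$areas)
  domains <- assign_domains(tally, plots, cutoffs)
  filt <- filter_species(domains, config$min_plots_means, config$exclude)
  retained <- filt$species[filt$retained]
  mem <- .membership_lists(domains)
  shifts <- lapply(retained, function(sp)
    diff_estimate(plots, mem$seedling[[sp]], mem$mature[[sp]], "mat",
                  species = sp, stratified_var = config$stratified_var))
  comb <- combine_shifts(shifts, groups = NULL, cond_max = config$cond_max)
  cbind(data.frame(percentile = percentile),
        comb[comb$group == "all",
             c("mean_diff", "se", "ci_low", "ci_high", "n_species", "lambda")])
}

#' Run the full range-shift analysis
#'
#' @param plots plot table (data.frame) or path to `plots.csv`.
#' @param tally tally table (data.frame) or path to `tally.csv`.
#' @param config an [analysis_config()].
#' @param out_dir if non-`NULL`, write `cutoffs.csv`, `species_shifts.csv`,
#'   `combined.csv`, `quadrants.csv`, `percentile_shifts.csv`,
#'   `sensitivity.csv`, `manifest.json` and `run.log` there.
#' @return list: `cutoffs`, `domains`, `species_filter`, `species_shifts`
#'   (tidy table), `shifts` (per-attribute lists of `shift_estimate`
#'   objects), `combined`, `quadrants`, `percentile_shifts`, `sensitivity`,
#'   `manifest`, `log`.
#' @export
run_analysis <- function(plots, tally, config = analysis_config(),
                         out_dir = NULL) {
  if (is.character(plots) || is.character(tally)) {
    inv <- read_inventory(plots, tally, areas = config$areas)
    plots <- inv$plots; tally <- inv$tally
  } else {
    plots <- validate_plots(plots)
    tally <- validate_tally(tally, plots)
  }
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(config$stratum_density))
    plots <- assign_weights(plots, config$stratum_density)
  if (!"weight" %in% names(plots) || anyNA(plots$weight))
    stop("plots carry no design weights and no stratum_density was configured")

  say("seed: %d", config$seed)
  say("plots: %d total, %d forested (analysis universe)",
      nrow(plots), sum(plots$forested))

  cutoffs <- estimate_cutoffs(tally, plots, percentile = config$percentile,
                              areas = config$areas)
  say("cohort percentile %.2f: cutoffs estimated for %d species",
      config$percentile, nrow(cutoffs))
  domains <- assign_domains(tally, plots, cutoffs)
  filt <- filter_species(domains, config$min_plots_means, config$exclude)
  retained <- filt$species[filt$retained]
  for (i in which(!filt$retained))
    say("dropped %s: %s (%d seedling / %d mature plots)", filt$species[i],
        filt$reason[i], filt$n_seedling_plots[i], filt$n_mature_plots[i])
  say("retained %d of %d species (>= %d plots per domain)",
      length(retained), nrow(filt), config$min_plots_means)
  if (length(retained) == 0L) stop("no species passes the plot-count filter")
  mem <- .membership_lists(domains)

  shifts <- list(); shift_rows <- list(); combined_rows <- list()
  lambda_by_attr <- list()
  for (attribute in config$attributes) {
    col <- attribute_column(attribute)
    n_missing <- sum(plots$forested & is.na(plots[[col]]))
    if (n_missing > 0)
      say("attribute %s: %d forested plots missing a value, skipped",
          attribute, n_missing)
    shifts[[attribute]] <- lapply(retained, function(sp)
      diff_estimate(plots, mem$seedling[[sp]], mem$mature[[sp]], attribute,
                    species = sp, stratified_var = config$stratified_var))
    names(shifts[[attribute]]) <- retained
    shift_rows[[attribute]] <- shifts_table(shifts[[attribute]])
    if (length(retained) >= 2L) {
      comb <- combine_shifts(shifts[[attribute]], groups = config$groups,
                             cond_max = config$cond_max)
      combined_rows[[attribute]] <- comb
      lambda_by_attr[[attribute]] <- comb$lambda[comb$group == "all"]
      say("attribute %s: combined over %d species (lambda %.2f)", attribute,
          length(retained), lambda_by_attr[[attribute]])
    }
  }
  species_shifts <- do.call(rbind, unname(shift_rows))
  combined <- if (length(combined_rows)) do.call(rbind, unname(combined_rows))

  quadrants <- NULL
  if (all(c("latitude", "elevation") %in% config$attributes)) {
    quadrants <- summarize_quadrants(
      shift_rows[["latitude"]], shift_rows[["elevation"]],
      level = config$significance_level)
  }

  percentile_shifts <- NULL
  if (config$run_percentiles && "mat" %in% config$attributes) {
    filt_pct <- filter_species(domains, config$min_plots_percentiles,
                               config$exclude)
    pct_species <- intersect(retained,
                             filt_pct$species[filt_pct$retained])
    say("percentile analysis: %d species with >= %d plots per domain",
        length(pct_species), config$min_plots_percentiles)
    ps <- lapply(seq_along(pct_species), function(j) {
      sp <- pct_species[j]
      percentile_shift(plots, mem$seedling[[sp]], mem$mature[[sp]], "mat",
                       p = config$tail_probs, n_boot = config$n_boot,
                       seed = config$seed + j, species = sp,
                       min_plots = config$min_plots_percentiles)
    })
    percentile_shifts <- do.call(rbind, ps)
    if (!is.null(percentile_shifts) && length(pct_species) >= 2L) {
      # across-species summary: inverse-variance weights from the bootstrap
      # intervals (diagonal approximation; quantile estimators carry no
      # influence vectors to rebuild the full covariance from)
      comb_pct <- do.call(rbind, lapply(config$tail_probs, function(pp) {
        rows <- percentile_shifts[percentile_shifts$p == pp, ]
        v <- ((rows$ci_high - rows$ci_low) / (2 * Z_975))^2
        wgt <- 1 / pmax(v, .Machine$double.eps)
        m <- sum(wgt * rows$diff) / sum(wgt)
        se <- sqrt(1 / sum(wgt))
        data.frame(species = "ALL", attribute = "mat", p = pp,
                   q_seedling = NA_real_, q_mature = NA_real_, diff = m,
                   ci_low = m - Z_975 * se, ci_high = m + Z_975 * se,
                   n_seedling_plots = NA_integer_,
                   n_mature_plots = NA_integer_,
                   n_boot = config$n_boot, row.names = NULL)
      }))
      percentile_shifts <- rbind(percentile_shifts, comb_pct)
    }
  }

  sensitivity <- NULL
  if (config$run_sensitivity && "mat" %in% config$attributes) {
    pcts <- sort(unique(c(config$percentile, config$sensitivity_percentiles)))
    sensitivity <- do.call(rbind, lapply(pcts, function(p)
      .combined_at_percentile(plots, tally, config, p)))
    for (i in seq_len(nrow(sensitivity)))
      say("sensitivity: cohort percentile %.2f -> combined mat shift %.4f",
          sensitivity$percentile[i], sensitivity$mean_diff[i])
  }

  manifest <- list(
    package = "rangeshift",
    settings = config[setdiff(names(config), c("areas", "groups"))],
    areas = unclass(config$areas),
    groups = as.list(config$groups),
    n_plots = nrow(plots), n_forested = sum(plots$forested),
    species = list(retained = retained,
                   dropped = filt$species[!filt$retained],
                   reasons = filt$reason[!filt$retained]),
    lambda = lambda_by_attr)

  result <- list(cutoffs = cutoffs, domains = domains, species_filter = filt,
                 species_shifts = species_shifts, shifts = shifts,
                 combined = combined, quadrants = quadrants,
                 percentile_shifts = percentile_shifts,
                 sensitivity = sensitivity, manifest = manifest,
                 log = log_lines)
  if (!is.null(out_dir)) write_results(result, out_dir)
  invisible(result)
}

#' Write a results bundle to a directory
#'
#' @param result a [run_analysis()] result.
#' @param out_dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_results <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  data.table::fwrite(result$cutoffs, file.path(out_dir, "cutoffs.csv"))
  data.table::fwrite(result$species_shifts,
                     file.path(out_dir, "species_shifts.csv"))
  if (!is.null(result$combined))
    data.table::fwrite(result$combined, file.path(out_dir, "combined.csv"))
  if (!is.null(result$quadrants))
    data.table::fwrite(result$quadrants, file.path(out_dir, "quadrants.csv"))
  if (!is.null(result$percentile_shifts))
    data.table::fwrite(result$percentile_shifts,
                       file.path(out_dir, "percentile_shifts.csv"), na = "NA")
  if (!is.null(result$sensitivity))
    data.table::fwrite(result$sensitivity,
                       file.path(out_dir, "sensitivity.csv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Joint latitude/elevation quadrant summary
#'
#' Classifies each species by the signs of its latitude and elevation
#' seedling-minus-tree differences (a difference of exactly 0 counts as
#' positive) and by which of the two differences excludes 0 at the given
#' level, then counts species per sign quadrant.
#'
#' @param shifts_lat,shifts_elev data.frames with columns `species`, `diff`,
#'   `ci_low`, `ci_high` for the latitude and elevation attributes,
#'   covering the same species set.
#' @param level significance level implied by the intervals (labeling only).
#' @return data.frame, one row per quadrant: `quadrant` (e.g.
#'   `"lat+,elev-"`), `n_species`, `n_neither`, `n_lat_only`,
#'   `n_elev_only`, `n_both`.
#' @export
summarize_quadrants <- function(shifts_lat, shifts_elev, level = 0.05) {
  if (!setequal(shifts_lat$species, shifts_elev$species))
    stop("latitude and elevation shift tables cover different species")
  m <- merge(shifts_lat[, c("species", "diff", "ci_low", "ci_high")],
             shifts_elev[, c("species", "diff", "ci_low", "ci_high")],
             by = "species", suffixes = c("_lat", "_elev"))
  lat_sign <- ifelse(m$diff_lat >= 0, "+", "-")
  elev_sign <- ifelse(m$diff_elev >= 0, "+", "-")
  sig_lat <- m$ci_low_lat > 0 | m$ci_high_lat < 0
  sig_elev <- m$ci_low_elev > 0 | m$ci_high_elev < 0
  cls <- ifelse(sig_lat & sig_elev, "both",
                ifelse(sig_lat, "lat_only",
                       ifelse(sig_elev, "elev_only", "neither")))
  quadrant <- paste0("lat", lat_sign, ",elev", elev_sign)
  all_q <- c("lat+,elev+", "lat+,elev-", "lat-,elev+", "lat-,elev-")
  out <- do.call(rbind, lapply(all_q, function(q) {
    in_q <- quadrant == q
    data.frame(quadrant = q, n_species = sum(in_q),
               n_neither = sum(in_q & cls == "neither"),
               n_lat_only = sum(in_q & cls == "lat_only"),
               n_elev_only = sum(in_q & cls == "elev_only"),
               n_both = sum(in_q & cls == "both"), row.names = NULL)
  }))
  attr(out, "level") <- level
  out
}
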