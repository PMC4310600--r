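# Small hand-built fixtures shared across tests.

toy_plots <- function(n = 6, weight = rep(1, n), mat = seq(4, 14, length.out = n),
                      stratum = rep("CA-OR", n), forested = rep(TRUE, n),
                      elevation = seq(100, 600, length.out = n),
                      latitude = seq(33, 48, length.out = n)) {
  data.frame(plot_id = sprintf("T%02d", seq_len(n)), stratum = stratum,
             latitude = latitude, longitude = rep(-120, n),
             elevation_m = elevation, mat_c = mat, tmin_c = mat - 8,
             tmax_c = mat + 8, forested = forested, weight = weight,
             row.names = NULL)
}

toy_tally <- function(plot_id, species, diameter_cm, count = 1L) {
  data.frame(plot_id = plot_id, species = species,
             size_class = ifelse(is.na(diameter_cm), "seedling",
                                 ifelse(diameter_cm >= 12.7, "large_tree",
                                        "small_tree")),
             diameter_cm = diameter_cm, count = as.integer(count),
             row.names = NULL)
}

# minimal shift_estimate stand-in for combine tests that supply an explicit
# covariance matrix (no influence vector needed)
fake_shift <- function(species, diff, attribute = "mat") {
  structure(list(species = species, attribute = attribute, diff = diff,
                 se = NA_real_, influence = NULL),
            class = "shift_estimate")
}

# brute-force domain ratio mean: sum(w z y) / sum(w z)
oracle_ratio_mean <- function(y, w, z) sum(w[z] * y[z]) / sum(w[z])

# run the estimator chain on a generated inventory for one attribute and
# return the per-species shift objects for retained species
estimate_shifts <- function(inv, attribute = "mat", min_plots = 25,
                            percentile = 0.75) {
  plots <- inv$plots; tally <- inv$tally
  cutoffs <- estimate_cutoffs(tally, plots, percentile = percentile)
  domains <- assign_domains(tally, plots, cutoffs)
  filt <- filter_species(domains, min_plots)
  keep <- filt$species[filt$retained]
  smem <- split(domains$plot_id[domains$has_seedling],
                domains$species[domains$has_seedling])
  mmem <- split(domains$plot_id[domains$has_mature],
                domains$species[domains$has_mature])
  shifts <- lapply(keep, function(sp)
    diff_estimate(plots, smem[[sp]], mmem[[sp]], attribute, species = sp))
  names(shifts) <- keep
  shifts
}

# one Monte-Carlo replicate of the combined mean-temperature shift
mc_combined_rep <- function(seed, landscape, niches, n_plots) {
  inv <- generate_inventory(landscape, niches, n_plots = n_plots, seed = seed)
  shifts <- estimate_shifts(inv, "mat")
  comb <- combine_shifts(shifts)
  keep <- names(shifts)
  truth <- mean(inv$truth$population_seedling_mean_mat[inv$truth$species %in% keep] -
                  inv$truth$population_tree_mean_mat[inv$truth$species %in% keep])
  c(est = comb$mean_diff[1], se = comb$se[1], truth = truth,
    n_species = length(keep))
}
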