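# Synthetic forest-inventory generator.
#
# A virtual landscape (latitude band, sinusoidal-ridge elevation field,
# linear temperature model) is populated with a stratified, spatially
# spread plot sample emulating a national-inventory design: two strata with
# different sampling densities, nested tally subplots, and per-species
# Gaussian thermal niches.  Seedling occupancy uses a niche center displaced
# by a planted shift delta (degrees C colder), giving every estimator an
# exact ground truth recorded in the truth table.

#' Landscape configuration for the synthetic generator
#'
#' @param lat_range south/north latitude limits, degrees N.
#' @param lon_range west/east longitude limits, degrees E.
#' @param t0 sea-level mean annual temperature at the southern edge, deg C.
#' @param lat_gradient cooling per degree of latitude, deg C.
#' @param lapse_rate cooling per km of elevation, deg C.
#' @param elev elevation-field parameters: `base` (m), `n_ridges`, `amp`
#'   (ridge amplitude, m), `noise_sd` (m), `lat_trend` (m per degree
#'   latitude; a negative value makes terrain fall off northwards,
#'   confounding elevation with latitude).
#' @param seasonal_amp_mean,seasonal_amp_sd mean and sd of the plot-level
#'   seasonal half-amplitude (deg C) separating tmin/tmax from mat.
#' @param strata data.frame `label`, `fraction` (of area; must sum to 1),
#'   `km2_per_plot` (sampling density, the design weight).
#' @param forested_fraction probability that a plot is forested.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(lat_range = c(32.5, 49.0),
                             lon_range = c(-124.5, -116.5),
                             t0 = 17, lat_gradient = 0.8, lapse_rate = 6.5,
                             elev = list(base = 700, n_ridges = 4, amp = 450,
                                         noise_sd = 150, lat_trend = 0),
                             seasonal_amp_mean = 8, seasonal_amp_sd = 1,
                             strata = data.frame(
                               label = c("CA-OR", "WA"),
                               fraction = c(0.78, 0.22),
                               km2_per_plot = c(24, 26.6)),
                             forested_fraction = 1) {
  if (lapse_rate <= 0) stop("lapse_rate must be positive")
  if (abs(sum(strata$fraction) - 1) > 1e-8)
    stop("stratum area fractions must sum to 1")
  if (forested_fraction <= 0 || forested_fraction > 1)
    stop("forested_fraction must lie in (0, 1]")
  elev_defaults <- list(base = 700, n_ridges = 4, amp = 450, noise_sd = 150,
                        lat_trend = 0)
  elev <- utils::modifyList(elev_defaults, elev)
  structure(list(lat_range = lat_range, lon_range = lon_range, t0 = t0,
                 lat_gradient = lat_gradient, lapse_rate = lapse_rate,
                 elev = elev, seasonal_amp_mean = seasonal_amp_mean,
                 seasonal_amp_sd = seasonal_amp_sd, strata = strata,
                 forested_fraction = forested_fraction),
            class = "landscape_config")
}

#' Default species niche set
#'
#' Builds a set of Gaussian thermal niches with centers spread over the
#' interior of the landscape's temperature range (so niche tails are not
#' truncated by the study-area boundary), lognormal stem-diameter
#' distributions spanning realistic 75th-percentile cutoffs, and alternating
#' angiosperm/gymnosperm group labels.
#'
#' @param n_species number of species.
#' @param delta planted seedling shift, deg C (seedling niche center =
#'   `mu_tree - delta`, i.e. colder for positive `delta`); recycled over
#'   species.
#' @param sigma niche width, deg C.
#' @param p_max peak occupancy probability.
#' @param mu_range range of niche-center temperatures, deg C.
#' @param p75_range range of target 75th-percentile diameters, cm, spread
#'   across species.
#' @param diameter_sdlog lognormal sdlog of stem diameters.
#' @param stems_rate expected stems per occupied plot.
#' @param seedling_rate expected seedlings per occupied plot.
#' @return data.frame of class `species_niches`, one row per species.
#' @export
species_niches <- function(n_species = 40, delta = 0.12, sigma = 2,
                           p_max = 0.4, mu_range = c(4, 12),
                           p75_range = c(8, 28), diameter_sdlog = 0.6,
                           stems_rate = 5, seedling_rate = 4) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(p_max <= 0 | p_max > 1)) stop("p_max must lie in (0, 1]")
  mu <- seq(mu_range[1], mu_range[2], length.out = n_species)
  # meanlog chosen so the lognormal 75th percentile hits the target
  p75 <- seq(p75_range[1], p75_range[2], length.out = n_species)
  meanlog <- log(p75) - stats::qnorm(0.75) * diameter_sdlog
  out <- data.frame(
    species = sprintf("SP%02d", seq_len(n_species)),
    mu = mu, sigma = sigma, delta = delta, p_max = p_max,
    niche_var = "mat",
    diameter_meanlog = meanlog, diameter_sdlog = diameter_sdlog,
    stems_rate = stems_rate, seedling_rate = seedling_rate,
    group = rep_len(c("gymnosperm", "angiosperm"), n_species),
    warm_edge_factor = NA_real_,
    patch_lat = NA_real_, patch_lon = NA_real_, patch_radius = NA_real_,
    patch_tree_factor = NA_real_, patch_seedling_factor = NA_real_,
    row.names = NULL)
  class(out) <- c("species_niches", "data.frame")
  out
}

# stratified-grid jitter: quasi-uniform point pattern emulating a spatially
# balanced sample inside one stratum's latitude band
.jittered_grid <- function(n, lat_lo, lat_hi, lon_lo, lon_hi) {
  side <- ceiling(sqrt(n))
  cells <- sample.int(side * side, n)  # which cells receive a plot
  row <- (cells - 1L) %/% side
  col <- (cells - 1L) %% side
  lat <- lat_lo + (row + stats::runif(n)) / side * (lat_hi - lat_lo)
  lon <- lon_lo + (col + stats::runif(n)) / side * (lon_hi - lon_lo)
  list(lat = lat, lon = lon)
}

# occupancy probability of one cohort of one species on each plot
.presence_prob <- function(niche, cohort, plots_env) {
  x <- switch(as.character(niche$niche_var),
              mat = plots_env$mat,
              elevation = plots_env$elev,
              stop("unknown niche_var: ", niche$niche_var))
  delta_eff <- if (!is.null(niche$delta_eff) && !is.na(niche$delta_eff))
    niche$delta_eff else niche$delta
  center <- if (cohort == "seedling") niche$mu - delta_eff else niche$mu
  p <- niche$p_max * exp(-(x - center)^2 / (2 * niche$sigma^2))
  if (cohort == "seedling" && !is.na(niche$warm_edge_factor)) {
    # relative seedling abundance falls off on the warm side of the niche
    warm <- plots_env$mat > niche$mu + niche$sigma
    p[warm] <- p[warm] * niche$warm_edge_factor
  }
  if (!is.na(niche$patch_lat)) {
    inside <- (plots_env$lat - niche$patch_lat)^2 +
      (plots_env$lon - niche$patch_lon)^2 <= niche$patch_radius^2
    f <- if (cohort == "seedling") niche$patch_seedling_factor else
      niche$patch_tree_factor
    p[inside] <- p[inside] * f
  }
  p * plots_env$forested  # no trees off forest land
}

#' Generate a synthetic plot/tally inventory with known truth
#'
#' Draws a stratified, spatially spread plot sample over the landscape,
#' computes each plot's elevation from a seeded sum of sinusoidal ridges plus
#' noise, derives mean annual temperature from the exact linear model
#' `mat = t0 - lat_gradient (lat - lat_min) - lapse_rate elev / 1000`, and
#' tallies stems and seedlings per species from Bernoulli occupancy under the
#' Gaussian niches.  Stems below 12.7 cm are retained with probability
#' `small_tree_m2 / large_tree_m2`, emulating detection on the nested small
#' subplot; the expansion weighting in [estimate_cutoffs()] undoes exactly
#' this thinning.  The truth table records each species' population-level
#' seedling and mature-tree mean temperature, integrated over the generated
#' plot population using the exact occupancy probabilities.
#'
#' @param landscape a [landscape_config()].
#' @param niches a [species_niches()] data.frame.
#' @param n_plots total number of plots (>= 10).
#' @param seed integer master seed; all random sub-streams derive from it, so
#'   equal seeds give byte-identical output files.
#' @param dir if non-`NULL`, write `plots.csv`, `tally.csv`, `truth.csv`
#'   there.
#' @param areas a [subplot_areas()] object (controls small-stem detection).
#' @param calibrate if `TRUE` (default), solve for each temperature-niche
#'   species' seedling center so that the population-level seedling-minus-
#'   tree mean temperature difference equals exactly `-delta`; the bounded
#'   study area otherwise attenuates a raw center shift slightly.  The truth
#'   table records the center actually used.
#' @return list with `plots`, `tally`, `truth` data.frames (invisibly when
#'   `dir` is given).
#' @export
generate_inventory <- function(landscape, niches, n_plots, seed,
                               dir = NULL, areas = subplot_areas(),
                               calibrate = TRUE) {
  if (n_plots < 10) stop("n_plots must be at least 10")
  if (nrow(niches) == 0L) stop("species niche list is empty")
  set.seed(as.integer(seed))

  st <- landscape$strata
  n_h <- diff(c(0L, round(cumsum(st$fraction) * n_plots)))
  bounds <- landscape$lat_range[1] +
    c(0, cumsum(st$fraction)) * diff(landscape$lat_range)

  lat <- numeric(0); lon <- numeric(0); stratum <- character(0)
  weight <- numeric(0)
  for (h in seq_len(nrow(st))) {
    g <- .jittered_grid(n_h[h], bounds[h], bounds[h + 1],
                        landscape$lon_range[1], landscape$lon_range[2])
    lat <- c(lat, g$lat); lon <- c(lon, g$lon)
    stratum <- c(stratum, rep.int(st$label[h], n_h[h]))
    weight <- c(weight, rep.int(st$km2_per_plot[h], n_h[h]))
  }
  n <- length(lat)

  # seeded ridge field: sum of sinusoids in rotated coordinates, plus noise
  ec <- landscape$elev
  ridge <- numeric(n)
  lat_mid <- mean(landscape$lat_range); lon_mid <- mean(landscape$lon_range)
  for (j in seq_len(ec$n_ridges)) {
    amp <- ec$amp * stats::runif(1, 0.5, 1)
    theta <- stats::runif(1, 0, 2 * pi)
    wavelength <- stats::runif(1, 1.5, 4)
    phase <- stats::runif(1, 0, 2 * pi)
    ridge <- ridge + amp * sin(2 * pi * (cos(theta) * (lon - lon_mid) +
                                           sin(theta) * (lat - lat_mid)) /
                                 wavelength + phase)
  }
  elev <- ec$base + ridge + ec$lat_trend * (lat - lat_mid) +
    stats::rnorm(n, 0, ec$noise_sd)
  elev <- pmax(elev, -86)  # floor at the deepest real land surface

  mat <- landscape$t0 - landscape$lat_gradient * (lat - landscape$lat_range[1]) -
    landscape$lapse_rate * elev / 1000
  amp_season <- pmax(stats::rnorm(n, landscape$seasonal_amp_mean,
                                  landscape$seasonal_amp_sd), 0.5)
  forested <- stats::runif(n) < landscape$forested_fraction

  plots <- data.frame(
    plot_id = sprintf("P%06d", seq_len(n)),
    stratum = stratum, latitude = lat, longitude = lon,
    elevation_m = elev, mat_c = mat,
    tmin_c = mat - amp_season, tmax_c = mat + amp_season,
    forested = forested, weight = weight, row.names = NULL)

  plots_env <- list(lat = lat, lon = lon, elev = elev, mat = mat,
                    forested = as.numeric(forested))
  p_detect_small <- areas$small_tree_m2 / areas$large_tree_m2

  tally_parts <- vector("list", nrow(niches))
  truth_rows <- vector("list", nrow(niches))
  fw0 <- weight * as.numeric(forested)
  for (k in seq_len(nrow(niches))) {
    nk <- niches[k, ]
    if (calibrate && nk$niche_var == "mat" && nk$delta != 0) {
      # The study area is bounded, so a Gaussian occupancy kernel shifted by
      # delta in its center realizes a population mean shift slightly
      # smaller than delta (the kernel tails feel the edges of the
      # temperature distribution).  Solve for the seedling center that makes
      # the population-level mean difference equal exactly -delta, so the
      # planted delta IS the ground truth the estimators are judged against.
      pop_mean <- function(center) {
        p <- fw0 * exp(-(mat - center)^2 / (2 * nk$sigma^2))
        sum(p * mat) / sum(p)
      }
      target <- pop_mean(nk$mu) - nk$delta
      half <- 10 * abs(nk$delta) + 0.5
      sol <- stats::uniroot(function(c) pop_mean(c) - target,
                            interval = c(nk$mu - half, nk$mu + half),
                            extendInt = "yes", tol = 1e-9)
      nk$delta_eff <- nk$mu - sol$root
    }
    p_tree <- .presence_prob(nk, "tree", plots_env)
    p_seed <- .presence_prob(nk, "seedling", plots_env)

    occ_tree <- which(stats::runif(n) < p_tree)
    n_stems <- 1L + stats::rpois(length(occ_tree), max(nk$stems_rate - 1, 0))
    stem_plot <- rep.int(occ_tree, n_stems)
    d <- stats::rlnorm(length(stem_plot), nk$diameter_meanlog, nk$diameter_sdlog)
    keep_large <- d >= LARGE_TREE_MIN_CM
    keep_small <- d >= SMALL_TREE_MIN_CM & d < LARGE_TREE_MIN_CM &
      stats::runif(length(d)) < p_detect_small
    keep <- keep_large | keep_small
    stem_rows <- if (any(keep)) data.frame(
      plot_id = plots$plot_id[stem_plot[keep]], species = nk$species,
      size_class = ifelse(d[keep] >= LARGE_TREE_MIN_CM, "large_tree",
                          "small_tree"),
      diameter_cm = d[keep], count = 1L, row.names = NULL) else NULL

    occ_seed <- which(stats::runif(n) < p_seed)
    seed_rows <- if (length(occ_seed)) data.frame(
      plot_id = plots$plot_id[occ_seed], species = nk$species,
      size_class = "seedling", diameter_cm = NA_real_,
      count = 1L + stats::rpois(length(occ_seed),
                                max(nk$seedling_rate - 1, 0)),
      row.names = NULL) else NULL
    tally_parts[[k]] <- rbind(stem_rows, seed_rows)

    delta_used <- if (!is.null(nk$delta_eff) && !is.na(nk$delta_eff))
      nk$delta_eff else nk$delta
    truth_rows[[k]] <- data.frame(
      species = nk$species,
      true_mu_tree = nk$mu, true_mu_seedling = nk$mu - delta_used,
      true_delta = nk$delta,
      population_tree_mean_mat = sum(fw0 * p_tree * mat) / sum(fw0 * p_tree),
      population_seedling_mean_mat = sum(fw0 * p_seed * mat) / sum(fw0 * p_seed),
      row.names = NULL)
  }
  tally <- do.call(rbind, tally_parts)
  if (is.null(tally))
    tally <- data.frame(plot_id = character(), species = character(),
                        size_class = character(), diameter_cm = numeric(),
                        count = integer())
  row.names(tally) <- NULL
  truth <- do.call(rbind, truth_rows)
  row.names(truth) <- NULL

  out <- list(plots = plots, tally = tally, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    data.table::fwrite(plots, file.path(dir, "plots.csv"), na = "NA")
    data.table::fwrite(tally, file.path(dir, "tally.csv"), na = "NA")
    data.table::fwrite(truth, file.path(dir, "truth.csv"), na = "NA")
    return(invisible(out))
  }
  out
}

#' Perturb niches into a stress-test scenario
#'
#' Scenarios emulate mechanisms that decouple geographic shifts from
#' temperature shifts:
#' \describe{
#'   \item{edge_contraction}{seedling occupancy is multiplied by `factor`
#'     only where `mat > mu + sigma`, so relative abundance within the range
#'     grows towards its cold end without moving the range footprint.}
#'   \item{pathogen_patch}{occupancy is multiplied inside a seeded circular
#'     patch, with separate tree and seedling factors — a spatially localized
#'     mortality agent.}
#'   \item{elevational_confound}{the niche is re-defined on elevation instead
#'     of temperature, with the seedling center `delta_m` metres higher.
#'     Paired with [confound_landscape()], whose terrain falls northwards at
#'     exactly `1000 lat_gradient / lapse_rate` m per degree, an upward
#'     seedling shift drags mean latitude south while leaving mean
#'     temperature essentially unchanged — opposed elevation/latitude shifts
#'     with no thermal signal.}
#' }
#'
#' @param niches a [species_niches()] data.frame.
#' @param scenario one of `"edge_contraction"`, `"pathogen_patch"`,
#'   `"elevational_confound"`, or `character(0)` for no change.
#' @param landscape the [landscape_config()] the niches will be used with
#'   (required for `pathogen_patch` placement and `elevational_confound`).
#' @param factor warm-edge seedling multiplier (edge_contraction).
#' @param patch_radius,tree_factor,seedling_factor pathogen-patch geometry
#'   (degrees) and occupancy multipliers.
#' @param seed seed for the patch placement.
#' @param delta_m upward seedling displacement in metres
#'   (elevational_confound).
#' @param sigma_m elevational niche width in metres (elevational_confound).
#' @return the modified niche data.frame.
#' @export
perturb_scenario <- function(niches, scenario, landscape = NULL,
                             factor = 0.3, patch_radius = 2,
                             tree_factor = 0.8, seedling_factor = 0.3,
                             seed = 1, delta_m = 90, sigma_m = 150) {
  if (length(scenario) == 0L) return(niches)
  scenario <- match.arg(scenario, c("edge_contraction", "pathogen_patch",
                                    "elevational_confound"))
  if (scenario == "edge_contraction") {
    niches$warm_edge_factor <- factor
  } else if (scenario == "pathogen_patch") {
    if (is.null(landscape)) stop("pathogen_patch needs the landscape to place the patch")
    set.seed(as.integer(seed))
    niches$patch_lat <- stats::runif(1, landscape$lat_range[1],
                                     landscape$lat_range[2])
    niches$patch_lon <- stats::runif(1, landscape$lon_range[1],
                                     landscape$lon_range[2])
    niches$patch_radius <- patch_radius
    niches$patch_tree_factor <- tree_factor
    niches$patch_seedling_factor <- seedling_factor
  } else {  # elevational_confound
    if (is.null(landscape)) stop("elevational_confound needs the landscape")
    lat_mid <- mean(landscape$lat_range)
    span <- diff(landscape$lat_range)
    # place elevational niche centers on the terrain trend at interior
    # latitudes: the occupancy kernel projected on latitude has width
    # sqrt(sigma_m^2 + relief^2) / |lat_trend| degrees, and must not be
    # truncated by the study-area boundary or the upward/southward
    # equivalence breaks down
    lat_centers <- seq(lat_mid - 0.25 * span, lat_mid + 0.25 * span,
                       length.out = nrow(niches))
    niches$niche_var <- "elevation"
    niches$mu <- landscape$elev$base +
      landscape$elev$lat_trend * (lat_centers - lat_mid)
    niches$sigma <- sigma_m
    niches$delta <- -delta_m  # seedling center = mu + delta_m (higher ground)
  }
  niches
}

#' Landscape whose terrain confounds elevation with latitude
#'
#' Returns `landscape` with its elevation field tilted so that mean terrain
#' height falls northwards at exactly `1000 lat_gradient / lapse_rate` metres
#' per degree of latitude.  Along that slope the temperature model is
#' constant: moving up in elevation and south in latitude are thermally
#' equivalent, which is the confounding structure the
#' `elevational_confound` scenario exploits.
#'
#' @param landscape a [landscape_config()].
#' @param base mean terrain height at the central latitude, m.
#' @param noise_sd local relief standard deviation, m.
#' @param amp ridge amplitude, m.
#' @return a modified [landscape_config()].
#' @export
confound_landscape <- function(landscape, base = 1200, noise_sd = 100,
                               amp = 100) {
  landscape$elev$base <- base
  landscape$elev$noise_sd <- noise_sd
  landscape$elev$amp <- amp
  landscape$elev$lat_trend <- -1000 * landscape$lat_gradient /
    landscape$lapse_rate
  landscape
}
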