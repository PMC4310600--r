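test_that("identical seeds yield byte-identical inventory files", {
  L <- landscape_config(); N <- species_niches(n_species = 4)
  d1 <- tempfile(); d2 <- tempfile()
  generate_inventory(L, N, n_plots = 400, seed = 99, dir = d1)
  generate_inventory(L, N, n_plots = 400, seed = 99, dir = d2)
  for (f in c("plots.csv", "tally.csv", "truth.csv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  d3 <- tempfile()
  generate_inventory(L, N, n_plots = 400, seed = 100, dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "tally.csv"))),
                         unname(tools::md5sum(file.path(d3, "tally.csv")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("the temperature field satisfies the linear model exactly", {
  L <- landscape_config()
  inv <- generate_inventory(L, species_niches(n_species = 2),
                            n_plots = 300, seed = 4)
  p <- inv$plots
  expected <- L$t0 - L$lat_gradient * (p$latitude - L$lat_range[1]) -
    L$lapse_rate * p$elevation_m / 1000
  expect_equal(p$mat_c, expected, tolerance = 1e-12)
  expect_true(all(p$latitude >= L$lat_range[1] & p$latitude <= L$lat_range[2]))
  expect_true(all(p$tmin_c < p$mat_c & p$mat_c < p$tmax_c))
})

test_that("plot counts per stratum track the configured area fractions", {
  L <- landscape_config()
  inv <- generate_inventory(L, species_niches(n_species = 2),
                            n_plots = 5000, seed = 8)
  tab <- table(inv$plots$stratum)
  expect_equal(as.numeric(tab[L$strata$label]) / 5000, L$strata$fraction,
               tolerance = 0.01)
  expect_equal(unique(inv$plots$weight[inv$plots$stratum == "CA-OR"]), 24)
  expect_equal(unique(inv$plots$weight[inv$plots$stratum == "WA"]), 26.6)
})

test_that("the planted shift is the exact population-level ground truth", {
  inv <- generate_inventory(landscape_config(),
                            species_niches(n_species = 6, delta = 0.12),
                            n_plots = 2000, seed = 31)
  diff <- inv$truth$population_seedling_mean_mat -
    inv$truth$population_tree_mean_mat
  expect_equal(diff, rep(-0.12, 6), tolerance = 1e-7)

  null <- generate_inventory(landscape_config(),
                             species_niches(n_species = 6, delta = 0),
                             n_plots = 2000, seed = 31)
  null_diff <- null$truth$population_seedling_mean_mat -
    null$truth$population_tree_mean_mat
  expect_equal(null_diff, rep(0, 6), tolerance = 1e-12)
})

test_that("recovered shift grows monotonically with the planted delta", {
  L <- landscape_config()
  deltas <- c(0, 0.06, 0.12, 0.24)
  mean_rec <- vapply(deltas, function(dl) {
    N <- species_niches(n_species = 10, delta = dl)
    ests <- vapply(1:12, function(r) {
      inv <- generate_inventory(L, N, n_plots = 2000, seed = 1000 * dl + r)
      combine_shifts(estimate_shifts(inv, "mat"))$mean_diff[1]
    }, numeric(1))
    mean(ests)
  }, numeric(1))
  # seedlings move colder: recovered (seedling - tree) falls as delta rises
  expect_equal(stats::cor(deltas, mean_rec, method = "spearman"), -1)
})

test_that("scenario perturbations behave as documented", {
  N <- species_niches(n_species = 4)
  L <- landscape_config()
  expect_identical(perturb_scenario(N, character(0)), N)
  expect_error(perturb_scenario(N, "volcano"), "arg")

  # a pathogen patch with multiplier 1 changes nothing
  P1 <- perturb_scenario(N, "pathogen_patch", landscape = L,
                         tree_factor = 1, seedling_factor = 1, seed = 2)
  a <- generate_inventory(L, N, n_plots = 500, seed = 77)
  b <- generate_inventory(L, P1, n_plots = 500, seed = 77)
  expect_equal(b$truth$population_tree_mean_mat,
               a$truth$population_tree_mean_mat, tolerance = 1e-12)
  expect_identical(b$tally, a$tally)

  # warm-edge contraction pushes the seedling population mean colder
  E <- perturb_scenario(N, "edge_contraction", factor = 0.2)
  ce <- generate_inventory(L, E, n_plots = 2000, seed = 13, calibrate = FALSE)
  cb <- generate_inventory(L, N, n_plots = 2000, seed = 13, calibrate = FALSE)
  expect_true(all(ce$truth$population_seedling_mean_mat <
                    cb$truth$population_seedling_mean_mat))
  expect_equal(ce$truth$population_tree_mean_mat,
               cb$truth$population_tree_mean_mat, tolerance = 1e-12)

  # elevational confound: niche moves to the elevation axis
  C <- perturb_scenario(N, "elevational_confound",
                        landscape = confound_landscape(L))
  expect_true(all(C$niche_var == "elevation"))
  expect_true(all(C$delta < 0))  # seedling centers sit on higher ground
})

test_that("confounded terrain falls northward at the thermally neutral slope", {
  L <- confound_landscape(landscape_config())
  expect_equal(L$elev$lat_trend, -1000 * L$lat_gradient / L$lapse_rate)
  inv <- generate_inventory(L, species_niches(n_species = 2),
                            n_plots = 2000, seed = 6)
  fit <- stats::lm(elevation_m ~ latitude, data = inv$plots)
  expect_equal(unname(stats::coef(fit)[2]), L$elev$lat_trend, tolerance = 0.1)
})
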