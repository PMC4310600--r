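test_that("weighted quantile follows the left-continuous inverse CDF", {
  # equal weights: classical type-1 quantile
  expect_equal(weighted_quantile(c(10, 20, 30, 40), p = 0.75), 30)
  expect_equal(weighted_quantile(1:100, p = 0.05), 5)
  expect_equal(weighted_quantile(1:100, p = 0.95), 95)

  # hand-computed weighted CDF: w = (2, 1, 1) on (1, 2, 3)
  # F(1) = 0.5, F(2) = 0.75, F(3) = 1
  x <- c(3, 1, 2); w <- c(1, 2, 1)
  expect_equal(weighted_quantile(x, w, 0.5), 1)   # F(1) >= 0.5
  expect_equal(weighted_quantile(x, w, 0.51), 2)
  expect_equal(weighted_quantile(x, w, 0.75), 2)
  expect_equal(weighted_quantile(x, w, 0.76), 3)

  expect_error(weighted_quantile(1:3, p = 0), "strictly inside")
  expect_error(weighted_quantile(1:3, c(1, -1, 1), 0.5), "positive")
})

test_that("equal-weight single-subplot cutoffs match the plain sample quantile", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    d <- round(runif(n, 13, 80), 1)  # all on the large subplot
    plots <- toy_plots(n)
    tally <- toy_tally(plots$plot_id, "AA", d)
    for (p in c(0.6, 0.75, 0.85)) {
      got <- estimate_diameter_cutoff(tally, plots, "AA", p)$cutoff_cm
      expect_equal(got, unname(stats::quantile(d, p, type = 1)))
    }
  }
})

test_that("small-subplot stems carry larger expansion weight in the cutoff", {
  # one 5 cm stem seen on 54 m^2, one 40 cm stem on 672.5 m^2, equal plot
  # weights: weights 1/54 > 1/672.5, so F(5) = (1/54)/(1/54 + 1/672.5)
  # = 0.9257 >= 0.5 and the median is the SMALL stem
  plots <- toy_plots(2)
  tally <- toy_tally(c("T01", "T02"), "AA", c(5, 40))
  expect_equal(estimate_diameter_cutoff(tally, plots, "AA", 0.5)$cutoff_cm, 5)
  # at a percentile beyond F(5) = 0.9257 the large stem takes over
  expect_equal(estimate_diameter_cutoff(tally, plots, "AA", 0.93)$cutoff_cm, 40)
})

test_that("raising the percentile never lowers the cutoff", {
  inv <- generate_inventory(landscape_config(), species_niches(n_species = 5),
                            n_plots = 1500, seed = 3)
  cuts <- lapply(c(0.60, 0.75, 0.85), function(p)
    estimate_cutoffs(inv$tally, inv$plots, percentile = p))
  expect_true(all(cuts[[2]]$cutoff_cm >= cuts[[1]]$cutoff_cm))
  expect_true(all(cuts[[3]]$cutoff_cm >= cuts[[2]]$cutoff_cm))

  # and the mature-domain plot count is non-increasing in the cutoff
  counts <- vapply(cuts, function(ct) {
    d <- assign_domains(inv$tally, inv$plots, ct)
    sum(d$has_mature[d$species == "SP03"])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("domain assignment respects the inclusive cutoff boundary", {
  plots <- toy_plots(3)
  cutoffs <- data.frame(species = "AA", percentile = 0.75, cutoff_cm = 25.4)
  tally <- rbind(
    toy_tally("T01", "AA", NA),     # seedling
    toy_tally("T01", "AA", 25.4),   # exactly at the cutoff -> mature
    toy_tally("T02", "AA", 25.3))   # just below -> neither domain
  dom <- assign_domains(tally, plots, cutoffs)
  r1 <- dom[dom$plot_id == "T01", ]
  expect_true(r1$has_seedling && r1$has_mature)  # plot in both domains
  expect_false("T02" %in% dom$plot_id)           # in neither
  expect_false("T03" %in% dom$plot_id)           # empty plot: no membership
})

test_that("cutoff tables round-trip and can inject published values", {
  cutoffs <- data.frame(species = "PSME", percentile = 0.75, cutoff_cm = 25.4)
  path <- tempfile(fileext = ".csv")
  write_cutoffs(cutoffs, path)
  back <- read_cutoffs(path)
  expect_equal(back$cutoff_cm, 25.4)
  unlink(path)

  plots <- toy_plots(2)
  tally <- rbind(toy_tally("T01", "PSME", 25.4), toy_tally("T02", "PSME", NA))
  dom <- assign_domains(tally, plots, back)
  expect_true(dom$has_mature[dom$plot_id == "T01"])
})

test_that("species filtering applies count thresholds and the exclusion list", {
  mk <- function(sp, n_seed, n_mat) {
    data.frame(species = sp,
               plot_id = sprintf("%s%04d", sp, seq_len(max(n_seed, n_mat))),
               has_seedling = seq_len(max(n_seed, n_mat)) <= n_seed,
               has_mature = seq_len(max(n_seed, n_mat)) <= n_mat)
  }
  dom <- rbind(mk("KEEP", 25, 25), mk("FEWSEED", 99, 500),
               mk("FEWMAT", 500, 24), mk("BANNED", 500, 500))

  f25 <- filter_species(dom, 25, exclude = "BANNED")
  expect_true(f25$retained[f25$species == "KEEP"])
  expect_true(f25$retained[f25$species == "FEWSEED"])
  expect_false(f25$retained[f25$species == "FEWMAT"])
  expect_equal(f25$reason[f25$species == "BANNED"], "excluded-by-config")

  f100 <- filter_species(dom, 100)
  expect_false(f100$retained[f100$species == "FEWSEED"])  # 99 < 100
  expect_equal(f100$reason[f100$species == "FEWSEED"], "too-few-seedling-plots")
  expect_true(f100$retained[f100$species == "BANNED"])    # no exclusion here
})

test_that("a species with no measured stems raises an insufficient-data error", {
  plots <- toy_plots(2)
  tally <- toy_tally("T01", "AA", NA)  # seedlings only
  expect_error(estimate_diameter_cutoff(tally, plots, "AA"), "no measured stems")
})
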