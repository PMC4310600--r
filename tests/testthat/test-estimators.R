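test_that("domain means match hand arithmetic", {
  plots <- toy_plots(2, weight = c(1, 1), mat = c(4, 6))
  expect_equal(domain_mean(plots, c("T01", "T02"), "mat")$mean, 5.0)

  plots <- toy_plots(2, weight = c(24, 26.6), mat = c(4, 6))
  expect_equal(domain_mean(plots, c("T01", "T02"), "mat")$mean,
               (24 * 4 + 26.6 * 6) / (24 + 26.6), tolerance = 1e-15)

  # full-domain case: any weights give the overall weighted mean
  w <- c(3, 1, 7, 2, 5, 4)
  plots <- toy_plots(6, weight = w)
  expect_equal(domain_mean(plots, rep(TRUE, 6), "mat")$mean,
               sum(w * plots$mat_c) / sum(w), tolerance = 1e-15)
})

test_that("degenerate differences are exactly zero with zero variance", {
  plots <- toy_plots(6)
  mem <- c("T01", "T03", "T05")
  same <- diff_estimate(plots, mem, mem, "mat")
  expect_identical(same$diff, 0)
  expect_identical(same$se, 0)

  const <- toy_plots(6, mat = rep(7.3, 6))
  est <- diff_estimate(const, c("T01", "T02"), c("T03", "T04"), "mat")
  expect_equal(est$diff, 0, tolerance = 1e-15)
  expect_equal(est$se, 0, tolerance = 1e-15)
})

test_that("six-plot difference matches brute force and jackknife", {
  w <- c(24, 24, 26.6, 26.6, 24, 26.6)
  y <- c(3.2, 8.1, 5.5, 11.0, 6.4, 9.7)
  plots <- toy_plots(6, weight = w, mat = y)
  zs <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  zt <- c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  est <- diff_estimate(plots, zs, zt, "mat")

  # brute-force ratio estimators
  oracle_diff <- oracle_ratio_mean(y, w, zs) - oracle_ratio_mean(y, w, zt)
  expect_equal(est$diff, oracle_diff, tolerance = 1e-14)

  # brute-force influence values and the with-replacement variance
  Rs <- oracle_ratio_mean(y, w, zs); Rt <- oracle_ratio_mean(y, w, zt)
  u <- w * (zs * (y - Rs) / sum(w * zs) - zt * (y - Rt) / sum(w * zt))
  expect_equal(unname(est$influence), u, tolerance = 1e-14)
  expect_equal(est$se, sqrt(6 / 5 * sum(u^2)), tolerance = 1e-14)

  # delete-one-plot jackknife as an independent variance oracle
  theta <- vapply(1:6, function(i) {
    oracle_ratio_mean(y[-i], w[-i], zs[-i]) -
      oracle_ratio_mean(y[-i], w[-i], zt[-i])
  }, numeric(1))
  se_jack <- sqrt(5 / 6 * sum((theta - mean(theta))^2))
  expect_lt(abs(est$se - se_jack) / se_jack, 0.25)
})

test_that("estimates are location-equivariant and weight-scale invariant", {
  set.seed(21)
  plots <- toy_plots(8, weight = runif(8, 10, 30), mat = rnorm(8, 8, 3))
  zs <- sample(c(TRUE, FALSE), 8, replace = TRUE, prob = c(0.6, 0.4))
  zt <- sample(c(TRUE, FALSE), 8, replace = TRUE, prob = c(0.6, 0.4))
  zs[1] <- TRUE; zt[2] <- TRUE
  base <- diff_estimate(plots, zs, zt, "mat")

  shifted <- plots; shifted$mat_c <- shifted$mat_c + 4.2
  s <- diff_estimate(shifted, zs, zt, "mat")
  expect_equal(s$diff, base$diff, tolerance = 1e-12)
  expect_equal(s$se, base$se, tolerance = 1e-12)

  scaled <- plots; scaled$weight <- scaled$weight * 1234
  sc <- diff_estimate(scaled, zs, zt, "mat")
  expect_equal(sc$diff, base$diff, tolerance = 1e-12)
  expect_equal(sc$se, base$se, tolerance = 1e-12)
})

test_that("plots with a missing attribute value are dropped for that attribute only", {
  plots <- toy_plots(6)
  plots$tmin_c[3] <- NA
  est_mat <- diff_estimate(plots, c("T01", "T03"), c("T02", "T04"), "mat")
  est_tmin <- diff_estimate(plots, c("T01", "T03"), c("T02", "T04"), "tmin")
  expect_equal(length(est_mat$influence), 6L)
  expect_equal(length(est_tmin$influence), 5L)
  expect_equal(est_tmin$n_seedling_plots, 1L)  # T03 unusable for tmin
})

test_that("percentile shifts follow the quantile convention and equivariance", {
  n <- 200
  plots <- toy_plots(n, weight = rep(1, n), mat = rep(1:100, 2))
  seed_mem <- plots$plot_id[1:100]    # mat values 1..100
  mat_mem <- plots$plot_id[101:200]   # identical distribution
  ps <- percentile_shift(plots, seed_mem, mat_mem, "mat", p = c(0.05, 0.95),
                         n_boot = 200, seed = 9, min_plots = 50)
  expect_equal(ps$q_seedling[ps$p == 0.05], 5)
  expect_equal(ps$q_mature[ps$p == 0.95], 95)
  expect_equal(ps$diff, c(0, 0))
  expect_true(all(ps$ci_low <= 0 & ps$ci_high >= 0))

  # shifting every seedling-domain plot by +1 shifts its quantile by +1
  plots2 <- plots
  plots2$mat_c[1:100] <- plots2$mat_c[1:100] + 1
  ps2 <- percentile_shift(plots2, seed_mem, mat_mem, "mat", p = 0.05,
                          n_boot = 50, seed = 9, min_plots = 50)
  expect_equal(ps2$q_seedling, ps$q_seedling[ps$p == 0.05] + 1)
  expect_equal(ps2$q_mature, ps$q_mature[ps$p == 0.05])

  expect_error(percentile_shift(plots, seed_mem, mat_mem, "mat",
                                n_boot = 1), "n_boot")
  expect_error(percentile_shift(plots, seed_mem[1:10], mat_mem, "mat",
                                n_boot = 10, min_plots = 100),
               "insufficient data")
})

test_that("empty domains and tiny universes raise errors", {
  plots <- toy_plots(4)
  expect_error(diff_estimate(plots, character(0), c("T01"), "mat"),
               "seedling domain")
  expect_error(diff_estimate(plots, c("T01"), character(0), "mat"),
               "mature-tree domain")
  one <- toy_plots(1)
  expect_error(diff_estimate(one, "T01", "T01", "mat"), "fewer than 2")
})
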