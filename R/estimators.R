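# Design-based domain estimation.
#
# For a domain d (plots holding a species' seedlings, or its mature trees)
# and a plot attribute y (temperature, elevation, latitude), the domain mean
# is the ratio estimator R_d = sum(w z y) / sum(w z) over forested plots,
# with z the 0/1 domain indicator and w the design weight.  The seedling
# minus tree difference R_s - R_t is linearized through the per-plot
# influence values
#     u_i = w_i * [ z_si (y_i - R_s) / Nhat_s  -  z_ti (y_i - R_t) / Nhat_t ],
# Nhat_d = sum(w z_d), and its variance approximated by the with-replacement
# form  n/(n-1) * sum(u_i^2)  over the n plots of the analysis universe
# (sum(u_i) = 0 identically, so this is the usual centered sum of squares).
# Because both indicators live on the same plots, the covariance between the
# two domain means is carried entirely by u; no independence is assumed.

Z_975 <- 1.959964  # normal 97.5% quantile used for all 95% intervals

# restrict to the analysis universe for an attribute: forested plots with a
# weight and a non-missing attribute value
.analysis_frame <- function(plots, attribute) {
  col <- attribute_column(attribute)
  if (!col %in% names(plots))
    stop("plot table has no column '", col, "' for attribute '", attribute, "'")
  if (!"weight" %in% names(plots) || anyNA(plots$weight))
    stop("plots must carry design weights; see assign_weights()")
  keep <- plots$forested & !is.na(plots[[col]])
  list(plot_id = as.character(plots$plot_id[keep]),
       stratum = as.character(plots$stratum[keep]),
       y = as.numeric(plots[[col]][keep]),
       w = as.numeric(plots$weight[keep]),
       n_dropped_missing = sum(plots$forested) - sum(keep))
}

# coerce a membership specification (plot_id vector, or logical over the full
# plot table) to a logical vector over the analysis universe
.membership_on <- function(universe_ids, member, plots) {
  if (is.logical(member)) {
    if (length(member) != length(plots$plot_id))
      stop("logical membership must have one entry per plot-table row")
    universe_ids %in% as.character(plots$plot_id)[member]
  } else {
    universe_ids %in% as.character(member)
  }
}

# shared linearization kernel; either indicator may be all-FALSE for the
# single-domain (mean) case
.ratio_diff <- function(y, w, zs, zt, stratum = NULL, stratified_var = FALSE) {
  n <- length(y)
  if (n < 2L) stop("variance undefined with fewer than 2 analysis plots")
  Rs <- 0; Ns <- 0; Rt <- 0; Nt <- 0
  us <- numeric(n); ut <- numeric(n)
  if (any(zs)) {
    Ns <- sum(w[zs])
    Rs <- sum(w[zs] * y[zs]) / Ns
    us[zs] <- w[zs] * (y[zs] - Rs) / Ns
  }
  if (any(zt)) {
    Nt <- sum(w[zt])
    Rt <- sum(w[zt] * y[zt]) / Nt
    ut[zt] <- w[zt] * (y[zt] - Rt) / Nt
  }
  u <- us - ut
  if (stratified_var) {
    v <- 0
    for (h in unique(stratum)) {
      uh <- u[stratum == h]
      nh <- length(uh)
      if (nh >= 2L) v <- v + nh / (nh - 1) * sum((uh - mean(uh))^2)
    }
  } else {
    v <- n / (n - 1) * sum(u * u)
  }
  list(Rs = Rs, Rt = Rt, diff = Rs - Rt, var = v, u = u, n = n)
}

#' Weighted domain mean of a plot attribute
#'
#' Ratio estimator of the mean attribute value over the plots of one domain,
#' with a Taylor-linearized standard error.
#'
#' @param plots plot table with design weights.
#' @param member domain membership: either a vector of `plot_id`s or a
#'   logical vector over the rows of `plots`.
#' @param attribute one of `"mat"`, `"tmin"`, `"tmax"`, `"elevation"`,
#'   `"latitude"`.
#' @return list of class `domain_estimate`: `mean`, `se`, `n_plots`,
#'   `attribute`.
#' @export
domain_mean <- function(plots, member, attribute) {
  af <- .analysis_frame(plots, attribute)
  z <- .membership_on(af$plot_id, member, plots)
  if (!any(z)) stop("insufficient data: empty domain for attribute ", attribute)
  res <- .ratio_diff(af$y, af$w, zs = z, zt = rep(FALSE, length(z)))
  structure(list(mean = res$Rs, se = sqrt(res$var), n_plots = sum(z),
                 attribute = attribute),
            class = "domain_estimate")
}

#' Seedling-minus-tree difference of domain means
#'
#' Difference between the seedling-domain and mature-tree-domain ratio
#' estimators of a plot attribute, with Taylor-linearized variance and a 95%
#' normal confidence interval.  The per-plot influence values are retained so
#' that the covariance between species estimated from the same plots can be
#' reconstructed (see [cross_species_covariance()]).
#'
#' @inheritParams domain_mean
#' @param seedling_member,mature_member domain memberships (plot_id vectors
#'   or logicals over `plots` rows).
#' @param species optional species code carried into the result.
#' @param stratified_var if `TRUE`, sum within-stratum centered
#'   sums of squares instead of pooling all plots (default `FALSE`).
#' @return object of class `shift_estimate`: `species`, `attribute`, `diff`,
#'   `se`, `ci_low`, `ci_high`, `n_seedling_plots`, `n_mature_plots`,
#'   `mean_seedling`, `mean_mature`, and the named `influence` vector over
#'   the analysis universe.
#' @export
diff_estimate <- function(plots, seedling_member, mature_member, attribute,
                          species = NA_character_, stratified_var = FALSE) {
  af <- .analysis_frame(plots, attribute)
  zs <- .membership_on(af$plot_id, seedling_member, plots)
  zt <- .membership_on(af$plot_id, mature_member, plots)
  if (!any(zs)) stop("insufficient data: empty seedling domain (", species,
                     ", ", attribute, ")")
  if (!any(zt)) stop("insufficient data: empty mature-tree domain (", species,
                     ", ", attribute, ")")
  res <- .ratio_diff(af$y, af$w, zs, zt, stratum = af$stratum,
                     stratified_var = stratified_var)
  se <- sqrt(res$var)
  structure(list(species = species, attribute = attribute,
                 diff = res$diff, se = se,
                 ci_low = res$diff - Z_975 * se,
                 ci_high = res$diff + Z_975 * se,
                 n_seedling_plots = sum(zs), n_mature_plots = sum(zt),
                 mean_seedling = res$Rs, mean_mature = res$Rt,
                 influence = stats::setNames(res$u, af$plot_id)),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf(
    "shift_estimate: %s %s\n  seedling - tree diff = %.4f (se %.4f, 95%% CI %.4f to %.4f)\n  plots: %d seedling, %d mature\n",
    x$species, x$attribute, x$diff, x$se, x$ci_low, x$ci_high,
    x$n_seedling_plots, x$n_mature_plots))
  invisible(x)
}

#' Difference of domain quantiles with bootstrap confidence intervals
#'
#' Estimates the `p`-th quantile (inverse of the weighted empirical
#' distribution function; see [weighted_quantile()]) of a plot attribute over
#' the seedling domain and over the mature-tree domain, their difference, and
#' a percentile-method bootstrap confidence interval.  Bootstrap resamples
#' draw whole plots with replacement within each stratum, keeping both domain
#' memberships attached, which preserves the seedling/tree dependence.
#'
#' @inheritParams diff_estimate
#' @param p quantile levels in (0, 1); default the 5th and 95th percentiles.
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param min_plots minimum plots required in each domain (default 100,
#'   mirroring the stricter filter used for range extremes).
#' @param conf confidence level for the percentile interval.
#' @return data.frame of class `percentile_shift`, one row per `p`:
#'   `species`, `attribute`, `p`, `q_seedling`, `q_mature`, `diff`,
#'   `ci_low`, `ci_high`, `n_seedling_plots`, `n_mature_plots`, `n_boot`.
#' @export
percentile_shift <- function(plots, seedling_member, mature_member, attribute,
                             p = c(0.05, 0.95), n_boot = 2000, seed = 1,
                             species = NA_character_, min_plots = 100,
                             conf = 0.95) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  af <- .analysis_frame(plots, attribute)
  zs <- .membership_on(af$plot_id, seedling_member, plots)
  zt <- .membership_on(af$plot_id, mature_member, plots)
  if (sum(zs) < min_plots || sum(zt) < min_plots)
    stop(sprintf(
      "insufficient data: %d seedling / %d mature plots, need %d in each (%s)",
      sum(zs), sum(zt), min_plots, species))

  qs <- .wq(af$y[zs], af$w[zs], p)
  qt <- .wq(af$y[zt], af$w[zt], p)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  strata <- split(seq_along(af$y), af$stratum)
  boots <- matrix(NA_real_, nrow = n_boot, ncol = length(p))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(strata, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    bs <- zs[idx]; bt <- zt[idx]
    if (!any(bs) || !any(bt)) next  # degenerate resample; row stays NA
    boots[b, ] <- .wq(af$y[idx][bs], af$w[idx][bs], p) -
      .wq(af$y[idx][bt], af$w[idx][bt], p)
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(boots, 2, function(col) {
    col <- col[!is.na(col)]
    .wq(col, rep.int(1, length(col)), c(alpha, 1 - alpha))
  }))
  out <- data.frame(species = species, attribute = attribute, p = p,
                    q_seedling = qs, q_mature = qt, diff = qs - qt,
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    n_seedling_plots = sum(zs), n_mature_plots = sum(zt),
                    n_boot = n_boot, row.names = NULL)
  class(out) <- c("percentile_shift", "data.frame")
  out
}

#' Collect shift estimates into a tidy table
#'
#' @param shifts list of `shift_estimate` objects.
#' @return data.frame with one row per estimate (influence vectors dropped).
#' @export
shifts_table <- function(shifts) {
  shifts <- unname(shifts)
  do.call(rbind, lapply(shifts, function(s)
    data.frame(species = s$species, attribute = s$attribute, diff = s$diff,
               se = s$se, ci_low = s$ci_low, ci_high = s$ci_high,
               n_seedling_plots = s$n_seedling_plots,
               n_mature_plots = s$n_mature_plots,
               mean_seedling = s$mean_seedling, mean_mature = s$mean_mature,
               row.names = NULL)))
}
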