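# Combining correlated per-species differences.
#
# Per-species seedling-minus-tree differences are estimated from the same
# probability sample of plots, so they are correlated.  The cross-species
# covariance is rebuilt from the stored per-plot influence values,
#   Sigma[j, k] = n/(n-1) * sum_i u_i^(j) u_i^(k),
# which by construction has each species' linearized variance on the
# diagonal.  The overall (or group) mean difference is the generalized least
# squares mean weighted by the inverse covariance matrix:
#   mean = (1' Sigma^-1 d) / (1' Sigma^-1 1),  se = (1' Sigma^-1 1)^(-1/2).

#' Cross-species covariance of shift estimates
#'
#' @param shifts list of [diff_estimate()] results sharing one attribute and
#'   one plot universe (identical influence-vector names).
#' @return symmetric covariance matrix with species codes as dimnames.
#' @export
cross_species_covariance <- function(shifts) {
  if (length(shifts) < 2L) stop("need at least 2 species to form a covariance")
  attrs <- unique(vapply(shifts, function(s) s$attribute, character(1)))
  if (length(attrs) != 1L)
    stop("shifts mix attributes: ", paste(attrs, collapse = ", "))
  ids <- lapply(shifts, function(s) names(s$influence))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("shifts were computed over different plot universes; cannot align")
  U <- vapply(shifts, function(s) unname(s$influence),
              numeric(length(ids[[1]])))
  n <- nrow(U)
  Sigma <- n / (n - 1) * crossprod(U)
  sp <- vapply(shifts, function(s) s$species, character(1))
  dimnames(Sigma) <- list(sp, sp)
  Sigma
}

# condition number of a symmetric matrix; Inf if not positive definite
.sym_condition <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  max(ev) / min(ev)
}

# shrink toward the diagonal until the condition number is acceptable
.regularize <- function(S, cond_max = 1e8, lambda_grid = seq(0, 1, by = 0.05)) {
  D <- diag(diag(S), nrow = nrow(S))
  for (lambda in lambda_grid) {
    S_l <- (1 - lambda) * S + lambda * D
    cond <- .sym_condition(S_l)
    if (is.finite(cond) && cond < cond_max)
      return(list(S = S_l, lambda = lambda, condition_number = cond))
  }
  stop(sprintf(
    "covariance matrix singular even after diagonal shrinkage (condition %.3g)",
    .sym_condition(D)))
}

# GLS mean via Cholesky solves (no explicit inverse)
.gls_mean <- function(d, S) {
  R <- chol(S)
  ones <- rep.int(1, length(d))
  x1 <- backsolve(R, forwardsolve(t(R), ones))
  xd <- backsolve(R, forwardsolve(t(R), d))
  denom <- sum(x1)
  list(mean = sum(xd) / denom, se = 1 / sqrt(denom))
}

#' Combine per-species shifts into overall and group means
#'
#' Generalized least squares combination of correlated per-species
#' differences, weighted by the inverse of the estimated cross-species
#' covariance matrix.  With a diagonal covariance this reduces to the
#' classical fixed-effect inverse-variance-weighted mean.  Near-singular
#' covariances are shrunk toward their diagonal, `(1-lambda) Sigma + lambda
#' diag(Sigma)`, taking the smallest `lambda` on a 0.05 grid that brings the
#' condition number under `cond_max`; the `lambda` used is reported.
#'
#' @param shifts list of [diff_estimate()] results (one attribute).
#' @param covariance optional covariance matrix; computed from the influence
#'   vectors when `NULL`.
#' @param groups optional named character vector, species code -> group label
#'   (e.g. `"angiosperm"`/`"gymnosperm"`); an `"all"` group over every
#'   species is always included.  Groups with fewer than 2 member species are
#'   dropped with a warning.
#' @param cond_max condition-number ceiling triggering shrinkage.
#' @return data.frame of class `combined_estimate`: `group`, `attribute`,
#'   `mean_diff`, `se`, `ci_low`, `ci_high`, `n_species`, `lambda`,
#'   `condition_number`.
#' @export
combine_shifts <- function(shifts, covariance = NULL, groups = NULL,
                           cond_max = 1e8) {
  sp <- vapply(shifts, function(s) s$species, character(1))
  if (anyDuplicated(sp)) stop("duplicate species in shifts")
  d <- vapply(shifts, function(s) s$diff, numeric(1))
  names(d) <- sp
  attribute <- unique(vapply(shifts, function(s) s$attribute, character(1)))
  if (length(attribute) != 1L) stop("shifts mix attributes")
  if (is.null(covariance)) covariance <- cross_species_covariance(shifts)
  if (!all(sp %in% rownames(covariance)))
    stop("covariance matrix does not cover all species")

  group_members <- list(all = sp)
  if (!is.null(groups)) {
    for (g in unique(unname(groups[sp[sp %in% names(groups)]]))) {
      members <- sp[sp %in% names(groups)[groups == g]]
      if (length(members) < 2L) {
        warning("group '", g, "' has fewer than 2 species; skipped")
        next
      }
      group_members[[g]] <- members
    }
  }

  rows <- lapply(names(group_members), function(g) {
    members <- group_members[[g]]
    reg <- .regularize(covariance[members, members, drop = FALSE],
                       cond_max = cond_max)
    fit <- .gls_mean(d[members], reg$S)
    data.frame(group = g, attribute = attribute, mean_diff = fit$mean,
               se = fit$se,
               ci_low = fit$mean - Z_975 * fit$se,
               ci_high = fit$mean + Z_975 * fit$se,
               n_species = length(members), lambda = reg$lambda,
               condition_number = reg$condition_number, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("combined_estimate", "data.frame")
  out
}

#' Joint-bootstrap cross-species covariance
#'
#' Sensitivity alternative to the linearized covariance: resamples whole
#' plots with replacement within stratum, recomputes every species'
#' seedling-minus-tree difference per resample, and returns the empirical
#' covariance of the resampled difference vectors.
#'
#' @param plots plot table with weights.
#' @param domains membership table from [assign_domains()].
#' @param species species codes to include.
#' @param attribute analysis attribute.
#' @param n_boot number of resamples.
#' @param seed integer seed (global RNG state restored on exit).
#' @return covariance matrix with species codes as dimnames.
#' @export
bootstrap_cross_species_covariance <- function(plots, domains, species,
                                               attribute, n_boot = 500,
                                               seed = 1) {
  af <- .analysis_frame(plots, attribute)
  zs <- vapply(species, function(sp)
    af$plot_id %in% domains$plot_id[domains$species == sp & domains$has_seedling],
    logical(length(af$plot_id)))
  zt <- vapply(species, function(sp)
    af$plot_id %in% domains$plot_id[domains$species == sp & domains$has_mature],
    logical(length(af$plot_id)))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  strata <- split(seq_along(af$y), af$stratum)
  D <- matrix(NA_real_, nrow = n_boot, ncol = length(species))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(strata, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    y <- af$y[idx]; w <- af$w[idx]
    D[b, ] <- vapply(seq_along(species), function(j) {
      s <- zs[idx, j]; t <- zt[idx, j]
      if (!any(s) || !any(t)) return(NA_real_)
      sum(w[s] * y[s]) / sum(w[s]) - sum(w[t] * y[t]) / sum(w[t])
    }, numeric(1))
  }
  Sigma <- stats::cov(D, use = "complete.obs")
  dimnames(Sigma) <- list(species, species)
  Sigma
}
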