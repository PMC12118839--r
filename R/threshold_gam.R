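#' Configuration for the Bayesian threshold model
#'
#' Sampler and prior settings for [fit_threshold_model()]. Defaults follow
#' common practice for conjugate Gibbs samplers on small ecological
#' datasets: diffuse normal priors on fixed effects and half-Cauchy priors
#' on standard deviations (implemented by inverse-gamma parameter expansion,
#' which keeps every update conjugate).
#'
#' @param n_knots Interior spline knots for the cover smooth (default 5).
#' @param chains Number of MCMC chains (default 3).
#' @param iterations Iterations per chain including burn-in (default 20000).
#' @param burn_in Discarded iterations per chain (default 5000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 5).
#' @param seed Integer seed; mandatory, recorded in the fit.
#' @param prior_fixed_var Prior variance of fixed effects (default 1e6).
#' @param prior_sd_scale Half-Cauchy scale for standard deviations
#'   (default 25).
#' @return A `gam_config` list.
#' @export
gam_config <- function(n_knots = 5, chains = 3, iterations = 20000,
                       burn_in = 5000, thin = 5, seed,
                       prior_fixed_var = 1e6, prior_sd_scale = 25) {
  if (missing(seed) || is.null(seed))
    stop("gam_config: a seed is mandatory", call. = FALSE)
  stopifnot(iterations > burn_in, n_knots >= 3, chains >= 1, thin >= 1,
            prior_fixed_var > 0, prior_sd_scale > 0)
  structure(list(n_knots = n_knots, chains = chains,
                 iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), prior_fixed_var = prior_fixed_var,
                 prior_sd_scale = prior_sd_scale),
            class = "gam_config")
}

# split-chain potential scale reduction factor (rank-normalization omitted;
# plain split-Rhat is adequate for these conjugate chains)
split_rhat <- function(draws, chain_id) {
  halves <- lapply(split(seq_along(chain_id), chain_id), function(idx) {
    h <- length(idx) %/% 2
    list(idx[seq_len(h)], idx[h + seq_len(h)])
  })
  groups <- unlist(halves, recursive = FALSE)
  m <- length(groups)
  n <- min(lengths(groups))
  if (n < 2) return(NA_real_)
  means <- vapply(groups, function(g) mean(draws[g[seq_len(n)]]), numeric(1))
  vars <- vapply(groups, function(g) stats::var(draws[g[seq_len(n)]]),
                 numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Bayesian additive mixed model for net production vs coral cover
#'
#' Gaussian additive mixed model for transect net carbonate production:
#' an O'Sullivan spline smooth of live coral cover, a categorical fixed
#' effect of depth, and a normal random intercept per site, fitted by a
#' blocked conjugate Gibbs sampler. All coefficients (fixed, spline, site)
#' are updated jointly from their multivariate-normal full conditional;
#' the residual, spline-penalty, and site variances get inverse-gamma
#' updates under half-Cauchy priors via parameter expansion. Convergence is
#' judged by split-chain scale reduction (all below 1.1).
#'
#' @param data Data frame with columns `net` (kg CaCO3 m-2 y-1), `lcc`
#'   (percent live coral cover, 0-100), `depth` (coded categorical), `site`
#'   (at least 2 levels).
#' @param config A [gam_config()].
#' @param cover_range Interval the cover smooth lives on (default
#'   `c(0, 100)` so curves can be evaluated over the full percent range).
#' @return A `gam_fit` object: posterior `draws` (matrix; columns named),
#'   `chain_id`, the `basis`, factor level metadata, `rhat` per parameter,
#'   `converged` flag, and the `config`.
#' @export
fit_threshold_model <- function(data, config, cover_range = c(0, 100)) {
  stopifnot(inherits(config, "gam_config"),
            all(c("net", "lcc", "depth", "site") %in% names(data)))
  data$depth <- factor(data$depth)
  data$site <- factor(data$site)
  if (nlevels(data$site) < 2)
    stop("fit_threshold_model: need at least 2 sites", call. = FALSE)
  y <- data$net
  n <- length(y)

  basis <- osullivan_basis(data$lcc, n_knots = config$n_knots,
                           boundary = cover_range)
  # fixed part: intercept + linear cover (spline null space) + depth effects
  Xd <- if (nlevels(data$depth) > 1)
    stats::model.matrix(~depth, data)[, -1, drop = FALSE]
  else matrix(0, n, 0)
  X <- cbind(`(Intercept)` = 1, lcc = data$lcc, Xd)
  Zs <- basis$Z
  colnames(Zs) <- paste0("spl", seq_len(ncol(Zs)))
  Za <- stats::model.matrix(~site - 1, data)
  C <- cbind(X, Zs, Za)
  p <- ncol(X); q <- ncol(Zs); s <- ncol(Za)
  CtC <- crossprod(C)
  Cty <- crossprod(C, y)
  A2 <- config$prior_sd_scale^2

  keep_per_chain <- (config$iterations - config$burn_in) %/% config$thin
  draws <- matrix(NA_real_, keep_per_chain * config$chains,
                  p + q + s + 3,
                  dimnames = list(NULL, c(colnames(C), "sigma2_e",
                                          "sigma2_u", "sigma2_a")))
  chain_id <- rep(seq_len(config$chains), each = keep_per_chain)

  set.seed(config$seed)
  row_at <- 0L
  for (ch in seq_len(config$chains)) {
    # dispersed but deterministic initial values
    sig2e <- stats::var(y) * stats::runif(1, 0.5, 2)
    sig2u <- stats::runif(1, 0.1, 10)
    sig2a <- stats::runif(1, 0.1, 10)
    nu_e <- nu_u <- nu_a <- 1
    for (it in seq_len(config$iterations)) {
      prior_prec <- c(rep(1 / config$prior_fixed_var, p),
                      rep(1 / sig2u, q), rep(1 / sig2a, s))
      Q <- CtC / sig2e + diag(prior_prec, p + q + s)
      L <- chol(Q)
      mu <- backsolve(L, forwardsolve(t(L), Cty / sig2e))
      theta <- mu + backsolve(L, stats::rnorm(p + q + s))
      resid <- y - as.numeric(C %*% theta)

      # half-Cauchy(0, A) via sigma2 | nu ~ IG(1/2, 1/nu), nu ~ IG(1/2, 1/A^2)
      sig2e <- 1 / stats::rgamma(1, (n + 1) / 2,
                                 1 / nu_e + sum(resid^2) / 2)
      nu_e <- 1 / stats::rgamma(1, 1, 1 / A2 + 1 / sig2e)
      u <- theta[p + seq_len(q)]
      sig2u <- 1 / stats::rgamma(1, (q + 1) / 2, 1 / nu_u + sum(u^2) / 2)
      nu_u <- 1 / stats::rgamma(1, 1, 1 / A2 + 1 / sig2u)
      a <- theta[p + q + seq_len(s)]
      sig2a <- 1 / stats::rgamma(1, (s + 1) / 2, 1 / nu_a + sum(a^2) / 2)
      nu_a <- 1 / stats::rgamma(1, 1, 1 / A2 + 1 / sig2a)

      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0) {
        row_at <- row_at + 1L
        draws[row_at, ] <- c(theta, sig2e, sig2u, sig2a)
      }
    }
  }

  rhat <- apply(draws, 2, split_rhat, chain_id = chain_id)
  converged <- all(rhat < 1.1, na.rm = TRUE)
  if (!converged)
    warning("fit_threshold_model: split-Rhat >= 1.1 for ",
            paste(names(rhat)[which(rhat >= 1.1)], collapse = ", "),
            "; thresholds from this fit are unreliable", call. = FALSE)
  structure(
    list(draws = draws, chain_id = chain_id, basis = basis,
         p_fixed = p, q_spline = q, n_sites = s,
         depth_levels = levels(data$depth), site_levels = levels(data$site),
         rhat = rhat, converged = converged, config = config, n_obs = n),
    class = "gam_fit"
  )
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("<gam_fit> Bayesian additive mixed model\n")
  cat(sprintf("  n = %d; %d chains x %d draws kept; seed %d\n", x$n_obs,
              x$config$chains, nrow(x$draws) / x$config$chains,
              x$config$seed))
  cat(sprintf("  max split-Rhat = %.3f (%s)\n", max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# posterior curve matrix (grid x draws) for one depth, site effect at 0
curve_draws <- function(fit, depth, grid, chunk = 1000L) {
  depth <- as.character(depth)
  if (!depth %in% fit$depth_levels)
    stop("depth '", depth, "' not among fitted depth levels", call. = FALSE)
  ndw <- nrow(fit$draws)
  Xg <- cbind(1, grid)
  if (length(fit$depth_levels) > 1) {
    dd <- matrix(0, length(grid), length(fit$depth_levels) - 1)
    j <- match(depth, fit$depth_levels) - 1
    if (j >= 1) dd[, j] <- 1
    Xg <- cbind(Xg, dd)
  }
  Cg <- cbind(Xg, osullivan_predict(fit$basis, grid))
  coefs <- t(fit$draws[, seq_len(fit$p_fixed + fit$q_spline), drop = FALSE])
  out <- matrix(NA_real_, length(grid), ndw)
  for (st in seq(1, ndw, by = chunk)) {
    en <- min(st + chunk - 1, ndw)
    out[, st:en] <- Cg %*% coefs[, st:en, drop = FALSE]
  }
  out
}

# first negative -> positive crossing of one curve; linearly interpolated.
# all-positive curves are censored at the lower boundary, all-negative at
# the upper one.
first_crossing <- function(eta, grid) {
  neg <- eta < 0
  if (!any(neg)) return(grid[1])
  k <- length(eta)
  idx <- which(neg[-k] & !neg[-1])
  if (length(idx) == 0) return(grid[k])
  i <- idx[1]
  grid[i] + (grid[i + 1] - grid[i]) * eta[i] / (eta[i] - eta[i + 1])
}

#' Live-coral-cover threshold for positive net production
#'
#' For one depth, evaluates every posterior draw of the fitted
#' net-production curve (site effect at its population mean of zero) on a
#' fine cover grid and finds the smallest cover at which the curve crosses
#' from negative to positive. The point estimate is the crossing of the
#' posterior-mean curve; the credible interval comes from the 2.5 and 97.5
#' percentiles of the per-draw crossings. Draws whose curve never crosses
#' are censored at the grid boundary (0 when everywhere positive, 100 when
#' everywhere negative).
#'
#' @param fit A converged `gam_fit` (non-converged fits give a warning).
#' @param depth_m One of the fitted depth levels.
#' @param grid_step Cover grid resolution in percent (default 0.01; the
#'   crossing is interpolated within grid cells, so coarser grids remain
#'   accurate for smooth curves).
#' @return A `threshold_estimate` tibble row: `depth_m`, `threshold_lcc`,
#'   `ci_lower`, `ci_upper` (percent), `censored` (share of censored
#'   draws).
#' @export
coral_cover_threshold <- function(fit, depth_m, grid_step = 0.01) {
  stopifnot(inherits(fit, "gam_fit"))
  if (!fit$converged)
    warning("coral_cover_threshold: fit not converged; estimate unreliable",
            call. = FALSE)
  grid <- seq(fit$basis$boundary[1], fit$basis$boundary[2], by = grid_step)
  eta <- curve_draws(fit, depth_m, grid)
  th_draws <- apply(eta, 2, first_crossing, grid = grid)
  mean_curve <- rowMeans(eta)
  point <- first_crossing(mean_curve, grid)
  ci <- unname(stats::quantile(th_draws, c(0.025, 0.975)))
  tibble::tibble(
    depth_m = depth_m, threshold_lcc = point,
    ci_lower = ci[1], ci_upper = ci[2],
    censored = mean(th_draws %in% grid[c(1, length(grid))])
  )
}

#' Thresholds for every fitted depth
#'
#' Applies [coral_cover_threshold()] to each depth level of the fit and
#' appends the across-depth average threshold.
#'
#' @inheritParams coral_cover_threshold
#' @return Tibble with one row per depth plus an `"average"` row.
#' @export
coral_cover_thresholds <- function(fit, grid_step = 0.01) {
  rows <- dplyr::bind_rows(lapply(fit$depth_levels, function(d)
    coral_cover_threshold(fit, d, grid_step)))
  avg <- tibble::tibble(
    depth_m = "average", threshold_lcc = mean(rows$threshold_lcc),
    ci_lower = NA_real_, ci_upper = NA_real_, censored = NA_real_)
  rows$depth_m <- as.character(rows$depth_m)
  dplyr::bind_rows(rows, avg)
}
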