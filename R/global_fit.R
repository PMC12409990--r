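# Global fitting of multi-probe, multi-concentration unfolding data.
#
# The thermodynamic parameters (dG_i, m_i) are shared across every dataset;
# baselines are shared per probe across concentrations, replicates and
# directions. For fixed thermodynamic parameters the baselines enter the
# signal linearly, so they are profiled out exactly by per-probe linear least
# squares; the nonlinear search then runs over only the 2 (two-state) or 4
# (three-state) thermodynamic parameters, from Latin-hypercube multistarts.

fit_bounds <- function(model) {
  if (model == "two_state")
    list(lower = c(dG1 = 0, m1 = 1e-3), upper = c(dG1 = 15, m1 = 3))
  else
    list(lower = c(dG1 = 0, m1 = 1e-3, dG2 = 0, m2 = 1e-3),
         upper = c(dG1 = 15, m1 = 3, dG2 = 15, m2 = 3))
}

theta_to_params <- function(theta, model, temperature) {
  if (model == "two_state")
    thermo_params("two_state", dG = theta[1], m = theta[2],
                  temperature = temperature)
  else
    thermo_params("three_state", dG = c(theta[1], theta[3]),
                  m = c(theta[2], theta[4]), temperature = temperature)
}

# Profile baselines for fixed thermo params: per-probe linear least squares.
# Returns RSS and fitted baselines.
profile_baselines <- function(theta, model, data, temperature) {
  params <- theta_to_params(theta, model, temperature)
  rss <- 0
  baselines <- list()
  for (probe in unique(data$probe)) {
    d <- data[data$probe == probe, ]
    u <- d$urea_M
    if (model == "two_state") {
      fr <- fractions_two_state(params, u)
      X <- cbind(fr$fN, fr$fN * u, fr$fU, fr$fU * u)
      nm <- c("aN", "bN", "aU", "bU")
    } else {
      fr <- fractions_three_state(params, u)
      X <- cbind(fr$fN, fr$fN * u, fr$fU, fr$fU * u, fr$fI)
      nm <- c("aN", "bN", "aU", "bU", "cI")
    }
    fit <- stats::lm.fit(X, d$signal)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    rss <- rss + sum(fit$residuals^2)
    baselines[[probe]] <- as.list(stats::setNames(beta, nm))
  }
  list(rss = rss, baselines = baselines)
}

#' Globally fit equilibrium-unfolding datasets
#'
#' Fits all datasets simultaneously: thermodynamic parameters shared across
#' probes, concentrations and directions; linear baselines shared per probe.
#' The nonlinear objective (residual sum of squares with baselines profiled
#' out) is minimized by L-BFGS-B from `n_starts` Latin-hypercube starting
#' points within the bounds dG in [0, 15] kcal/mol, m in (0, 3] kcal/mol/M.
#'
#' @param data data.frame with columns `urea_M`, `signal`, `probe` (and
#'   optionally `conc_uM`, `replicate`, `direction`, which are pooled).
#' @param model `"two_state"` or `"three_state"`.
#' @param n_starts number of multistart points; default 25.
#' @param seed integer seed for the Latin-hypercube draw.
#' @param temperature Kelvin; default 298.15.
#' @return a `folding_fit_result`: fitted [thermo_params()] (`params`),
#'   `rss`, `aic`, `n_parameters`, `n_obs`, `converged`, standard errors
#'   (`se`, thermodynamic parameters only, from the Gauss-Newton curvature),
#'   and the per-start objective trace (`start_rss`).
#' @export
global_fit <- function(data, model = c("two_state", "three_state"),
                       n_starts = 25L, seed = 1L, temperature = 298.15) {
  model <- match.arg(model)
  stopifnot(all(c("urea_M", "signal", "probe") %in% names(data)),
            nrow(data) > 0)
  for (probe in unique(data$probe)) {
    n_p <- sum(data$probe == probe)
    if (n_p < 8) stop("probe '", probe, "' has fewer than 8 points")
  }
  if (max(data$urea_M) < 6)
    warning("urea range extends only to ", max(data$urea_M),
            " M; baselines may be poorly determined")
  bounds <- fit_bounds(model)
  p <- length(bounds$lower)
  objective <- function(theta)
    profile_baselines(theta, model, data, temperature)$rss

  starts <- with_seed(seed, lhs::randomLHS(n_starts, p))
  starts <- sweep(sweep(starts, 2, bounds$upper - bounds$lower, "*"),
                  2, bounds$lower, "+")
  best <- NULL
  start_rss <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    start_rss[s] <- if (is.null(fit)) NA_real_ else fit$value
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(structure(list(params = NULL, rss = NA_real_, aic = NA_real_,
                          converged = FALSE, se = NULL,
                          start_rss = start_rss),
                     class = "folding_fit_result"))
  polish <- tryCatch(
    stats::optim(best$par, objective, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = 2000, factr = 1e5)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  prof <- profile_baselines(best$par, model, data, temperature)
  params <- theta_to_params(best$par, model, temperature)
  params$baselines <- prof$baselines
  n_obs <- nrow(data)
  n_base <- length(prof$baselines) * (if (model == "two_state") 4L else 5L)
  k <- p + n_base
  rss <- prof$rss
  aic <- n_obs * log(rss / n_obs) + 2 * (k + 1)
  converged <- best$convergence == 0

  # Gauss-Newton standard errors for the thermodynamic parameters, from the
  # profiled objective's curvature: cov = 2 * sigma^2 * H^-1 with H the
  # numerical Hessian of the RSS.
  se <- rep(NA_real_, p)
  if (converged && n_obs > k) {
    sigma2 <- rss / (n_obs - k)
    H <- numeric_hessian(objective, best$par)
    cv <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) > 0)) se <- sqrt(diag(cv))
  }
  names(se) <- names(bounds$lower)
  structure(
    list(params = params, theta = stats::setNames(best$par, names(bounds$lower)),
         rss = rss, aic = aic, n_parameters = k, n_obs = n_obs,
         converged = converged, se = se, start_rss = start_rss,
         model = model, seed = seed),
    class = "folding_fit_result"
  )
}

numeric_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- rep(0, p); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei) - f(x + ej) + f0) / h^2
  }
  H
}

#' @export
print.folding_fit_result <- function(x, ...) {
  if (is.null(x$params)) {
    cat("<folding_fit_result> fit failed to converge\n")
    return(invisible(x))
  }
  cat(sprintf("<folding_fit_result> %s model, %d obs, RSS %.4g, AIC %.2f\n",
              x$model, x$n_obs, x$rss, x$aic))
  for (i in seq_along(x$params$dG))
    cat(sprintf("  transition %d: dG = %.3f kcal/mol, m = %.3f kcal/mol/M (Cm %.2f M)\n",
                i, x$params$dG[i], x$params$m[i],
                x$params$dG[i] / x$params$m[i]))
  invisible(x)
}

#' Test for protein-concentration dependence of unfolding curves
#'
#' Monomer folding models predict identical normalized curves at every
#' protein concentration. Per probe, replicate-averaged curves at each
#' concentration are min-max normalized; the statistic is the maximum over
#' urea points (all probes) of the across-concentration range of normalized
#' signal. Under concentration independence that maximum is pure noise, so
#' the threshold is the level-`alpha` family-wise bound for the largest of
#' all pairwise curve differences: `sqrt(2) * sd * qnorm(1 - alpha / (2 *
#' n_pairs * n_bins))`, with the per-point noise sd estimated by the
#' second-difference estimator on the normalized curves. Data are flagged
#' concentration-independent when the statistic stays below the threshold.
#'
#' @param data unfolding data.frame (needs >= 2 distinct `conc_uM`).
#' @param alpha family-wise false-alarm rate of the dependence call;
#'   default 0.01.
#' @return list with per-probe statistics, pooled noise sd, threshold and the
#'   logical flag `concentration_independent`.
#' @export
concentration_dependence_test <- function(data, alpha = 0.01) {
  concs <- sort(unique(data$conc_uM))
  if (length(concs) < 2) stop("need at least two distinct concentrations")
  probe_stats <- list()
  noise_sds <- c()
  n_bins <- 0L
  for (probe in unique(data$probe)) {
    d <- data[data$probe == probe, ]
    grid <- sort(unique(d$urea_M))
    n_bins <- n_bins + length(grid)
    curves <- sapply(concs, function(cc) {
      dc <- d[d$conc_uM == cc, ]
      y <- tapply(dc$signal, factor(dc$urea_M, levels = grid), mean)
      (y - min(y)) / (max(y) - min(y))
    })
    noise_sds <- c(noise_sds, apply(curves, 2, function(y)
      stats::sd(diff(y, differences = 2)) / sqrt(6)))
    probe_stats[[probe]] <- max(apply(curves, 1, function(r) diff(range(r))))
  }
  pooled_sd <- sqrt(mean(noise_sds^2))
  statistic <- max(unlist(probe_stats))
  n_pairs <- choose(length(concs), 2)
  threshold <- sqrt(2) * pooled_sd *
    stats::qnorm(1 - alpha / (2 * n_pairs * n_bins))
  list(per_probe = unlist(probe_stats), statistic = statistic,
       pooled_noise_sd = pooled_sd, threshold = threshold,
       concentration_independent = statistic < threshold)
}

#' Fit a single-exponential decay to a proteolysis time course
#'
#' Fits I(t) = A*exp(-k*t) + C by Levenberg-Marquardt least squares with
#' k constrained non-negative, as used for limited-proteolysis band
#' intensities.
#'
#' @param time time points (minutes, >= 0), at least 5.
#' @param intensity band intensities.
#' @return list with `k_app` (1/min), `amplitude`, `offset`, `rss`,
#'   `degenerate` (TRUE when the data do not decay and k is pinned at 0).
#' @export
fit_exponential <- function(time, intensity) {
  stopifnot(length(time) >= 5, length(intensity) == length(time),
            all(time >= 0))
  y <- intensity
  if (stats::sd(y) == 0 || stats::coef(stats::lm(y ~ time))[2] >= 0) {
    warning("time course does not decay; returning k_app = 0")
    return(list(k_app = 0, amplitude = 0, offset = mean(y), rss = sum((y - mean(y))^2),
                degenerate = TRUE))
  }
  C0 <- min(y) - 0.05 * diff(range(y))
  A0 <- y[which.min(time)] - C0
  pos <- y - C0 > 0
  k0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(y[pos] - C0) ~ time[pos]))[2]
    max(1e-4, -sl)
  }, error = function(e) 0.1)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-k * time) + C,
    start = list(A = A0, k = k0, C = max(C0, 0)),
    lower = c(A = -Inf, k = 0, C = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  list(k_app = unname(cf["k"]), amplitude = unname(cf["A"]),
       offset = unname(cf["C"]), rss = sum(stats::residuals(fit)^2),
       degenerate = FALSE)
}
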