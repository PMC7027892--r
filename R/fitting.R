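#' Generate a synthetic batch time course
#'
#' Evaluates the analytical batch solution of the chosen growth law on a
#' sampling schedule and applies independent multiplicative log-normal noise
#' to biomass and substrate. The log-normal sigma is chosen so the
#' coefficient of variation of the multiplicative factor equals `noise_cv`
#' (`sigma = sqrt(log(1 + noise_cv^2))`) with unit median, so `noise_cv = 0`
#' returns exactly the analytic trajectory. Deterministic given `seed`.
#'
#' @inheritParams sample_trajectory
#' @param schedule strictly increasing sampling times (hr).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (fraction, >= 0; e.g. 0.02 for 2\% measurement scatter).
#' @param seed integer seed for the noise generator.
#' @return an object of class `timecourse_data`: data frame with columns
#'   `time_hr`, `biomass_g_L`, `substrate_g_L`, and attributes `model`,
#'   `noise_cv`, `seed`, `parameters`, `conditions`.
#' @examples
#' p <- growth_parameters(0.5, 4, 12.5, 0.5)
#' bc <- batch_conditions(0.25, 25)
#' head(generate_timecourse("hybrid", p, bc, seq(0, 25, length.out = 6),
#'                          noise_cv = 0.02, seed = 1))
#' @export
generate_timecourse <- function(model, p, bc, schedule, noise_cv = 0,
                                seed = 1L) {
  model <- model_kind(model)
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  check_time_grid(schedule)
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0)
    stop("noise_cv must be a single non-negative number", call. = FALSE)
  validate_feasibility(p, bc = bc, warn = TRUE)
  traj <- suppressWarnings(sample_trajectory(model, p, bc, schedule))
  X <- traj$biomass_g_L; S <- traj$substrate_g_L
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    n <- length(schedule)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    X <- X * exp(stats::rnorm(n, 0, sigma))
    S <- S * exp(stats::rnorm(n, 0, sigma))
  }
  structure(
    data.frame(time_hr = traj$time_hr, biomass_g_L = X, substrate_g_L = S),
    model = model, noise_cv = noise_cv, seed = as.integer(seed),
    parameters = p, conditions = bc,
    class = c("timecourse_data", "data.frame"))
}

#' Default fitting bounds
#'
#' The default box constraints for [fit_batch()]: `mu_max` in (0, 10] 1/hr,
#' `K_s` in (0, 100] g/L, `X_m` in (max observed X, 10 x max observed X]
#' g/L, `Y_xs` in (0, 1.5] g/g. The lower ends are strictly positive small
#' numbers because all parameters are optimized on the log scale.
#'
#' @param X_obs observed biomass values (g/L), used to anchor the `X_m` box.
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_fit_bounds <- function(X_obs) {
  xmax <- max(X_obs)
  list(mu_max = c(1e-3, 10),
       K_s = c(1e-4, 100),
       X_m = c(xmax * (1 + 1e-6), 10 * xmax),
       Y_xs = c(1e-3, 1.5))
}

# Parameters actually driving each law's biomass curve plus the yield that
# links substrate; all four are still reported.
fit_param_names <- function(model, has_S) {
  switch(model,
         monod = c("mu_max", "K_s", "Y_xs"),
         logistic = if (has_S) c("mu_max", "X_m", "Y_xs") else c("mu_max", "X_m"),
         hybrid = c("mu_max", "K_s", "X_m", "Y_xs"))
}

# Residual vector of relative errors at a parameter vector theta (log scale).
# Returns NULL when the trial trajectory cannot be evaluated.
fit_residuals <- function(theta, names_theta, fixed, model, tt, X_obs, S_obs,
                          S_floor) {
  par <- fixed
  par[names_theta] <- exp(theta)
  p <- list(mu_max = par[["mu_max"]], K_s = par[["K_s"]],
            X_m = par[["X_m"]], Y_xs = par[["Y_xs"]])
  class(p) <- "growth_parameters"
  bc <- list(X_0 = par[["X_0"]],
             S_0 = if ("S_0" %in% names(par)) par[["S_0"]] else 0)
  class(bc) <- "batch_conditions"
  X_fit <- tryCatch(
    suppressWarnings(biomass_at_time(model, p, bc, tt)),
    error = function(e) NULL)
  if (is.null(X_fit))
    X_fit <- tryCatch(
      suppressWarnings(integrate_batch(model, p, bc, tt,
        integrator_settings(rel_tol = 1e-8, abs_tol = 1e-10))$biomass_g_L),
      error = function(e) NULL)
  if (is.null(X_fit) || any(!is.finite(X_fit))) return(NULL)
  res <- (X_fit - X_obs) / X_obs
  if (!is.null(S_obs)) {
    ok <- is.finite(S_obs)   # substrate may be missing per row
    S_fit <- bc$S_0 - (X_fit - bc$X_0) / p$Y_xs
    res <- c(res, (S_fit[ok] - S_obs[ok]) / pmax(S_obs[ok], S_floor))
  }
  res
}

#' Fit growth parameters to batch time-course data
#'
#' Weighted nonlinear least squares on batch observations: minimizes the sum
#' of squared relative residuals in biomass (and in substrate when a
#' substrate column is present), with the model trajectory evaluated through
#' the analytical solutions (falling back to the numerical integrator when
#' inversion fails at a trial point). Relative residuals weight the early
#' exponential phase and the plateau equally, which an absolute loss would
#' not. All parameters are optimized on the log scale inside box constraints
#' (L-BFGS-B) from multiple starts drawn log-uniformly within the bounds, to
#' reduce the local-minimum risk; the best start is reported.
#'
#' The initial state is not pinned to the (noisy) first observation:
#' `X_0` — and `S_0` when substrate is observed — are estimated as nuisance
#' parameters initialized at the first row.
#'
#' Only the parameters a law actually uses are fitted (e.g. `K_s` is not
#' estimated for the logistic law); unused constants are reported at
#' placeholder values with `NA` standard errors. When the observed curve
#' never approaches its estimated carrying capacity
#' (`max X_obs < 0.8 * X_m_hat`), `X_m` is weakly identifiable and the
#' result carries `xm_identifiable = FALSE`.
#'
#' @param model growth law to fit, see [model_kind()].
#' @param data a `timecourse_data` object or data frame with columns
#'   `time_hr`, `biomass_g_L` and optionally `substrate_g_L`; at least 6
#'   rows, strictly increasing times, positive biomass.
#' @param bounds named list of `c(lower, upper)` boxes per parameter;
#'   defaults from [default_fit_bounds()], entries may be overridden
#'   individually.
#' @param init optional [growth_parameters()] used as one of the starts.
#' @param n_starts number of multi-starts (default 8).
#' @param seed seed for the start-point generator (independent of any data
#'   noise seed).
#' @return an object of class `fit_result`: list with `parameters`
#'   (a [growth_parameters()]), `initial_state` (estimated `X_0`, `S_0`),
#'   `rss`, `std_errors` (named, natural scale), `converged`,
#'   `xm_identifiable`, `model`, `n_obs`, and `starts` diagnostics.
#' @export
fit_batch <- function(model, data, bounds = list(), init = NULL,
                      n_starts = 8L, seed = 42L) {
  model <- model_kind(model)
  df <- as.data.frame(data)
  if (!all(c("time_hr", "biomass_g_L") %in% names(df)))
    stop("data must have columns time_hr and biomass_g_L", call. = FALSE)
  if (nrow(df) < 6L)
    stop("at least 6 observations are required to fit (got ", nrow(df), ")",
         call. = FALSE)
  tt <- df$time_hr
  if (any(diff(tt) <= 0)) stop("time_hr must be strictly increasing", call. = FALSE)
  X_obs <- df$biomass_g_L
  if (any(!is.finite(X_obs)) || any(X_obs <= 0))
    stop("biomass_g_L must be finite and positive", call. = FALSE)
  has_S <- "substrate_g_L" %in% names(df) && any(is.finite(df$substrate_g_L))
  if (!has_S && model != "logistic")
    stop("fitting the ", model, " law requires a substrate column: without ",
         "substrate observations only the product Y_xs * S_0 is identifiable ",
         "from the biomass curve", call. = FALSE)
  S_obs <- if (has_S) df$substrate_g_L else NULL
  tt <- tt - tt[1]

  b <- default_fit_bounds(X_obs)
  b[names(bounds)] <- bounds
  if (any(!vapply(b, function(v) all(is.finite(v)) && all(v > 0) && v[1] < v[2],
                  logical(1))))
    stop("bounds must be finite positive intervals", call. = FALSE)

  kin_names <- fit_param_names(model, has_S)
  nuis_names <- c("X_0", if (has_S) "S_0")
  b$X_0 <- c(X_obs[1] / 10, max(X_obs[1] * 10, X_obs[1] + 1e-6))
  s1 <- if (has_S) max(S_obs[is.finite(S_obs)][1], 1e-6) else NA_real_
  if (has_S) b$S_0 <- c(s1 / 10, s1 * 10)
  theta_names <- c(kin_names, nuis_names)
  lower <- log(vapply(b[theta_names], `[`, numeric(1), 1))
  upper <- log(vapply(b[theta_names], `[`, numeric(1), 2))

  # constants a law does not use: keep them out of the optimizer at values
  # that make the law's rate exact (huge X_m for Monod, tiny K_s never used
  # by logistic computations anyway)
  fixed <- c(mu_max = NA_real_, K_s = 1, X_m = 1e12, Y_xs = 1,
             X_0 = X_obs[1])
  if (has_S) fixed["S_0"] <- s1
  S_floor <- if (has_S) 1e-3 * max(S_obs, na.rm = TRUE) else NA_real_

  objective <- function(theta) {
    r <- fit_residuals(theta, theta_names, fixed, model, tt, X_obs, S_obs,
                       S_floor)
    if (is.null(r)) return(1e10)
    sum(r^2)
  }

  # start points: data-driven heuristic + log-uniform draws, on a dedicated
  # RNG stream so data noise and starts never share a generator
  heur <- c(mu_max = max(min(diff(log(X_obs))[1] / diff(tt)[1], 5), 0.05),
            K_s = 1, X_m = max(X_obs) * 1.2, Y_xs = 0.5,
            X_0 = X_obs[1], S_0 = if (has_S) s1 else NA)
  starts <- list(pmin(pmax(log(heur[theta_names]), lower), upper))
  if (!is.null(init)) {
    init <- as_growth_parameters(init)
    v <- c(mu_max = init$mu_max, K_s = init$K_s, X_m = init$X_m,
           Y_xs = init$Y_xs, X_0 = X_obs[1], S_0 = if (has_S) s1 else NA)
    starts <- c(starts, list(pmin(pmax(log(v[theta_names]), lower), upper)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  while (length(starts) < n_starts)
    starts <- c(starts, list(stats::runif(length(theta_names), lower, upper)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  fits <- lapply(starts, function(s0) {
    tryCatch(
      stats::optim(s0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e3,
                                  ndeps = rep(1e-7, length(s0)))),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  })
  values <- vapply(fits, `[[`, numeric(1), "value")
  if (all(!is.finite(values)) || min(values) >= 1e10) {
    diag <- vapply(fits, function(f)
      paste0("value=", format(f$value), " conv=", f$convergence), character(1))
    stop("all ", length(fits), " starts failed to converge:\n",
         paste(diag, collapse = "\n"), call. = FALSE)
  }
  best <- fits[[which.min(values)]]
  theta <- best$par
  names(theta) <- theta_names

  par <- fixed
  par[theta_names] <- exp(theta)
  p_hat <- growth_parameters(par[["mu_max"]], par[["K_s"]], par[["X_m"]],
                             min(par[["Y_xs"]], 1))  # constructor only warns >1
  p_hat$Y_xs <- par[["Y_xs"]]

  rss <- best$value
  se <- fit_std_errors(theta, theta_names, fixed, model, tt, X_obs, S_obs,
                       S_floor, rss)
  all_se <- stats::setNames(rep(NA_real_, 4), c("mu_max", "K_s", "X_m", "Y_xs"))
  keep <- intersect(names(se), names(all_se))
  all_se[keep] <- se[keep]

  structure(list(
    parameters = p_hat,
    initial_state = list(X_0 = unname(par[["X_0"]]),
                         S_0 = if (has_S) unname(par[["S_0"]]) else NA_real_),
    rss = rss,
    std_errors = all_se,
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    xm_identifiable = !(model %in% c("logistic", "hybrid")) ||
      max(X_obs) >= 0.8 * par[["X_m"]],
    model = model,
    n_obs = nrow(df),
    starts = data.frame(start = seq_along(values), rss = values)
  ), class = "fit_result")
}

# Gauss-Newton approximate standard errors from a forward-difference
# Jacobian of the residual vector with respect to log-parameters, mapped
# back to the natural scale (SE_nat ~ theta_nat * SE_log).
fit_std_errors <- function(theta, theta_names, fixed, model, tt, X_obs,
                           S_obs, S_floor, rss) {
  r0 <- fit_residuals(theta, theta_names, fixed, model, tt, X_obs, S_obs,
                      S_floor)
  if (is.null(r0)) return(stats::setNames(rep(NA_real_, length(theta)), theta_names))
  m <- length(r0); k <- length(theta)
  if (m <= k) return(stats::setNames(rep(NA_real_, k), theta_names))
  J <- matrix(NA_real_, m, k)
  hstep <- 1e-6
  for (j in seq_len(k)) {
    th <- theta; th[j] <- th[j] + hstep
    rj <- fit_residuals(th, theta_names, fixed, model, tt, X_obs, S_obs,
                        S_floor)
    if (is.null(rj)) return(stats::setNames(rep(NA_real_, k), theta_names))
    J[, j] <- (rj - r0) / hstep
  }
  sigma2 <- rss / (m - k)
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) NULL)
  if (is.null(cov_log)) return(stats::setNames(rep(NA_real_, k), theta_names))
  se_log <- sqrt(pmax(diag(cov_log), 0))
  stats::setNames(exp(theta) * se_log, theta_names)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Batch fit (%s model, %d observations)\n", x$model, x$n_obs))
  est <- unlist(x$parameters)
  for (nm in names(est))
    cat(sprintf("  %-6s = %.6g (SE %.3g)\n", nm, est[[nm]], x$std_errors[[nm]]))
  cat(sprintf("  RSS = %.6g; converged: %s\n", x$rss, x$converged))
  if (!x$xm_identifiable)
    cat("  note: curve never approaches the estimated X_m; X_m is weakly identifiable\n")
  invisible(x)
}
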