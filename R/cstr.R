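#' @section CSTR steady states:
#' At steady state the chemostat mass balances `dX/dt = (mu - D) X = 0` and
#' `dS/dt = D (S_F - S) - mu X / Y_xs = 0` force `mu = D` on the non-trivial
#' branch and `X = Y_xs (S_F - S)`. Substituting each growth law for mu:
#' \itemize{
#'   \item Monod: `S* = K_s D / (mu_max - D)`, `X* = Y_xs (S_F - S*)`.
#'   \item Logistic: `X* = X_m (1 - D/mu_max)`, `S* = S_F - X*/Y_xs`
#'     (requires `X_m <= Y_xs S_F` for a non-negative effluent substrate).
#'   \item Hybrid: substituting `X = Y_xs (S_F - S)` into
#'     `mu_max (S/(K_s+S)) (1 - X/X_m) = D` gives the quadratic
#'     `mu_max Y_xs S^2 + [mu_max (X_m - Y_xs S_F) - D X_m] S - D X_m K_s = 0`
#'     whose two roots have opposite signs for `D > 0` (the constant term is
#'     negative); the physically admissible root is the positive one, which
#'     always lies in `[0, S_F]` below washout.
#' }
#' Above the washout dilution rate the only steady state is the trivial one,
#' `X* = 0`, `S* = S_F`.
#' @name cstr
NULL

#' Closed-form CSTR steady state
#'
#' Computes the steady-state effluent substrate and biomass for the chosen
#' growth law at dilution rate `D` and feed substrate `S_F` (see [cstr] for
#' the formulas). For `D >= ` [washout_dilution()] the washout branch
#' `(S* = S_F, X* = 0)` is returned, with the branch recorded. Biomass
#' productivity `P = D * X*` is always included.
#'
#' A logistic configuration with `X_m > Y_xs S_F` and `D` small enough that
#' the closed form yields a negative effluent substrate is a genuine
#' misconfiguration (the carrying capacity demands more biomass than the
#' feed can support) and raises an error rather than being clamped. The
#' hybrid law respects the substrate balance by construction; an infeasible
#' `X_m` there only draws the feasibility warning.
#'
#' @param model growth law, see [model_kind()].
#' @param p [growth_parameters()].
#' @param conditions a [cstr_conditions()] object (dilution rate + feed).
#' @return an object of class `steady_state`: list with `S_star`, `X_star`
#'   (g/L), `productivity` (g/L/hr), `branch` (`"nontrivial"` or
#'   `"washout"`), `D` and `S_F`.
#' @examples
#' p <- growth_parameters(1.6, 1, 10, 0.8)
#' steady_state("hybrid", p, cstr_conditions(D = 0.8, S_F = 20))
#' @export
steady_state <- function(model, p, conditions) {
  model <- model_kind(model)
  p <- as_growth_parameters(p)
  cc <- as_cstr_conditions(conditions)
  D <- cc$D; S_F <- cc$S_F
  if (model %in% c("logistic", "hybrid"))
    validate_feasibility(p, S_F = S_F, warn = TRUE)
  D_w <- washout_dilution(model, p, S_F)
  if (D >= D_w) {
    return(new_steady_state(S_F, 0, D, S_F, "washout"))
  }
  if (D == 0) {
    S_star <- switch(model,
                     monod = 0,
                     logistic = S_F - p$X_m / p$Y_xs,
                     hybrid = max(0, S_F - p$X_m / p$Y_xs))
    if (model == "logistic" && S_star < 0)
      stop("infeasible logistic chemostat: X_m > Y_xs * S_F, so the steady-state substrate would be negative; the carrying capacity must satisfy X_m <= S_F * Y_xs",
           call. = FALSE)
    X_star <- p$Y_xs * (S_F - S_star)
    return(new_steady_state(S_star, X_star, D, S_F, "nontrivial"))
  }
  S_star <- switch(model,
    monod = p$K_s * D / (p$mu_max - D),
    logistic = {
      S <- S_F - p$X_m * (p$mu_max - D) / (p$Y_xs * p$mu_max)
      if (S < 0)
        stop("infeasible logistic chemostat: X_m > Y_xs * S_F and D is low enough that the steady-state substrate is negative; the carrying capacity must satisfy X_m <= S_F * Y_xs",
             call. = FALSE)
      S
    },
    hybrid = {
      a <- p$mu_max * p$Y_xs
      b <- p$mu_max * (p$X_m - p$Y_xs * S_F) - D * p$X_m
      cq <- -D * p$X_m * p$K_s
      # roots have opposite signs (cq < 0); keep the positive one, computed
      # in the cancellation-free form (q = -(b + sign(b) sqrt(disc))/2)
      if (b == 0) sqrt(-cq / a)
      else {
        q <- -(b + sign(b) * sqrt(b^2 - 4 * a * cq)) / 2
        max(q / a, cq / q)
      }
    })
  X_star <- p$Y_xs * (S_F - S_star)
  new_steady_state(S_star, X_star, D, S_F, "nontrivial")
}

new_steady_state <- function(S_star, X_star, D, S_F, branch) {
  structure(list(S_star = S_star, X_star = X_star,
                 productivity = D * X_star, branch = branch,
                 D = D, S_F = S_F),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("CSTR steady state (%s branch) at D = %g 1/hr, S_F = %g g/L:\n",
              x$branch, x$D, x$S_F))
  cat(sprintf("  S* = %g g/L\n  X* = %g g/L\n  P  = %g g/L/hr\n",
              x$S_star, x$X_star, x$productivity))
  invisible(x)
}

#' Washout dilution rate
#'
#' The dilution rate above which no non-trivial steady state exists and
#' biomass washes out of the reactor. Obtained by letting `X -> 0` in the
#' steady-state growth condition `mu = D`: for Monod and the hybrid law the
#' logistic factor is 1 at zero biomass, so both give
#' `mu_max S_F / (K_s + S_F)`; for the logistic law it is `mu_max`.
#'
#' @inheritParams steady_state
#' @param S_F feed substrate concentration (g/L).
#' @return washout dilution rate (1/hr).
#' @export
washout_dilution <- function(model, p, S_F) {
  model <- model_kind(model)
  p <- as_growth_parameters(p)
  if (!is.numeric(S_F) || length(S_F) != 1L || S_F <= 0)
    stop("S_F must be a single positive number", call. = FALSE)
  switch(model,
         monod = p$mu_max * S_F / (p$K_s + S_F),
         logistic = p$mu_max,
         hybrid = p$mu_max * S_F / (p$K_s + S_F))
}

#' Productivity-optimal dilution rate
#'
#' Maximizes the steady-state biomass productivity `P(D) = D * X*(D)` over
#' the non-trivial branch `(0, D_washout)`:
#' \itemize{
#'   \item Monod: closed form `D_opt = mu_max (1 - sqrt(K_s / (K_s + S_F)))`.
#'   \item Logistic: `P(D) = D X_m (1 - D/mu_max)` is a parabola with vertex
#'     `D_opt = mu_max / 2`, `P_max = mu_max X_m / 4`.
#'   \item Hybrid: no simple closed form; `P(D)` is maximized numerically
#'     (Brent via [stats::optimize()], refined to ~1e-8 relative in D),
#'     guarded by a grid pre-scan for unimodality.
#' }
#'
#' @inheritParams washout_dilution
#' @return an object of class `dilution_analysis`: list with `D_washout`,
#'   `D_optimal` (1/hr) and `P_max` (g/L/hr).
#' @export
optimal_dilution <- function(model, p, S_F) {
  model <- model_kind(model)
  p <- as_growth_parameters(p)
  D_w <- washout_dilution(model, p, S_F)
  prod_at <- function(D) vapply(D, function(d)
    steady_state(model, p, cstr_conditions(d, S_F))$productivity, numeric(1))
  res <- switch(model,
    monod = {
      D_opt <- p$mu_max * (1 - sqrt(p$K_s / (p$K_s + S_F)))
      list(D = D_opt, P = prod_at(D_opt))
    },
    logistic = list(D = p$mu_max / 2, P = p$mu_max * p$X_m / 4),
    hybrid = {
      grid <- seq(D_w * 1e-4, D_w * (1 - 1e-9), length.out = 201)
      Pg <- suppressWarnings(prod_at(grid))
      imax <- which.max(Pg)
      d2 <- diff(sign(diff(Pg)))
      if (sum(d2 < 0) > 1)
        stop("productivity curve is not unimodal on (0, D_washout); cannot optimize",
             call. = FALSE)
      lo <- grid[max(1L, imax - 1L)]; hi <- grid[min(length(grid), imax + 1L)]
      opt <- suppressWarnings(
        stats::optimize(prod_at, lower = lo, upper = hi, maximum = TRUE,
                        tol = 1e-10))
      list(D = opt$maximum, P = opt$objective)
    })
  structure(list(D_washout = D_w, D_optimal = res$D, P_max = res$P),
            class = "dilution_analysis")
}

#' @export
print.dilution_analysis <- function(x, ...) {
  cat(sprintf("Dilution analysis:\n  D_washout = %g 1/hr\n  D_optimal = %g 1/hr\n  P_max     = %g g/L/hr\n",
              x$D_washout, x$D_optimal, x$P_max))
  invisible(x)
}

#' Steady-state sweep over dilution rates
#'
#' Evaluates [steady_state()] on each dilution rate of an increasing grid
#' and returns one row per rate. On the non-trivial branch the effluent
#' substrate is non-decreasing and the biomass non-increasing in D for all
#' three laws.
#'
#' @inheritParams washout_dilution
#' @param D_grid non-negative, strictly increasing dilution rates (1/hr).
#' @return data frame (class `dilution_sweep`) with columns `D_per_hr`,
#'   `S_star_g_L`, `X_star_g_L`, `productivity_g_L_hr`, `branch`.
#' @export
dilution_sweep <- function(model, p, S_F, D_grid) {
  model <- model_kind(model)
  p <- as_growth_parameters(p)
  if (length(D_grid) == 0L || any(!is.finite(D_grid)) || any(D_grid < 0))
    stop("D_grid must be non-empty, finite and non-negative", call. = FALSE)
  if (length(D_grid) > 1L && any(diff(D_grid) <= 0))
    stop("D_grid must be strictly increasing", call. = FALSE)
  if (model %in% c("logistic", "hybrid"))
    validate_feasibility(p, S_F = S_F, warn = TRUE)
  rows <- lapply(D_grid, function(d)
    suppressWarnings(steady_state(model, p, cstr_conditions(d, S_F))))
  structure(
    data.frame(
      D_per_hr = D_grid,
      S_star_g_L = vapply(rows, `[[`, numeric(1), "S_star"),
      X_star_g_L = vapply(rows, `[[`, numeric(1), "X_star"),
      productivity_g_L_hr = vapply(rows, `[[`, numeric(1), "productivity"),
      branch = vapply(rows, `[[`, character(1), "branch"),
      stringsAsFactors = FALSE),
    model = model, parameters = p, S_F = S_F,
    class = c("dilution_sweep", "data.frame"))
}

# Dynamic (transient) CSTR balances; used only for the stability cross-check
# that perturbed states relax to the closed-form steady state below washout.
cstr_ode_fn <- function(model, p, D, S_F) {
  force(model); force(p); force(D); force(S_F)
  function(t, y) {
    mu <- specific_growth_rate(model, p, S = max(y[2], 0), X = max(y[1], 0))
    c((mu - D) * y[1],
      D * (S_F - y[2]) - mu * y[1] / p$Y_xs)
  }
}

# Integrate the dynamic CSTR from (X0, S0) to time `horizon`.
integrate_cstr <- function(model, p, conditions, X0, S0, horizon,
                           settings = integrator_settings()) {
  model <- model_kind(model)
  p <- as_growth_parameters(p)
  cc <- as_cstr_conditions(conditions)
  f <- cstr_ode_fn(model, p, cc$D, cc$S_F)
  max_step <- if (is.null(settings$max_step)) horizon / 100 else settings$max_step
  y <- dp_integrate(f, 0, c(X0, S0), horizon,
                    settings$rel_tol, settings$abs_tol, max_step)[1, ]
  list(X = y[1], S = y[2])
}
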