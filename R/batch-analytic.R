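#' @section Analytical batch solutions:
#' With substrate eliminated through the conservation law
#' `X - X_0 = Y_xs (S_0 - S)`, each growth law reduces to a scalar ODE in X
#' that separates. Writing `A = X_0 + Y_xs S_0` (total substrate-supported
#' biomass) and `B = A + K_s Y_xs`, separation of variables with partial
#' fractions gives, for time as a function of biomass,
#' \itemize{
#'   \item Monod: `t = (1/mu_max) [ (B/A) ln(X/X_0) +
#'         (K_s Y_xs / A) ln((A - X_0)/(A - X)) ]`
#'   \item Logistic (explicit inverse of the sigmoid):
#'         `t = (1/mu_max) ln[ X (X_m - X_0) / (X_0 (X_m - X)) ]`
#'   \item Hybrid: `t = (X_m/mu_max) [ a ln(X/X_0) +
#'         b ln((A - X_0)/(A - X)) + c ln((X_m - X_0)/(X_m - X)) ]` with
#'         `a = B/(A X_m)`, `b = K_s Y_xs / (A (X_m - A))`,
#'         `c = (B - X_m)/(X_m (A - X_m))`.
#' }
#' Each t(X) is strictly increasing on `(X_0, X_sup)` and diverges at the
#' reachable supremum `X_sup` (`A` for Monod, `X_m` for Logistic,
#' `min(A, X_m)` for the hybrid law). Biomass at a given time is recovered by
#' bracketed root finding on the monotone t(X).
#' @name batch_analytic
NULL

# Reachable biomass supremum for a model.
biomass_supremum <- function(model, p, bc) {
  A <- bc$X_0 + p$Y_xs * bc$S_0
  switch(model,
         monod = A,
         logistic = p$X_m,
         hybrid = min(A, p$X_m))
}

# Guard the degenerate hybrid case X_m == X_0 + Y_xs*S_0, where the
# partial-fraction coefficients blow up: perturb X_m by 1e-6 relative.
resolve_degenerate_hybrid <- function(p, bc) {
  A <- bc$X_0 + p$Y_xs * bc$S_0
  if (abs(p$X_m - A) < 1e-9 * p$X_m) {
    warning(sprintf(
      "degenerate hybrid configuration X_m = X_0 + Y_xs*S_0 = %g g/L; perturbing X_m by 1e-6 relative",
      p$X_m), call. = FALSE)
    p$X_m <- p$X_m * (1 + 1e-6)
  }
  p
}

#' Explicit logistic biomass curve
#'
#' The closed-form sigmoid
#' `X(t) = X_0 X_m e^{mu_max t} / (X_m - X_0 + X_0 e^{mu_max t})`, evaluated
#' in the overflow-safe equivalent form
#' `X_m / (1 + ((X_m - X_0)/X_0) e^{-mu_max t})` so that arbitrarily large
#' `mu_max * t` cannot overflow.
#'
#' @param p [growth_parameters()].
#' @param bc [batch_conditions()].
#' @param t time (hr), >= 0; vectorised.
#' @return biomass X(t) in g/L.
#' @export
logistic_biomass <- function(p, bc, t) {
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  check_times(t)
  p$X_m / (1 + ((p$X_m - bc$X_0) / bc$X_0) * exp(-p$mu_max * t))
}

#' Substrate under logistic growth
#'
#' Substrate depletes in proportion to logistic biomass formation:
#' `S(t) = S_0 - (X(t) - X_0)/Y_xs`. Because logistic growth ignores the
#' substrate level, this can become negative whenever the carrying capacity
#' exceeds the substrate-supported biomass; the raw value is returned and a
#' warning is emitted in that case.
#'
#' @inheritParams logistic_biomass
#' @return substrate S(t) in g/L (possibly negative, with a warning).
#' @export
logistic_substrate <- function(p, bc, t) {
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  S <- bc$S_0 - (logistic_biomass(p, bc, t) - bc$X_0) / p$Y_xs
  if (any(S < 0))
    warning("logistic substrate is negative: the logistic asymptote exceeds the available substrate (X_m > S_0*Y_xs + X_0)",
            call. = FALSE)
  S
}

check_times <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("time t must be finite and >= 0", call. = FALSE)
  invisible(t)
}

check_biomass_reachable <- function(X, bc, X_sup) {
  bad <- X < bc$X_0 | X >= X_sup
  if (any(bad))
    stop(sprintf("biomass target %g g/L outside the reachable interval [X_0, X_sup) = [%g, %g) g/L",
                 X[which(bad)[1]], bc$X_0, X_sup), call. = FALSE)
  invisible(X)
}

#' Implicit Monod batch solution: time to reach a biomass level
#'
#' Inverts the separated-variables solution of the substrate-coupled Monod
#' ODE (see [batch_analytic]): strictly increasing in X, zero at `X = X_0`,
#' diverging logarithmically as X approaches the substrate-supported
#' supremum `X_0 + Y_xs S_0`.
#'
#' @inheritParams logistic_biomass
#' @param X biomass level (g/L) in `[X_0, X_0 + Y_xs S_0)`; vectorised.
#' @return time t (hr) at which the culture reaches `X`.
#' @export
monod_time_of_biomass <- function(p, bc, X) {
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  A <- bc$X_0 + p$Y_xs * bc$S_0
  B <- A + p$K_s * p$Y_xs
  check_biomass_reachable(X, bc, A)
  (1 / p$mu_max) *
    ((B / A) * log(X / bc$X_0) +
       (p$K_s * p$Y_xs / A) * log((A - bc$X_0) / (A - X)))
}

#' Implicit hybrid Logistic-Monod batch solution: time to reach a biomass level
#'
#' Inverts the separated-variables solution of the substrate-coupled hybrid
#' ODE (see [batch_analytic] for the re-derived partial-fraction form).
#' Strictly increasing in X, zero at `X = X_0`, diverging as X approaches
#' `X_sup = min(X_m, X_0 + Y_xs S_0)`. The degenerate configuration
#' `X_m = X_0 + Y_xs S_0` (vanishing partial-fraction denominator) is handled
#' by a 1e-6 relative perturbation of `X_m`, with a warning.
#'
#' @inheritParams logistic_biomass
#' @param X biomass level (g/L) in `[X_0, X_sup)`; vectorised.
#' @return time t (hr) at which the culture reaches `X`.
#' @export
hybrid_time_of_biomass <- function(p, bc, X) {
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  p <- resolve_degenerate_hybrid(p, bc)
  A <- bc$X_0 + p$Y_xs * bc$S_0
  B <- A + p$K_s * p$Y_xs
  Xm <- p$X_m
  check_biomass_reachable(X, bc, min(A, Xm))
  a <- B / (A * Xm)
  b <- p$K_s * p$Y_xs / (A * (Xm - A))
  cc <- (B - Xm) / (Xm * (A - Xm))
  (Xm / p$mu_max) *
    (a * log(X / bc$X_0) +
       b * log((A - bc$X_0) / (A - X)) +
       cc * log((Xm - bc$X_0) / (Xm - X)))
}

#' Time to reach a biomass level, any model
#'
#' Dispatches to the explicit logistic inverse or the implicit Monod/hybrid
#' relations.
#'
#' @inheritParams logistic_biomass
#' @param model growth law, see [model_kind()].
#' @param X biomass level (g/L) in `[X_0, X_sup)`; vectorised.
#' @return time t (hr).
#' @export
time_of_biomass <- function(model, p, bc, X) {
  model <- model_kind(model)
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  switch(model,
         monod = monod_time_of_biomass(p, bc, X),
         hybrid = hybrid_time_of_biomass(p, bc, X),
         logistic = {
           check_biomass_reachable(X, bc, p$X_m)
           (1 / p$mu_max) *
             log((X * (p$X_m - bc$X_0)) / (bc$X_0 * (p$X_m - X)))
         })
}

#' Implicit-solution object
#'
#' Packages the monotone time-of-biomass map together with the reachable
#' biomass supremum, for callers that want to work with t(X) directly.
#'
#' @inheritParams time_of_biomass
#' @return an object of class `implicit_solution`: a list with `model`,
#'   `t_of_X` (a function of biomass) and `X_sup` (g/L).
#' @export
implicit_solution <- function(model, p, bc) {
  model <- model_kind(model)
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  if (model == "hybrid") p <- resolve_degenerate_hybrid(p, bc)
  structure(list(
    model = model,
    t_of_X = function(X) time_of_biomass(model, p, bc, X),
    X_sup = biomass_supremum(model, p, bc)
  ), class = "implicit_solution")
}

#' Biomass at a given time, any model
#'
#' Logistic dispatches to the explicit sigmoid; Monod and hybrid invert the
#' monotone implicit relation t(X) by bracketed root finding (Brent's method
#' via [stats::uniroot()]) on `[X_0, X_sup)`, to an absolute biomass
#' tolerance of 1e-12 g/L.
#'
#' @inheritParams time_of_biomass
#' @param t time (hr), >= 0; vectorised.
#' @return biomass X(t) in g/L.
#' @export
biomass_at_time <- function(model, p, bc, t) {
  model <- model_kind(model)
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  check_times(t)
  if (model == "logistic") return(logistic_biomass(p, bc, t))
  if (model == "hybrid") p <- resolve_degenerate_hybrid(p, bc)
  X_sup <- biomass_supremum(model, p, bc)
  if (bc$S_0 == 0 || X_sup <= bc$X_0) return(rep(bc$X_0, length(t)))
  t_of_X <- function(X) suppressWarnings(time_of_biomass(model, p, bc, X))
  lo0 <- bc$X_0 * (1 + 1e-12)
  hi0 <- X_sup - max(1e-12 * X_sup, 4 * .Machine$double.eps * X_sup)
  t_lo <- t_of_X(lo0); t_hi <- t_of_X(hi0)

  n <- length(t)
  X <- numeric(n)
  below <- t <= t_lo          # below bracket resolution: X ~ X_0
  above <- t >= t_hi          # numerically at the asymptote
  X[below] <- bc$X_0
  X[above] <- hi0
  act <- which(!below & !above)
  if (length(act)) {
    # vectorized safeguarded Newton on the monotone g(X) = t(X) - t_target;
    # dt/dX = 1/(mu * X) is available in closed form
    tt <- t[act]
    lo <- rep(lo0, length(act)); hi <- rep(hi0, length(act))
    x <- sqrt(lo * hi)
    for (iter in 1:200) {
      g <- t_of_X(x) - tt
      lo[g < 0] <- x[g < 0]
      hi[g >= 0] <- x[g >= 0]
      S <- pmax(bc$S_0 - (x - bc$X_0) / p$Y_xs, 0)
      mu <- specific_growth_rate(model, p, S = S, X = x)
      step <- g * mu * x               # Newton: dX = -g / (dt/dX)
      x_new <- x - step
      oob <- !(x_new > lo & x_new < hi) | !is.finite(x_new)
      x_new[oob] <- (lo[oob] + hi[oob]) / 2
      done <- abs(x_new - x) <= 1e-12 * pmax(1, x) & abs(g) <= 1e-9 * pmax(1, tt)
      x <- x_new
      if (all(hi - lo <= 1e-12) || all(done)) break
    }
    if (max(hi - lo) > 1e-6 && max(abs(t_of_X(x) - tt)) > 1e-8 * max(1, max(tt)))
      stop(sprintf("biomass inversion did not converge (worst bracket width %g g/L, worst time residual %g hr)",
                   max(hi - lo), max(abs(t_of_X(x) - tt))), call. = FALSE)
    X[act] <- x
  }
  X
}

#' Substrate at a given time, any model
#'
#' Computed from the conservation identity
#' `S(t) = S_0 - (X(t) - X_0)/Y_xs`, which the implicit substrate relations
#' reduce to on the reachable interval. For the substrate-limited laws tiny
#' negative values from inversion round-off (>= -1e-9 g/L) are clipped to 0;
#' logistic substrate may be genuinely negative (see [logistic_substrate()]).
#'
#' @inheritParams biomass_at_time
#' @return substrate S(t) in g/L.
#' @export
substrate_at_time <- function(model, p, bc, t) {
  model <- model_kind(model)
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  if (model == "logistic") return(logistic_substrate(p, bc, t))
  S <- bc$S_0 - (biomass_at_time(model, p, bc, t) - bc$X_0) / p$Y_xs
  S[S < 0 & S >= -1e-9] <- 0
  S
}

new_batch_trajectory <- function(t, X, S, mu, provenance, model, p, bc) {
  structure(
    data.frame(time_hr = t, biomass_g_L = X, substrate_g_L = S,
               mu_per_hr = mu),
    provenance = provenance, model = model,
    parameters = p, conditions = bc,
    class = c("batch_trajectory", "data.frame"))
}

#' Sample an analytical batch trajectory on a time grid
#'
#' Evaluates [biomass_at_time()] and [substrate_at_time()] on every grid
#' point and records the specific growth rate at each state.
#'
#' @inheritParams biomass_at_time
#' @param t_grid strictly increasing times (hr), first element >= 0.
#' @return a `batch_trajectory`: a data frame with columns `time_hr`,
#'   `biomass_g_L`, `substrate_g_L`, `mu_per_hr` and attributes
#'   `provenance = "analytic"`, `model`, `parameters`, `conditions`.
#' @examples
#' p <- growth_parameters(0.5, 4, 12.5, 0.5)
#' bc <- batch_conditions(0.25, 25)
#' head(sample_trajectory("hybrid", p, bc, seq(0, 25, by = 5)))
#' @export
sample_trajectory <- function(model, p, bc, t_grid) {
  model <- model_kind(model)
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  check_time_grid(t_grid)
  X <- biomass_at_time(model, p, bc, t_grid)
  S <- bc$S_0 - (X - bc$X_0) / p$Y_xs
  if (model != "logistic") S[S < 0 & S >= -1e-9] <- 0
  mu <- specific_growth_rate(model, p, S = pmax(S, 0), X = X)
  new_batch_trajectory(t_grid, X, S, mu, "analytic", model, p, bc)
}

check_time_grid <- function(t_grid) {
  if (length(t_grid) == 0L)
    stop("t_grid must be non-empty", call. = FALSE)
  if (any(!is.finite(t_grid)) || t_grid[1] < 0)
    stop("t_grid must be finite with t_grid[1] >= 0", call. = FALSE)
  if (length(t_grid) > 1L && any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing", call. = FALSE)
  invisible(t_grid)
}
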