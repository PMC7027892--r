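#' Specific growth rate under a chosen growth law
#'
#' Evaluates mu = (1/X) dX/dt for the selected model:
#' \itemize{
#'   \item Monod: `mu_max * S / (K_s + S)` — saturation in the limiting
#'     substrate, independent of biomass.
#'   \item Logistic: `mu_max * (1 - X / X_m)` — linear self-inhibition toward
#'     the carrying capacity, independent of substrate.
#'   \item Hybrid: the product of the two factors, capturing the transition
#'     from a substrate-limited to a self-inhibited phase.
#' }
#' The result can be negative only for Logistic/hybrid when `X > X_m`
#' (decay back toward the carrying capacity).
#'
#' @param model growth law, see [model_kind()].
#' @param p [growth_parameters()].
#' @param S substrate concentration (g/L), >= 0; vectorised.
#' @param X biomass concentration (g/L), >= 0; vectorised.
#' @return specific growth rate (1/hr), recycled to `length(S)`/`length(X)`.
#' @examples
#' p <- growth_parameters(0.5, 4, 12.5, 0.5)
#' specific_growth_rate("monod", p, S = 4, X = 1)   # mu_max / 2
#' specific_growth_rate("hybrid", p, S = 4, X = 6.25)
#' @export
specific_growth_rate <- function(model, p, S, X) {
  model <- model_kind(model)
  p <- as_growth_parameters(p)
  if (any(!is.finite(S)) || any(S < 0))
    stop("substrate concentration S must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(X)) || any(X < 0))
    stop("biomass concentration X must be finite and >= 0", call. = FALSE)
  monod_factor <- S / (p$K_s + S)
  logistic_factor <- 1 - X / p$X_m
  switch(model,
         monod    = p$mu_max * monod_factor + 0 * X,
         logistic = p$mu_max * logistic_factor + 0 * S,
         hybrid   = p$mu_max * monod_factor * logistic_factor)
}

#' Coupled batch right-hand side
#'
#' The batch mass balances: `dX/dt = mu * X` and `dS/dt = -mu * X / Y_xs`
#' (substrate consumed in proportion to growth through the yield
#' coefficient). Growth ceases exactly at substrate depletion for the
#' substrate-dependent laws: at `S = 0` the Monod/hybrid rate is identically
#' zero, so depletion is a true fixed point (no epsilon floor).
#'
#' @inheritParams specific_growth_rate
#' @param X biomass (g/L), scalar.
#' @param S substrate (g/L), scalar.
#' @return named numeric vector `c(dX = ..., dS = ...)` in g/L/hr.
#' @export
batch_rhs <- function(model, p, X, S) {
  mu <- specific_growth_rate(model, p, S = S, X = X)
  dX <- mu * X
  c(dX = dX, dS = -dX / p$Y_xs)
}
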