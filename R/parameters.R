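#' Kinetic model kinds
#'
#' The three unstructured specific growth-rate laws supported throughout the
#' package: Monod saturation kinetics, Logistic (carrying-capacity) kinetics,
#' and the hybrid Logistic-Monod product of the two.
#'
#' @format Character vector of the three canonical model names.
#' @export
MODEL_KINDS <- c("monod", "logistic", "hybrid")

#' Normalise a model-kind argument
#'
#' Accepts any case and unambiguous abbreviation of "monod", "logistic" or
#' "hybrid" and returns the canonical lower-case name.
#'
#' @param model character scalar naming the growth law.
#' @return one of `"monod"`, `"logistic"`, `"hybrid"`.
#' @export
model_kind <- function(model) {
  if (length(model) != 1L || !is.character(model) || is.na(model))
    stop("`model` must be a single string: one of ",
         paste(MODEL_KINDS, collapse = ", "), call. = FALSE)
  match.arg(tolower(model), MODEL_KINDS)
}

#' Kinetic parameter set
#'
#' Bundles the four kinetic constants shared by all three growth laws:
#' the maximal specific growth rate, the substrate saturation (half-velocity)
#' constant, the carrying capacity, and the biomass yield on substrate.
#' `K_s` plays no role in Logistic computations and `X_m` plays no role in
#' Monod computations; both are still stored so one parameter object can be
#' evaluated under any model.
#'
#' @param mu_max maximal specific growth rate (1/hr), > 0.
#' @param K_s substrate saturation constant (g/L), > 0.
#' @param X_m carrying capacity (g/L), > 0.
#' @param Y_xs biomass yield on substrate (g biomass / g substrate), > 0.
#'   Values above 1 are physically suspect and trigger a warning, not an error.
#' @return an object of class `growth_parameters`.
#' @examples
#' growth_parameters(mu_max = 0.5, K_s = 4, X_m = 12.5, Y_xs = 0.5)
#' @export
growth_parameters <- function(mu_max, K_s, X_m, Y_xs) {
  for (nm in c("mu_max", "K_s", "X_m", "Y_xs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(nm, " must be a single positive number", call. = FALSE)
  }
  if (Y_xs > 1)
    warning("Y_xs = ", format(Y_xs),
            " exceeds 1 g/g; more biomass than substrate consumed is unusual",
            call. = FALSE)
  structure(list(mu_max = as.numeric(mu_max), K_s = as.numeric(K_s),
                 X_m = as.numeric(X_m), Y_xs = as.numeric(Y_xs)),
            class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat("Growth parameters:\n")
  cat(sprintf("  mu_max = %g 1/hr\n  K_s    = %g g/L\n  X_m    = %g g/L\n  Y_xs   = %g g/g\n",
              x$mu_max, x$K_s, x$X_m, x$Y_xs))
  invisible(x)
}

#' Batch initial conditions
#'
#' @param X_0 initial biomass (g/L), > 0 (the Logistic and hybrid solutions
#'   divide by `X_0`).
#' @param S_0 initial substrate (g/L), >= 0.
#' @return an object of class `batch_conditions`.
#' @export
batch_conditions <- function(X_0, S_0) {
  if (!is.numeric(X_0) || length(X_0) != 1L || is.na(X_0) || X_0 <= 0)
    stop("X_0 must be a single positive number", call. = FALSE)
  if (!is.numeric(S_0) || length(S_0) != 1L || is.na(S_0) || S_0 < 0)
    stop("S_0 must be a single non-negative number", call. = FALSE)
  structure(list(X_0 = as.numeric(X_0), S_0 = as.numeric(S_0)),
            class = "batch_conditions")
}

#' CSTR operating conditions
#'
#' @param D dilution rate (1/hr), >= 0; the inverse residence time
#'   flow/volume of the chemostat.
#' @param S_F feed substrate concentration (g/L), > 0.
#' @return an object of class `cstr_conditions`.
#' @export
cstr_conditions <- function(D, S_F) {
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 0)
    stop("D must be a single non-negative number", call. = FALSE)
  if (!is.numeric(S_F) || length(S_F) != 1L || is.na(S_F) || S_F <= 0)
    stop("S_F must be a single positive number", call. = FALSE)
  structure(list(D = as.numeric(D), S_F = as.numeric(S_F)),
            class = "cstr_conditions")
}

#' Check whether the carrying capacity is substrate-feasible
#'
#' In practice the carrying capacity should not exceed the biomass the
#' available substrate can support: `X_m <= S_0 * Y_xs + X_0` in batch and
#' `X_m <= S_F * Y_xs` in a CSTR (assuming all substrate can be converted to
#' biomass). Violations are reported as warnings, not errors: the logistic
#' factor remains well defined, but the substrate balance, not the carrying
#' capacity, will then cap growth. The bound is inclusive.
#'
#' @param p a [growth_parameters()] object.
#' @param bc optional [batch_conditions()]; checked against the batch bound.
#' @param S_F optional feed substrate (g/L); checked against the CSTR bound.
#' @param warn signal the messages as R warnings (default `TRUE`) in addition
#'   to returning them.
#' @return character vector of warning messages (length 0 when feasible),
#'   invisibly when `warn = TRUE`.
#' @export
validate_feasibility <- function(p, bc = NULL, S_F = NULL, warn = TRUE) {
  p <- as_growth_parameters(p)
  msgs <- character(0)
  if (!is.null(bc)) {
    bc <- as_batch_conditions(bc)
    cap <- bc$S_0 * p$Y_xs + bc$X_0
    if (p$X_m > cap)
      msgs <- c(msgs, sprintf(
        "carrying capacity X_m = %g g/L exceeds the substrate-supported biomass S_0*Y_xs + X_0 = %g g/L (batch)",
        p$X_m, cap))
    if (bc$X_0 > p$X_m)
      msgs <- c(msgs, sprintf(
        "initial biomass X_0 = %g g/L already exceeds the carrying capacity X_m = %g g/L",
        bc$X_0, p$X_m))
  }
  if (!is.null(S_F)) {
    cap <- S_F * p$Y_xs
    if (p$X_m > cap)
      msgs <- c(msgs, sprintf(
        "carrying capacity X_m = %g g/L exceeds the feed-supported biomass S_F*Y_xs = %g g/L (CSTR)",
        p$X_m, cap))
  }
  if (warn && length(msgs)) {
    for (m in msgs) warning(m, call. = FALSE)
    return(invisible(msgs))
  }
  msgs
}

as_growth_parameters <- function(p) {
  if (inherits(p, "growth_parameters")) return(p)
  if (is.list(p) && all(c("mu_max", "K_s", "X_m", "Y_xs") %in% names(p)))
    return(growth_parameters(p$mu_max, p$K_s, p$X_m, p$Y_xs))
  stop("expected growth_parameters or a list with mu_max, K_s, X_m, Y_xs",
       call. = FALSE)
}

as_batch_conditions <- function(bc) {
  if (inherits(bc, "batch_conditions")) return(bc)
  if (is.list(bc) && all(c("X_0", "S_0") %in% names(bc)))
    return(batch_conditions(bc$X_0, bc$S_0))
  stop("expected batch_conditions or a list with X_0, S_0", call. = FALSE)
}

as_cstr_conditions <- function(cc) {
  if (inherits(cc, "cstr_conditions")) return(cc)
  if (is.list(cc) && all(c("D", "S_F") %in% names(cc)))
    return(cstr_conditions(cc$D, cc$S_F))
  stop("expected cstr_conditions or a list with D, S_F", call. = FALSE)
}
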