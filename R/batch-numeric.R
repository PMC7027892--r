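#' Integrator settings for the numerical oracle
#'
#' Controls the adaptive Dormand-Prince 5(4) integrator used as the
#' independent numerical check on the analytical solutions. The batch system
#' is non-stiff for realistic parameters; the sharp corner near substrate
#' depletion is handled by tight tolerances rather than stiffness machinery.
#'
#' @param rel_tol relative error tolerance per step (default 1e-10).
#' @param abs_tol absolute error tolerance per step, g/L (default 1e-12).
#' @param max_step cap on the step size (hr); `NULL` (default) means
#'   horizon/100, resolved when the horizon is known.
#' @param event_tolerance absolute tolerance (g/L) for locating biomass
#'   crossings (default 1e-10).
#' @return an object of class `integrator_settings`.
#' @export
integrator_settings <- function(rel_tol = 1e-10, abs_tol = 1e-12,
                                max_step = NULL, event_tolerance = 1e-10) {
  for (nm in c("rel_tol", "abs_tol", "event_tolerance")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(nm, " must be a single positive number", call. = FALSE)
  }
  if (!is.null(max_step) && (!is.numeric(max_step) || max_step <= 0))
    stop("max_step must be NULL or a single positive number", call. = FALSE)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 event_tolerance = event_tolerance),
            class = "integrator_settings")
}

# Dormand-Prince 5(4) coefficients (FSAL pair).
.dp_a <- list(
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
.dp_e <- c(35/384 - 5179/57600, 0, 500/1113 - 7571/16695,
           125/192 - 393/640, -2187/6784 + 92097/339200,
           11/84 - 187/2100, -1/40)

# One adaptive DP5(4) step attempt from (t, y). Returns list(t, y, h_next,
# accepted, err). `f` maps (t, y) -> dy.
dp_step <- function(f, t, y, h, k1, rel_tol, abs_tol) {
  k <- matrix(0, nrow = length(y), ncol = 7)
  k[, 1] <- k1
  for (i in 1:5) {
    a <- .dp_a[[i]]
    k[, i + 1] <- f(t + h * sum(a), y + h * (k[, seq_along(a), drop = FALSE] %*% a))
  }
  a <- .dp_a[[6]]
  y_new <- y + h * as.vector(k[, 1:6, drop = FALSE] %*% a)
  k[, 7] <- f(t + h, y_new)
  err_vec <- h * as.vector(k %*% .dp_e)
  scale <- abs_tol + rel_tol * pmax(abs(y), abs(y_new))
  err <- sqrt(mean((err_vec / scale)^2))
  list(y_new = y_new, k_last = k[, 7], err = err)
}

# Integrate f from (t0, y0) to each time in `times` (increasing, > t0).
# Returns a matrix with one row per requested time.
dp_integrate <- function(f, t0, y0, times, rel_tol, abs_tol, max_step) {
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  t <- t0; y <- y0
  k1 <- f(t, y)
  h <- min(max_step, 1e-3 * max(max_step, 1))
  i <- 1L
  while (i <= length(times)) {
    target <- times[i]
    if (target <= t + 1e-14 * max(1, abs(t))) { out[i, ] <- y; i <- i + 1L; next }
    repeat {
      h <- min(h, max_step, target - t)
      st <- dp_step(f, t, y, h, k1, rel_tol, abs_tol)
      if (!all(is.finite(st$y_new)))
        stop("integrator produced non-finite state; step-size collapse at t = ",
             format(t), call. = FALSE)
      if (st$err <= 1) {
        t <- t + h
        y <- st$y_new
        k1 <- st$k_last
        h <- h * min(5, max(0.2, 0.9 * (max(st$err, 1e-16))^(-0.2)))
        if (h < 1e-14 * max(1, abs(t)))
          stop("step-size collapse at t = ", format(t),
               "; last accepted state: ", paste(format(y), collapse = ", "),
               call. = FALSE)
        if (t >= target - 1e-14 * max(1, target)) break
      } else {
        h <- h * max(0.1, 0.9 * st$err^(-0.2))
        if (h < 1e-14 * max(1, abs(t)))
          stop("step-size collapse at t = ", format(t),
               "; last accepted state: ", paste(format(y), collapse = ", "),
               call. = FALSE)
      }
    }
    out[i, ] <- y
    i <- i + 1L
  }
  out
}

# Batch right-hand side as a closure for the integrator; the growth rate is
# evaluated with S floored at 0 so substrate depletion cannot feed a negative
# concentration back into the kinetics.
batch_ode_fn <- function(model, p) {
  force(model); force(p)
  function(t, y) {
    mu <- specific_growth_rate(model, p, S = max(y[2], 0), X = max(y[1], 0))
    dX <- mu * y[1]
    c(dX, -dX / p$Y_xs)
  }
}

#' Numerically integrate a batch culture (independent oracle)
#'
#' Adaptive Dormand-Prince 5(4) integration of the coupled biomass/substrate
#' mass balances for any of the three growth laws. This route shares no code
#' with the analytical solutions and serves as their independent check.
#' The right-hand side floors substrate at 0 inside the kinetics, so the
#' Monod/hybrid rates vanish smoothly at depletion; for the logistic law the
#' substrate balance is integrated as-is and may go negative, mirroring the
#' analytical solution.
#'
#' @inheritParams sample_trajectory
#' @param settings an [integrator_settings()] object.
#' @return a `batch_trajectory` with `provenance = "numeric"`.
#' @export
integrate_batch <- function(model, p, bc, t_grid,
                            settings = integrator_settings()) {
  model <- model_kind(model)
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  check_time_grid(t_grid)
  horizon <- max(t_grid[length(t_grid)], 1e-6)
  max_step <- if (is.null(settings$max_step)) horizon / 100 else settings$max_step
  f <- batch_ode_fn(model, p)
  y0 <- c(bc$X_0, bc$S_0)
  first <- t_grid[1]
  states <- matrix(NA_real_, nrow = length(t_grid), ncol = 2)
  idx <- t_grid > 0
  if (any(!idx)) states[!idx, ] <- matrix(y0, nrow = sum(!idx), ncol = 2, byrow = TRUE)
  if (any(idx)) {
    states[idx, ] <- dp_integrate(f, 0, y0, t_grid[idx],
                                  settings$rel_tol, settings$abs_tol, max_step)
  }
  X <- states[, 1]; S <- states[, 2]
  if (any(S < -1e-12) && model != "logistic")
    warning("numeric substrate fell below -1e-12 g/L; clipping", call. = FALSE)
  if (model != "logistic") S <- pmax(S, 0)
  mu <- specific_growth_rate(model, p, S = pmax(S, 0), X = pmax(X, 0))
  new_batch_trajectory(t_grid, X, S, mu, "numeric", model, p, bc)
}

#' First time the integrated biomass reaches a target (event detection)
#'
#' Steps the numerical integrator until the (monotone) biomass crosses
#' `X_target`, then refines the crossing time by bracketed root finding on
#' re-integrations inside the crossing step, to the event tolerance in
#' `settings`. Used as the independent oracle for the implicit
#' time-of-biomass relations.
#'
#' An unreachable target (at or above the reachable supremum, or not reached
#' within `horizon`) signals a condition of class
#' `"hybridgrowth_unreachable"` rather than an ordinary numerical error.
#'
#' @inheritParams integrate_batch
#' @param X_target biomass level (g/L), in `(X_0, X_sup)`.
#' @param horizon cap (hr) on the searched time interval (default 1e4).
#' @return crossing time (hr).
#' @export
biomass_crossing_time <- function(model, p, bc, X_target,
                                  settings = integrator_settings(),
                                  horizon = 1e4) {
  model <- model_kind(model)
  p <- as_growth_parameters(p); bc <- as_batch_conditions(bc)
  if (X_target < bc$X_0)
    stop("X_target below the initial biomass X_0", call. = FALSE)
  if (X_target == bc$X_0) return(0)
  X_sup <- biomass_supremum(model, p, bc)
  unreachable <- function(msg)
    stop(structure(class = c("hybridgrowth_unreachable", "error", "condition"),
                   list(message = msg, call = NULL)))
  if (X_target >= X_sup)
    unreachable(sprintf("biomass target %g g/L is at or above the reachable supremum %g g/L",
                        X_target, X_sup))
  f <- batch_ode_fn(model, p)
  max_step <- if (is.null(settings$max_step)) horizon / 1e4 * 100 else settings$max_step
  max_step <- min(max_step, horizon / 100)
  t <- 0; y <- c(bc$X_0, bc$S_0); k1 <- f(t, y)
  h <- min(max_step, 1e-3)
  while (t < horizon) {
    h <- min(h, max_step, horizon - t)
    st <- dp_step(f, t, y, h, k1, settings$rel_tol, settings$abs_tol)
    if (st$err <= 1) {
      t_prev <- t; y_prev <- y
      t <- t + h; y <- st$y_new; k1 <- st$k_last
      if (y[1] >= X_target) {
        # refine inside [t_prev, t] by re-integrating from the step start
        g <- function(tau) {
          if (tau <= t_prev) return(y_prev[1] - X_target)
          dp_integrate(f, t_prev, y_prev, tau, settings$rel_tol,
                       settings$abs_tol, max_step)[1, 1] - X_target
        }
        r <- stats::uniroot(g, lower = t_prev, upper = t,
                            f.lower = y_prev[1] - X_target,
                            f.upper = y[1] - X_target,
                            tol = min(1e-13 * max(1, t), settings$event_tolerance))
        return(r$root)
      }
      h <- h * min(5, max(0.2, 0.9 * (max(st$err, 1e-16))^(-0.2)))
    } else {
      h <- h * max(0.1, 0.9 * st$err^(-0.2))
    }
    if (h < 1e-14 * max(1, t))
      stop("step-size collapse during event search at t = ", format(t), call. = FALSE)
  }
  unreachable(sprintf("biomass target %g g/L not reached within the %g hr horizon",
                      X_target, horizon))
}
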