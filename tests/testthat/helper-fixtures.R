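# Shared parameter sets: the batch-figure set (X_m = 12.5 g/L, Y_xs = 0.5,
# K_s = 4 g/L, S_0 = 25 g/L, X_0 = 0.25 g/L; mu_max is user-chosen, 0.5/hr
# here) and the CSTR-figure set (mu_max = 1.6/hr, X_m = 10 g/L, K_s = 1 g/L,
# S_F = 20 g/L, Y_xs 0.3 or 0.8).

batch_fig_params <- function(mu_max = 0.5) {
  growth_parameters(mu_max = mu_max, K_s = 4, X_m = 12.5, Y_xs = 0.5)
}

batch_fig_bc <- function() batch_conditions(X_0 = 0.25, S_0 = 25)

cstr_fig_params <- function(Y_xs = 0.8) {
  growth_parameters(mu_max = 1.6, K_s = 1, X_m = 10, Y_xs = Y_xs)
}

cstr_fig_SF <- 20

# Feasible parameter grid for analytic-vs-numeric sweeps: X_m chosen inside
# the substrate-supported bound so every law's trajectory is well-posed.
oracle_grid <- function() {
  g <- expand.grid(mu_max = c(0.2, 0.8, 1.6),
                   K_s = c(0.5, 4, 10),
                   Y_xs = c(0.3, 0.5, 0.8))
  g$X_m <- 0.9 * (0.25 + g$Y_xs * 25)
  g
}

expect_close <- function(actual, expected, tol, label = NULL) {
  expect_true(max(abs(actual - expected)) <= tol,
              info = paste0(label, ": max abs diff ",
                            format(max(abs(actual - expected))),
                            " > ", format(tol)))
}
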