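p_fig <- batch_fig_params()
bc_fig <- batch_fig_bc()

test_that("explicit logistic solution: anchors, asymptote, overflow safety", {
  expect_equal(logistic_biomass(p_fig, bc_fig, 0), bc_fig$X_0)
  # asymptote reached to >= 10 significant digits at t = 200 hr
  expect_equal(logistic_biomass(p_fig, bc_fig, 200), p_fig$X_m,
               tolerance = 1e-11)
  # hand-derived interior point: X_0 = X_m/2, t = ln(3)/mu -> (3/4) X_m
  bc_half <- batch_conditions(p_fig$X_m / 2, 25)
  expect_equal(logistic_biomass(p_fig, bc_half, log(3) / p_fig$mu_max),
               0.75 * p_fig$X_m)
  # overflow-safe for huge mu*t
  expect_equal(logistic_biomass(p_fig, bc_fig, 1e6), p_fig$X_m)
})

test_that("logistic substrate follows conservation and flags over-capacity", {
  expect_equal(logistic_substrate(p_fig, bc_fig, 0), bc_fig$S_0)
  # asymptote: S_0 - (X_m - X_0)/Y_xs = 0.5 g/L leftover
  expect_equal(logistic_substrate(p_fig, bc_fig, 1e4),
               bc_fig$S_0 - (p_fig$X_m - bc_fig$X_0) / p_fig$Y_xs)
  expect_equal(logistic_substrate(p_fig, bc_fig, 1e4), 0.5)
  tt <- seq(0, 30, length.out = 40)
  X <- logistic_biomass(p_fig, bc_fig, tt)
  S <- logistic_substrate(p_fig, bc_fig, tt)
  expect_close(S, bc_fig$S_0 - (X - bc_fig$X_0) / p_fig$Y_xs, 1e-10,
               "conservation form")
  # carrying capacity above what substrate supports: negative S + warning
  p_over <- growth_parameters(0.5, 4, 20, 0.5)
  expect_warning(S_neg <- logistic_substrate(p_over, bc_fig, 100), "negative")
  expect_lt(S_neg, 0)
})

test_that("implicit time-of-biomass relations anchor at X_0 and match the ODE oracle", {
  expect_equal(monod_time_of_biomass(p_fig, bc_fig, bc_fig$X_0), 0)
  expect_equal(hybrid_time_of_biomass(p_fig, bc_fig, bc_fig$X_0), 0)
  # event-detection oracle agreement (rel tol 1e-6)
  t6 <- monod_time_of_biomass(p_fig, bc_fig, 6)
  t6_num <- biomass_crossing_time("monod", p_fig, bc_fig, 6)
  expect_lt(abs(t6 - t6_num) / t6, 1e-6)
  t10 <- hybrid_time_of_biomass(p_fig, bc_fig, 10)
  t10_num <- biomass_crossing_time("hybrid", p_fig, bc_fig, 10)
  expect_lt(abs(t10 - t10_num) / t10, 1e-6)
  # strictly increasing in X
  Xs <- seq(0.3, 12, length.out = 50)
  expect_true(all(diff(hybrid_time_of_biomass(p_fig, bc_fig, Xs)) > 0))
  expect_true(all(diff(monod_time_of_biomass(p_fig, bc_fig, Xs)) > 0))
  # domain errors name the reachable interval
  expect_error(monod_time_of_biomass(p_fig, bc_fig, 12.8), "reachable")
  expect_error(hybrid_time_of_biomass(p_fig, bc_fig, 12.5), "reachable")
  expect_error(hybrid_time_of_biomass(p_fig, bc_fig, 0.1), "reachable")
})

test_that("hybrid relation collapses to the closed-form logistic inverse as K_s -> 0", {
  p_k0 <- growth_parameters(0.5, 1e-9, 12.5, 0.5)
  Xs <- seq(0.3, 12.4, length.out = 30)
  t_hyb <- hybrid_time_of_biomass(p_k0, bc_fig, Xs)
  t_log <- (1 / p_fig$mu_max) *
    log(Xs * (p_fig$X_m - bc_fig$X_0) / (bc_fig$X_0 * (p_fig$X_m - Xs)))
  expect_lt(max(abs(t_hyb - t_log) / t_log), 1e-5)
})

test_that("degenerate hybrid configuration X_m = X_0 + Y_xs*S_0 is perturbed with a warning", {
  p_deg <- growth_parameters(0.5, 4, 12.75, 0.5)  # exactly X_0 + Y_xs*S_0
  expect_warning(t5 <- hybrid_time_of_biomass(p_deg, bc_fig, 5), "degenerate")
  t5_num <- biomass_crossing_time("hybrid", p_deg, bc_fig, 5)
  expect_lt(abs(t5 - t5_num) / t5, 1e-4)
})

test_that("biomass_at_time inverts the implicit relations and honours asymptotes", {
  for (m in MODEL_KINDS)
    expect_equal(biomass_at_time(m, p_fig, bc_fig, 0), bc_fig$X_0)
  # round trip t -> X -> t (times where the state is resolvable in doubles;
  # beyond ~20 hr the Monod curve sits within machine eps of its asymptote)
  tg_h <- seq(0.3, 30, length.out = 25)
  Xh <- biomass_at_time("hybrid", p_fig, bc_fig, tg_h)
  expect_lt(max(abs(time_of_biomass("hybrid", p_fig, bc_fig, Xh) - tg_h) / tg_h),
            1e-8)
  tg_m <- seq(0.3, 15, length.out = 25)
  Xm_ <- biomass_at_time("monod", p_fig, bc_fig, tg_m)
  expect_lt(max(abs(time_of_biomass("monod", p_fig, bc_fig, Xm_) - tg_m) / tg_m),
            1e-8)
  # hybrid asymptote: X_sup = X_m = 12.5 here (12.5 < 12.75)
  expect_equal(biomass_at_time("hybrid", p_fig, bc_fig, 200), 12.5,
               tolerance = 1e-4)
  # monod asymptote: all substrate converted
  expect_equal(biomass_at_time("monod", p_fig, bc_fig, 200),
               bc_fig$X_0 + p_fig$Y_xs * bc_fig$S_0, tolerance = 1e-6)
})

test_that("substrate_at_time matches conservation, depletion and leftover", {
  for (m in MODEL_KINDS)
    expect_equal(substrate_at_time(m, p_fig, bc_fig, 0), bc_fig$S_0)
  # hybrid leftover 25 - (12.5 - 0.25)/0.5 = 0.5 g/L
  expect_equal(substrate_at_time("hybrid", p_fig, bc_fig, 400), 0.5,
               tolerance = 1e-4)
  # Monod consumes everything
  expect_equal(substrate_at_time("monod", p_fig, bc_fig, 200), 0,
               tolerance = 1e-6)
  expect_gte(substrate_at_time("monod", p_fig, bc_fig, 200), 0)
})

test_that("sampled trajectories are monotone, conservative and oracle-accurate", {
  g1 <- sample_trajectory("hybrid", p_fig, bc_fig, 0)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$biomass_g_L, bc_fig$X_0)
  expect_equal(g1$substrate_g_L, bc_fig$S_0)
  expect_equal(g1$mu_per_hr,
               specific_growth_rate("hybrid", p_fig, bc_fig$S_0, bc_fig$X_0))
  grid <- seq(0, 25, length.out = 100)
  for (m in MODEL_KINDS) {
    traj <- sample_trajectory(m, p_fig, bc_fig, grid)
    expect_equal(attr(traj, "provenance"), "analytic")
    expect_true(all(diff(traj$biomass_g_L) >= 0))
    expect_close(traj$biomass_g_L - bc_fig$X_0,
                 p_fig$Y_xs * (bc_fig$S_0 - traj$substrate_g_L), 1e-9,
                 paste(m, "conservation"))
    num <- integrate_batch(m, p_fig, bc_fig, grid)
    expect_close(traj$biomass_g_L, num$biomass_g_L, 1e-6,
                 paste(m, "vs oracle"))
  }
  expect_error(sample_trajectory("hybrid", p_fig, bc_fig, c(0, 2, 1)),
               "increasing")
})

test_that("implicit_solution exposes the monotone map and the correct supremum", {
  sol_m <- implicit_solution("monod", p_fig, bc_fig)
  sol_h <- implicit_solution("hybrid", p_fig, bc_fig)
  expect_equal(sol_m$X_sup, bc_fig$X_0 + p_fig$Y_xs * bc_fig$S_0)
  expect_equal(sol_h$X_sup, min(p_fig$X_m, bc_fig$X_0 + p_fig$Y_xs * bc_fig$S_0))
  expect_equal(sol_h$t_of_X(bc_fig$X_0), 0)
  # t -> +Inf approaching the supremum
  expect_gt(sol_h$t_of_X(sol_h$X_sup * (1 - 1e-12)), 100)
})

test_that("trajectory CSV round-trips losslessly to 12 significant digits", {
  grid <- seq(0, 20, length.out = 15)
  traj <- sample_trajectory("hybrid", p_fig, bc_fig, grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(names(back),
               c("time_hr", "biomass_g_L", "substrate_g_L", "mu_per_hr"))
  for (col in names(back))
    expect_close(back[[col]], traj[[col]],
                 max(abs(traj[[col]])) * 1e-11 + 1e-15, col)
})
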