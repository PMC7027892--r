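p_hi <- cstr_fig_params(Y_xs = 0.8)   # high-yield regime
p_lo <- cstr_fig_params(Y_xs = 0.3)   # low-yield regime

# residuals of the two steady-state mass balances at a solved state
balance_residuals <- function(model, p, ss) {
  mu <- specific_growth_rate(model, p, S = max(ss$S_star, 0),
                             X = max(ss$X_star, 0))
  c(growth = (mu - ss$D) * ss$X_star,
    substrate = ss$D * (ss$S_F - ss$S_star) - mu * ss$X_star / p$Y_xs)
}

test_that("steady states hit their closed-form anchors", {
  # Monod, D -> 0: complete conversion
  ss <- steady_state("monod", p_hi, cstr_conditions(1e-9, cstr_fig_SF))
  expect_lt(ss$S_star, 1e-8)
  expect_equal(ss$X_star, p_hi$Y_xs * cstr_fig_SF, tolerance = 1e-8)
  ss0 <- steady_state("monod", p_hi, cstr_conditions(0, cstr_fig_SF))
  expect_equal(ss0$S_star, 0)
  # Logistic at D = mu_max/2: X* = X_m/2 by linearity
  ss <- suppressWarnings(
    steady_state("logistic", p_hi, cstr_conditions(p_hi$mu_max / 2, cstr_fig_SF)))
  expect_equal(ss$X_star, p_hi$X_m / 2)
  # hybrid at D -> 0 with Y_xs = 0.8: carrying capacity binds (Y_xs*S_F = 16 > 10)
  ss <- steady_state("hybrid", p_hi, cstr_conditions(1e-10, cstr_fig_SF))
  expect_equal(ss$X_star, p_hi$X_m, tolerance = 1e-6)
  ss0 <- steady_state("hybrid", p_hi, cstr_conditions(0, cstr_fig_SF))
  expect_equal(ss0$X_star, p_hi$X_m)
  expect_equal(ss0$productivity, 0)
})

test_that("nontrivial steady states satisfy both mass balances to 1e-10", {
  for (p in list(p_hi, p_lo)) {
    D_w <- washout_dilution("hybrid", p, cstr_fig_SF)
    for (D in seq(0.05, 0.95, by = 0.1) * D_w) {
      for (m in MODEL_KINDS) {
        ss <- tryCatch(
          suppressWarnings(steady_state(m, p, cstr_conditions(D, cstr_fig_SF))),
          error = function(e) NULL)  # infeasible logistic configs skip
        if (is.null(ss) || ss$branch == "washout") next
        expect_lt(max(abs(balance_residuals(m, p, ss))), 1e-10)
        expect_true(ss$S_star >= -1e-9 && ss$S_star <= ss$S_F + 1e-9)
        expect_true(ss$X_star >= -1e-9 &&
                      ss$X_star <= p$Y_xs * ss$S_F + 1e-9)
      }
    }
  }
})

test_that("washout dilution rates match their closed forms and flip the branch", {
  # CSTR-figure parameters: logistic washout at mu_max = 1.6/hr
  expect_equal(washout_dilution("logistic", p_hi, cstr_fig_SF), 1.6)
  # Monod: mu_max S_F/(K_s + S_F) = 1.6 * 20/21
  expect_equal(washout_dilution("monod", p_hi, cstr_fig_SF), 1.6 * 20 / 21)
  # hybrid washout equals Monod washout whatever X_m (logistic factor is 1 at X = 0)
  for (Xm in c(2, 10, 50, 1e6)) {
    p <- growth_parameters(1.6, 1, Xm, 0.8)
    expect_equal(washout_dilution("hybrid", p, cstr_fig_SF),
                 washout_dilution("monod", p, cstr_fig_SF))
  }
  # branch switches exactly at D_w (within 1e-9)
  for (m in MODEL_KINDS) {
    D_w <- washout_dilution(m, p_hi, cstr_fig_SF)
    below <- suppressWarnings(
      steady_state(m, p_hi, cstr_conditions(D_w - 1e-9, cstr_fig_SF)))
    above <- suppressWarnings(
      steady_state(m, p_hi, cstr_conditions(D_w + 1e-9, cstr_fig_SF)))
    expect_equal(below$branch, "nontrivial")
    expect_equal(above$branch, "washout")
    expect_equal(above$X_star, 0)
    expect_equal(above$S_star, cstr_fig_SF)
  }
  # bisection on X*(D) = 0 recovers the closed form (independent check)
  for (m in c("monod", "hybrid")) {
    xstar <- function(D) suppressWarnings(
      steady_state(m, p_hi, cstr_conditions(D, cstr_fig_SF)))$X_star
    D_bis <- uniroot(function(D) xstar(D) - 1e-12, c(0.1, 1.6),
                     tol = 1e-12)$root
    expect_equal(D_bis, washout_dilution(m, p_hi, cstr_fig_SF),
                 tolerance = 1e-8)
  }
})

test_that("optimal dilution maximizes productivity for every law", {
  # logistic: vertex of the productivity parabola
  da <- optimal_dilution("logistic", p_hi, cstr_fig_SF)
  expect_equal(da$D_optimal, p_hi$mu_max / 2)
  expect_equal(da$P_max, p_hi$mu_max * p_hi$X_m / 4)
  # Monod closed form vs independent numeric maximization
  da_m <- optimal_dilution("monod", p_hi, cstr_fig_SF)
  expect_equal(da_m$D_optimal,
               p_hi$mu_max * (1 - sqrt(p_hi$K_s / (p_hi$K_s + cstr_fig_SF))))
  opt <- optimize(function(D)
    steady_state("monod", p_hi, cstr_conditions(D, cstr_fig_SF))$productivity,
    c(1e-6, da_m$D_washout), maximum = TRUE, tol = 1e-10)
  expect_lt(abs(opt$maximum - da_m$D_optimal) / da_m$D_optimal, 1e-6)
  # hybrid with enormous X_m reduces to Monod
  p_big <- growth_parameters(1.6, 1, 1e9, 0.8)
  da_h <- suppressWarnings(optimal_dilution("hybrid", p_big, cstr_fig_SF))
  expect_lt(abs(da_h$D_optimal - da_m$D_optimal) / da_m$D_optimal, 1e-6)
  # P(D_opt) dominates a 1000-point grid, all three laws
  for (m in MODEL_KINDS) {
    da <- suppressWarnings(optimal_dilution(m, p_hi, cstr_fig_SF))
    expect_true(da$D_optimal > 0 && da$D_optimal < da$D_washout)
    grid <- seq(da$D_washout * 1e-3, da$D_washout * (1 - 1e-6),
                length.out = 1000)
    P <- vapply(grid, function(D) suppressWarnings(
      steady_state(m, p_hi, cstr_conditions(D, cstr_fig_SF)))$productivity,
      numeric(1))
    expect_gte(da$P_max, max(P) - 1e-8)
  }
})

test_that("dilution sweeps are monotone, linear where expected, and carry the branch", {
  grid <- seq(0, 2, length.out = 41)
  for (m in MODEL_KINDS) {
    p <- if (m == "logistic") p_hi else p_lo  # logistic needs X_m <= Y_xs S_F
    sw <- suppressWarnings(dilution_sweep(m, p, cstr_fig_SF, grid))
    nontriv <- sw$branch == "nontrivial"
    expect_true(any(!nontriv))  # grid extends past washout
    expect_true(all(sw$X_star_g_L[!nontriv] == 0))
    expect_true(all(sw$S_star_g_L[!nontriv] == cstr_fig_SF))
    expect_true(all(diff(sw$S_star_g_L[nontriv]) >= -1e-12))
    expect_true(all(diff(sw$X_star_g_L[nontriv]) <= 1e-12))
    expect_equal(sw$productivity_g_L_hr, sw$D_per_hr * sw$X_star_g_L)
  }
  # logistic X*(D) is exactly linear: zero second differences
  sw <- suppressWarnings(
    dilution_sweep("logistic", p_hi, cstr_fig_SF, seq(0.1, 1.5, by = 0.1)))
  expect_lt(max(abs(diff(sw$X_star_g_L, differences = 2))), 1e-12)
  # hybrid mass-balance ratio X*/(S_F - S*) = Y_xs on the nontrivial branch
  sw <- suppressWarnings(
    dilution_sweep("hybrid", p_hi, cstr_fig_SF, seq(0.1, 1.4, by = 0.1)))
  expect_close(sw$X_star_g_L / (cstr_fig_SF - sw$S_star_g_L), p_hi$Y_xs,
               1e-12, "yield ratio")
  expect_error(dilution_sweep("monod", p_hi, cstr_fig_SF, c(0.5, 0.4)),
               "increasing")
})

test_that("the physical root of the hybrid quadratic is the admissible one", {
  set.seed(7)
  combos <- expand.grid(D = seq(0.05, 1.45, length.out = 10),
                        Y_xs = seq(0.25, 1.0, length.out = 10))
  for (i in seq_len(nrow(combos))) {
    D <- combos$D[i]; Y <- combos$Y_xs[i]
    p <- growth_parameters(1.6, 1, 10, Y)
    if (D >= washout_dilution("hybrid", p, cstr_fig_SF)) next
    ss <- suppressWarnings(steady_state("hybrid", p, cstr_conditions(D, cstr_fig_SF)))
    expect_lt(max(abs(balance_residuals("hybrid", p, ss))), 1e-10)
    # the rejected quadratic root is negative, hence outside [0, S_F]
    a <- p$mu_max * Y
    b <- p$mu_max * (p$X_m - Y * cstr_fig_SF) - D * p$X_m
    cq <- -D * p$X_m * p$K_s
    other <- (-b - sqrt(b^2 - 4 * a * cq)) / (2 * a)
    expect_lt(other, 0)
  }
})

test_that("perturbed dynamic CSTR states relax to the closed-form steady state", {
  for (m in MODEL_KINDS) {
    p <- if (m == "logistic") p_hi else p_lo
    cc <- cstr_conditions(0.5, cstr_fig_SF)
    ss <- suppressWarnings(steady_state(m, p, cc))
    relaxed <- hybridgrowth:::integrate_cstr(
      m, p, cc, X0 = ss$X_star * 1.3, S0 = min(ss$S_star * 1.5 + 0.5, 19),
      horizon = 120)
    expect_lt(abs(relaxed$X - ss$X_star), 1e-6)
    expect_lt(abs(relaxed$S - ss$S_star), 1e-6)
  }
})

test_that("infeasible logistic chemostats error instead of clamping", {
  p_bad <- cstr_fig_params(Y_xs = 0.3)  # X_m = 10 > Y_xs S_F = 6
  expect_error(
    suppressWarnings(steady_state("logistic", p_bad, cstr_conditions(0.2, cstr_fig_SF))),
    "X_m <= S_F \\* Y_xs")
  # the same configuration is merely a warning for the hybrid law
  expect_warning(steady_state("hybrid", p_bad, cstr_conditions(0.2, cstr_fig_SF)),
                 "carrying capacity")
})
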