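test_that("view aggregates factorize on uniform states", {
  pars <- default_params()
  mix <- strategy_mix("DISC", p = 0.3)
  st <- reputation_state(mix, pars$structure, init = 1)
  ag <- view_aggregates(st, mix, pars$structure)
  for (x in ag) expect_true(all(abs(x - 1) < 1e-15))

  g <- 0.7; s <- 0.4
  st$g_ind[] <- g; st$g_st[] <- s
  ag <- view_aggregates(st, mix, pars$structure)
  expect_equal(ag$ga1[1, 2], g^2)
  expect_equal(ag$ga2[2, 1], g * s)
  expect_equal(ag$ga3[1, 1], s * g)
  expect_equal(ag$ga4[2, 2], s^2)
  expect_equal(ag$g_dot, c(g, g))
  expect_equal(ag$g_star, c(s, s))

  # nu-weighted population mean over donor groups
  st$g_ind[, 1, ] <- 0.9; st$g_ind[, 2, ] <- 0.5
  ag <- view_aggregates(st, mix, pars$structure)
  expect_equal(ag$g_dot, c(0.7, 0.7))
})

test_that("update map reproduces the unconditional-strategy recursions", {
  pars <- default_params()  # Stern Judging, u = 0.02
  for (g0 in c(0.2, 0.5, 0.8)) {
    mixD <- strategy_mix("ALLD")
    st <- reputation_state(mixD, pars$structure, init = g0)
    up <- reputation_update_map(st, mixD, pars)
    expect_equal(as.vector(up$g_ind),
                 rep(g0 * 0.02 + (1 - g0) * 0.98, 4), tolerance = 1e-12)
    mixC <- strategy_mix("ALLC")
    st <- reputation_state(mixC, pars$structure, init = g0)
    up <- reputation_update_map(st, mixC, pars)
    eps <- 0.9608
    expect_equal(as.vector(up$g_ind),
                 rep(g0 * eps + (1 - g0) * (1 - eps), 4), tolerance = 1e-12)
  }
})

test_that("monomorphic equilibria match closed forms and a bisection oracle", {
  pars <- default_params()
  # unconditional strategies equilibrate at 1/2 under Stern Judging errors
  for (kind in c("ALLD", "ALLC")) {
    eq <- solve_reputation_equilibrium(strategy_mix(kind), pars)
    expect_true(all(abs(eq$state$g_ind - 0.5) < 1e-8), info = kind)
  }
  # 0DISC under public individual monitoring: g = g P_GC + (1-g) P_BD
  g_pub <- 0.98 / 1.0192
  for (ss in scales3) {
    p2 <- model_params("SternJudging", "public", ss)
    eq <- solve_reputation_equilibrium(strategy_mix("DISC", p = 0), p2)
    expect_true(all(abs(eq$state$g_ind - g_pub) < 1e-8), info = ss)
  }
  # 0DISC under private individual monitoring: cubic solved by bisection
  P <- assessment_probabilities(pars$norm, 0.02, 0.02)
  g_priv <- bisect01(function(g) private_disc0_residual(g, P))
  p3 <- model_params("SternJudging", "private", "private")
  eq <- solve_reputation_equilibrium(strategy_mix("DISC", p = 0), p3)
  expect_true(all(abs(eq$state$g_ind - g_priv) < 1e-8))
})

test_that("equilibria are valid fixed points for random configurations", {
  set.seed(7)
  for (rep in 1:30) {
    mix <- random_mix()
    pars <- random_params()
    eq <- solve_reputation_equilibrium(mix, pars)
    expect_lt(eq$residual, 1e-12)
    expect_true(all(eq$state$g_ind >= 0 & eq$state$g_ind <= 1))
    expect_true(all(eq$state$g_st >= 0 & eq$state$g_st <= 1))
    # re-applying the map moves nothing
    up <- reputation_update_map(eq$state, mix, pars)
    expect_lt(max(abs(up$g_ind - eq$state$g_ind)), 1e-10)
  }
})

test_that("public monitoring collapses observer dependence", {
  set.seed(11)
  for (rep in 1:5) {
    mix <- random_mix()
    pars <- model_params("SternJudging", "public", "public",
                         b = 3, c = 1, u_e = runif(1, 0, 0.1),
                         u_a = runif(1, 0.001, 0.1))
    eq <- solve_reputation_equilibrium(mix, pars)
    expect_lt(max(abs(eq$state$g_ind[, , 1] - eq$state$g_ind[, , 2])), 1e-10)
    expect_lt(max(abs(eq$state$g_st[, 1] - eq$state$g_st[, 2])), 1e-10)
  }
})

test_that("equal groups give group-exchange symmetric equilibria", {
  set.seed(13)
  for (rep in 1:5) {
    mix <- random_mix()
    pars <- random_params()
    eq <- solve_reputation_equilibrium(mix, pars)
    gi <- eq$state$g_ind
    # swap group labels in both donor and observer dimensions
    swapped <- gi[, 2:1, 2:1, drop = FALSE]
    expect_lt(max(abs(gi - swapped)), 1e-9)
    expect_lt(max(abs(eq$state$g_st - eq$state$g_st[2:1, 2:1])), 1e-9)
  }
})

test_that("error-free Stern Judging discrimination sustains an all-good state", {
  pars <- model_params("SternJudging", "public", "public", u_e = 0, u_a = 0)
  for (p in c(0, 0.5, 1)) {
    mix <- strategy_mix("DISC", p = p)
    eq <- solve_reputation_equilibrium(mix, pars,
                                       solver_settings(init = 1))
    expect_true(all(abs(eq$state$g_ind - 1) < 1e-12), info = p)
    expect_true(all(abs(eq$state$g_st - 1) < 1e-12), info = p)
  }
})

test_that("neutral fixed-point families are flagged, not iterated", {
  # error-free unconditional cooperators under Stern Judging: every uniform
  # state is fixed
  pars <- model_params("SternJudging", "public", "public", u_e = 0, u_a = 0)
  eq <- solve_reputation_equilibrium(strategy_mix("ALLC"), pars,
                                     solver_settings(init = 0.37))
  expect_true(eq$neutral)
  expect_true(all(abs(eq$state$g_ind - 0.37) < 1e-12))
})

test_that("reputation tables are tidy and complete", {
  pars <- default_params()
  mix <- strategy_mix(c("ALLD", "DISC"), p = c(0, 0.5), f = c(0.3, 0.7))
  eq <- solve_reputation_equilibrium(mix, pars)
  tab <- reputation_table(eq$state, mix)
  expect_equal(nrow(tab), 2 * 2 * 2 + 2 * 2)
  expect_true(all(tab$g >= 0 & tab$g <= 1))
})
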