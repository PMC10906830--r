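test_that("identical resident and mutant propensities are neutral", {
  set.seed(31)
  for (rep in 1:5) {
    pars <- random_params()
    for (p in c(0, 0.25, 0.6, 1)) {
      expect_lt(abs(invasion_fitness(p, p, pars)$fitness_diff), 1e-10)
    }
  }
})

test_that("the zero-frequency limit agrees with a small-frequency solve", {
  pars <- default_params(eta = 0.3)
  cases <- list(c(0.1, 0.2), c(0.7, 0.5), c(0.4, 0.45))
  for (cs in cases) {
    p_R <- cs[1]; p_Q <- cs[2]
    inv <- invasion_fitness(p_R, p_Q, pars)
    # independent route: two-type equilibrium at mutant frequency 1e-6
    eps <- 1e-6
    mix2 <- strategy_mix(c("DISC", "DISC"), p = c(p_R, p_Q),
                         f = c(1 - eps, eps))
    eq2 <- solve_reputation_equilibrium(mix2, pars)
    fit2 <- strategy_fitness(mix2, eq2$state, pars, eq2$aggregates)
    nu <- pars$structure$nu
    diff2 <- sum(nu * (fit2$Pi[2, ] - fit2$Pi[1, ]))
    expect_equal(inv$fitness_diff, diff2, tolerance = 1e-4)
  }
})

test_that("private monitoring neutralizes stereotype choice except for cost", {
  pars0 <- model_params("SternJudging", "private", "private", eta = 0)
  for (p in seq(0.1, 0.9, by = 0.2)) {
    expect_lt(abs(selection_gradient(p, pars0)), 1e-10)
  }
  # with a positive access cost the gradient is exactly + eta everywhere:
  # reputations and received cooperation are propensity-independent, so only
  # the lookup cost differentiates mutants
  pars2 <- model_params("SternJudging", "private", "private", eta = 0.2)
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(selection_gradient(p, pars2), 0.2, tolerance = 1e-8)
  }
})

test_that("singular-point finder classifies boundaries and interior roots", {
  pars <- default_params(eta = 0.3)
  sp <- find_singular_points(pars, resolution = 51)
  att <- sp[sp$attractive, ]
  expect_equal(att$p_star, 0)           # unique attractor: no stereotyping
  expect_false(any(sp$kind == "interior" & sp$attractive))

  pars35 <- default_params(eta = 0.35)
  sp35 <- find_singular_points(pars35, resolution = 101)
  int_att <- sp35[sp35$kind == "interior" & sp35$attractive, ]
  int_rep <- sp35[sp35$kind == "interior" & !sp35$attractive, ]
  expect_equal(nrow(int_att), 1)        # high-stereotyping attractor appears
  expect_equal(nrow(int_rep), 1)        # separated from p = 0 by a repeller
  expect_lt(int_rep$p_star, int_att$p_star)
  expect_true(0 %in% sp35$p_star[sp35$attractive])
})

test_that("group-wise monitoring produces bistability via an interior repeller", {
  pars <- model_params("SternJudging", "group-wise", "group-wise", eta = 0.3)
  sp <- find_singular_points(pars, resolution = 51)
  expect_true(any(sp$p_star == 0 & sp$attractive))
  expect_true(any(sp$p_star == 1 & sp$attractive))
  expect_true(any(sp$kind == "interior" & !sp$attractive))
})

test_that("PIP grids are neutral on the diagonal and consistent with gradients", {
  pars <- default_params(eta = 0.3)
  pg <- pip_grid(pars, resolution = 21)
  expect_false(any(diag(pg$invades)))
  # near-diagonal invasion direction matches the selection gradient sign
  for (r in c(3, 9, 15)) {
    g <- selection_gradient(pg$p[r], pars)
    expect_equal(unname(pg$invades[r, r + 1]), g > 0)
    expect_equal(unname(pg$invades[r, r - 1]), g < 0)
  }
})

test_that("a fixed defector background leaves the propensity dynamics intact", {
  bg <- list(kind = "ALLD", f = 0.2)
  pars <- default_params(eta = 0.1)
  expect_lt(abs(invasion_fitness(0.3, 0.3, pars, background = bg)$fitness_diff),
            1e-10)
  sp_bg <- find_singular_points(pars, background = bg, resolution = 51)
  sp_no <- find_singular_points(pars, resolution = 51)
  # same qualitative regime: p = 0 is the unique attractor in both
  expect_equal(sp_bg$p_star[sp_bg$attractive], 0)
  expect_equal(sp_no$p_star[sp_no$attractive], 0)
  # cooperation is lower when a fifth of the population always defects
  expect_lt(sp_bg$cooperation[sp_bg$p_star == 0],
            sp_no$cooperation[sp_no$p_star == 0])
})

test_that("bifurcation sweeps recover the private-monitoring regimes", {
  pars <- model_params("SternJudging", "private", "private")
  sw <- bifurcation_sweep(pars, "eta", c(0, 0.1, 0.5), resolution = 51)
  # eta = 0: selection is flat; eta > 0: full stereotyping is the attractor
  expect_equal(sw$regime[sw$value == 0][1], "neutral")
  for (v in c(0.1, 0.5)) {
    att <- sw[sw$value == v & sw$attractive %in% TRUE, ]
    expect_equal(att$p_star, 1)
  }
})
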