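test_that("discriminator fitness matches the public-monitoring closed form", {
  pars <- default_params(eta = 0)
  mix <- strategy_mix("DISC", p = 0)
  eq <- solve_reputation_equilibrium(mix, pars)
  fit <- strategy_fitness(mix, eq$state, pars, eq$aggregates)
  g_star <- 0.98 / 1.0192
  expect_equal(as.vector(fit$Pi), rep(0.98 * (3 - 1) * g_star, 2),
               tolerance = 1e-10)
  expect_equal(fit$Pi_bar, as.vector(fit$Pi), tolerance = 1e-12)
})

test_that("access cost enters fitness only through -eta (1 - p)", {
  set.seed(3)
  for (p in c(0, 0.4, 1)) {
    mix <- strategy_mix("DISC", p = p)
    pars0 <- default_params(eta = 0.2)
    pars1 <- default_params(eta = 0.35)
    eq <- solve_reputation_equilibrium(mix, pars0)
    f0 <- strategy_fitness(mix, eq$state, pars0, eq$aggregates)
    f1 <- strategy_fitness(mix, eq$state, pars1, eq$aggregates)
    slope <- unname((f1$Pi[1, 1] - f0$Pi[1, 1]) / (0.35 - 0.2))
    expect_equal(slope, -(1 - p), tolerance = 1e-10)
  }
})

test_that("a population of defectors earns nothing and cooperates never", {
  pars <- default_params()
  mix <- strategy_mix("ALLD")
  eq <- solve_reputation_equilibrium(mix, pars)
  fit <- strategy_fitness(mix, eq$state, pars, eq$aggregates)
  expect_equal(as.vector(fit$Pi), c(0, 0))
  cr <- cooperation_rates(mix, eq$state, pars, eq$aggregates)
  expect_equal(cr$overall, 0)
})

test_that("cooperation rates are invariant to payoff parameters", {
  set.seed(19)
  mix <- strategy_mix(c("ALLC", "DISC"), p = c(0, 0.6), f = c(0.3, 0.7))
  base <- NULL
  for (rep in 1:5) {
    b <- runif(1, 2, 6)
    pars <- model_params("SternJudging", "group-wise", "public",
                         b = b, c = runif(1, 0.1, b - 1),
                         eta = runif(1, 0, 2))
    eq <- solve_reputation_equilibrium(mix, pars)
    cr <- cooperation_rates(mix, eq$state, pars, eq$aggregates)
    if (is.null(base)) base <- cr
    expect_equal(cr$by_pair, base$by_pair, tolerance = 1e-10)
  }
})

test_that("group-average fitness is the frequency-weighted mean", {
  set.seed(23)
  for (rep in 1:10) {
    mix <- random_mix()
    pars <- random_params()
    eq <- solve_reputation_equilibrium(mix, pars)
    fit <- strategy_fitness(mix, eq$state, pars, eq$aggregates)
    for (I in 1:2) {
      expect_lt(abs(sum(mix$f * (fit$Pi[, I] - fit$Pi_bar[I]))), 1e-12)
    }
  }
})

test_that("cooperation decomposes consistently across group pairs", {
  pars <- default_params()
  mix <- strategy_mix("DISC", p = 0)
  eq <- solve_reputation_equilibrium(mix, pars)
  cr <- cooperation_rates(mix, eq$state, pars, eq$aggregates)
  g_star <- 0.98 / 1.0192
  expect_equal(cr$overall, 0.98 * g_star, tolerance = 1e-9)
  expect_equal(cr$in_group, cr$out_group, tolerance = 1e-12)
  nu <- pars$structure$nu
  expect_equal(cr$overall, sum(outer(nu, nu) * cr$by_pair), tolerance = 1e-14)
})

test_that("in-group favoritism emerges only under group-wise monitoring", {
  mix <- strategy_mix("DISC", p = 0)
  for (sc in c("public", "private")) {
    pars <- model_params("SternJudging", sc, sc)
    eq <- solve_reputation_equilibrium(mix, pars)
    cr <- cooperation_rates(mix, eq$state, pars, eq$aggregates)
    expect_lt(abs(cr$in_group - cr$out_group), 1e-10, )
  }
  pars <- model_params("SternJudging", "group-wise", "group-wise")
  eq <- solve_reputation_equilibrium(mix, pars)
  cr <- cooperation_rates(mix, eq$state, pars, eq$aggregates)
  expect_gt(cr$in_group - cr$out_group, 1e-4)
})

test_that("cooperation curves track monotone branches over p", {
  pars <- model_params("SternJudging", "group-wise", "group-wise")
  curve <- cooperation_curve(pars, seq(0, 1, length.out = 11))
  expect_equal(nrow(curve), 11)
  expect_true(all(curve$overall >= 0 & curve$overall <= 1))
  # symmetric monitoring scales: the two pure strategies do equally well
  expect_equal(curve$overall[1], curve$overall[11], tolerance = 1e-8)
})
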