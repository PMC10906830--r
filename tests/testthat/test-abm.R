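test_that("simulator runs are reproducible given a seed", {
  cfg <- abm_config(N = 20, generations = 3, rounds_per_generation = 10,
                    seed = 99)
  expect_identical(run_abm(cfg), run_abm(cfg))
  expect_identical(run_abm(cfg, engine = "r"), run_abm(cfg, engine = "r"))
})

test_that("view tables have the observer counts implied by each scale", {
  for (sc in scales3) {
    cfg <- abm_config(N = 12, K = 3, individual_scale = sc,
                      stereotype_scale = sc, seed = 1)
    set.seed(1)
    st <- init_population(cfg)
    n_exp <- c(private = 12L, `group-wise` = 3L, public = 1L)[[sc]]
    expect_equal(dim(st$views_ind), c(n_exp, 12))
    expect_equal(dim(st$views_st), c(n_exp, 3))
    expect_true(all(st$views_ind %in% 0:1))
  }
})

test_that("round bookkeeping matches the payoff rules", {
  # all views good, no errors, pure individual lookups: everyone cooperates
  cfg <- abm_config(N = 10, b = 3, c = 1, eta = 0.2, u_e = 0, u_a = 0,
                    p0 = 0, seed = 5)
  set.seed(5)
  st <- init_population(cfg)
  st$views_ind[] <- 1L; st$views_st[] <- 1L
  pr <- play_round(st, cfg)
  expect_true(all(pr$act))
  expect_equal(pr$state$payoff, rep(10 * (3 - 1 - 0.2), 10))
  # pure stereotyping with all views bad: no cooperation, no access cost
  st$views_ind[] <- 0L; st$views_st[] <- 0L
  st$p[] <- 1; st$payoff[] <- 0
  pr <- play_round(st, cfg)
  expect_false(any(pr$act))
  expect_equal(pr$state$payoff, rep(0, 10))
  # individual lookups are charged even when the donor then defects
  st$p[] <- 0
  pr <- play_round(st, cfg)
  expect_equal(pr$state$payoff, rep(-10 * 0.2, 10))
  # conservation: payoff change = (b - c) coops - eta lookups
  st$views_ind[] <- 1L
  st$p[] <- 0.5; st$payoff[] <- 0
  cfg2 <- abm_config(N = 10, b = 3, c = 1, eta = 0.2, u_e = 0.1, p0 = 0.5,
                     seed = 6)
  pr <- play_round(st, cfg2)
  expect_equal(sum(pr$state$payoff),
               (3 - 1) * sum(pr$act) - 0.2 * sum(pr$used_ind),
               tolerance = 1e-10)
})

test_that("execution errors halve realized cooperation at u_e = 1/2", {
  cfg <- abm_config(N = 40, u_e = 0.5, u_a = 0, p0 = 0, seed = 8)
  set.seed(8)
  st <- init_population(cfg)
  st$views_ind[] <- 1L
  coop <- mean(replicate(30, mean(play_round(st, cfg)$act)))
  expect_lt(abs(coop - 0.5), 3 * sqrt(0.25 / (30 * 1600)))
})

test_that("maximal assessment noise yields coin-flip reputations", {
  cfg <- abm_config(N = 30, u_a = 0.5, u_e = 0, p0 = 0, seed = 9)
  set.seed(9)
  st <- init_population(cfg)
  st$views_ind[] <- 1L
  samples <- replicate(200, {
    pr <- play_round(st, cfg)
    mean(update_reputations(pr$state, pr$act, cfg)$views_ind)
  })
  expect_lt(abs(mean(samples) - 0.5), 0.02)
})

test_that("Fermi imitation is neutral at equal payoffs or zero intensity", {
  cfg <- abm_config(N = 30, w = 0, u_s = 0, n_update_pairs = 1, seed = 10)
  set.seed(10)
  st <- init_population(cfg)
  st$p <- runif(30)   # distinct values, so any adoption changes the vector
  # w = 0: adoption probability is 1/2 regardless of payoffs
  pis <- runif(30, 0, 5)
  adopted <- replicate(400, {
    any(imitate_and_mutate(st, pis, cfg)$p != st$p)
  })
  expect_lt(abs(mean(adopted) - 0.5), 0.08)
  # no mutation, homogeneous p: nothing can ever change
  st$p[] <- 0.42
  cfg3 <- abm_config(N = 30, u_s = 0, seed = 11)
  s3 <- imitate_and_mutate(st, pis, cfg3)
  expect_true(all(s3$p == 0.42))
})

test_that("propensities remain probabilities under repeated mutation", {
  cfg <- abm_config(N = 10, u_s = 1, sigma_p = 0.5, n_update_pairs = 0,
                    p0 = 0.5, seed = 12)
  set.seed(12)
  st <- init_population(cfg)
  for (i in 1:200) st <- imitate_and_mutate(st, numeric(10), cfg)
  expect_true(all(st$p >= 0 & st$p <= 1))
})

test_that("compiled and reference engines agree on fixed-p cooperation", {
  cfg <- abm_config(N = 50, p0 = 0.3, eta = 0, rounds_per_generation = 300,
                    generations = 1, seed = 21)
  r_cpp <- run_abm(cfg, evolve = FALSE, record_rounds = TRUE)
  r_r <- run_abm(cfg, evolve = FALSE, record_rounds = TRUE, engine = "r")
  c_cpp <- attr(r_cpp, "round_coop")[101:300]
  c_r <- attr(r_r, "round_coop")[101:300]
  se <- sqrt(stats::var(c_cpp) / 200 + stats::var(c_r) / 200)
  expect_lt(abs(mean(c_cpp) - mean(c_r)), 4 * se + 1e-3)
})

test_that("long-run cooperation matches the mean-field equilibrium", {
  # fixed homogeneous p, no evolution: the stochastic process should hover
  # around the infinite-population cooperation rate
  for (case in list(list(sc = c("public", "public"), p = 0.4),
                    list(sc = c("group-wise", "private"), p = 0.7))) {
    cfg <- abm_config(N = 120, individual_scale = case$sc[1],
                      stereotype_scale = case$sc[2], p0 = case$p,
                      rounds_per_generation = 260, generations = 1, seed = 33)
    rec <- run_abm(cfg, evolve = FALSE, record_rounds = TRUE)
    rc <- attr(rec, "round_coop")[61:260]
    pars <- model_params("SternJudging", case$sc[1], case$sc[2])
    mix <- strategy_mix("DISC", p = case$p)
    eq <- solve_reputation_equilibrium(mix, pars)
    mf <- cooperation_rates(mix, eq$state, pars, eq$aggregates)$overall
    se <- stats::sd(rc) / sqrt(length(rc))
    expect_lt(abs(mean(rc) - mf), 3 * se + 0.01)
  }
})

test_that("replicate runner spawns independent seeded streams", {
  cfg <- abm_config(N = 15, generations = 2, rounds_per_generation = 5,
                    seed = 100)
  rec <- run_abm_replicates(cfg, replicates = 3)
  expect_equal(unique(rec$replicate), 1:3)
  cfg2 <- cfg; cfg2$seed <- 101L
  expect_equal(rec[rec$replicate == 2, -1], run_abm(cfg2),
               ignore_attr = TRUE)
})
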