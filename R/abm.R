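#' Configuration for the finite-population simulator
#'
#' Stochastic counterpart of the mean-field model: N discriminators split
#' across K groups play repeated donation games, observers update binary
#' good/bad views under the configured monitoring scales, and stereotype-use
#' propensities evolve by Fermi pairwise-comparison imitation plus rare local
#' mutation. Defaults follow the study conditions: N = 50, 2500 rounds per
#' generation, 5 imitation pairs, mutation probability u_s = 10/N = 0.2 with
#' normal perturbations of standard deviation 0.05.
#'
#' @param N population size (>= 2).
#' @param K number of groups; agents are assigned to groups in equal blocks.
#' @param norm a \code{social_norm} or norm name.
#' @param individual_scale,stereotype_scale monitoring scales.
#' @param b,c,eta,u_e,u_a payoff and error parameters as in
#'   \code{\link{model_params}}.
#' @param p0 initial stereotype-use propensity shared by all agents.
#' @param rounds_per_generation rounds of games + reputation updates per
#'   generation. The default 2500 gives reputations ample time to equilibrate
#'   within a generation; 100 matches the per-generation payoff normalization
#'   (see \code{games_per_generation}).
#' @param n_update_pairs imitation pairs drawn per generation.
#' @param w selection intensity of the Fermi rule.
#' @param u_s per-generation mutation probability.
#' @param sigma_p mutation standard deviation (perturbations are clipped so p
#'   stays in [0, 1]).
#' @param generations number of generations to simulate.
#' @param games_per_generation payoff normalization: imitation compares
#'   cumulative payoffs rescaled to this many games (default 100), so the
#'   effective selection strength is independent of
#'   \code{rounds_per_generation}.
#' @param sample_every record cadence in generations.
#' @param seed RNG seed.
#' @return object of class \code{abm_config}.
#' @export
abm_config <- function(N = 50L, K = 2L,
                       norm = "SternJudging",
                       individual_scale = "public",
                       stereotype_scale = "public",
                       b = 3, c = 1, eta = 0, u_e = 0.02, u_a = 0.02,
                       p0 = 0.5,
                       rounds_per_generation = 2500L,
                       n_update_pairs = 5L,
                       w = 1,
                       u_s = 10 / N,
                       sigma_p = 0.05,
                       generations = 100L,
                       games_per_generation = 100,
                       sample_every = 1L,
                       seed = 1L) {
  N <- as.integer(N); K <- as.integer(K)
  if (N < 2L) stop("N must be at least 2", call. = FALSE)
  if (K < 1L || K > N) stop("K must be in [1, N]", call. = FALSE)
  if (is.character(norm)) norm <- social_norm(norm)
  check_rate(u_e, "u_e"); check_rate(u_a, "u_a")
  stopifnot(b > c, c > 0, eta >= 0, p0 >= 0, p0 <= 1,
            rounds_per_generation >= 1, n_update_pairs >= 0,
            u_s >= 0, u_s <= 1, sigma_p >= 0, generations >= 1,
            sample_every >= 1)
  structure(list(
    N = N, K = K, norm = norm,
    individual_scale = match_scale(individual_scale),
    stereotype_scale = match_scale(stereotype_scale),
    b = b, c = c, eta = eta, u_e = u_e, u_a = u_a, p0 = p0,
    rounds_per_generation = as.integer(rounds_per_generation),
    n_update_pairs = as.integer(n_update_pairs),
    w = w, u_s = u_s, sigma_p = sigma_p,
    generations = as.integer(generations),
    games_per_generation = games_per_generation,
    sample_every = as.integer(sample_every),
    seed = as.integer(seed)
  ), class = "abm_config")
}

# number of observers (= view rows) implied by a monitoring scale
n_observers <- function(scale, N, K) {
  switch(scale, "public" = 1L, "group-wise" = K, "private" = N)
}

# view row consulted by each agent under a monitoring scale
observer_of_agent <- function(scale, group, N) {
  switch(scale,
    "public"     = rep(1L, N),
    "group-wise" = group,
    "private"    = seq_len(N))
}

#' Initialize the simulator state
#'
#' All agents share the initial propensity \code{p0}; every view bit
#' (individual and stereotyped) is independently good with probability 1/2;
#' payoff accumulators start at zero. Deterministic given the seed carried by
#' the config (the seed is applied by \code{\link{run_abm}}; calling this
#' directly draws from the current RNG stream).
#'
#' @param config an \code{abm_config}.
#' @return list with elements \code{p}, \code{group}, \code{views_ind}
#'   (n_observers x N binary matrix), \code{views_st} (n_observers x K),
#'   \code{payoff}.
#' @export
init_population <- function(config) {
  N <- config$N; K <- config$K
  group <- sort(rep_len(seq_len(K), N))  # equal contiguous blocks
  noi <- n_observers(config$individual_scale, N, K)
  nos <- n_observers(config$stereotype_scale, N, K)
  list(
    p = rep(config$p0, N),
    group = group,
    views_ind = matrix(as.integer(stats::runif(noi * N) < 0.5), noi, N),
    views_st  = matrix(as.integer(stats::runif(nos * K) < 0.5), nos, K),
    payoff = numeric(N)
  )
}

#' Play one round of donation games
#'
#' Every agent interacts with everyone (including herself), once as donor and
#' once as recipient. Each donor consults her individual view of the recipient
#' with probability 1 - p (paying the access cost eta for the lookup, whether
#' or not she then cooperates) and the stereotype of the recipient's group
#' otherwise; she intends to cooperate iff the consulted view is good, and
#' erroneously defects with probability u_e. Donors pay c per realized
#' cooperation; recipients gain b.
#'
#' @param state simulator state from \code{\link{init_population}}.
#' @param config an \code{abm_config}.
#' @return list with updated \code{state}, the realized-action matrix
#'   \code{act} (donors in rows, 1 = cooperated), and the lookup matrix
#'   \code{used_ind}.
#' @export
play_round <- function(state, config) {
  N <- config$N
  oi <- observer_of_agent(config$individual_scale, state$group, N)
  os <- observer_of_agent(config$stereotype_scale, state$group, N)
  ind_view <- state$views_ind[oi, , drop = FALSE]            # [donor, recipient]
  st_view  <- state$views_st[os, state$group, drop = FALSE]  # [donor, recipient]
  used_ind <- matrix(stats::runif(N * N) < rep(1 - state$p, times = N), N, N)
  intend <- ifelse(used_ind, ind_view == 1L, st_view == 1L)
  act <- intend & (stats::runif(N * N) >= config$u_e)
  act <- matrix(act, N, N)
  state$payoff <- state$payoff -
    config$c * rowSums(act) -
    config$eta * rowSums(used_ind) +
    config$b * colSums(act)
  list(state = state, act = act, used_ind = used_ind)
}

#' Synchronous reputation update
#'
#' Each observer required by the individual monitoring scale samples one
#' interaction per donor and assesses the donor's realized action against the
#' observer's own pre-update individual view of the recipient, under the
#' norm; the assignment is flipped with probability u_a. Each observer
#' required by the stereotype scale samples one donor per group and one of
#' her interactions, assessing against the observer's pre-update stereotype
#' of the recipient's group. All views are replaced synchronously.
#'
#' @param state simulator state.
#' @param act realized-action matrix from \code{\link{play_round}}.
#' @param config an \code{abm_config}.
#' @return state with updated \code{views_ind} and \code{views_st}.
#' @export
update_reputations <- function(state, act, config) {
  N <- config$N; K <- config$K
  qC <- config$norm$q_C; qD <- config$norm$q_D
  noi <- nrow(state$views_ind)
  nos <- nrow(state$views_st)

  # individual assessments: (observer, donor) pairs
  rec <- matrix(sample.int(N, noi * N, replace = TRUE), noi, N)
  a <- matrix(act[cbind(rep(seq_len(N), each = noi), as.vector(rec))], noi, N)
  x <- matrix(state$views_ind[cbind(rep(seq_len(noi), N), as.vector(rec))],
              noi, N)
  good_prob <- a * x + a * (1 - x) * qC + (1 - a) * (1 - x) * qD
  assigned <- stats::runif(noi * N) < good_prob
  flip <- stats::runif(noi * N) < config$u_a
  new_ind <- matrix(as.integer(xor(assigned, flip)), noi, N)

  # stereotype assessments: (observer, group) pairs
  new_st <- state$views_st
  donors <- vapply(seq_len(K), function(k) {
    members <- which(state$group == k)
    members[sample.int(length(members), nos, replace = TRUE)]
  }, integer(nos))
  donors <- matrix(donors, nos, K)
  rec_s <- matrix(sample.int(N, nos * K, replace = TRUE), nos, K)
  a_s <- matrix(act[cbind(as.vector(donors), as.vector(rec_s))], nos, K)
  x_s <- matrix(state$views_st[cbind(rep(seq_len(nos), K),
                                     state$group[as.vector(rec_s)])], nos, K)
  good_prob_s <- a_s * x_s + a_s * (1 - x_s) * qC + (1 - a_s) * (1 - x_s) * qD
  assigned_s <- stats::runif(nos * K) < good_prob_s
  flip_s <- stats::runif(nos * K) < config$u_a
  new_st <- matrix(as.integer(xor(assigned_s, flip_s)), nos, K)

  state$views_ind <- new_ind
  state$views_st <- new_st
  state
}

#' Fermi imitation and local mutation of p
#'
#' Draws \code{n_update_pairs} ordered pairs (i, j); j adopts i's propensity
#' with probability \eqn{1 / (1 + e^{-w (\pi_i - \pi_j)})}. Then, with
#' probability u_s, one random agent's propensity is perturbed by a
#' Normal(0, sigma_p^2) deviate, clipped to [0, 1].
#'
#' @param state simulator state.
#' @param pi_gen per-agent generation payoffs used for comparison.
#' @param config an \code{abm_config}.
#' @return state with updated \code{p}.
#' @export
imitate_and_mutate <- function(state, pi_gen, config) {
  N <- config$N
  for (k in seq_len(config$n_update_pairs)) {
    pair <- sample.int(N, 2L)
    i <- pair[1]; j <- pair[2]
    prob <- 1 / (1 + exp(-config$w * (pi_gen[i] - pi_gen[j])))
    if (stats::runif(1) < prob) state$p[j] <- state$p[i]
  }
  if (stats::runif(1) < config$u_s) {
    m <- sample.int(N, 1L)
    state$p[m] <- min(1, max(0, state$p[m] +
                               stats::rnorm(1, 0, config$sigma_p)))
  }
  state
}

#' Run the finite-population simulation
#'
#' Full generation loop: \code{rounds_per_generation} rounds of games and
#' synchronous reputation updates, then Fermi imitation over per-generation
#' payoffs (cumulative payoff rescaled to \code{games_per_generation} games)
#' and local mutation of p. Reproducible given the seed.
#'
#' @param config an \code{abm_config}.
#' @param evolve if FALSE, imitation and mutation are switched off (fixed,
#'   homogeneous p), which is the mode used to compare realized cooperation
#'   against the mean-field prediction.
#' @param record_rounds if TRUE, also return the per-round cooperation
#'   fractions of the final generation (useful for burn-in analysis).
#' @param engine \code{"cpp"} (default) runs the compiled generation loop;
#'   \code{"r"} runs the pure-R reference loop built from
#'   \code{\link{play_round}}, \code{\link{update_reputations}} and
#'   \code{\link{imitate_and_mutate}}. Both consume R's RNG, so each is
#'   reproducible given the seed, but their random streams (and hence exact
#'   trajectories) differ.
#' @return data.frame with one row per sampled generation: generation,
#'   mean_p, sd_p, coop, mean_payoff. When \code{record_rounds} is TRUE the
#'   data.frame carries the final generation's per-round cooperation vector as
#'   attribute \code{"round_coop"}.
#' @export
run_abm <- function(config, evolve = TRUE, record_rounds = FALSE,
                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  set.seed(config$seed)
  if (engine == "cpp") {
    N <- config$N; K <- config$K
    group <- sort(rep_len(seq_len(K), N))
    out <- .abm_run_cpp(
      N = N, K = K, qC = config$norm$q_C, qD = config$norm$q_D,
      noi = n_observers(config$individual_scale, N, K),
      nos = n_observers(config$stereotype_scale, N, K),
      obs_ind = observer_of_agent(config$individual_scale, group, N) - 1L,
      obs_st = observer_of_agent(config$stereotype_scale, group, N) - 1L,
      group = group - 1L,
      b = config$b, c = config$c, eta = config$eta,
      ue = config$u_e, ua = config$u_a, p0 = config$p0,
      rounds = config$rounds_per_generation,
      pairs = config$n_update_pairs, w = config$w,
      us = config$u_s, sigma_p = config$sigma_p,
      generations = config$generations,
      games_norm = config$games_per_generation,
      sample_every = config$sample_every,
      evolve = evolve, record_rounds = record_rounds)
    rec <- out$records
    if (record_rounds) attr(rec, "round_coop") <- out$round_coop
    return(rec)
  }
  state <- init_population(config)
  N <- config$N
  R <- config$rounds_per_generation
  records <- vector("list", config$generations %/% config$sample_every + 1L)
  nrec <- 0L
  round_coop <- NULL
  for (gen in seq_len(config$generations)) {
    state$payoff <- numeric(N)
    coop_acts <- 0
    if (record_rounds && gen == config$generations) {
      round_coop <- numeric(R)
    }
    for (r in seq_len(R)) {
      pr <- play_round(state, config)
      state <- pr$state
      coop_acts <- coop_acts + sum(pr$act)
      if (!is.null(round_coop)) round_coop[r] <- mean(pr$act)
      state <- update_reputations(state, pr$act, config)
    }
    pi_gen <- state$payoff / (R * N) * config$games_per_generation
    coop_frac <- coop_acts / (R * N * N)
    if (evolve) state <- imitate_and_mutate(state, pi_gen, config)
    if (gen %% config$sample_every == 0L) {
      nrec <- nrec + 1L
      records[[nrec]] <- data.frame(
        generation = gen, mean_p = mean(state$p), sd_p = stats::sd(state$p),
        coop = coop_frac, mean_payoff = mean(pi_gen))
    }
  }
  out <- do.call(rbind, records[seq_len(nrec)])
  if (record_rounds) attr(out, "round_coop") <- round_coop
  out
}

#' Run replicate simulations with independent seeds
#'
#' @param config an \code{abm_config}; replicate r uses seed
#'   \code{config$seed + r - 1}.
#' @param replicates number of replicates.
#' @param ... passed to \code{\link{run_abm}}.
#' @return data.frame stacking the replicate records with a leading
#'   \code{replicate} column.
#' @export
run_abm_replicates <- function(config, replicates = 10L, ...) {
  rows <- lapply(seq_len(replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    cbind(replicate = r, run_abm(cfg, ...))
  })
  do.call(rbind, rows)
}
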