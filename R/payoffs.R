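#' Strategy fitness at a reputation equilibrium
#'
#' Expected per-round payoff of each strategy in each group. A focal
#' individual of strategy s in group I receives b from every donor who
#' (intends to) cooperate with her — unconditional cooperators always, a
#' discriminator with propensity p_i with probability
#' \code{(1 - p_i) g_s^{I,J} + p_i g_S^{I,J}} (her individual standing or her
#' group's stereotype in the donor group's eyes), an in-group cooperator
#' (TAG) iff she shares its group — and pays c whenever she herself intends to
#' cooperate, plus the access cost eta for every individual-reputation lookup.
#' Intended cooperation fails with probability u_e, which scales both the
#' benefit and cost terms; the access cost is paid regardless.
#'
#' @param mix a \code{strategy_mix}.
#' @param state an equilibrium \code{reputation_state} for \code{(mix, params)}.
#' @param params a \code{model_params}.
#' @param aggregates optional precomputed \code{\link{view_aggregates}}.
#' @return list with \code{Pi} (n_strategies x K matrix of per-round payoffs,
#'   groups in columns) and \code{Pi_bar} (length-K vector of f-weighted group
#'   averages).
#' @export
strategy_fitness <- function(mix, state, params, aggregates = NULL) {
  st <- params$structure
  K  <- st$K
  nu <- st$nu
  n  <- length(mix$kinds)
  ag <- if (is.null(aggregates)) view_aggregates(state, mix, st) else aggregates
  ue <- params$u_e

  Pi <- matrix(NA_real_, n, K, dimnames = list(mix$labels, NULL))
  for (I in seq_len(K)) {
    for (s in seq_len(n)) {
      # benefit: probability each donor strategy cooperates with the focal
      benefit <- 0
      for (J in seq_len(K)) {
        d <- 0
        for (i in seq_len(n)) {
          d <- d + mix$f[i] * switch(mix$kinds[i],
            ALLC = 1,
            ALLD = 0,
            DISC = (1 - mix$p[i]) * state$g_ind[s, I, J] +
                   mix$p[i] * state$g_st[I, J],
            TAG  = as.numeric(J == I))
        }
        benefit <- benefit + nu[J] * d
      }
      cost <- switch(mix$kinds[s],
        ALLC = params$c,
        ALLD = 0,
        DISC = params$c * ((1 - mix$p[s]) * ag$g_dot[I] +
                           mix$p[s] * ag$g_star[I]),
        TAG  = params$c * nu[I])
      access <- if (mix$kinds[s] == "DISC") params$eta * (1 - mix$p[s]) else 0
      Pi[s, I] <- (1 - ue) * (params$b * benefit - cost) - access
    }
  }
  Pi_bar <- as.numeric(mix$f %*% Pi)
  list(Pi = Pi, Pi_bar = Pi_bar)
}

#' Cooperation rates at a reputation equilibrium
#'
#' Probability that a donor from group I cooperates with a random recipient
#' from group J, averaging over donor strategies: a discriminator cooperates
#' when her consulted view — her group's individual view of the recipient with
#' probability 1 - p, the recipient group's stereotype with probability p —
#' is good, degraded by the execution error. These rates are independent of
#' the payoff parameters b, c and eta.
#'
#' @inheritParams strategy_fitness
#' @return list with \code{by_pair} (K x K matrix, donor group in rows),
#'   \code{overall} (nu^2-weighted mean), \code{in_group} and \code{out_group}
#'   (nu-weighted means over the diagonal and off-diagonal pairs; for K = 1
#'   \code{out_group} is NA).
#' @export
cooperation_rates <- function(mix, state, params, aggregates = NULL) {
  st <- params$structure
  K  <- st$K
  nu <- st$nu
  ag <- if (is.null(aggregates)) view_aggregates(state, mix, st) else aggregates
  n  <- length(mix$kinds)

  by_pair <- matrix(0, K, K)  # [donor group I, recipient group J]
  for (I in seq_len(K)) for (J in seq_len(K)) {
    coop <- 0
    for (i in seq_len(n)) {
      coop <- coop + mix$f[i] * switch(mix$kinds[i],
        ALLC = 1,
        ALLD = 0,
        DISC = (1 - mix$p[i]) * ag$g_grp[J, I] + mix$p[i] * state$g_st[J, I],
        TAG  = as.numeric(I == J))
    }
    by_pair[I, J] <- (1 - params$u_e) * coop
  }
  w <- outer(nu, nu)
  overall <- sum(w * by_pair)
  in_group <- sum(diag(w) * diag(by_pair)) / sum(diag(w))
  out_group <- if (K > 1L) {
    off <- w; diag(off) <- 0
    sum(off * by_pair) / sum(off)
  } else NA_real_
  list(by_pair = by_pair, overall = overall,
       in_group = in_group, out_group = out_group)
}

#' Equilibrium cooperation as a function of stereotype propensity
#'
#' Solves the reputation equilibrium of a monomorphic discriminator population
#' for each propensity value on a grid and summarizes cooperation. Equilibria
#' are warm-started along the grid so continuous branches are followed.
#'
#' @param params a \code{model_params}.
#' @param p_grid vector of propensities in [0, 1].
#' @param settings \code{\link{solver_settings}}.
#' @return data.frame with columns p, overall, in_group, out_group.
#' @examples
#' \donttest{
#' pars <- model_params("SternJudging", "public", "group-wise")
#' cooperation_curve(pars, seq(0, 1, 0.25))
#' }
#' @export
cooperation_curve <- function(params, p_grid = seq(0, 1, length.out = 101),
                              settings = solver_settings()) {
  stopifnot(all(p_grid >= 0), all(p_grid <= 1))
  warm <- NULL
  rows <- lapply(p_grid, function(p) {
    mix <- strategy_mix("DISC", p = p)
    eq <- solve_reputation_equilibrium(mix, params, settings, warm_start = warm)
    warm <<- eq$state
    cr <- cooperation_rates(mix, eq$state, params, eq$aggregates)
    data.frame(p = p, overall = cr$overall,
               in_group = cr$in_group, out_group = cr$out_group)
  })
  do.call(rbind, rows)
}
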