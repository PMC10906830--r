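#' Reputation state container
#'
#' Mean-field reputations for a strategy mix in a group-structured population:
#' \code{g_ind[i, J, I]} is the probability that a strategy-i member of group J
#' is viewed as good (individual reputation) by group I, and \code{g_st[J, I]}
#' is the probability that group J has a good stereotyped reputation in the
#' eyes of group I. Storage is fully general (observer-dependent) even though
#' unconditional strategies have observer-independent individual reputations.
#'
#' @param mix a \code{strategy_mix}.
#' @param structure a \code{population_structure}.
#' @param init initial fill value in [0, 1].
#' @return object of class \code{reputation_state}.
#' @export
reputation_state <- function(mix, structure, init = 0.5) {
  stopifnot(init >= 0, init <= 1)
  K <- structure$K
  n <- length(mix$kinds)
  structure(list(
    g_ind = array(init, dim = c(n, K, K),
                  dimnames = list(mix$labels, NULL, NULL)),
    g_st  = matrix(init, K, K)
  ), class = "reputation_state")
}

#' View aggregates
#'
#' Precomputes the population-level view summaries used by the reputation
#' recursions and the fitness function:
#' \itemize{
#'   \item \code{g_grp[L, I]}: frequency-weighted fraction of group L viewed as
#'     good individually by group I;
#'   \item \code{g_dot[I]}: fraction of the whole population viewed as good
#'     individually by group I;
#'   \item \code{g_star[I]}: nu-weighted fraction of groups with a good
#'     stereotype in I's eyes;
#'   \item \code{ga1..ga4[J, I]}: probabilities that a random third party is
#'     viewed as good simultaneously by a group-J donor and a group-I observer,
#'     for the four combinations of (donor, observer) using individual or
#'     stereotyped information. E.g. \code{ga1} pairs individual views held by
#'     both: \eqn{\sum_L \nu_L \sum_i f_i g_i^{L,I} g_i^{L,J}}.
#' }
#'
#' @param state a \code{reputation_state}.
#' @param mix a \code{strategy_mix}.
#' @param structure a \code{population_structure}.
#' @return list of aggregates.
#' @export
view_aggregates <- function(state, mix, structure) {
  K  <- structure$K
  nu <- structure$nu
  n  <- length(mix$kinds)
  if (!identical(dim(state$g_ind), c(n, K, K)) ||
      !identical(dim(state$g_st), c(K, K))) {
    stop("reputation state dimensions do not match mix/structure", call. = FALSE)
  }
  f <- mix$f
  # g_grp[L, I] = sum_i f_i g_ind[i, L, I]
  g_grp <- matrix(0, K, K)
  for (L in seq_len(K)) for (I in seq_len(K)) {
    g_grp[L, I] <- sum(f * state$g_ind[, L, I])
  }
  g_dot  <- as.numeric(nu %*% g_grp)        # length K (index I)
  g_star <- as.numeric(nu %*% state$g_st)   # length K (index I)

  # agreement terms, indexed [J = donor group, I = observer group]; K is
  # small so explicit loops are clearer than matrix gymnastics
  ga1 <- ga2 <- ga3 <- ga4 <- matrix(0, K, K)
  for (J in seq_len(K)) for (I in seq_len(K)) {
    ga1[J, I] <- sum(nu * colSums(matrix(f * state$g_ind[, , I] *
                                             state$g_ind[, , J], n, K)))
    ga2[J, I] <- sum(nu * state$g_st[, J] * g_grp[, I])
    ga3[J, I] <- sum(nu * state$g_st[, I] * g_grp[, J])
    ga4[J, I] <- sum(nu * state$g_st[, I] * state$g_st[, J])
  }
  list(g_grp = g_grp, g_dot = g_dot, g_star = g_star,
       ga1 = ga1, ga2 = ga2, ga3 = ga3, ga4 = ga4)
}

#' One synchronous reputation update
#'
#' Applies the right-hand sides of the mean-field reputation recursions once:
#' each observer group re-assesses each (strategy, donor group) individual
#' reputation from an independently sampled interaction, and each group's
#' stereotype from a randomly sampled donor, folding in the assessment kernel
#' and the agreement structure of the two monitoring scales. The map is total
#' on [0,1] states; its fixed points are the equilibrium reputations.
#'
#' @inheritParams view_aggregates
#' @param params a \code{model_params}.
#' @return updated \code{reputation_state}.
#' @export
reputation_update_map <- function(state, mix, params) {
  st <- params$structure
  K  <- st$K
  nu <- st$nu
  P  <- assessment_probabilities(params$norm, params$u_a, params$u_e)
  A  <- agreement_matrix(params$individual_scale, K)  # A[I, J] symmetric
  B  <- agreement_matrix(params$stereotype_scale, K)
  ag <- view_aggregates(state, mix, st)
  g_dot <- ag$g_dot; g_star <- ag$g_star
  n <- length(mix$kinds)

  new_ind <- array(NA_real_, dim = dim(state$g_ind), dimnames = dimnames(state$g_ind))
  for (I in seq_len(K)) {
    allc <- g_dot[I] * P$P_GC + (1 - g_dot[I]) * P$P_BC
    alld <- g_dot[I] * P$P_GD + (1 - g_dot[I]) * P$P_BD
    for (J in seq_len(K)) {
      for (i in seq_len(n)) {
        kind <- mix$kinds[i]
        new_ind[i, J, I] <- switch(kind,
          ALLC = allc,
          ALLD = alld,
          DISC = disc_individual_rhs(mix$p[i], I, J, A, P, ag),
          TAG  = sum(nu * ifelse(seq_len(K) == J,
                   ag$g_grp[, I] * P$P_GC + (1 - ag$g_grp[, I]) * P$P_BC,
                   ag$g_grp[, I] * P$P_GD + (1 - ag$g_grp[, I]) * P$P_BD))
        )
      }
    }
  }

  new_st <- matrix(NA_real_, K, K)
  for (I in seq_len(K)) for (J in seq_len(K)) {
    total <- 0
    for (i in seq_len(n)) {
      kind <- mix$kinds[i]
      contrib <- switch(kind,
        ALLC = g_star[I] * P$P_GC + (1 - g_star[I]) * P$P_BC,
        ALLD = g_star[I] * P$P_GD + (1 - g_star[I]) * P$P_BD,
        DISC = disc_stereotype_rhs(mix$p[i], I, J, B, P, ag),
        TAG  = sum(nu * ifelse(seq_len(K) == J,
                 state$g_st[, I] * P$P_GC + (1 - state$g_st[, I]) * P$P_BC,
                 state$g_st[, I] * P$P_GD + (1 - state$g_st[, I]) * P$P_BD))
      )
      total <- total + mix$f[i] * contrib
    }
    new_st[J, I] <- total
  }

  structure(list(g_ind = new_ind, g_st = new_st), class = "reputation_state")
}

# Individual-reputation recursion for a discriminator with propensity p:
# donor in group J assessed by observer group I.
disc_individual_rhs <- function(p, I, J, A, P, ag) {
  g_dot <- ag$g_dot; g_star <- ag$g_star
  agree    <- g_dot[I] * P$P_GC + (1 - g_dot[I]) * P$P_BD
  ga1 <- ag$ga1[J, I]
  disagree <- ga1 * P$P_GC +
    (g_dot[I] - ga1) * P$P_GD +
    (g_dot[J] - ga1) * P$P_BC +
    (1 - g_dot[I] - g_dot[J] + ga1) * P$P_BD
  ga2 <- ag$ga2[J, I]
  stereo <- ga2 * P$P_GC +
    (g_dot[I] - ga2) * P$P_GD +
    (g_star[J] - ga2) * P$P_BC +
    (1 - g_dot[I] - g_star[J] + ga2) * P$P_BD
  (1 - p) * (A[I, J] * agree + (1 - A[I, J]) * disagree) + p * stereo
}

# Stereotype recursion contribution of a discriminator donor sampled from
# group J, assessed by observer group I against I's stereotype views.
disc_stereotype_rhs <- function(p, I, J, B, P, ag) {
  g_dot <- ag$g_dot; g_star <- ag$g_star
  ga3 <- ag$ga3[J, I]
  ind_branch <- ga3 * P$P_GC +
    (g_star[I] - ga3) * P$P_GD +
    (g_dot[J] - ga3) * P$P_BC +
    (1 - g_star[I] - g_dot[J] + ga3) * P$P_BD
  ga4 <- ag$ga4[J, I]
  st_disagree <- ga4 * P$P_GC +
    (g_star[I] - ga4) * P$P_GD +
    (g_star[J] - ga4) * P$P_BC +
    (1 - g_star[I] - g_star[J] + ga4) * P$P_BD
  st_agree <- g_star[I] * P$P_GC + (1 - g_star[I]) * P$P_BD
  (1 - p) * ind_branch +
    p * ((1 - B[I, J]) * st_disagree + B[I, J] * st_agree)
}

#' Solver settings
#'
#' @param tol sup-norm residual tolerance.
#' @param max_iter iteration cap.
#' @param damping relaxation weight lambda in (0, 1]; the iteration is
#'   x <- (1 - lambda) x + lambda F(x). Undamped iteration oscillates on maps
#'   like g' = 1 - g (error-free defector populations), so the default is 0.5.
#' @param init initial fill value for all reputations; the fixed point reached
#'   can depend on it when multiple equilibria coexist, and 0.5 is the
#'   canonical root reported throughout.
#' @return list of settings.
#' @export
solver_settings <- function(tol = 1e-12, max_iter = 1e5, damping = 0.5,
                            init = 0.5) {
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1,
            init >= 0, init <= 1)
  list(tol = tol, max_iter = max_iter, damping = damping, init = init)
}

#' Solve the self-consistent reputation equilibrium
#'
#' Damped synchronous fixed-point iteration of
#' \code{\link{reputation_update_map}} until the sup-norm residual
#' \code{||F(x) - x||} falls below \code{tol}. Reputations are assumed to
#' equilibrate much faster than strategy frequencies, so all payoff and
#' dynamics computations downstream consume the equilibrium state.
#'
#' @inheritParams reputation_update_map
#' @param settings a \code{\link{solver_settings}} list.
#' @param warm_start optional \code{reputation_state} used as the starting
#'   point (e.g. the equilibrium at a nearby parameter value).
#' @return list with elements \code{state} (the equilibrium
#'   \code{reputation_state}), \code{aggregates} (its
#'   \code{\link{view_aggregates}}), \code{residual}, \code{iterations}, and
#'   \code{neutral} (TRUE when the update map is the identity at the starting
#'   point, i.e. a neutral family of fixed points such as error-free
#'   unconditional cooperators under Stern Judging — the initialized value is
#'   then returned as-is).
#' @export
solve_reputation_equilibrium <- function(mix, params,
                                         settings = solver_settings(),
                                         warm_start = NULL) {
  st <- params$structure
  x <- if (is.null(warm_start)) reputation_state(mix, st, settings$init)
       else warm_start
  lam <- settings$damping
  res <- Inf
  neutral <- FALSE
  for (it in seq_len(settings$max_iter)) {
    fx <- reputation_update_map(x, mix, params)
    res <- max(abs(fx$g_ind - x$g_ind), abs(fx$g_st - x$g_st))
    if (res < settings$tol) {
      if (it == 1L) neutral <- TRUE
      x <- fx
      break
    }
    x$g_ind <- (1 - lam) * x$g_ind + lam * fx$g_ind
    x$g_st  <- (1 - lam) * x$g_st  + lam * fx$g_st
  }
  if (res >= settings$tol) {
    stop("reputation solver did not converge within ", settings$max_iter,
         " iterations (last residual ", format(res), "); ",
         "retry with stronger damping", call. = FALSE)
  }
  list(state = x, aggregates = view_aggregates(x, mix, st),
       residual = res, iterations = it, neutral = neutral)
}

#' Export an equilibrium reputation state as a tidy table
#'
#' @param state a \code{reputation_state}.
#' @param mix the \code{strategy_mix} the state belongs to.
#' @return data.frame with columns strategy, donor_group, observer_group, g
#'   (individual reputations) followed by rows with strategy
#'   \code{"<stereotype>"} for the group-level stereotypes.
#' @export
reputation_table <- function(state, mix) {
  d <- dim(state$g_ind)
  grid <- expand.grid(strategy = mix$labels,
                      donor_group = seq_len(d[2]),
                      observer_group = seq_len(d[3]),
                      stringsAsFactors = FALSE)
  grid$g <- as.vector(state$g_ind)
  stg <- expand.grid(strategy = "<stereotype>",
                     donor_group = seq_len(d[2]),
                     observer_group = seq_len(d[3]),
                     stringsAsFactors = FALSE)
  stg$g <- as.vector(state$g_st)
  rbind(grid, stg)
}
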