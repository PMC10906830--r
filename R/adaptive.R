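#' Invasion fitness of a rare mutant stereotype propensity
#'
#' Considers a resident discriminator population with propensity \code{p_R}
#' (optionally sharing the population with a fixed background mix, e.g. 20%
#' unconditional defectors) and a vanishingly rare mutant discriminator with
#' propensity \code{p_Q}. The resident reputation field is solved
#' self-consistently; the mutant, carrying zero weight in all population
#' aggregates, has an *explicit* individual reputation given by the
#' discriminator recursion evaluated with her own propensity on the resident
#' aggregates. The invasion fitness is the nu-weighted payoff difference
#' \eqn{\sum_J \nu_J (\Pi_Q^J - \Pi_R^J)} at zero mutant frequency; the mutant
#' invades iff it is positive.
#'
#' @param p_R resident propensity in [0, 1].
#' @param p_Q mutant propensity in [0, 1].
#' @param params a \code{model_params}.
#' @param background optional named list \code{list(kind =, f =)} giving a
#'   fixed background strategy (e.g. \code{list(kind = "ALLD", f = 0.2)});
#'   the resident discriminators then make up the remaining fraction.
#' @param settings \code{\link{solver_settings}}.
#' @param resident optional precomputed resident equilibrium (the return value
#'   of \code{\link{solve_reputation_equilibrium}} for the resident mix),
#'   allowing one resident solve to serve several mutant evaluations.
#' @return list with \code{p_R}, \code{p_Q}, \code{fitness_diff},
#'   \code{Pi_Q}, \code{Pi_R} (per-group payoffs) and \code{resident}
#'   (the resident equilibrium, reusable as a warm start).
#' @export
invasion_fitness <- function(p_R, p_Q, params, background = NULL,
                             settings = solver_settings(), resident = NULL) {
  stopifnot(p_R >= 0, p_R <= 1, p_Q >= 0, p_Q <= 1)
  mix <- resident_mix(p_R, background)
  if (is.null(resident)) {
    resident <- solve_reputation_equilibrium(mix, params, settings)
  }
  st <- params$structure
  K  <- st$K
  nu <- st$nu
  P  <- assessment_probabilities(params$norm, params$u_a, params$u_e)
  A  <- agreement_matrix(params$individual_scale, K)
  ag <- resident$aggregates
  state <- resident$state
  idx_R <- which(mix$kinds == "DISC")

  # mutant individual reputation: explicit (no self-dependence at zero weight)
  g_Q <- matrix(NA_real_, K, K)  # [J, I]
  for (J in seq_len(K)) for (I in seq_len(K)) {
    g_Q[J, I] <- disc_individual_rhs(p_Q, I, J, A, P, ag)
  }

  Pi_Q <- Pi_R <- numeric(K)
  for (I in seq_len(K)) {
    ben_Q <- ben_R <- 0
    for (J in seq_len(K)) {
      d_Q <- d_R <- 0
      for (i in seq_along(mix$kinds)) {
        d_Q <- d_Q + mix$f[i] * switch(mix$kinds[i],
          ALLC = 1, ALLD = 0, TAG = as.numeric(J == I),
          DISC = (1 - mix$p[i]) * g_Q[I, J] + mix$p[i] * state$g_st[I, J])
        d_R <- d_R + mix$f[i] * switch(mix$kinds[i],
          ALLC = 1, ALLD = 0, TAG = as.numeric(J == I),
          DISC = (1 - mix$p[i]) * state$g_ind[idx_R, I, J] +
                 mix$p[i] * state$g_st[I, J])
      }
      ben_Q <- ben_Q + nu[J] * d_Q
      ben_R <- ben_R + nu[J] * d_R
    }
    cost_Q <- params$c * ((1 - p_Q) * ag$g_dot[I] + p_Q * ag$g_star[I])
    cost_R <- params$c * ((1 - p_R) * ag$g_dot[I] + p_R * ag$g_star[I])
    Pi_Q[I] <- (1 - params$u_e) * (params$b * ben_Q - cost_Q) -
      params$eta * (1 - p_Q)
    Pi_R[I] <- (1 - params$u_e) * (params$b * ben_R - cost_R) -
      params$eta * (1 - p_R)
  }
  list(p_R = p_R, p_Q = p_Q,
       fitness_diff = sum(nu * (Pi_Q - Pi_R)),
       Pi_Q = Pi_Q, Pi_R = Pi_R, resident = resident)
}

resident_mix <- function(p_R, background) {
  if (is.null(background)) return(strategy_mix("DISC", p = p_R))
  stopifnot(is.list(background), background$f > 0, background$f < 1)
  strategy_mix(c(background$kind, "DISC"),
               p = c(0, p_R),
               f = c(background$f, 1 - background$f))
}

#' Selection gradient of stereotype propensity
#'
#' Central finite difference of \code{\link{invasion_fitness}} in the mutant
#' propensity at \code{p_Q = p_R = p} (one-sided at the boundaries), sharing a
#' single resident equilibrium solve between the two mutant evaluations.
#'
#' @param p propensity at which to evaluate the gradient.
#' @inheritParams invasion_fitness
#' @param h finite-difference step (default 1e-3).
#' @return gradient value (scalar).
#' @export
selection_gradient <- function(p, params, background = NULL,
                               settings = solver_settings(), h = 1e-3,
                               resident = NULL) {
  lo <- max(0, p - h)
  hi <- min(1, p + h)
  inv_lo <- invasion_fitness(p, lo, params, background, settings, resident)
  inv_hi <- invasion_fitness(p, hi, params, background, settings,
                             resident = inv_lo$resident)
  (inv_hi$fitness_diff - inv_lo$fitness_diff) / (hi - lo)
}

#' Singular points of the adaptive dynamics in p
#'
#' Evaluates the selection gradient on a grid over [0, 1], brackets interior
#' sign changes and refines them by bisection. A sign change from positive to
#' negative is an attractive (convergence-stable) singular point; negative to
#' positive is repulsive. The boundaries are classified from the one-sided
#' gradients: p = 0 is attractive iff selection pushes downward near 0, p = 1
#' iff it pushes upward near 1. Each point is annotated with the cooperation
#' summary of a monomorphic population at that propensity.
#'
#' @inheritParams invasion_fitness
#' @param resolution number of grid points (>= 50).
#' @param p_tol bisection tolerance on p.
#' @param neutral_tol gradient magnitudes below this are treated as neutral
#'   (no selection); if the gradient is neutral on the whole grid an empty
#'   set with attribute \code{neutral = TRUE} is returned.
#' @return data.frame with columns p_star, attractive, kind
#'   ("interior"/"boundary"), gradient (at the point, 0 for interior roots),
#'   cooperation, ingroup_gap.
#' @export
find_singular_points <- function(params, background = NULL,
                                 resolution = 101,
                                 settings = solver_settings(),
                                 p_tol = 1e-4, neutral_tol = 1e-8) {
  stopifnot(resolution >= 50)
  grid <- seq(0, 1, length.out = resolution)
  grad <- numeric(resolution)
  warm <- NULL
  for (k in seq_len(resolution)) {
    mix <- resident_mix(grid[k], background)
    res <- solve_reputation_equilibrium(mix, params, settings,
                                        warm_start = warm)
    warm <- res$state
    grad[k] <- selection_gradient(grid[k], params, background, settings,
                                  resident = res)
  }

  pts <- list()
  if (all(abs(grad) < neutral_tol)) {
    out <- empty_singular_df()
    attr(out, "neutral") <- TRUE
    return(out)
  }
  gfun <- function(p) selection_gradient(p, params, background, settings)
  # interior sign changes (ignore neutral plateaus: require a strict change)
  for (k in seq_len(resolution - 1)) {
    g1 <- grad[k]; g2 <- grad[k + 1]
    if (g1 == 0 || sign(g1) == sign(g2)) next
    root <- stats::uniroot(gfun, c(grid[k], grid[k + 1]),
                           f.lower = g1, f.upper = g2, tol = p_tol)$root
    if (root <= p_tol || root >= 1 - p_tol) next  # boundary handled below
    pts[[length(pts) + 1]] <- data.frame(
      p_star = root, attractive = (g1 > 0 && g2 < 0), kind = "interior",
      gradient = 0)
  }
  # boundaries
  if (abs(grad[1]) >= neutral_tol) {
    pts[[length(pts) + 1]] <- data.frame(
      p_star = 0, attractive = (grad[1] < 0), kind = "boundary",
      gradient = grad[1])
  }
  if (abs(grad[resolution]) >= neutral_tol) {
    pts[[length(pts) + 1]] <- data.frame(
      p_star = 1, attractive = (grad[resolution] > 0), kind = "boundary",
      gradient = grad[resolution])
  }
  out <- do.call(rbind, pts)
  out <- out[order(out$p_star), , drop = FALSE]
  # annotate with cooperation at the singular propensity
  ann <- t(vapply(out$p_star, function(p) {
    mix <- resident_mix(p, background)
    eq <- solve_reputation_equilibrium(mix, params, settings)
    cr <- cooperation_rates(mix, eq$state, params, eq$aggregates)
    c(cr$overall, cr$in_group - cr$out_group)
  }, numeric(2)))
  out$cooperation <- ann[, 1]
  out$ingroup_gap <- ann[, 2]
  rownames(out) <- NULL
  attr(out, "neutral") <- FALSE
  out
}

empty_singular_df <- function() {
  data.frame(p_star = numeric(0), attractive = logical(0),
             kind = character(0), gradient = numeric(0),
             cooperation = numeric(0), ingroup_gap = numeric(0))
}

#' Bifurcation sweep of singular points over a model parameter
#'
#' Runs \code{\link{find_singular_points}} at each value of a parameter grid
#' (typically the access cost eta) and classifies the regime at each value:
#' \code{"p0-only"} (no stereotyping is the only attractor),
#' \code{"bistable"} (p = 0 and a high-stereotyping attractor coexist),
#' \code{"high-p-only"} (only an interior or p = 1 attractor remains), or
#' \code{"neutral"}.
#'
#' @inheritParams find_singular_points
#' @param parameter name of the swept \code{model_params} field
#'   (\code{"eta"}, \code{"b"}, \code{"u_a"}, \code{"u_e"}, or \code{"c"}).
#' @param grid numeric vector of parameter values.
#' @return data.frame with one row per (parameter value, singular point) and
#'   columns value, p_star, attractive, kind, cooperation, ingroup_gap,
#'   regime.
#' @export
bifurcation_sweep <- function(params, parameter = "eta", grid,
                              background = NULL, resolution = 101,
                              settings = solver_settings()) {
  stopifnot(parameter %in% c("eta", "b", "c", "u_a", "u_e"))
  rows <- lapply(grid, function(v) {
    pars <- params
    pars[[parameter]] <- v
    sp <- find_singular_points(pars, background, resolution, settings)
    regime <- classify_regime(sp)
    if (nrow(sp) == 0) {
      return(data.frame(value = v, p_star = NA_real_, attractive = NA,
                        kind = "neutral", cooperation = NA_real_,
                        ingroup_gap = NA_real_, regime = regime))
    }
    data.frame(value = v, p_star = sp$p_star, attractive = sp$attractive,
               kind = sp$kind, cooperation = sp$cooperation,
               ingroup_gap = sp$ingroup_gap, regime = regime)
  })
  do.call(rbind, rows)
}

classify_regime <- function(sp) {
  if (nrow(sp) == 0) return("neutral")
  att <- sp[sp$attractive, , drop = FALSE]
  has_p0  <- any(att$p_star < 1e-6)
  has_hi  <- any(att$p_star >= 1e-6)
  if (has_p0 && has_hi) "bistable"
  else if (has_p0) "p0-only"
  else if (has_hi) "high-p-only"
  else "neutral"
}

#' Pairwise invasibility plot grid
#'
#' Boolean matrix over (resident, mutant) propensity pairs: entry TRUE iff the
#' rare mutant invades (strictly positive invasion fitness). The diagonal is
#' neutral and therefore FALSE. One resident equilibrium solve is shared per
#' row.
#'
#' @inheritParams invasion_fitness
#' @param resolution grid resolution (>= 20).
#' @return list with \code{p} (the grid) and \code{invades} (resolution x
#'   resolution logical matrix, residents in rows).
#' @export
pip_grid <- function(params, resolution = 21, background = NULL,
                     settings = solver_settings()) {
  stopifnot(resolution >= 20)
  p <- seq(0, 1, length.out = resolution)
  invades <- matrix(FALSE, resolution, resolution,
                    dimnames = list(p_R = NULL, p_Q = NULL))
  for (r in seq_len(resolution)) {
    res <- NULL
    for (q in seq_len(resolution)) {
      inv <- invasion_fitness(p[r], p[q], params, background, settings,
                              resident = res)
      res <- inv$resident
      invades[r, q] <- inv$fitness_diff > 1e-12
    }
  }
  list(p = p, invades = invades)
}

#' Rare-invader fitness against a monomorphic resident
#'
#' Growth rate of an infinitesimally rare invader strategy in a monomorphic
#' resident population: \eqn{\sum_J \nu_J (\Pi_{inv}^J - \Pi_{res}^J)} at zero
#' invader frequency. This equals the replicator eigenvalue along the
#' resident-invader edge at the resident vertex; the invader's reputations
#' are computed explicitly from the resident equilibrium aggregates (a rare
#' type carries zero weight in all population-level views).
#'
#' @param resident_kind,resident_p resident strategy (kind and, for DISC,
#'   propensity).
#' @param invader_kind,invader_p invader strategy.
#' @param params a \code{model_params}.
#' @param settings \code{\link{solver_settings}}.
#' @return scalar invasion growth rate (positive means the invader invades).
#' @export
rare_invader_fitness <- function(resident_kind, invader_kind, params,
                                 resident_p = 0, invader_p = 0,
                                 settings = solver_settings()) {
  mix <- strategy_mix(resident_kind, p = resident_p)
  eq <- solve_reputation_equilibrium(mix, params, settings)
  st <- params$structure
  K <- st$K; nu <- st$nu
  P <- assessment_probabilities(params$norm, params$u_a, params$u_e)
  A <- agreement_matrix(params$individual_scale, K)
  ag <- eq$aggregates
  invader_kind <- toupper(invader_kind)

  # invader's individual reputation in each observer group's eyes, explicit
  g_inv <- matrix(NA_real_, K, K)  # [J = invader's group, I = observer]
  for (J in seq_len(K)) for (I in seq_len(K)) {
    g_inv[J, I] <- switch(invader_kind,
      ALLC = ag$g_dot[I] * P$P_GC + (1 - ag$g_dot[I]) * P$P_BC,
      ALLD = ag$g_dot[I] * P$P_GD + (1 - ag$g_dot[I]) * P$P_BD,
      DISC = disc_individual_rhs(invader_p, I, J, A, P, ag),
      TAG  = sum(nu * ifelse(seq_len(K) == J,
               ag$g_grp[, I] * P$P_GC + (1 - ag$g_grp[, I]) * P$P_BC,
               ag$g_grp[, I] * P$P_GD + (1 - ag$g_grp[, I]) * P$P_BD)))
  }

  Pi_inv <- Pi_res <- numeric(K)
  fit_res <- strategy_fitness(mix, eq$state, params, ag)
  for (I in seq_len(K)) {
    ben <- 0
    for (J in seq_len(K)) {
      # cooperation the invader receives from resident donors in group J
      d <- switch(mix$kinds[1],
        ALLC = 1, ALLD = 0, TAG = as.numeric(J == I),
        DISC = (1 - mix$p[1]) * g_inv[I, J] + mix$p[1] * eq$state$g_st[I, J])
      ben <- ben + nu[J] * d
    }
    cost <- switch(invader_kind,
      ALLC = params$c,
      ALLD = 0,
      DISC = params$c * ((1 - invader_p) * ag$g_dot[I] +
                         invader_p * ag$g_star[I]),
      TAG  = params$c * nu[I])
    access <- if (invader_kind == "DISC") params$eta * (1 - invader_p) else 0
    Pi_inv[I] <- (1 - params$u_e) * (params$b * ben - cost) - access
    Pi_res[I] <- fit_res$Pi[1, I]
  }
  sum(nu * (Pi_inv - Pi_res))
}
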