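#' Replicator right-hand side
#'
#' Velocity of strategy frequencies under global imitation,
#' \eqn{\dot f_i = f_i \sum_J \nu_J (\Pi_i^J - \bar\Pi^J)}. Reputations are
#' re-equilibrated at the current frequencies before payoffs are evaluated
#' (timescale separation: reputations settle between strategy updates).
#'
#' @param f frequency vector on the simplex over \code{mix_template}'s
#'   strategies.
#' @param mix_template a \code{strategy_mix} defining the strategy set (its
#'   frequencies are ignored).
#' @param params a \code{model_params}.
#' @param settings \code{\link{solver_settings}}.
#' @param warm_start optional \code{reputation_state} to start the equilibrium
#'   solve from.
#' @return list with \code{velocity} (same length as f, summing to zero),
#'   \code{fitness} (the \code{\link{strategy_fitness}} table), and
#'   \code{state} (the equilibrium reputation state, reusable as warm start).
#' @export
replicator_rhs <- function(f, mix_template, params,
                           settings = solver_settings(), warm_start = NULL) {
  mix <- set_frequencies(mix_template, f)
  eq <- solve_reputation_equilibrium(mix, params, settings,
                                     warm_start = warm_start)
  fit <- strategy_fitness(mix, eq$state, params, eq$aggregates)
  nu <- params$structure$nu
  adv <- as.numeric((fit$Pi - rep(fit$Pi_bar, each = nrow(fit$Pi))) %*% nu)
  list(velocity = mix$f * adv, fitness = fit, state = eq$state)
}

#' Integrate a replicator trajectory
#'
#' Integrates the replicator dynamics from an initial frequency vector with
#' \pkg{deSolve}, renormalizing drift off the simplex and warm-starting each
#' reputation solve from the previous one. A terminal point is flagged
#' converged when the velocity norm falls below \code{conv_tol}.
#'
#' @param f0 initial frequency vector (non-negative, summing to 1).
#' @inheritParams replicator_rhs
#' @param horizon integration horizon (time units of the replicator clock).
#' @param n_out number of reported time points.
#' @param conv_tol velocity sup-norm below which the terminal state counts as
#'   converged.
#' @param clamp optional index of a strategy whose frequency is held fixed
#'   (e.g. a defector background); the remaining frequencies evolve by the
#'   replicator dynamics restricted to the free portion of the simplex.
#' @return list with \code{trajectory} (data.frame: time plus one column per
#'   strategy), \code{terminal} (final frequencies) and \code{converged}.
#' @export
integrate_trajectory <- function(f0, mix_template, params,
                                 horizon = 200, n_out = 201,
                                 settings = solver_settings(),
                                 conv_tol = 1e-8, clamp = NULL) {
  n <- length(mix_template$kinds)
  stopifnot(length(f0) == n, all(f0 >= 0), abs(sum(f0) - 1) < 1e-9)
  env <- new.env()
  env$warm <- NULL
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    y <- y / sum(y)
    out <- replicator_rhs(y, mix_template, params, settings,
                          warm_start = env$warm)
    env$warm <- out$state
    v <- out$velocity
    if (!is.null(clamp)) {
      # hold the clamped strategy fixed; redistribute its velocity over the
      # free strategies proportionally so the total stays on the simplex
      free <- setdiff(seq_len(n), clamp)
      v[clamp] <- 0
      v[free] <- v[free] - y[free] / sum(y[free]) * sum(v[free])
    }
    list(v)
  }
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(y = f0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  traj <- as.data.frame(sol)
  names(traj) <- c("time", mix_template$labels)
  terminal <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
  terminal <- terminal / sum(terminal)
  vterm <- replicator_rhs(terminal, mix_template, params, settings,
                          warm_start = env$warm)$velocity
  if (!is.null(clamp)) vterm[clamp] <- 0
  list(trajectory = traj, terminal = terminal,
       converged = max(abs(vterm)) < conv_tol)
}

#' Enumerate and classify replicator equilibria
#'
#' Finds equilibria of the replicator dynamics for a strategy set: all simplex
#' vertices (always equilibria), edge equilibria located by sign changes of
#' the pairwise payoff difference along each edge, and interior equilibria
#' located by a barycentric grid scan of the velocity norm followed by a
#' derivative-free polish. Each equilibrium is classified by the eigenvalues
#' of the Jacobian of the projected (n-1)-dimensional system, computed by
#' central finite differences; eigenvalue real parts within \code{tol_eig} of
#' zero are flagged neutral.
#'
#' @inheritParams replicator_rhs
#' @param edge_resolution grid used to scan each edge.
#' @param interior_density barycentric grid density for the interior scan.
#' @param tol_eig neutrality band for eigenvalue real parts.
#' @return data.frame with one row per equilibrium: columns f1..fn, kind
#'   (vertex/edge/interior), stable, neutral, max_re (largest eigenvalue real
#'   part).
#' @export
classify_equilibria <- function(mix_template, params,
                                settings = solver_settings(),
                                edge_resolution = 41,
                                interior_density = 20,
                                tol_eig = 1e-8) {
  n <- length(mix_template$kinds)
  stopifnot(n >= 2, n <= 4)
  eqs <- list()
  # vertices
  for (i in seq_len(n)) {
    f <- numeric(n); f[i] <- 1
    eqs[[length(eqs) + 1]] <- list(f = f, kind = "vertex")
  }
  # edges: scan the payoff difference along each 1-d subsystem
  for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
    s_grid <- seq(0, 1, length.out = edge_resolution)
    diff_ab <- vapply(s_grid, function(s) {
      f <- numeric(n); f[a] <- s; f[b] <- 1 - s
      out <- replicator_rhs(f, mix_template, params, settings)
      nu <- params$structure$nu
      sum(nu * (out$fitness$Pi[a, ] - out$fitness$Pi[b, ]))
    }, numeric(1))
    for (k in seq_len(edge_resolution - 1)) {
      if (diff_ab[k] == 0 || sign(diff_ab[k]) == sign(diff_ab[k + 1])) next
      root <- stats::uniroot(function(s) {
        f <- numeric(n); f[a] <- s; f[b] <- 1 - s
        out <- replicator_rhs(f, mix_template, params, settings)
        nu <- params$structure$nu
        sum(nu * (out$fitness$Pi[a, ] - out$fitness$Pi[b, ]))
      }, c(s_grid[k], s_grid[k + 1]), tol = 1e-8)$root
      if (root < 1e-6 || root > 1 - 1e-6) next
      f <- numeric(n); f[a] <- root; f[b] <- 1 - root
      eqs[[length(eqs) + 1]] <- list(f = f, kind = "edge")
    }
  }
  # interior: grid scan + Nelder-Mead polish of the squared velocity norm
  if (n >= 3) {
    pts <- barycentric_grid(n, interior_density)
    vn <- apply(pts, 1, function(f) {
      sqrt(sum(replicator_rhs(f, mix_template, params, settings)$velocity^2))
    })
    cand <- pts[vn < 1e-3, , drop = FALSE]
    if (nrow(cand)) {
      for (r in seq_len(nrow(cand))) {
        obj <- function(x) {
          f <- c(x, 1 - sum(x))
          if (any(f < 0)) return(1e6)
          sum(replicator_rhs(f, mix_template, params, settings)$velocity^2)
        }
        opt <- stats::optim(cand[r, -n], obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-14, maxit = 500))
        f <- c(opt$par, 1 - sum(opt$par))
        if (opt$value < 1e-16 && all(f > 1e-4)) {
          eqs[[length(eqs) + 1]] <- list(f = f, kind = "interior")
        }
      }
    }
  }
  # deduplicate
  keep <- list()
  for (e in eqs) {
    dup <- any(vapply(keep, function(k) max(abs(k$f - e$f)) < 1e-6, logical(1)))
    if (!dup) keep[[length(keep) + 1]] <- e
  }
  rows <- lapply(keep, function(e) {
    ev <- equilibrium_eigenvalues(e$f, mix_template, params, settings)
    re <- Re(ev)
    data.frame(t(e$f), kind = e$kind,
               stable = all(re < -tol_eig),
               neutral = any(abs(re) <= tol_eig),
               max_re = max(re))
  })
  out <- do.call(rbind, rows)
  names(out)[seq_len(n)] <- mix_template$labels
  out
}

# eigenvalues of the projected Jacobian at a simplex point, by central
# finite differences in the first (n-1) coordinates
equilibrium_eigenvalues <- function(f, mix_template, params, settings,
                                    h = 1e-6) {
  n <- length(f)
  m <- n - 1
  # parameterize the simplex by all coordinates except the dominant one, so
  # that perturbations at vertices and edges stay feasible
  drop <- which.max(f)
  keep <- setdiff(seq_len(n), drop)
  feasible <- function(x) all(x >= 0) && sum(x) <= 1
  vel <- function(x) {
    full <- numeric(n)
    full[keep] <- x
    full[drop] <- 1 - sum(x)
    replicator_rhs(full, mix_template, params, settings)$velocity[keep]
  }
  J <- matrix(0, m, m)
  x0 <- f[keep]
  for (j in seq_len(m)) {
    e <- numeric(m); e[j] <- h
    # fall back to one-sided differences at simplex boundaries
    if (feasible(x0 + e) && feasible(x0 - e)) {
      J[, j] <- (vel(x0 + e) - vel(x0 - e)) / (2 * h)
    } else if (feasible(x0 + e)) {
      J[, j] <- (vel(x0 + e) - vel(x0)) / h
    } else {
      J[, j] <- (vel(x0) - vel(x0 - e)) / h
    }
  }
  eigen(J, only.values = TRUE)$values
}

# interior lattice points i / (density + 1) with all parts positive;
# density = 2 gives just the barycenter for n = 3
barycentric_grid <- function(n, density) {
  stopifnot(density >= 2)
  denom <- density + 1
  idx <- expand.grid(rep(list(seq_len(denom - 1)), n - 1))
  last <- denom - rowSums(idx)
  keep <- last >= 1
  f <- cbind(as.matrix(idx[keep, , drop = FALSE]), last[keep]) / denom
  unname(f)
}

#' Replicator flow field on the simplex
#'
#' Velocities at interior barycentric grid points, in long format for
#' plotting.
#'
#' @inheritParams replicator_rhs
#' @param density barycentric grid density (>= 2).
#' @return data.frame with frequency columns (one per strategy) and matching
#'   \code{d<label>} velocity columns.
#' @export
simplex_flow_field <- function(mix_template, params, density = 10,
                               settings = solver_settings()) {
  pts <- barycentric_grid(length(mix_template$kinds), density)
  vel <- t(apply(pts, 1, function(f) {
    replicator_rhs(f, mix_template, params, settings)$velocity
  }))
  out <- data.frame(pts, vel)
  names(out) <- c(mix_template$labels, paste0("d", mix_template$labels))
  out
}
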