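# Independent scalar oracles used to cross-check the reputation solver.

# Bisection root of a scalar function on [0, 1] (monotone bracket assumed
# after a coarse scan); independent of the package's fixed-point iteration.
bisect01 <- function(fn, tol = 1e-12) {
  grid <- seq(0, 1, length.out = 201)
  vals <- vapply(grid, fn, numeric(1))
  k <- which(vals[-1] * vals[-201] <= 0)[1]
  stopifnot(!is.na(k))
  lo <- grid[k]; hi <- grid[k + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fn(lo) * fn(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Scalar self-consistency residual for a monomorphic discriminator with
# propensity 0 under private individual monitoring and a uniform state g:
# the donor's and observer's views of the recipient are independent draws
# with the same marginal.
private_disc0_residual <- function(g, P) {
  g^2 * P$P_GC + (g - g^2) * (P$P_GD + P$P_BC) + (1 - g)^2 * P$P_BD - g
}

default_params <- function(...) {
  model_params("SternJudging", "public", "public", ...)
}

scales3 <- c("private", "group-wise", "public")

random_mix <- function() {
  n <- sample(1:3, 1)
  kinds <- sample(c("ALLC", "ALLD", "DISC"), n, replace = TRUE)
  f <- stats::runif(n); f <- f / sum(f)
  strategy_mix(kinds, p = stats::runif(n), f = f)
}

random_params <- function() {
  b <- stats::runif(1, 1.5, 5)
  model_params(sample(c("SternJudging", "SimpleStanding", "Scoring",
                        "Shunning"), 1),
               sample(scales3, 1), sample(scales3, 1),
               b = b, c = stats::runif(1, 0.2, b - 0.5),
               eta = stats::runif(1, 0, 1),
               u_e = stats::runif(1, 0, 0.1), u_a = stats::runif(1, 0, 0.1))
}
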