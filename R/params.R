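#' Population structure
#'
#' An infinitely large population partitioned into K non-overlapping groups
#' with fractions \code{nu} summing to one. The headline analyses use two
#' groups of equal size.
#'
#' @param K number of groups (integer >= 1).
#' @param nu vector of group fractions (positive, summing to 1); defaults to
#'   equal fractions.
#' @return object of class \code{population_structure}.
#' @export
population_structure <- function(K = 2L, nu = rep(1 / K, K)) {
  K <- as.integer(K)
  stopifnot(K >= 1L, is.numeric(nu), length(nu) == K, all(nu > 0))
  if (abs(sum(nu) - 1) > 1e-12) {
    stop("group fractions nu must sum to 1 (got ", format(sum(nu)), ")",
         call. = FALSE)
  }
  structure(list(K = K, nu = as.numeric(nu)), class = "population_structure")
}

#' Model parameterization
#'
#' Bundles everything that defines one instance of the mean-field model: the
#' social norm, the monitoring scales for individual and stereotyped
#' reputations, the group structure, the donation-game payoffs (benefit b,
#' cost c, with b > c > 0), the per-lookup access cost eta charged to a
#' discriminator each time she consults an individual reputation, and the
#' execution and assessment error rates.
#'
#' @param norm a \code{social_norm} or a norm name.
#' @param individual_scale monitoring scale for individual reputations.
#' @param stereotype_scale monitoring scale for stereotyped reputations.
#' @param structure a \code{population_structure}.
#' @param b benefit per cooperative act (b > c).
#' @param c cost per cooperative act (c > 0).
#' @param eta access cost per individual-reputation lookup (eta >= 0).
#' @param u_e execution error rate in [0, 1/2].
#' @param u_a assessment error rate in [0, 1/2].
#' @return object of class \code{model_params}.
#' @examples
#' model_params("SternJudging", "public", "public", eta = 0.3)
#' @export
model_params <- function(norm = "SternJudging",
                         individual_scale = "public",
                         stereotype_scale = "public",
                         structure = population_structure(),
                         b = 3, c = 1, eta = 0,
                         u_e = 0.02, u_a = 0.02) {
  if (is.character(norm)) norm <- social_norm(norm)
  stopifnot(inherits(norm, "social_norm"),
            inherits(structure, "population_structure"))
  if (!is.numeric(b) || !is.numeric(c) || b <= c || c <= 0) {
    stop("payoffs must satisfy b > c > 0 (got b = ", format(b),
         ", c = ", format(c), ")", call. = FALSE)
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0) {
    stop("eta must be a single value >= 0", call. = FALSE)
  }
  check_rate(u_e, "u_e")
  check_rate(u_a, "u_a")
  structure(list(
    norm = norm,
    individual_scale = match_scale(individual_scale),
    stereotype_scale = match_scale(stereotype_scale),
    structure = structure,
    b = b, c = c, eta = eta, u_e = u_e, u_a = u_a
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> %s | individual: %s, stereotype: %s | K = %d\n",
    x$norm$name, x$individual_scale, x$stereotype_scale, x$structure$K))
  cat(sprintf("  b = %g, c = %g, eta = %g, u_e = %g, u_a = %g\n",
              x$b, x$c, x$eta, x$u_e, x$u_a))
  invisible(x)
}

#' Strategy sets and frequency mixes
#'
#' Strategies are \code{ALLC} (always cooperate), \code{ALLD} (always defect),
#' \code{DISC} (discriminator: cooperate iff the recipient is viewed as good,
#' consulting the recipient's group stereotype with probability \code{p} and
#' her individual reputation, at access cost eta, with probability
#' \code{1 - p}), and \code{TAG} (unconditional in-group cooperator, an
#' extension strategy). Under global imitation strategy frequencies are common
#' across groups.
#'
#' @param kinds character vector of strategy kinds.
#' @param p stereotype-use propensities (recycled; ignored and stored as 0 for
#'   non-DISC kinds).
#' @param f frequency vector (non-negative, summing to 1).
#' @return object of class \code{strategy_mix}.
#' @examples
#' strategy_mix("DISC", p = 0.5)                     # monomorphic discriminator
#' strategy_mix(c("ALLC", "ALLD", "DISC"), p = c(0, 0, 0.67), f = c(0.2, 0.2, 0.6))
#' @export
strategy_mix <- function(kinds, p = 0, f = NULL) {
  kinds <- toupper(kinds)
  bad <- setdiff(kinds, c("ALLC", "ALLD", "DISC", "TAG"))
  if (length(bad)) {
    stop("unknown strategy kind(s): ", paste(bad, collapse = ", "),
         "; valid kinds are ALLC, ALLD, DISC, TAG", call. = FALSE)
  }
  n <- length(kinds)
  p <- rep_len(as.numeric(p), n)
  stopifnot(all(p >= 0), all(p <= 1))
  p[kinds != "DISC"] <- 0
  if (is.null(f)) f <- rep(1 / n, n)
  stopifnot(is.numeric(f), length(f) == n, all(f >= -1e-12))
  f <- pmax(f, 0)
  if (abs(sum(f) - 1) > 1e-9) {
    stop("strategy frequencies f must sum to 1", call. = FALSE)
  }
  labels <- ifelse(kinds == "DISC", sprintf("%gDISC", p), kinds)
  structure(list(kinds = kinds, p = p, f = as.numeric(f), labels = labels),
            class = "strategy_mix")
}

#' @export
print.strategy_mix <- function(x, ...) {
  cat("<strategy_mix> ",
      paste(sprintf("%s: %.3f", x$labels, x$f), collapse = ", "), "\n")
  invisible(x)
}

# replace frequencies, keeping the strategy set
set_frequencies <- function(mix, f) {
  f <- pmax(as.numeric(f), 0)
  s <- sum(f)
  if (s <= 0) stop("frequencies must have positive sum", call. = FALSE)
  mix$f <- f / s
  mix
}
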