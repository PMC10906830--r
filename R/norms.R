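#' Second-order social norms
#'
#' A second-order social norm assigns a donor a good or bad standing based on
#' the donor's action (cooperate or defect) and the observer's view of the
#' recipient (good or bad). Cooperating with a good recipient always earns a
#' good standing and defecting against a good recipient always earns a bad
#' standing; the norm is therefore characterised by two probabilities:
#' \code{q_C}, the probability that cooperating with a *bad* recipient yields
#' good standing, and \code{q_D}, the probability that defecting against a
#' *bad* recipient yields good standing.
#'
#' The four named norms in common use are, as (q_C, q_D) pairs:
#' Stern Judging (0, 1), Simple Standing (1, 1), Scoring (1, 0),
#' and Shunning (0, 0). Scoring is effectively first-order: it ignores the
#' recipient's standing. Arbitrary values in [0,1] are accepted so that
#' generalized (probabilistic) norms can be explored.
#'
#' @param name one of \code{"SternJudging"}, \code{"SimpleStanding"},
#'   \code{"Scoring"}, \code{"Shunning"} (case-insensitive; spaces, dashes and
#'   underscores are ignored).
#' @return an object of class \code{social_norm}: a list with elements
#'   \code{name}, \code{q_C}, \code{q_D}.
#' @examples
#' social_norm("SternJudging")
#' social_norm("simple standing")
#' custom_norm(0.5, 0.5, name = "coin-flip")
#' @export
social_norm <- function(name) {
  key <- tolower(gsub("[ _-]", "", name))
  norms <- list(
    sternjudging   = c(0, 1),
    simplestanding = c(1, 1),
    scoring        = c(1, 0),
    shunning       = c(0, 0)
  )
  labels <- c(
    sternjudging = "SternJudging", simplestanding = "SimpleStanding",
    scoring = "Scoring", shunning = "Shunning"
  )
  if (!key %in% names(norms)) {
    stop("unknown social norm '", name, "'; valid options are: ",
         "SternJudging, SimpleStanding, Scoring, Shunning", call. = FALSE)
  }
  q <- norms[[key]]
  custom_norm(q[1], q[2], name = labels[[key]])
}

#' @param q_C probability that cooperating with a bad recipient yields a good
#'   standing, in [0, 1].
#' @param q_D probability that defecting against a bad recipient yields a good
#'   standing, in [0, 1].
#' @rdname social_norm
#' @export
custom_norm <- function(q_C, q_D, name = "custom") {
  stopifnot(is.numeric(q_C), length(q_C) == 1L, q_C >= 0, q_C <= 1,
            is.numeric(q_D), length(q_D) == 1L, q_D >= 0, q_D <= 1)
  structure(list(name = name, q_C = q_C, q_D = q_D), class = "social_norm")
}

#' @export
print.social_norm <- function(x, ...) {
  cat(sprintf("<social_norm> %s (q_C = %g, q_D = %g)\n", x$name, x$q_C, x$q_D))
  invisible(x)
}

#' Assessment probabilities under errors
#'
#' Probability that a donor who *intends* action Y (cooperate C or defect D)
#' toward a recipient the observer views as X (good G or bad B) ends up with a
#' good standing, once execution errors (intended cooperation fails with
#' probability \code{u_e}) and assessment errors (the assigned standing is
#' flipped with probability \code{u_a}) are folded in:
#' \deqn{P_{GC} = (1-u_e)(1-u_a) + u_e u_a \equiv \epsilon,\quad
#'       P_{GD} = u_a,}
#' \deqn{P_{BC} = q_C(\epsilon - u_a) + q_D(1 - \epsilon - u_a) + u_a,\quad
#'       P_{BD} = q_D(1 - 2 u_a) + u_a.}
#' In the error-free limit these reduce to (1, 0, q_C, q_D).
#'
#' @param norm a \code{social_norm}.
#' @param u_a assessment error rate in [0, 1/2].
#' @param u_e execution error rate in [0, 1/2].
#' @return list with elements \code{eps}, \code{P_GC}, \code{P_GD},
#'   \code{P_BC}, \code{P_BD}.
#' @examples
#' assessment_probabilities(social_norm("SternJudging"), u_a = 0.02, u_e = 0.02)
#' @export
assessment_probabilities <- function(norm, u_a, u_e) {
  stopifnot(inherits(norm, "social_norm"))
  check_rate(u_a, "u_a")
  check_rate(u_e, "u_e")
  eps <- (1 - u_e) * (1 - u_a) + u_e * u_a
  list(
    eps  = eps,
    P_GC = eps,
    P_GD = u_a,
    P_BC = norm$q_C * (eps - u_a) + norm$q_D * (1 - eps - u_a) + u_a,
    P_BD = norm$q_D * (1 - 2 * u_a) + u_a
  )
}

check_rate <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 0.5) {
    stop(what, " must be a single value in [0, 1/2], got ",
         deparse(substitute(x)), " = ", format(x), call. = FALSE)
  }
  invisible(x)
}

#' Monitoring-scale agreement indicator
#'
#' Reputation information (individual or stereotyped) can be shared at three
#' scales: \code{"private"} (every individual holds her own views),
#' \code{"group-wise"} (each group holds a common view), or \code{"public"}
#' (a single population-wide view). The agreement indicator gives the
#' probability that a donor in group J and an observer in group I consult the
#' *same* view: 0 for private, \eqn{\delta_{IJ}} for group-wise, 1 for public.
#'
#' @param scale one of \code{"private"}, \code{"group-wise"}, \code{"public"}.
#' @param I,J group indices (1-based).
#' @return 0 or 1.
#' @export
agreement_indicator <- function(scale, I, J) {
  scale <- match_scale(scale)
  stopifnot(I >= 1, J >= 1, I == round(I), J == round(J))
  switch(scale,
    "private"    = 0,
    "group-wise" = as.numeric(I == J),
    "public"     = 1
  )
}

match_scale <- function(scale) {
  key <- tolower(gsub("[ _]", "-", scale))
  if (key == "groupwise") key <- "group-wise"
  if (!key %in% c("private", "group-wise", "public")) {
    stop("unknown monitoring scale '", scale,
         "'; valid options are: private, group-wise, public", call. = FALSE)
  }
  key
}

# K x K agreement matrix for a scale (rows/cols are groups)
agreement_matrix <- function(scale, K) {
  scale <- match_scale(scale)
  switch(scale,
    "private"    = matrix(0, K, K),
    "group-wise" = diag(K),
    "public"     = matrix(1, K, K)
  )
}
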