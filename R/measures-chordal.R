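#' Scalar chordal kernel on the unit interval
#'
#' The chordal (stereographic-sphere) metric restricted to \eqn{[0, 1]}:
#' \deqn{d(x, y) = \frac{|x - y|}{\sqrt{1 + x^2}\,\sqrt{1 + y^2}}.}
#' On this domain the norm in the general definition reduces to the
#' absolute value, and the kernel is bounded by \eqn{1/\sqrt{2}}, attained
#' at \eqn{(1, 0)}. Unlike a linear difference, the kernel shrinks the same
#' gap \eqn{|x - y|} more when the grades themselves are large, which is
#' what makes the induced set distance nonlinear.
#'
#' @param x,y Numeric vectors in \eqn{[0, 1]} (recycled to a common
#'   length).
#' @return Numeric vector of kernel values in \eqn{[0, 1/\sqrt{2}]}.
#' @examples
#' chordal_kernel(1, 0)        # 1/sqrt(2)
#' chordal_kernel(0.7, 0.6)
#' @export
chordal_kernel <- function(x, y) {
  check_unit_interval(x, "x"); check_unit_interval(y, "y")
  abs(x - y) / (sqrt(1 + x^2) * sqrt(1 + y^2))
}

#' Scalar non-Archimedean kernel on the unit interval
#'
#' A valuation-style distance with floor parameter \eqn{\lambda \in [0, 1]}:
#' \deqn{d_\lambda(x, y) = \frac{|x - y|}{\max(\lambda, x)\,\max(\lambda, y)}.}
#' Small grades inflate the distance (up to \eqn{1/\lambda^2}), so
#' \eqn{\lambda} acts as a pessimism floor: lowering it magnifies
#' disagreement on weakly graded elements. At \eqn{\lambda = 0} the kernel
#' is genuinely undefined when exactly one argument is zero; that case is
#' surfaced as a degeneracy error rather than silently returning `Inf`.
#' The removable \eqn{0/0} case (both arguments zero) evaluates to 0.
#'
#' @inheritParams chordal_kernel
#' @param lam Floor parameter \eqn{\lambda} in \eqn{[0, 1]}.
#' @return Numeric vector of non-negative kernel values.
#' @examples
#' nonarch_kernel(1, 0, lam = 0.1)   # 10
#' nonarch_kernel(0.7, 0.6, lam = 0.8)
#' @export
nonarch_kernel <- function(x, y, lam) {
  check_unit_interval(x, "x"); check_unit_interval(y, "y")
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0 || lam > 1) {
    abort("`lam` must be a single number in [0, 1].",
          class = "pfdist_validation_error")
  }
  num <- abs(x - y)
  den <- pmax(lam, x) * pmax(lam, y)
  bad <- den == 0 & num > 0
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Non-Archimedean kernel undefined: lam = 0 and exactly one of (x = %g, y = %g) is zero.",
      x[i], y[i]),
      class = "pfdist_degenerate_error")
  }
  ifelse(den == 0, 0, num / den)
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1].", name),
          class = "pfdist_validation_error")
  }
  invisible(TRUE)
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0) {
    abort("`p` must be a single positive number.",
          class = "pfdist_validation_error")
  }
  invisible(TRUE)
}

#' Generalized chordal distance between Pythagorean fuzzy sets
#'
#' Aggregates the [chordal_kernel()] over membership and non-membership
#' channels with a Minkowski-like exponent \eqn{p > 0}:
#' \deqn{D_p(P, Q) = \left( \frac{1}{2^{1 - p/2}\, n} \sum_{i=1}^n
#'   \left[ d(\mu_P, \mu_Q)^p + d(\nu_P, \nu_Q)^p \right] \right)^{1/p},}
#' where \eqn{d} is the chordal kernel and \eqn{n} the universe size. The
#' prefactor's power applies to 2 only; with \eqn{p = 1, n = 1} the crisp
#' opposite pair \eqn{(1,0)} vs \eqn{(0,1)} attains exactly 1, and the
#' distance is bounded in \eqn{[0, 1]}, separable and symmetric. Being a
#' sum of two symmetric channel terms, it cannot distinguish a profile
#' pair from its mirrored pair (a documented trade-off of the
#' construction; see [pf_discriminate()]).
#'
#' @param P,Q `pfset` objects on the same universe.
#' @param p Positive exponent; larger values emphasise the worst-matching
#'   element.
#' @return A single non-negative number in \eqn{[0, 1]}.
#' @examples
#' pf_chordal(pfset(1, 0), pfset(0, 1), p = 1)  # exactly 1
#' @export
pf_chordal <- function(P, Q, p = 1) {
  P <- as_pfset(P); Q <- as_pfset(Q)
  check_universe(P, Q)
  check_p(p)
  n <- nrow(P)
  km <- chordal_kernel(P$mu, Q$mu)
  kn <- chordal_kernel(P$nu, Q$nu)
  (sum(km^p + kn^p) / (2^(1 - p / 2) * n))^(1 / p)
}

#' Non-Archimedean chordal distance between Pythagorean fuzzy sets
#'
#' Aggregates the [nonarch_kernel()] over both grade channels:
#' \deqn{D_p^\lambda(P, Q) = \left( \sum_{i=1}^n \left[
#'   \left(\frac{d_\lambda(\mu_P, \mu_Q)}{20n}\right)^p +
#'   \left(\frac{d_\lambda(\nu_P, \nu_Q)}{20n}\right)^p \right] \right)^{1/p}.}
#' Each kernel term is divided by \eqn{20n} before raising to \eqn{p};
#' with \eqn{n = 1, p = 1, \lambda = 0.1} the crisp opposite pair attains
#' exactly 1. The value is not clamped to \eqn{[0, 1]}: for small
#' \eqn{\lambda} the kernel can reach \eqn{1/\lambda^2} and no unit bound
#' holds in general. At \eqn{\lambda = 0} a kernel degeneracy
#' (see [nonarch_kernel()]) propagates as an error.
#'
#' @inheritParams pf_chordal
#' @param lam Floor parameter \eqn{\lambda \in [0, 1]}; larger values give
#'   uniformly smaller distances (an optimistic reading of the data).
#' @return A single non-negative number.
#' @examples
#' pf_nonarch(pfset(1, 0), pfset(0, 1), p = 1, lam = 0.1)  # exactly 1
#' @export
pf_nonarch <- function(P, Q, p = 1, lam = 0.5) {
  P <- as_pfset(P); Q <- as_pfset(Q)
  check_universe(P, Q)
  check_p(p)
  n <- nrow(P)
  km <- nonarch_kernel(P$mu, Q$mu, lam)
  kn <- nonarch_kernel(P$nu, Q$nu, lam)
  (sum((km / (20 * n))^p + (kn / (20 * n))^p))^(1 / p)
}

#' Distance between two Pythagorean fuzzy sets under any supported measure
#'
#' Unified front end over the two chordal distances of this package and
#' the sixteen established measures (see [pf_conventions()] for the
#' replication dialects of the latter).
#'
#' @param P,Q `pfset` objects (or data frames coercible via [as_pfset()])
#'   on the same universe.
#' @param measure `"chordal"`, `"nonarch"`, or one of `pf_measures`.
#' @param context Replication context for established measures; ignored by
#'   the chordal family.
#' @param convention Optional one-row convention (as returned by
#'   [pf_convention()]) overriding `context`.
#' @param p Exponent for the chordal family.
#' @param lam Floor parameter for `"nonarch"`.
#' @return A single numeric distance.
#' @examples
#' P <- pfset(c(0.7, 1.0, 0.2), c(0.1, 0.0, 0.6))
#' Q <- pfset(c(0.6, 0.9, 0.1), c(0.2, 0.1, 0.7))
#' pf_distance(P, Q, "hamming", context = "table3")
#' pf_distance(P, Q, "chordal", p = 1)
#' @export
pf_distance <- function(P, Q, measure, context = "as_printed",
                        convention = NULL, p = 1, lam = 0.5) {
  measure <- match.arg(measure, c("chordal", "nonarch", pf_measures))
  if (measure == "chordal") return(pf_chordal(P, Q, p = p))
  if (measure == "nonarch") return(pf_nonarch(P, Q, p = p, lam = lam))
  P <- as_pfset(P); Q <- as_pfset(Q)
  check_universe(P, Q)
  if (is.null(convention)) convention <- pf_convention(measure, context)
  stopifnot(is.data.frame(convention), nrow(convention) == 1)
  eval_existing(measure, P, Q,
                power = convention$power,
                hesitancy = convention$hesitancy,
                variant = convention$variant)
}
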