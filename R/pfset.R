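#' Construct a Pythagorean (or intuitionistic) fuzzy set
#'
#' A Pythagorean fuzzy set (PFS) grades every element of a finite universe
#' with a membership degree \eqn{\mu} and a non-membership degree \eqn{\nu},
#' both in \eqn{[0, 1]}, under the constraint \eqn{\mu^2 + \nu^2 \le 1}.
#' Intuitionistic fuzzy sets (IFS) use the stricter constraint
#' \eqn{\mu + \nu \le 1}; every IFS is a PFS but not conversely. The object
#' returned is a tibble with columns `element`, `mu` and `nu`, so all the
#' usual data-frame verbs apply.
#'
#' @param mu,nu Numeric vectors of equal length with the membership and
#'   non-membership degrees.
#' @param element Optional character vector of unique element labels (the
#'   universe). Defaults to `"x1", "x2", ...`.
#' @param mode Validation mode: `"pythagorean"` (default) enforces
#'   \eqn{\mu^2 + \nu^2 \le 1}, `"intuitionistic"` enforces
#'   \eqn{\mu + \nu \le 1}. A tolerance of `1e-9` absorbs decimal
#'   round-trip noise.
#' @return A tibble of class `pfset` with columns `element`, `mu`, `nu`.
#' @examples
#' pfset(mu = c(0.7, 1), nu = c(0.6, 0))          # valid PFS
#' try(pfset(0.7, 0.6, mode = "intuitionistic"))  # 0.7 + 0.6 > 1
#' @export
pfset <- function(mu, nu, element = NULL, mode = c("pythagorean", "intuitionistic")) {
  mode <- match.arg(mode)
  validate_pf_pair(mu, nu, mode)
  if (is.null(element)) element <- paste0("x", seq_along(mu))
  element <- as.character(element)
  if (length(element) != length(mu)) {
    abort("`element` must have one label per (mu, nu) pair.",
          class = "pfdist_validation_error")
  }
  if (anyDuplicated(element)) {
    abort("Universe labels must be unique.", class = "pfdist_validation_error")
  }
  if (length(mu) < 1) {
    abort("A fuzzy set needs at least one element.",
          class = "pfdist_validation_error")
  }
  new_pfset(tibble(element = element, mu = as.double(mu), nu = as.double(nu)))
}

new_pfset <- function(x) {
  class(x) <- c("pfset", class(tibble()))
  x
}

#' Coerce a data frame to a `pfset`
#'
#' @param x A data frame with columns `mu` and `nu`, and optionally
#'   `element`.
#' @inheritParams pfset
#' @return A `pfset` tibble.
#' @export
as_pfset <- function(x, mode = c("pythagorean", "intuitionistic")) {
  if (inherits(x, "pfset")) return(x)
  stopifnot(is.data.frame(x), all(c("mu", "nu") %in% names(x)))
  pfset(x$mu, x$nu, element = if ("element" %in% names(x)) x$element, mode = mode)
}

#' Validate membership/non-membership pairs
#'
#' Checks that all grades lie in \eqn{[0, 1]} and that the constraint of the
#' requested family holds: \eqn{\mu^2 + \nu^2 \le 1} (Pythagorean) or
#' \eqn{\mu + \nu \le 1} (intuitionistic). Everything the intuitionistic
#' mode accepts the Pythagorean mode accepts too.
#'
#' @inheritParams pfset
#' @return Invisibly, a tibble with columns `mu`, `nu`.
#' @export
validate_pf_pair <- function(mu, nu, mode = c("pythagorean", "intuitionistic")) {
  mode <- match.arg(mode)
  eps <- 1e-9
  if (!is.numeric(mu) || !is.numeric(nu) || length(mu) != length(nu)) {
    abort("`mu` and `nu` must be numeric vectors of equal length.",
          class = "pfdist_validation_error")
  }
  if (anyNA(mu) || anyNA(nu)) {
    abort("Membership grades must not be missing.",
          class = "pfdist_validation_error")
  }
  out <- mu < -eps | mu > 1 + eps | nu < -eps | nu > 1 + eps
  if (any(out)) {
    i <- which(out)[1]
    abort(sprintf("Grades must lie in [0, 1]; got (mu = %g, nu = %g).",
                  mu[i], nu[i]),
          class = c("pfdist_constraint_error", "pfdist_validation_error"))
  }
  bad <- if (mode == "pythagorean") mu^2 + nu^2 > 1 + eps else mu + nu > 1 + eps
  if (any(bad)) {
    i <- which(bad)[1]
    msg <- if (mode == "pythagorean") {
      sprintf("Pythagorean constraint mu^2 + nu^2 <= 1 violated: %g^2 + %g^2 = %g > 1.",
              mu[i], nu[i], mu[i]^2 + nu[i]^2)
    } else {
      sprintf("Intuitionistic constraint mu + nu <= 1 violated: %g + %g = %g > 1.",
              mu[i], nu[i], mu[i] + nu[i])
    }
    abort(msg, class = c("pfdist_constraint_error", "pfdist_validation_error"))
  }
  invisible(tibble(mu = as.double(mu), nu = as.double(nu)))
}

#' Hesitancy (indeterminacy) degree
#'
#' Adds the residual grade \eqn{\pi} to a fuzzy set. Under the Pythagorean
#' convention \eqn{\pi = \sqrt{1 - \mu^2 - \nu^2}}, which lies in
#' \eqn{[0, 1]} for every valid pair. Under the intuitionistic convention
#' \eqn{\pi = 1 - \mu - \nu}, returned unclamped: for grades that are valid
#' Pythagorean but not intuitionistic pairs (e.g. \eqn{(0.2, 0.9)}) the
#' value is negative, which is exactly what measures referencing the
#' intuitionistic hesitancy see on such data.
#'
#' @param x A `pfset` (or data frame with `mu`, `nu` columns).
#' @param convention `"pythagorean"` or `"intuitionistic"`.
#' @return `x` with an added `hesitancy` column.
#' @examples
#' pf_hesitancy(pfset(0.7, 0.1))                       # sqrt(1 - .49 - .01)
#' pf_hesitancy(pfset(0.2, 0.9), "intuitionistic")     # -0.1, unclamped
#' @export
pf_hesitancy <- function(x, convention = c("pythagorean", "intuitionistic")) {
  convention <- match.arg(convention)
  x <- as_pfset(x)
  h <- if (convention == "pythagorean") {
    sqrt(pmax(0, 1 - x$mu^2 - x$nu^2))
  } else {
    1 - x$mu - x$nu
  }
  mutate(x, hesitancy = h)
}

#' Complement of a fuzzy set
#'
#' Swaps membership and non-membership element-wise; an involution.
#'
#' @param x A `pfset`.
#' @return A `pfset` on the same universe.
#' @export
pf_complement <- function(x) {
  x <- as_pfset(x)
  new_pfset(tibble(element = x$element, mu = x$nu, nu = x$mu))
}

check_universe <- function(x, y) {
  if (nrow(x) != nrow(y) || !identical(x$element, y$element)) {
    abort("The two sets must be defined on the same universe (same labels in the same order).",
          class = "pfdist_universe_error")
  }
  invisible(TRUE)
}

#' Set relations and operations on a shared universe
#'
#' `pf_is_subset(x, y)` is `TRUE` iff element-wise \eqn{\mu_x \le \mu_y}
#' and \eqn{\nu_x \ge \nu_y}. Union takes \eqn{(\max\mu, \min\nu)},
#' intersection \eqn{(\min\mu, \max\nu)}, element-wise. Both require the
#' two sets to share the universe; a mismatch is an error, never a silent
#' join.
#'
#' @param x,y `pfset` objects on the same universe.
#' @return `pf_is_subset()`: a logical scalar; the others: a `pfset`.
#' @export
pf_is_subset <- function(x, y) {
  x <- as_pfset(x); y <- as_pfset(y)
  check_universe(x, y)
  all(x$mu <= y$mu & x$nu >= y$nu)
}

#' @rdname pf_is_subset
#' @export
pf_union <- function(x, y) {
  x <- as_pfset(x); y <- as_pfset(y)
  check_universe(x, y)
  new_pfset(tibble(element = x$element,
                   mu = pmax(x$mu, y$mu), nu = pmin(x$nu, y$nu)))
}

#' @rdname pf_is_subset
#' @export
pf_intersection <- function(x, y) {
  x <- as_pfset(x); y <- as_pfset(y)
  check_universe(x, y)
  new_pfset(tibble(element = x$element,
                   mu = pmin(x$mu, y$mu), nu = pmax(x$nu, y$nu)))
}

#' Is a fuzzy set crisp?
#'
#' A set is crisp when every element is fully in, \eqn{(1, 0)}, or fully
#' out, \eqn{(0, 1)}.
#'
#' @param x A `pfset`.
#' @return Logical scalar.
#' @export
pf_is_crisp <- function(x) {
  x <- as_pfset(x)
  all((x$mu == 1 & x$nu == 0) | (x$mu == 0 & x$nu == 1))
}

#' @export
print.pfset <- function(x, ...) {
  cat(sprintf("# A Pythagorean fuzzy set over %d element%s\n",
              nrow(x), if (nrow(x) == 1) "" else "s"))
  print(as_tibble(unclass_pfset(x)), ...)
  invisible(x)
}

unclass_pfset <- function(x) {
  class(x) <- setdiff(class(x), "pfset")
  x
}
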