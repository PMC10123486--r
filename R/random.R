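#' Seeded random fuzzy sets for property testing
#'
#' Samples fuzzy sets whose validity holds by construction, used to drive
#' the package's property suites.
#'
#' * `"pythagorean"`: \eqn{(\mu, \nu)} uniform on the quarter disk
#'   \eqn{\mu^2 + \nu^2 \le 1} by rejection from the unit square
#'   (acceptance rate \eqn{\pi/4}).
#' * `"intuitionistic"`: uniform on the triangle \eqn{\mu + \nu \le 1},
#'   again by rejection.
#' * `"nested_triple"`: a chain \eqn{P \subseteq Q \subseteq R} built per
#'   element by sorting three membership draws ascending and pairing them
#'   with the three non-membership draws sorted descending; each
#'   resulting pair is dominated by one of the original valid draws, so
#'   the chain stays Pythagorean-valid.
#'
#' The same `seed` reproduces the same output; the caller's RNG state is
#' left untouched.
#'
#' @param n Universe size (\eqn{\ge 1}).
#' @param seed Optional integer seed.
#' @param mode Sampling mode, see above.
#' @return A `pfset`, or for `"nested_triple"` a list `list(P, Q, R)` of
#'   three `pfset`s with `pf_is_subset(P, Q)` and `pf_is_subset(Q, R)`.
#' @examples
#' pf_random(3, seed = 1)
#' tr <- pf_random(4, seed = 1, mode = "nested_triple")
#' pf_is_subset(tr$P, tr$Q)
#' @export
pf_random <- function(n, seed = NULL,
                      mode = c("pythagorean", "intuitionistic", "nested_triple")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer.",
          class = "pfdist_validation_error")
  }
  n <- as.integer(n)
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(seed)
  }
  switch(mode,
    pythagorean = {
      p <- sample_disk(n)
      pfset(p$mu, p$nu)
    },
    intuitionistic = {
      p <- sample_region(n, function(mu, nu) mu + nu <= 1)
      pfset(p$mu, p$nu, mode = "intuitionistic")
    },
    nested_triple = {
      draws <- replicate(3, sample_disk(n), simplify = FALSE)
      mus <- apply(cbind(draws[[1]]$mu, draws[[2]]$mu, draws[[3]]$mu), 1, sort)
      nus <- apply(cbind(draws[[1]]$nu, draws[[2]]$nu, draws[[3]]$nu), 1,
                   sort, decreasing = TRUE)
      list(P = pfset(mus[1, ], nus[1, ]),
           Q = pfset(mus[2, ], nus[2, ]),
           R = pfset(mus[3, ], nus[3, ]))
    })
}

sample_disk <- function(n) sample_region(n, function(mu, nu) mu^2 + nu^2 <= 1)

sample_region <- function(n, keep) {
  mu <- numeric(0); nu <- numeric(0)
  while (length(mu) < n) {
    m <- runif(2 * (n - length(mu)) + 4)
    v <- runif(length(m))
    ok <- keep(m, v)
    mu <- c(mu, m[ok]); nu <- c(nu, v[ok])
  }
  list(mu = mu[seq_len(n)], nu = nu[seq_len(n)])
}
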