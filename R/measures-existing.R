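#' @rdname pf_conventions
#' @format NULL
#' @export
pf_measures <- c("hamming", "euclidean", "norm_hamming", "norm_euclidean",
                 "ba_sq1", "ba_sq2", "grzegorzewski", "yang_chiclana",
                 "wang_xin", "jin", "song", "ren", "peng", "ejegwa_awolola",
                 "sarkar_biswas", "mahanta_panda")

# Measures whose formulas never reference the hesitancy degree.
pi_free_measures <- c("ba_sq1", "ba_sq2", "grzegorzewski", "wang_xin",
                      "mahanta_panda")
# Measures whose printed formulas operate on first powers regardless of the
# surrounding squared-grade dialect.
first_power_measures <- c("ba_sq1", "song", "ejegwa_awolola")

#' Replication conventions for the established distance measures
#'
#' The sixteen established PFS distance measures are printed in the
#' literature in a squared-grade (Pythagorean) dialect, yet the numerical
#' comparison tables that circulate with them were computed under mixed
#' dialects: most columns use first-power grade differences with the
#' intuitionistic hesitancy \eqn{1 - \mu - \nu}, a few use squared grades
#' and/or the Pythagorean hesitancy, and one (peng) uses a different
#' normalizer altogether. A *replication convention* records, per measure
#' and per published table, which dialect reproduces the printed cells:
#'
#' * `power` -- whether each occurrence of \eqn{\mu^2} (resp. \eqn{\nu^2},
#'   \eqn{\pi^2}) in the printed formula is evaluated as printed (`2`) or
#'   on the first powers (`1`);
#' * `hesitancy` -- which residual degree feeds the formula
#'   (`"pythagorean"`, `"intuitionistic"`, or `"none"` for measures that
#'   never reference it);
#' * `variant` -- an alternative normalizer where the table demonstrably
#'   used one (`peng` only: the tables match a `1/(2n)`-normalized
#'   absolute-difference sum over squared grades, not the printed
#'   `1/(4n)` squared-term formula).
#'
#' Contexts: `"as_printed"` is the literal reading of the published
#' formulas; `"table3"`, `"table4"`, `"table6"` reproduce, respectively,
#' the pattern-recognition, medical-diagnosis and medicine-selection
#' comparison tables. Conventions were verified cell-by-cell against the
#' printed tables; `sarkar_biswas` is shipped as printed because no tested
#' dialect reproduces its table cells, and `ejegwa_awolola` reproduces its
#' pattern-recognition column only (see the package vignette).
#'
#' @param measure One of `pf_measures`.
#' @param context One of `"as_printed"`, `"table3"`, `"table4"`, `"table6"`.
#' @return `pf_conventions()`: a tibble with one row per (measure, context)
#'   pair and columns `measure`, `formula` (a stable per-measure formula
#'   id, `F01`..`F16`, in registry order), `context`, `power`,
#'   `hesitancy`, `variant`, `verified`. `pf_convention()`: a one-row
#'   subset of it.
#' @examples
#' pf_convention("hamming", "table3")
#' pf_conventions()
#' @export
pf_conventions <- function() {
  rows <- lapply(pf_measures, function(m) {
    lapply(c("as_printed", "table3", "table4", "table6"), function(ctx) {
      cbind(measure = m, formula = measure_formula[[m]], context = ctx,
            convention_row(m, ctx))
    })
  })
  as_tibble(do.call(rbind, unlist(rows, recursive = FALSE)))
}

measure_formula <- stats::setNames(sprintf("F%02d", 1:16), pf_measures)

convention_row <- function(measure, context) {
  printed <- !context %in% c("table3", "table4", "table6")
  power <-
    if (measure %in% first_power_measures) 1L
    else if (measure %in% c("ren", "peng", "mahanta_panda", "sarkar_biswas")) 2L
    else if (printed) 2L
    else 1L
  hesitancy <-
    if (measure %in% pi_free_measures) "none"
    else if (!printed && context != "table6" &&
             !measure %in% c("ren", "peng", "ejegwa_awolola", "sarkar_biswas"))
      "intuitionistic"
    else "pythagorean"
  variant <- if (measure == "peng" && !printed) "table" else "printed"
  verified <- !printed &&
    !(measure == "sarkar_biswas") &&
    !(measure == "ejegwa_awolola" && context != "table3")
  data.frame(power = power, hesitancy = hesitancy, variant = variant,
             verified = verified, stringsAsFactors = FALSE)
}

#' @rdname pf_conventions
#' @export
pf_convention <- function(measure, context = "as_printed") {
  measure <- match.arg(measure, pf_measures)
  context <- match.arg(context, c("as_printed", "table3", "table4", "table6"))
  as_tibble(cbind(measure = measure, formula = measure_formula[[measure]],
                  context = context, convention_row(measure, context)))
}

# Hesitancy raised to the convention's power: with power 1 the pi of the
# chosen convention, with power 2 its square (pythagorean: 1 - mu^2 - nu^2).
powered_pi <- function(mu, nu, power, hesitancy) {
  switch(hesitancy,
    none = rep(0, length(mu)),
    intuitionistic = 1 - mu - nu,
    pythagorean = pmax(0, 1 - mu^2 - nu^2)^(power / 2))
}

# Element-wise evaluation of one established measure under a convention.
# P, Q: pfset tibbles on a shared universe.
eval_existing <- function(measure, P, Q, power, hesitancy, variant = "printed") {
  n <- nrow(P)
  mP <- P$mu^power; nP <- P$nu^power
  mQ <- Q$mu^power; nQ <- Q$nu^power
  pP <- powered_pi(P$mu, P$nu, power, hesitancy)
  pQ <- powered_pi(Q$mu, Q$nu, power, hesitancy)
  a <- abs(mP - mQ); b <- abs(nP - nQ); h <- abs(pP - pQ)
  switch(measure,
    hamming        = sum(a + b + h) / 2,
    euclidean      = sqrt(sum(a^2 + b^2 + h^2) / 2),
    norm_hamming   = sum(a + b + h) / (2 * n),
    norm_euclidean = sqrt(sum(a^2 + b^2 + h^2) / (2 * n)),
    ba_sq1         = sum((sqrt(P$mu) - sqrt(Q$mu))^2 +
                         (sqrt(P$nu) - sqrt(Q$nu))^2) / (2 * n),
    ba_sq2         = sum((sqrt(a) + sqrt(b))^2) / (4 * n),
    grzegorzewski  = sum(pmax(a, b)) / n,
    yang_chiclana  = sum(pmax(a, b, h)) / n,
    wang_xin       = sum((a + b) / 4 + pmax(a, b) / 2) / n,
    jin            = sum(a + b + h + 2 * pmax(a, b, h)) / (4 * n),
    song           = {
      # Operates on first powers as printed; only the hesitancy convention
      # varies. Products that are negative by floating-point noise only
      # (|x| <= 1e-9) are clamped to zero; genuinely negative products of
      # intuitionistic hesitancies on non-IFS data propagate as NaN.
      pP1 <- powered_pi(P$mu, P$nu, 1, hesitancy)
      pQ1 <- powered_pi(Q$mu, Q$nu, 1, hesitancy)
      pr <- pP1 * pQ1
      pr[pr < 0 & pr >= -1e-9] <- 0
      1 - sum(2 * sqrt(P$mu * Q$mu) + 2 * sqrt(P$nu * Q$nu) + sqrt(pr) +
              sqrt((1 - P$mu) * (1 - Q$mu)) +
              sqrt((1 - P$nu) * (1 - Q$nu))) / (3 * n)
    },
    ren            = sqrt(sum(a^2 + b^2 + h^2) / (2 * n)),
    peng           = if (variant == "table") sum(a + b + h) / (2 * n)
                     else sum(a^2 + b^2 + h^2) / (4 * n),
    ejegwa_awolola = sum(abs(mP - mQ) + abs(mP - nP) - abs(mQ - nQ) +
                         abs(mP - pP) - abs(mQ - pQ)) / (4 * n),
    sarkar_biswas  = sum(a + b + h +
                         abs(pmax(mP, nQ) - pmax(mQ, nP))) / (3 * n),
    mahanta_panda  = {
      den <- mP + mQ + nP + nQ
      # 0/0 element terms (both pairs entirely zero) contribute 0: the
      # numerator vanishes with the denominator and the continuous
      # extension keeps self-distance at zero.
      term <- ifelse(den == 0, 0, (a + b) / den)
      sum(term) / n
    },
    abort(paste0("Unknown measure: ", measure),
          class = "pfdist_validation_error"))
}
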