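# Split a long tibble (set, element, mu, nu) into named pfsets, keeping
# first-appearance order of the set column.
split_sets <- function(data, set_col) {
  stopifnot(all(c(set_col, "element", "mu", "nu") %in% names(data)))
  ids <- unique(data[[set_col]])
  sets <- lapply(ids, function(id) {
    rows <- data[data[[set_col]] == id, , drop = FALSE]
    pfset(rows$mu, rows$nu, element = rows$element)
  })
  names(sets) <- ids
  sets
}

new_pf_ranking <- function(tab, best, is_tie, measure_label) {
  structure(tab, best = best, is_tie = is_tie, measure = measure_label,
            class = c("pf_ranking", class(tibble())))
}

measure_label <- function(measure, context, p, lam) {
  switch(measure,
    chordal = sprintf("chordal (p = %g)", p),
    nonarch = sprintf("nonarch (p = %g, lambda = %g)", p, lam),
    sprintf("%s [%s]", measure, context))
}

#' Nearest-prototype classification
#'
#' Assigns a query set to the known pattern at minimum distance. Each
#' prototype and the query must share one universe; distances are computed
#' under the requested measure and the winner is the argmin. Exact ties
#' are broken deterministically in favour of the earliest prototype and
#' flagged via the `is_tie` attribute.
#'
#' @param data A tibble in long form with columns `prototype`,
#'   `element`, `mu`, `nu` (one block of rows per known pattern), or a
#'   named list of `pfset` objects.
#' @param query A `pfset` on the same universe.
#' @inheritParams pf_distance
#' @param ... Passed on to [pf_distance()] (`context`, `p`, `lam`, ...).
#' @return A `pf_ranking` tibble with columns `alternative`, `distance`,
#'   `rank`, and attributes `best`, `is_tie`, `measure`. Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @examples
#' prob <- pf_example("patterns")
#' pf_classify(prob$prototypes, prob$query, "hamming", context = "table3")
#' @export
pf_classify <- function(data, query, measure, ...) {
  sets <- if (is.data.frame(data)) split_sets(data, "prototype") else data
  if (!length(sets)) {
    abort("`data` must contain at least one prototype pattern.",
          class = "pfdist_validation_error")
  }
  query <- as_pfset(query)
  d <- vapply(sets, function(P) pf_distance(P, query, measure, ...),
              numeric(1))
  rank_from_distances(names(sets), d, measure, ...)
}

rank_from_distances <- function(alternatives, d, measure, context = "as_printed",
                                p = 1, lam = 0.5, ...) {
  ord <- order(d)  # stable: ties keep input order
  tab <- tibble(alternative = alternatives[ord], distance = unname(d[ord]),
                rank = seq_along(d))
  is_tie <- sum(abs(d - min(d)) < 1e-12) > 1
  new_pf_ranking(tab, best = tab$alternative[1], is_tie = is_tie,
                 measure_label(measure, context, p, lam))
}

#' Decision matrices of Pythagorean fuzzy assessments
#'
#' Bundles an alternatives-by-criteria table of \eqn{(\mu, \nu)}
#' assessments with the per-criterion polarity needed to orient it:
#' benefit criteria are to be maximized, cost criteria minimized.
#'
#' @param data Long tibble with columns `alternative`, `criterion`, `mu`,
#'   `nu`; every alternative must grade every criterion exactly once.
#' @param polarity Named character vector (or tibble with columns
#'   `criterion`, `polarity`) mapping every criterion to `"benefit"` or
#'   `"cost"`.
#' @return A `pf_decision_matrix` tibble with a `polarity` attribute.
#' @examples
#' pf_example("medicines")
#' @export
pf_decision_matrix <- function(data, polarity) {
  stopifnot(all(c("alternative", "criterion", "mu", "nu") %in% names(data)))
  if (is.data.frame(polarity)) {
    polarity <- stats::setNames(polarity$polarity, polarity$criterion)
  }
  criteria <- unique(data$criterion)
  alts <- unique(data$alternative)
  if (nrow(data) != length(criteria) * length(alts) ||
      anyDuplicated(data[c("alternative", "criterion")])) {
    abort("Decision matrix must be rectangular: one cell per (alternative, criterion).",
          class = "pfdist_validation_error")
  }
  if (!all(criteria %in% names(polarity)) ||
      !all(polarity[criteria] %in% c("benefit", "cost"))) {
    abort("`polarity` must map every criterion to \"benefit\" or \"cost\".",
          class = "pfdist_validation_error")
  }
  validate_pf_pair(data$mu, data$nu, "pythagorean")
  structure(as_tibble(data), polarity = polarity[criteria],
            class = c("pf_decision_matrix", class(tibble())))
}

#' Ideal solution of a decision matrix
#'
#' Builds the synthetic best alternative criterion-wise from column
#' extrema, oriented by polarity: a benefit criterion takes
#' \eqn{(\max_i \mu_{ij}, \min_i \nu_{ij})}, a cost criterion
#' \eqn{(\min_i \mu_{ij}, \max_i \nu_{ij})}. The result weakly dominates
#' every alternative once criteria are polarity-oriented.
#'
#' @param x A [pf_decision_matrix()].
#' @return A `pfset` over the criteria labels.
#' @export
pf_ideal <- function(x) {
  stopifnot(inherits(x, "pf_decision_matrix"))
  pol <- attr(x, "polarity")
  criteria <- names(pol)
  mu <- vapply(criteria, function(cj) {
    v <- x$mu[x$criterion == cj]
    if (pol[[cj]] == "benefit") max(v) else min(v)
  }, numeric(1))
  nu <- vapply(criteria, function(cj) {
    v <- x$nu[x$criterion == cj]
    if (pol[[cj]] == "benefit") min(v) else max(v)
  }, numeric(1))
  pfset(mu, nu, element = criteria)
}

#' Rank alternatives by distance to the ideal solution
#'
#' Each alternative's row is read as a fuzzy set over the criteria and its
#' distance to [pf_ideal()] is computed under the requested measure; the
#' smallest distance identifies the best alternative.
#'
#' @inheritParams pf_ideal
#' @inheritParams pf_classify
#' @return A `pf_ranking` (see [pf_classify()]).
#' @examples
#' pf_rank(pf_example("medicines"), "grzegorzewski", context = "table6")
#' @export
pf_rank <- function(x, measure, ...) {
  stopifnot(inherits(x, "pf_decision_matrix"))
  ideal <- pf_ideal(x)
  rows <- split_sets(mutate(as_tibble(x), element = .data$criterion),
                     "alternative")
  d <- vapply(rows, function(P) pf_distance(P, ideal, measure, ...), numeric(1))
  rank_from_distances(names(rows), d, measure, ...)
}

#' Sensitivity sweep over the chordal-family parameters
#'
#' Recomputes a whole decision problem over a grid of exponents `p` (and
#' floors `lam` for the non-Archimedean family) and reports, per grid
#' cell, the distances and induced ranking. The sweep's `stable` attribute
#' is `TRUE` iff the ranking order is identical across all non-degenerate
#' cells; cells where the \eqn{\lambda = 0} kernel is undefined are marked
#' `degenerate` and reported as `NA` rather than invented numbers.
#'
#' @param x Either a prototype tibble (see [pf_classify()]) together with
#'   `query`, or a [pf_decision_matrix()].
#' @param query The query `pfset` (prototype problems only).
#' @param family `"chordal"` or `"nonarch"`.
#' @param p_grid,lam_grid Parameter grids; `lam_grid` is ignored by the
#'   chordal family.
#' @return A `pf_sweep` tibble with columns `family`, `p`, `lam`,
#'   `alternative`, `distance`, `rank`, `degenerate`, and attribute
#'   `stable`.
#' @examples
#' prob <- pf_example("patterns")
#' sw <- pf_sweep(prob$prototypes, prob$query, family = "chordal",
#'                p_grid = c(1, 2))
#' attr(sw, "stable")
#' @export
pf_sweep <- function(x, query = NULL, family = c("chordal", "nonarch"),
                     p_grid = c(1, 2, 5, 10, 50),
                     lam_grid = c(0, 0.4, 0.6, 0.8, 1)) {
  family <- match.arg(family)
  if (!length(p_grid) || (family == "nonarch" && !length(lam_grid))) {
    abort("Parameter grids must be non-empty.",
          class = "pfdist_validation_error")
  }
  if (inherits(x, "pf_decision_matrix")) {
    ideal <- pf_ideal(x)
    sets <- split_sets(mutate(as_tibble(x), element = .data$criterion),
                       "alternative")
    ref <- ideal
  } else {
    sets <- if (is.data.frame(x)) split_sets(x, "prototype") else x
    ref <- as_pfset(query)
  }
  grid <- if (family == "chordal") {
    tidyr::expand_grid(p = p_grid, lam = NA_real_)
  } else {
    tidyr::expand_grid(p = p_grid, lam = lam_grid)
  }
  cells <- purrr::pmap(grid, function(p, lam) {
    d <- vapply(sets, function(P) {
      tryCatch(
        if (family == "chordal") pf_chordal(P, ref, p = p)
        else pf_nonarch(P, ref, p = p, lam = lam),
        pfdist_degenerate_error = function(e) NA_real_)
    }, numeric(1))
    tibble(family = family, p = p, lam = lam,
           alternative = names(sets), distance = unname(d),
           rank = if (anyNA(d)) NA_integer_ else rank(d, ties.method = "first"),
           degenerate = is.na(d))
  })
  out <- bind_rows(cells)
  orders <- purrr::map(cells, function(cell) {
    if (anyNA(cell$distance)) NULL else cell$alternative[order(cell$distance)]
  })
  orders <- purrr::compact(orders)
  stable <- length(orders) > 0 &&
    all(vapply(orders, identical, logical(1), y = orders[[1]]))
  structure(out, stable = stable,
            class = c("pf_sweep", class(tibble())))
}

#' Discrimination diagnostic across profile pairs
#'
#' A distance measure is poorly discriminating when it assigns identical
#' values to distinct profile pairs. Given a list of profiles -- each a
#' pair of single-element fuzzy sets \eqn{(A, B)} -- and a list of measure
#' specifications, this computes \eqn{d(A, B)} per profile and groups
#' profiles whose distances agree within `tol` (default `5e-5`, matching
#' four-decimal reporting).
#'
#' @param profiles Tibble with columns `label`, `muA`, `nuA`, `muB`,
#'   `nuB`; any universe size is accepted when `muA` etc. are replaced by
#'   list columns, but the canonical use is single-element profiles.
#' @param specs Tibble of measure specifications with columns `spec`
#'   (display label), `measure`, and optionally `context`, `p`, `lam`.
#'   Defaults to [pf_default_specs()].
#' @param tol Absolute tolerance for "identical" distances.
#' @return A `pf_discrimination` tibble with columns `spec`, `label`,
#'   `distance`, `group` (integer id shared by profiles with equal
#'   distance under that spec) and `group_size`.
#' @examples
#' rep <- pf_discriminate(pf_example("profiles"))
#' dplyr::filter(rep, spec == "hamming [table3]", group_size > 1)
#' @export
pf_discriminate <- function(profiles, specs = pf_default_specs(),
                            tol = 5e-5) {
  stopifnot(all(c("label", "muA", "nuA", "muB", "nuB") %in% names(profiles)))
  rows <- purrr::pmap(specs, function(spec, measure, context = "as_printed",
                                      p = 1, lam = 0.5, ...) {
    d <- purrr::pmap_dbl(
      profiles[c("muA", "nuA", "muB", "nuB")],
      function(muA, nuA, muB, nuB) {
        pf_distance(pfset(muA, nuA), pfset(muB, nuB), measure,
                    context = context, p = p, lam = lam)
      })
    grp <- group_within_tol(d, tol)
    tibble(spec = spec, label = profiles$label, distance = d, group = grp)
  })
  out <- bind_rows(rows)
  out <- mutate(group_by(out, .data$spec, .data$group),
                group_size = dplyr::n())
  out <- ungroup(out)
  structure(out, tol = tol,
            class = c("pf_discrimination", class(tibble())))
}

# Integer group ids such that two values share an id iff they agree within
# tol of a chain neighbour (single-linkage on the sorted values; with tol
# well below the data resolution this equals exact-agreement grouping).
group_within_tol <- function(d, tol) {
  ord <- order(d)
  grp_sorted <- cumsum(c(1, diff(d[ord]) > tol))
  grp <- integer(length(d))
  grp[ord] <- grp_sorted
  grp
}

#' Measure specifications for the discrimination diagnostic
#'
#' The sixteen established measures under a chosen replication context,
#' plus the two chordal-family distances at canonical parameters.
#'
#' @param context Replication context for the established measures.
#' @param p,lam Parameters for the chordal-family rows.
#' @return A tibble with columns `spec`, `measure`, `context`, `p`, `lam`.
#' @export
pf_default_specs <- function(context = "table3", p = 1, lam = 0.6) {
  bind_rows(
    tibble(spec = paste0(pf_measures, " [", context, "]"),
           measure = pf_measures, context = context, p = 1, lam = 0.5),
    tibble(spec = sprintf("chordal (p = %g)", p),
           measure = "chordal", context = "as_printed", p = p, lam = 0.5),
    tibble(spec = sprintf("nonarch (p = %g, lambda = %g)", p, lam),
           measure = "nonarch", context = "as_printed", p = p, lam = lam))
}
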