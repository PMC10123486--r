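#' Built-in case-study datasets
#'
#' Four small benchmark datasets used throughout the package's examples
#' and tests, transcribed from the published case studies:
#'
#' * `"profiles"` -- twelve profile pairs of intuitionistic fuzzy numbers
#'   used by the discrimination diagnostic; returns a tibble with columns
#'   `label`, `muA`, `nuA`, `muB`, `nuB`.
#' * `"patterns"` -- three known patterns plus an unknown query over a
#'   three-element universe; returns
#'   `list(prototypes = <tibble>, query = <pfset>)`.
#' * `"diagnoses"` -- five candidate diagnoses (malaria, kidney stone,
#'   typhoid, dengue, viral fever) over five symptoms plus one patient;
#'   same shape as `"patterns"`.
#' * `"medicines"` -- six COVID-19 medicines assessed on eight
#'   performance criteria (fever, shortness of breath, cough, myalgia,
#'   anorexia, ease of breathing, antiviral activity, coolify); the first
#'   five criteria are costs, the last three benefits; returns a
#'   [pf_decision_matrix()]. Some cells, e.g. \eqn{(0.2, 0.9)}, are valid
#'   Pythagorean but not intuitionistic pairs, which is exactly why the
#'   Pythagorean family is needed here.
#'
#' @param name One of `"profiles"`, `"patterns"`, `"diagnoses"`,
#'   `"medicines"`.
#' @return See above.
#' @examples
#' pf_example("patterns")$query
#' @export
pf_example <- function(name = c("profiles", "patterns", "diagnoses",
                                "medicines")) {
  name <- match.arg(name)
  switch(name,
         profiles = example_profiles(),
         patterns = example_patterns(),
         diagnoses = example_diagnoses(),
         medicines = example_medicines())
}

example_profiles <- function() {
  tibble(
    label = paste0("Profile ", 1:12),
    muA = c(0.5, 0.3, 0.2, 0.6, 0.4, 0.6, 0.3, 0.4, 0.0, 0.0, 0.1, 0.2),
    nuA = c(0.5, 0.6, 0.4, 0.4, 0.4, 0.4, 0.3, 0.5, 0.0, 0.0, 0.3, 0.5),
    muB = c(0.4, 0.4, 0.4, 0.4, 0.5, 0.5, 0.2, 0.5, 1.0, 0.5, 0.2, 0.3),
    nuB = c(0.55, 0.55, 0.45, 0.45, 0.5, 0.5, 0.2, 0.4, 0.0, 0.5, 0.4, 0.7))
}

long_sets <- function(sets, universe, set_col = "prototype") {
  bind_rows(lapply(names(sets), function(id) {
    m <- sets[[id]]
    tibble("{set_col}" := id, element = universe, mu = m[[1]], nu = m[[2]])
  }))
}

example_patterns <- function() {
  u <- paste0("x", 1:3)
  prototypes <- long_sets(list(
    P1 = list(c(1.0, 0.6, 0.4), c(0.0, 0.2, 0.3)),
    P2 = list(c(0.7, 1.0, 0.2), c(0.1, 0.0, 0.6)),
    P3 = list(c(0.8, 0.5, 0.9), c(0.1, 0.1, 0.0))), u)
  query <- pfset(c(0.6, 0.9, 0.1), c(0.2, 0.1, 0.7), element = u)
  list(prototypes = prototypes, query = query)
}

example_diagnoses <- function() {
  u <- c("headache", "cough", "chest_pain", "temperature", "stomach_pain")
  prototypes <- long_sets(list(
    "P1 (Malaria)"      = list(c(0.7, 0.5, 0.2, 0.5, 0.3), c(0.1, 0.5, 0.8, 0.3, 0.7)),
    "P2 (Kidney Stone)" = list(c(0.1, 0.9, 0.5, 0.7, 0.8), c(0.4, 0.0, 0.2, 0.1, 0.1)),
    "P3 (Typhoid)"      = list(c(0.2, 1.0, 0.6, 0.1, 0.3), c(0.7, 0.0, 0.3, 0.9, 0.4)),
    "P4 (Dengue)"       = list(c(0.6, 0.7, 0.5, 0.2, 0.7), c(0.1, 0.2, 0.4, 0.3, 0.3)),
    "P5 (Viral Fever)"  = list(c(0.9, 0.1, 0.4, 0.1, 0.8), c(0.0, 0.2, 0.4, 0.2, 0.2))), u)
  query <- pfset(c(0.8, 0.4, 0.1, 0.5, 0.2), c(0.2, 0.4, 0.8, 0.4, 0.6),
                 element = u)
  list(prototypes = prototypes, query = query)
}

example_medicines <- function() {
  crit <- paste0("C", 1:8)
  rows <- list(
    M1 = list(c(0.2, 0.2, 0.4, 0.5, 0.5, 0.5, 0.1, 0.5),
              c(0.7, 0.6, 0.7, 0.8, 0.6, 0.7, 0.7, 0.8)),
    M2 = list(c(0.4, 0.3, 0.1, 0.4, 0.7, 0.4, 0.4, 0.3),
              c(0.7, 0.9, 0.8, 0.7, 0.7, 0.6, 0.8, 0.6)),
    M3 = list(c(0.2, 0.1, 0.2, 0.4, 0.6, 0.3, 0.2, 0.4),
              c(0.9, 0.8, 0.7, 0.4, 0.7, 0.8, 0.9, 0.7)),
    M4 = list(c(0.1, 0.4, 0.4, 0.2, 0.3, 0.2, 0.3, 0.5),
              c(0.7, 0.7, 0.8, 0.5, 0.7, 0.8, 0.7, 0.5)),
    M5 = list(c(0.1, 0.2, 0.3, 0.4, 0.1, 0.9, 0.8, 0.8),
              c(0.6, 0.9, 0.8, 0.6, 0.8, 0.2, 0.3, 0.4)),
    M6 = list(c(0.3, 0.3, 0.4, 0.1, 0.4, 0.1, 0.2, 0.6),
              c(0.8, 0.6, 0.9, 0.8, 0.7, 0.9, 0.8, 0.7)))
  data <- long_sets(rows, crit, set_col = "alternative")
  names(data)[names(data) == "element"] <- "criterion"
  pf_decision_matrix(data, polarity = stats::setNames(
    c(rep("cost", 5), rep("benefit", 3)), crit))
}
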