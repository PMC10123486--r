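# Grades are stored as decimal strings in JSON so fixture files round-trip
# without binary float drift.
num_chr <- function(x) vapply(x, format, character(1), digits = 15)

chr_num <- function(x, where) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    abort(sprintf("Non-numeric grade in %s: %s", where,
                  paste(x[is.na(v)], collapse = ", ")),
          class = c("pfdist_parse_error", "pfdist_validation_error"))
  }
  v
}

pairs_out <- function(mu, nu) list(mu = num_chr(mu), nu = num_chr(nu))

pairs_in <- function(obj, where, universe = NULL) {
  mu <- chr_num(unlist(obj$mu), paste0(where, "$mu"))
  nu <- chr_num(unlist(obj$nu), paste0(where, "$nu"))
  if (length(mu) != length(nu) ||
      (!is.null(universe) && length(mu) != length(universe))) {
    abort(sprintf("Field %s: mu/nu lengths disagree with the universe.", where),
          class = c("pfdist_parse_error", "pfdist_validation_error"))
  }
  tryCatch(validate_pf_pair(mu, nu, "pythagorean"),
           pfdist_constraint_error = function(e) {
             abort(sprintf("Field %s: %s", where, conditionMessage(e)),
                   class = c("pfdist_parse_error", "pfdist_validation_error"))
           })
  list(mu = mu, nu = nu)
}

#' Read and write fuzzy decision datasets
#'
#' A small JSON schema (`schema_version` `"1.0"`) covers the three problem
#' shapes the package works with: `prototype_problem` (named prototype
#' sets plus a query over a shared universe), `decision_problem`
#' (alternatives by criteria with per-criterion benefit/cost polarity),
#' and `profile_list` (pairs of single-element sets for the
#' discrimination diagnostic). Grades are stored as decimal strings so a
#' save/load round trip reproduces values exactly; every pair is
#' validated in Pythagorean mode on read, and malformed files fail with
#' the offending field named. A `profile_list` may also be a CSV file
#' with columns `label,muA,nuA,muB,nuB`.
#'
#' @param path File path; `.csv` is treated as a profile list.
#' @param x For `write_pf_dataset()`: a `list(prototypes =, query =)`
#'   prototype problem, a [pf_decision_matrix()], or a profiles tibble.
#' @return `read_pf_dataset()`: a list with element `kind` and, depending
#'   on the kind, `prototypes` + `query`, `matrix`, or `profiles`.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_pf_dataset(pf_example("medicines"), path)
#' read_pf_dataset(path)$matrix
#' @export
read_pf_dataset <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(read_profiles_csv(path))
  }
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    abort(paste0("Cannot parse JSON: ", conditionMessage(e)),
                          class = c("pfdist_parse_error", "pfdist_validation_error"))
                  })
  kind <- obj$kind
  if (is.null(kind) ||
      !kind %in% c("prototype_problem", "decision_problem", "profile_list")) {
    abort("Dataset `kind` must be prototype_problem, decision_problem or profile_list.",
          class = c("pfdist_parse_error", "pfdist_validation_error"))
  }
  switch(kind,
    prototype_problem = {
      u <- as.character(unlist(obj$universe))
      protos <- bind_rows(lapply(names(obj$prototypes), function(id) {
        p <- pairs_in(obj$prototypes[[id]], paste0("prototypes$", id), u)
        tibble(prototype = id, element = u, mu = p$mu, nu = p$nu)
      }))
      q <- pairs_in(obj$query, "query", u)
      list(kind = kind, prototypes = protos,
           query = pfset(q$mu, q$nu, element = u))
    },
    decision_problem = {
      crit <- as.character(unlist(obj$criteria))
      pol <- unlist(obj$polarity)
      data <- bind_rows(lapply(names(obj$alternatives), function(id) {
        p <- pairs_in(obj$alternatives[[id]], paste0("alternatives$", id), crit)
        tibble(alternative = id, criterion = crit, mu = p$mu, nu = p$nu)
      }))
      list(kind = kind, matrix = pf_decision_matrix(data, polarity = pol))
    },
    profile_list = {
      profiles <- bind_rows(lapply(seq_along(obj$profiles), function(i) {
        pr <- obj$profiles[[i]]
        where <- sprintf("profiles[%d]", i)
        tibble(label = as.character(pr$label),
               muA = chr_num(pr$muA, where), nuA = chr_num(pr$nuA, where),
               muB = chr_num(pr$muB, where), nuB = chr_num(pr$nuB, where))
      }))
      validate_pf_pair(profiles$muA, profiles$nuA, "pythagorean")
      validate_pf_pair(profiles$muB, profiles$nuB, "pythagorean")
      list(kind = kind, profiles = profiles)
    })
}

read_profiles_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   abort(paste0("Cannot parse CSV: ", conditionMessage(e)),
                         class = c("pfdist_parse_error", "pfdist_validation_error"))
                 })
  need <- c("label", "muA", "nuA", "muB", "nuB")
  if (!all(need %in% names(df))) {
    abort("Profile CSV needs columns label,muA,nuA,muB,nuB.",
          class = c("pfdist_parse_error", "pfdist_validation_error"))
  }
  validate_pf_pair(df$muA, df$nuA, "pythagorean")
  validate_pf_pair(df$muB, df$nuB, "pythagorean")
  list(kind = "profile_list", profiles = as_tibble(df[need]))
}

#' @rdname read_pf_dataset
#' @export
write_pf_dataset <- function(x, path) {
  obj <- dataset_json(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

dataset_json <- function(x) {
  if (inherits(x, "pf_decision_matrix")) {
    pol <- attr(x, "polarity")
    alts <- split_sets(mutate(as_tibble(x), element = .data$criterion),
                       "alternative")
    return(list(schema_version = "1.0", kind = "decision_problem",
                criteria = names(pol), polarity = as.list(pol),
                alternatives = lapply(alts, function(s) pairs_out(s$mu, s$nu))))
  }
  if (is.list(x) && !is.data.frame(x) && !is.null(x$prototypes)) {
    protos <- if (is.data.frame(x$prototypes)) {
      split_sets(x$prototypes, "prototype")
    } else {
      x$prototypes
    }
    q <- as_pfset(x$query)
    return(list(schema_version = "1.0", kind = "prototype_problem",
                universe = q$element,
                prototypes = lapply(protos, function(s) pairs_out(s$mu, s$nu)),
                query = pairs_out(q$mu, q$nu)))
  }
  if (is.list(x) && !is.data.frame(x) && !is.null(x$matrix)) {
    return(dataset_json(x$matrix))
  }
  if (is.data.frame(x) && all(c("label", "muA") %in% names(x)) ||
      (is.list(x) && !is.data.frame(x) && !is.null(x$profiles))) {
    profiles <- if (is.data.frame(x)) x else x$profiles
    return(list(schema_version = "1.0", kind = "profile_list",
                profiles = purrr::pmap(
                  profiles[c("label", "muA", "nuA", "muB", "nuB")],
                  function(label, muA, nuA, muB, nuB) {
                    list(label = label,
                         muA = num_chr(muA), nuA = num_chr(nuA),
                         muB = num_chr(muB), nuB = num_chr(nuB))
                  })))
  }
  abort("Don't know how to serialise this object as a dataset.",
        class = "pfdist_validation_error")
}

#' Export the built-in case-study datasets as files
#'
#' Writes the four datasets of [pf_example()] into `dir`:
#' `pattern_recognition.json`, `medical_diagnosis.json`,
#' `covid_medicines.json` and `profiles.csv`.
#'
#' @param dir Target directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
pf_write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    pattern_recognition = file.path(dir, "pattern_recognition.json"),
    medical_diagnosis = file.path(dir, "medical_diagnosis.json"),
    covid_medicines = file.path(dir, "covid_medicines.json"),
    profiles = file.path(dir, "profiles.csv"))
  write_pf_dataset(pf_example("patterns"), paths[["pattern_recognition"]])
  write_pf_dataset(pf_example("diagnoses"), paths[["medical_diagnosis"]])
  write_pf_dataset(pf_example("medicines"), paths[["covid_medicines"]])
  utils::write.csv(pf_example("profiles"), paths[["profiles"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
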