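#' @export
print.pf_ranking <- function(x, ...) {
  cat(sprintf("# Ranking under %s -- best: %s%s\n",
              attr(x, "measure"), attr(x, "best"),
              if (isTRUE(attr(x, "is_tie"))) " (tie)" else ""))
  print(as_tibble(unstructure(x)), ...)
  invisible(x)
}

#' @export
print.pf_sweep <- function(x, ...) {
  cat(sprintf("# Sensitivity sweep (%s family) -- ranking %s across cells\n",
              x$family[1],
              if (isTRUE(attr(x, "stable"))) "stable" else "NOT stable"))
  print(as_tibble(unstructure(x)), ...)
  invisible(x)
}

unstructure <- function(x) {
  attributes(x)[setdiff(names(attributes(x)),
                        c("names", "row.names", "class"))] <- NULL
  class(x) <- class(tibble())
  x
}

#' Tidy and summarise ranking results
#'
#' `tidy()` returns the per-alternative table; `glance()` a one-row
#' summary with the winner, its distance and the tie flag (rankings) or
#' the rank-stability flag and grid size (sweeps).
#'
#' @param x A `pf_ranking` or `pf_sweep` object.
#' @param ... Unused.
#' @return A tibble.
#' @name pfdist-tidiers
NULL

#' @rdname pfdist-tidiers
#' @method tidy pf_ranking
#' @export
tidy.pf_ranking <- function(x, ...) as_tibble(unstructure(x))

#' @rdname pfdist-tidiers
#' @method glance pf_ranking
#' @export
glance.pf_ranking <- function(x, ...) {
  tibble(best = attr(x, "best"),
         best_distance = x$distance[1],
         is_tie = attr(x, "is_tie"),
         n_alternatives = nrow(x),
         measure = attr(x, "measure"))
}

#' @rdname pfdist-tidiers
#' @method tidy pf_sweep
#' @export
tidy.pf_sweep <- function(x, ...) as_tibble(unstructure(x))

#' @rdname pfdist-tidiers
#' @method glance pf_sweep
#' @export
glance.pf_sweep <- function(x, ...) {
  cells <- dplyr::distinct(as_tibble(x)[c("p", "lam")])
  tibble(family = x$family[1],
         stable = attr(x, "stable"),
         n_cells = nrow(cells),
         n_degenerate_cells = nrow(dplyr::distinct(
           dplyr::filter(as_tibble(x), .data$degenerate)[c("p", "lam")])))
}

#' Plot ranking and sweep results
#'
#' `autoplot()` on a `pf_ranking` draws the per-alternative distances as a
#' bar chart (winner first); on a `pf_sweep` it traces the distance of
#' every alternative across the parameter grid, faceted by exponent `p`
#' for the non-Archimedean family.
#'
#' @param object A `pf_ranking` or `pf_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pfdist-autoplot
NULL

#' @rdname pfdist-autoplot
#' @method autoplot pf_ranking
#' @export
autoplot.pf_ranking <- function(object, ...) {
  df <- tidy(object)
  df$alternative <- factor(df$alternative, levels = df$alternative)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alternative, y = .data$distance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "distance",
                  title = attr(object, "measure"),
                  subtitle = paste("best:", attr(object, "best"))) +
    ggplot2::theme_minimal()
}

#' @rdname pfdist-autoplot
#' @method autoplot pf_sweep
#' @export
autoplot.pf_sweep <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !.data$degenerate)
  if (object$family[1] == "chordal") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$distance,
                                     colour = .data$alternative)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "exponent p", y = "distance") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$lam, y = .data$distance,
                                     colour = .data$alternative)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~p, labeller = ggplot2::label_both) +
      ggplot2::labs(x = expression(lambda), y = "distance") +
      ggplot2::theme_minimal()
  }
}
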