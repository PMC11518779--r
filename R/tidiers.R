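# broom-style tidiers and autoplot methods for result objects

#' @export
tidy.cpcapture_capture_report <- function(x, ...) {
  as_tibble(unclass(x)[c("id", "species", "neighbor_species", "margin",
                         "ambiguous", "flagged")])
}

#' @export
glance.cpcapture_capture_report <- function(x, ...) {
  tibble(n_accessions = nrow(x), n_flagged = sum(x$flagged),
         n_ambiguous = sum(x$ambiguous),
         parsimony = attr(x, "parsimony"), excess = attr(x, "excess"))
}

#' @export
tidy.cpcapture_mantel <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p, n_perm = x$n_perm, n = x$n)
}

#' @export
glance.cpcapture_mantel <- tidy.cpcapture_mantel

#' @export
tidy.cpcapture_quartet_votes <- function(x, ...) {
  as_tibble(unclass(x)[c("topology", "votes", "fraction")])
}

#' @export
glance.cpcapture_quartet_votes <- function(x, ...) {
  best <- which.max(x$votes)
  tibble(topology = x$topology[best], support = x$fraction[best],
         n_resolved = attr(x, "n_resolved"),
         n_sampled = attr(x, "n_sampled"))
}

#' @export
print.cpcapture_mantel <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Plot a capture report
#'
#' Patristic margin (distance to nearest same-species leaf minus nearest
#' other-species leaf) per accession; flagged accessions highlighted.
#'
#' @param object a `cpcapture_capture_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cpcapture_capture_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$margin,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ species, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "patristic margin (same - other species)",
                  fill = "capture flag") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot quartet topology votes
#'
#' @param object a `cpcapture_quartet_votes` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cpcapture_quartet_votes <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$topology, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "species topology", y = "quartet vote fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
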