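# ggplot2 views of the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an alternate-base frequency spectrum
#'
#' Bars of alternate-base observations per log-spaced frequency bin, the
#' standard view for separating a sequencing-error floor from true
#' intra-sample polymorphism.
#'
#' @param object A `lux_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lux_spectrum <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col(width = 0.08, fill = "grey35") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "alternate-base frequency",
                  y = "observations",
                  title = "Alternate-base frequency spectrum") +
    ggplot2::theme_minimal()
}

#' Plot TE positions along the genome
#'
#' One horizontal track per contig with a tick per transposase copy,
#' coloured by family: makes insertion-free regions visible at a glance.
#'
#' @param genome A [lux_genome()].
#' @param te_records TE record tibble (e.g. `tidy()` of a
#'   [te_census()]).
#' @return A ggplot.
#' @export
plot_te_map <- function(genome, te_records) {
  lens <- tibble(contig_id = names(genome$contigs),
                 len = unname(str_length(genome$contigs)))
  rec <- filter(te_records, !is.na(family_id))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = lens,
                          ggplot2::aes(x = 0, xend = len,
                                       y = contig_id, yend = contig_id),
                          linewidth = 0.6, colour = "grey70") +
    ggplot2::geom_point(data = rec,
                        ggplot2::aes(x = (start + end) / 2, y = contig_id,
                                     colour = family_id),
                        shape = "|", size = 4) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "IS family",
                  title = "Transposase insertions along the genome") +
    ggplot2::theme_minimal()
}

#' Plot a burst-test transposase phylogeny
#'
#' Base-graphics phylogram of the rooted NJ tree with copy tips
#' highlighted; the long stem under a shallow copy clade is the visual
#' signature of a single expansion.
#'
#' @param x A `lux_burst`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.lux_burst <- function(x, ...) {
  if (is.null(x$tree)) {
    inform("no tree to plot (fewer than 2 copies)")
    return(invisible(x))
  }
  ape::plot.phylo(x$tree, cex = 0.5, no.margin = TRUE, ...)
  invisible(x)
}
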