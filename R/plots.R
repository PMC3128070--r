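#' Contig length distribution plot
#'
#' Histogram of contig lengths, faceted by assembly when several contig sets
#' are given.
#'
#' @param assemblies A contig tibble, or a named list of contig tibbles.
#' @param binwidth Histogram bin width, bp.
#' @param min_length Optional strict length filter applied first.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(assemblies, binwidth = 50,
                                     min_length = NULL) {
  if (is.data.frame(assemblies)) assemblies <- list(assembly = assemblies)
  df <- purrr::map_dfr(names(assemblies), function(a) {
    tibble::tibble(assembly = a, length = nchar(assemblies[[a]]$seq))
  })
  if (!is.null(min_length)) df <- df[df$length > min_length, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$assembly), scales = "free_y") +
    ggplot2::labs(x = "contig length (bp)", y = "contigs")
}

#' Contig length versus average coverage plot
#'
#' @param records Coverage tibble from [length_coverage_table()].
#' @return A ggplot object (log-scaled coverage axis).
#' @export
plot_length_vs_coverage <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$ac, y = .data$cl)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "average coverage (ac = ssl/cl)",
                  y = "contig length (bp)")
}

#' Aligned-versus-total contig length and ratio diagnostics
#'
#' Two diagnostic views of a direct assessment: aligned contig span against
#' total contig length, and the aligned fraction (`ratio`) against the hit
#' E-value. Chimeric contigs stand out in the second panel as points with
#' very small E-values but low ratio.
#'
#' @param object A `gene_assessment` from [assess_against_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_assessment <- function(object, ...) {
  hits <- object$hits
  df <- dplyr::bind_rows(
    tibble::tibble(x = hits$contig_length,
                   y = hits$c_end - hits$c_start,
                   panel = "aligned vs total length (bp)"),
    tibble::tibble(x = -log10(pmax(hits$evalue, 1e-300)),
                   y = hits$ratio,
                   panel = "aligned fraction vs -log10 E-value")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
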