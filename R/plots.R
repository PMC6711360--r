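# ggplot2 displays for ordination and congruence results.

#' Plot an nMDS ordination
#'
#' Scatter of the first two nMDS axes, optionally coloured by a grouping
#' such as host species; the stress value is shown in the subtitle.
#'
#' @param object an [nmds()] result.
#' @param groups optional grouping vector, named by sample or in point order.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nmds
#' @export
autoplot.nmds <- function(object, groups = NULL, ...) {
  pts <- object$points
  if (!is.null(groups)) {
    pts$group <- as.character(align_groups(groups, pts$sample_id))
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::labs(
      subtitle = sprintf("stress-1 = %.3f", object$stress),
      x = "nMDS 1", y = "nMDS 2"
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Plot a phylosymbiosis report
#'
#' Dot plot of the normalized Robinson-Foulds and Matching-Cluster distances
#' per dataset (all sections combined and each intestinal section), with the
#' permutation p-value printed beside each point.
#'
#' @param object a [phylosymbiosis_report()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot phylosym_report
#' @export
autoplot.phylosym_report <- function(object, ...) {
  long <- tibble(
    dataset = rep(object$dataset, 2),
    metric = rep(c("nRF", "nMC"), each = nrow(object)),
    value = c(object$nrf, object$nmc),
    p = c(object$p_rf, object$p_mc)
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$value, y = .data$dataset, colour = .data$metric)
  ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("p=%.3f", .data$p)),
      vjust = -1, size = 3, show.legend = FALSE
    ) +
    ggplot2::xlim(-0.05, 1.05) +
    ggplot2::labs(
      x = "normalized distance to host phylogeny", y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}
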