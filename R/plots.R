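# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an association screen
#'
#' Dot plot of the partial Spearman coefficient per region, filled by
#' whether the region survives the FDR threshold.
#'
#' @param object A `netmed_screen` tibble from [roi_association_screen()].
#' @param q_threshold FDR significance level used for the fill.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netmed_screen <- function(object, q_threshold = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$significant <- d$q < q_threshold
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$region, .data$rho),
    y = .data$rho, fill = .data$significant)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey70"),
                               name = sprintf("q < %.2g", q_threshold)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "partial Spearman rho",
                  title = sprintf("Covariate-adjusted association with %s",
                                  d$outcome[1])) +
    ggplot2::theme_minimal()
}

#' Plot a mediation bootstrap distribution
#'
#' Histogram of the bootstrap indirect effects with the point estimate and
#' the bias-corrected interval marked.
#'
#' @param object A `netmed_mediation` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netmed_mediation <- function(object, bins = 60, ...) {
  d <- tibble::tibble(indirect = object$boot_indirects)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$indirect)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$indirect, colour = "#b2182b",
                        linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "bootstrap indirect effect (a*b)", y = "count",
      title = sprintf("%s -> %s -> %s", object$x, object$m, object$y),
      subtitle = sprintf("indirect = %.3f, %d%% BC CI (%.3f, %.3f)",
                         object$indirect, round(100 * (1 - object$alpha)),
                         object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' @param object A `netmed_perm` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netmed_perm <- function(object, bins = 60, ...) {
  d <- tibble::tibble(rho = object$null_rhos)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_rho, colour = "#b2182b",
                        linewidth = 0.8) +
    ggplot2::labs(x = "null partial Spearman rho", y = "count",
                  subtitle = sprintf("observed rho = %.3f, empirical p = %.4g",
                                     object$observed_rho, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a connectivity matrix
#'
#' @param x A `netmed_conn` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(x, ...) {
  stopifnot(inherits(x, "netmed_conn"))
  d <- tibble::as_tibble(as.data.frame.table(x$z, responseName = "z"))
  names(d)[1:2] <- c("roi_i", "roi_j")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi_i, y = .data$roi_j,
                                  fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Fisher-z connectivity: %s", x$subject_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
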