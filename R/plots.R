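#' Plot conversion tracts along the alignment
#'
#' One horizontal segment per detected tract, positioned at its alignment
#' span, faceted by query when several queries are present.
#'
#' @param object A `conversion_tracts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conversion_tracts
#' @export
autoplot.conversion_tracts <- function(object, ...) {
  if (!nrow(object)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no significant tracts") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$start, xend = .data$end,
                               y = .data$query_id, yend = .data$query_id)) +
    ggplot2::geom_segment(linewidth = 3, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2,
      label = paste0("p=", signif(.data$perm_p, 2))), vjust = -1, size = 3) +
    ggplot2::labs(x = "alignment column", y = NULL,
                  title = "Gene-conversion tracts") +
    ggplot2::theme_minimal()
}

#' Plot a qPCR panel as Ct profiles by fraction
#'
#' @param object A `qpcr_panel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qpcr_panel
#' @export
autoplot.qpcr_panel <- function(object, ...) {
  dat <- object |>
    dplyr::group_by(.data$locus_id, .data$compartment, .data$fraction) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction, y = .data$ct,
                                    group = .data$locus_id,
                                    colour = .data$compartment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +   # lower Ct = more template
    ggplot2::labs(y = "mean Ct (reversed)", x = NULL,
                  title = "qPCR copy-number profiles") +
    ggplot2::theme_minimal()
}

#' Plot divergence estimates with bootstrap standard errors
#'
#' @param object A `divergence_estimate` tibble (one or more rows, e.g. the
#'   `divergence` table of an `hgt_report`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot divergence_estimate
#' @export
autoplot.divergence_estimate <- function(object, ...) {
  dat <- tidyr::pivot_longer(tibble::as_tibble(object),
                             cols = c("dN", "dS"), names_to = "measure",
                             values_to = "estimate")
  dat$se <- ifelse(dat$measure == "dN", object$se_dN[match(dat$id_a, object$id_a)],
                   object$se_dS[match(dat$id_a, object$id_a)])
  dat$pair <- paste(dat$id_a, dat$id_b, sep = " vs ")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pair, y = .data$estimate,
                                    fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$se,
                                        ymax = .data$estimate + .data$se),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "substitutions/site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot bootstrap support on the ML tree
#' @param tree A node-labeled tree from [bootstrap_support()].
#' @param support_threshold Labels below this are not drawn (default 50).
#' @return Invisibly, the tree; draws a base-graphics plot.
#' @export
plot_support_tree <- function(tree, support_threshold = 50) {
  lab <- suppressWarnings(as.numeric(tree$node.label))
  show <- ifelse(!is.na(lab) & lab >= support_threshold, lab, "")
  ape::plot.phylo(tree, cex = 0.8)
  ape::nodelabels(show, frame = "none", adj = c(1.2, -0.3), cex = 0.7)
  invisible(tree)
}
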