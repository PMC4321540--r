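#' Diagnostic plot of a pressure-volume fit
#'
#' Draws the observed total water potential, the fitted osmotic line (with
#' the points it was fitted to emphasised), the extracted turgor pressure,
#' and the fitted turgor curve, all against relative water content. Dashed
#' verticals mark the estimated RWC at turgor loss.
#'
#' @param object A `pv_fit` from [derive_pv_result()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pv_fit
#' @export
autoplot.pv_fit <- function(object, ...) {
  d <- object$data
  line <- object$line
  grid <- tibble::tibble(rwc = seq(min(d$rwc), 1, length.out = 200))
  grid$psi_o <- line$intercept + line$slope * grid$rwc
  grid$psi_p <- object$turgor_a *
    (exp(object$turgor_b * (grid$rwc - object$rwc_tlp)) - 1)
  grid$psi_p[grid$rwc < object$rwc_tlp] <- 0

  ggplot2::ggplot(d, ggplot2::aes(x = .data$rwc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$psi_mpa, shape = "total")) +
    ggplot2::geom_point(
      data = d[line$used, ],
      ggplot2::aes(y = .data$psi_mpa, shape = "total"), colour = "steelblue"
    ) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$psi_o, linetype = "osmotic line")
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$psi_p, shape = "turgor")) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$psi_p, linetype = "turgor curve")
    ) +
    ggplot2::geom_vline(xintercept = object$rwc_tlp, linetype = "dashed") +
    ggplot2::labs(
      x = "Relative water content", y = "Water potential (MPa)",
      shape = NULL, linetype = NULL,
      title = sprintf(
        "TLP %.2f MPa at RWC %.2f", object$tlp, object$rwc_tlp
      )
    ) +
    ggplot2::theme_minimal()
}

#' Ordination biplot
#'
#' Species scores on two principal components with trait loadings overlaid
#' as arrows (scaled to the score cloud), optionally coloured by a grouping
#' read from a species table.
#'
#' @param object An `lw_pca` from [phyl_pca()] or [ordinary_pca()].
#' @param components Two component indices (default `c(1, 2)`).
#' @param groups Optional named vector (by species) used to colour scores.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lw_pca
#' @export
autoplot.lw_pca <- function(object, components = c(1, 2), groups = NULL, ...) {
  pcs <- colnames(object$loadings)[components]
  sc <- tibble::as_tibble(object$scores, rownames = "species")
  ld <- tibble::as_tibble(object$loadings, rownames = "trait")
  scale_f <- 0.8 * max(abs(sc[[pcs[1]]]), abs(sc[[pcs[2]]])) /
    max(abs(ld[[pcs[1]]]), abs(ld[[pcs[2]]]))
  if (!is.null(groups)) sc$group <- groups[sc$species]

  p <- ggplot2::ggplot(sc, ggplot2::aes(
    x = .data[[pcs[1]]], y = .data[[pcs[2]]]
  )) +
    (if (is.null(groups)) {
      ggplot2::geom_point()
    } else {
      ggplot2::geom_point(ggplot2::aes(colour = .data$group))
    }) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(
        x = 0, y = 0,
        xend = .data[[pcs[1]]] * scale_f, yend = .data[[pcs[2]]] * scale_f
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey40"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(
        x = .data[[pcs[1]]] * scale_f * 1.08,
        y = .data[[pcs[2]]] * scale_f * 1.08, label = .data$trait
      ),
      size = 3, colour = "grey30"
    ) +
    ggplot2::labs(
      x = sprintf("%s (%.0f%%)", pcs[1], 100 * object$explained[components[1]]),
      y = sprintf("%s (%.0f%%)", pcs[2], 100 * object$explained[components[2]]),
      colour = NULL, title = paste(object$mode, "PCA")
    ) +
    ggplot2::theme_minimal()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
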