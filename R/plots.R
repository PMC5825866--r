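#' Plot a principal coordinates embedding
#'
#' Scatter of the first two principal coordinates, optionally highlighting one
#' sample (typically the query).
#'
#' @param object A `lens_pcoa` object.
#' @param highlight Optional label to emphasise.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lens_pcoa
#' @export
autoplot.lens_pcoa <- function(object, highlight = NULL, ...) {
  df <- tidy(object)
  if (ncol(df) < 3) {
    stop_validation("fewer than two positive components; nothing to plot.")
  }
  names(df)[2:3] <- c("PC1", "PC2")
  df$role <- ifelse(df$label %in% highlight, "query", "compendium")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 2.6, check_overlap = TRUE) +
    ggplot2::scale_colour_manual(values = c(compendium = "grey30", query = "red3"),
                                 guide = if (is.null(highlight)) "none" else "legend") +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = "Principal coordinates of binary expression profiles") +
    ggplot2::theme_minimal()
}

#' Plot a marker-set enrichment table
#'
#' Bar chart of -log10 FDR for the top tissues.
#'
#' @param object A `lens_enrichment` tibble from [fisher_enrichment()].
#' @param n_top Number of tissues shown (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lens_enrichment
#' @export
autoplot.lens_enrichment <- function(object, n_top = 10, ...) {
  df <- utils::head(as_tibble(object), n_top)
  df$tissue <- factor(df$tissue, levels = rev(df$tissue))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$fdr, 1e-300)),
                                   y = .data$tissue)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(x = expression(-log[10] ~ FDR), y = NULL,
                  title = "Tissue marker-set enrichment of the query") +
    ggplot2::theme_minimal()
}

#' Plot a focal stack as an image montage
#'
#' Grey-scale raster of the five planes, faceted by axial offset.
#'
#' @param object A `focal_stack`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot focal_stack
#' @export
autoplot.focal_stack <- function(object, ...) {
  df <- purrr::map_dfr(seq_along(object$planes), function(i) {
    m <- object$planes[[i]]
    tibble(
      plane = sprintf("z = %g um", object$z_offsets[i]),
      x = rep(seq_len(ncol(m)), each = nrow(m)),
      y = rep(seq_len(nrow(m)), times = ncol(m)),
      grey = as.vector(m)
    )
  })
  df$plane <- factor(df$plane, levels = unique(df$plane))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$grey)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~plane, nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "grey") +
    ggplot2::theme_void()
}

#' Plot a dose-response summary
#'
#' Mean +/- s.e.m. of the chosen metric by dose, as produced by
#' [dose_response_summary()].
#'
#' @param summary Tibble from [dose_response_summary()].
#' @param metric_label Axis label for the metric.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(summary, metric_label = "ratio") {
  needed <- c("dose", "mean", "sem")
  if (!all(needed %in% names(summary))) {
    stop_validation("`summary` must come from dose_response_summary().")
  }
  summary$dose <- factor(summary$dose, levels = unique(summary$dose))
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$dose, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = "dose", y = metric_label) +
    ggplot2::theme_minimal()
}
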