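# ggplot2 visualisations.

phase_fill <- c(Push = "#d95f02", Glid = "#7570b3", StPr = "#1b9e77",
                Swim = "#386cb0")

#' Plot a prepared lap with its phase segmentation
#'
#' Facets the global forward acceleration, the gyroscope channels and the
#' roll/pitch angles over time, shading the four phases.
#'
#' @param prep Output of [prepare_imu()] (list with `global`).
#' @param ann Optional `phase_annotation` to shade.
#' @return A ggplot object.
#' @export
plot_lap <- function(prep, ann = NULL) {
  g <- prep$global
  long <- dplyr::bind_rows(
    tibble::tibble(t = g$t, value = g$acc_y, channel = "AccY (m/s^2)"),
    tibble::tibble(t = g$t, value = g$gyr_x, channel = "GyrX (rad/s)"),
    tibble::tibble(t = g$t, value = g$gyr_y, channel = "GyrY (rad/s)"),
    tibble::tibble(t = g$t, value = g$theta * 180 / pi, channel = "theta (deg)"),
    tibble::tibble(t = g$t, value = g$phi * 180 / pi, channel = "phi (deg)")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(ann)) {
    shade <- tibble::tibble(
      phase = factor(PHASES, levels = PHASES),
      xmin = vapply(ann$phases, `[`, numeric(1), 1),
      xmax = vapply(ann$phases, `[`, numeric(1), 2)
    )
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$phase),
      ymin = -Inf, ymax = Inf, alpha = 0.15) +
      ggplot2::scale_fill_manual(values = phase_fill, name = "phase")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.swim_selection <- function(object, ...) {
  w <- object$weights
  w$name <- factor(w$name, levels = rev(w$name))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$weight_pct, y = .data$name,
                                  fill = .data$category,
                                  alpha = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$weight_cutoff, linetype = 2) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "relative weight (%)", y = NULL,
                  title = "LASSO relative weights") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.swim_regression <- function(object, ...) {
  ggplot2::ggplot(object$predictions, ggplot2::aes(x = .data$y, y = .data$yhat)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "reference goal metric", y = "LOO-CV estimate",
      title = sprintf("%s: R2 = %.2f, RMSE = %.3g (%.1f%%)", object$target,
                      object$r2, object$rmse, object$rel_rmse)) +
    ggplot2::theme_minimal()
}

#' Category-contribution bar chart across targets
#'
#' @param result A `swim_pipeline_result`.
#' @return A ggplot object.
#' @export
plot_category_contrib <- function(result) {
  df <- purrr::imap_dfr(result$reports, function(r, tg) {
    cc <- r$selection$category_contrib
    cc$target <- tg
    cc
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target,
                                   y = .data$weight_pct_renorm,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "category contribution (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
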