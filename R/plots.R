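#' Plot an ROC curve
#'
#' @param ... `kegfr_roc` objects, optionally named (names become the
#'   legend labels).
#' @return A ggplot object.
#' @export
plot_roc <- function(...) {
  curves <- list(...)
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    names(curves) <- paste0("curve ", seq_along(curves))
  }
  dat <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    tibble::tibble(
      method = sprintf("%s (AUC %.2f)", nm, cv$auc),
      fpr = 1 - cv$specificity,
      tpr = cv$sensitivity
    ) |>
      dplyr::arrange(.data$fpr, .data$tpr)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(.data$fpr, .data$tpr,
    colour = .data$method
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity", colour = NULL
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a Bland-Altman agreement analysis
#'
#' @param ba A `kegfr_bland_altman` object.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  stopifnot(inherits(ba, "kegfr_bland_altman"))
  dat <- tibble::tibble(mean = ba$means, difference = ba$differences)
  ggplot2::ggplot(dat, ggplot2::aes(.data$mean, .data$difference)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "dotted") +
    ggplot2::geom_hline(
      yintercept = c(ba$loa_lower, ba$loa_upper), linetype = "solid",
      colour = "grey40"
    ) +
    ggplot2::labs(
      x = "Mean of the two estimates (mL/min/1.73 m²)",
      y = "Difference (mL/min/1.73 m²)"
    ) +
    ggplot2::theme_minimal()
}
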