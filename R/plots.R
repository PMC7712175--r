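#' Change-versus-MDC band plot for an individual patient
#'
#' Reproduces the clinician-facing change chart: one horizontal row per
#' variable with a light grey band spanning `(-MDC, +MDC)`, a black bar from
#' 0 to the observed difference, and the probability of a relevant change
#' printed in the right margin. A bar crossing its grey band marks a change
#' larger than the measurement noise of the test.
#'
#' @param res a [monitor_patient()] result (class `balance_mbd`).
#' @param tasks optional character vector restricting the panel (e.g.
#'   `"LOS"`, or the four static tasks); default all.
#' @param facet_tasks facet the plot by task block (default TRUE when a
#'   `task` column is present).
#' @return a ggplot object.
#' @examples
#' p01 <- patient01_example()
#' res <- monitor_patient(p01$pre, p01$post, p01$thresholds)
#' plot_change(res, tasks = "LOS")
#' @export
plot_change <- function(res, tasks = NULL,
                        facet_tasks = "task" %in% names(res)) {
  if (nrow(res) == 0) {
    warn("empty monitoring result: nothing to plot.")
    return(invisible(NULL))
  }
  df <- as_tibble(res)
  if (!is.null(tasks) && "task" %in% names(df)) {
    df <- df[df$task %in% tasks, ]
  }
  df$row <- factor(df$variable, levels = rev(unique(df$variable)))
  df$prob_lab <- sprintf("%d%%", round_half_up(df$p_change))
  xmax <- max(abs(c(df$xdif, df$mdc))) * 1.25
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$row)) +
    ggplot2::geom_tile(
      ggplot2::aes(x = 0, width = 2 * .data$mdc, height = 0.75),
      fill = "grey80") +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = .data$xdif, yend = .data$row),
      linewidth = 1.6, colour = "black", lineend = "butt") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_text(
      ggplot2::aes(x = xmax, label = .data$prob_lab),
      hjust = 1, size = 3) +
    ggplot2::labs(x = "Difference (post - pre)", y = NULL) +
    ggplot2::theme_minimal()
  if (isTRUE(facet_tasks) && "task" %in% names(df)) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(factor(.data$task, levels = unique(df$task))),
      scales = "free_y", space = "free_y")
  }
  p
}

#' @rdname plot_change
#' @param object a `balance_mbd` object.
#' @param ... passed to [plot_change()].
#' @method autoplot balance_mbd
#' @export
autoplot.balance_mbd <- function(object, ...) {
  plot_change(object, ...)
}
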