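#' Histogram of per-participant best cross-correlations
#' @param verdict a [cohort_signal_decision()] result.
#' @return a ggplot object.
#' @export
plot_crosscorr_histogram <- function(verdict) {
  d <- data.frame(best_r = verdict$best_r)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$best_r)) +
    ggplot2::geom_histogram(breaks = seq(-1, 1, by = 0.1),
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = verdict$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "best cross-correlation (optimal lag)",
                  y = "participants",
                  title = "Signal level: optimal cross-correlations") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot with a-priori and empirical limits
#'
#' Green lines mark the a-priori acceptance boundaries, red lines the
#' empirical 95% limits of agreement, dashed black the mean difference.
#' @param ba a [bland_altman()] result.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  p <- ba$pairs
  ggplot2::ggplot(p, ggplot2::aes(x = .data$mean_of_two, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        colour = "red") +
    ggplot2::geom_hline(yintercept = c(-ba$boundary, ba$boundary),
                        colour = "darkgreen") +
    ggplot2::labs(x = "mean of the two devices", y = "wearable - reference",
                  title = sprintf("Bland-Altman: %s", ba$parameter),
                  subtitle = sprintf("%.0f%% within a-priori boundary",
                                     ba$pct_within_boundary)) +
    ggplot2::theme_minimal()
}

#' Per-task line plot (one device)
#'
#' Thin lines per participant, red mean +/- SE per task, zero axis.
#' @param summary a [summarize_tasks()] result.
#' @param y_trans optional y transform, e.g. `"sqrt"` or `"log10"`.
#' @return a ggplot object.
#' @export
plot_task_lines <- function(summary, y_trans = NULL) {
  vals <- attr(summary, "values")
  long <- data.frame(
    participant = rep(rownames(vals), times = ncol(vals)),
    task = factor(rep(colnames(vals), each = nrow(vals)),
                  levels = summary$task),
    value = as.vector(vals)
  )
  g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$task, y = .data$value,
                                          group = .data$participant)) +
    ggplot2::geom_line(alpha = 0.25, colour = "steelblue", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_pointrange(
      data = summary,
      mapping = ggplot2::aes(x = .data$task, y = .data$mean,
                             ymin = .data$mean - .data$se,
                             ymax = .data$mean + .data$se, group = 1),
      colour = "red", na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "task value",
                  title = sprintf("Per-task values (%s)",
                                  summary$device[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(y_trans)) g <- g + ggplot2::scale_y_continuous(trans = y_trans)
  g
}

#' Difference plot with reference-effect boundaries
#'
#' Mean +/- SE of the wearable-minus-reference difference per task, the zero
#' axis in black and the +/- reference-effect band in green.
#' @param comparisons list of [event_comparison()] results.
#' @return a ggplot object.
#' @export
plot_event_differences <- function(comparisons) {
  d <- do.call(rbind, lapply(comparisons, function(cm) {
    data.frame(task = cm$task, diff_mean = cm$diff_mean, diff_se = cm$diff_se,
               ref_effect = cm$ref_effect)
  }))
  d$task <- factor(d$task, levels = d$task)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$task, y = .data$diff_mean,
                                  group = 1)) +
    ggplot2::geom_hline(yintercept = 0, colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ref_effect), colour = "darkgreen",
                       na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = -.data$ref_effect), colour = "darkgreen",
                       na.rm = TRUE) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$diff_mean - .data$diff_se,
                                          ymax = .data$diff_mean + .data$diff_se),
                             colour = "red", na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "wearable - reference",
                  title = "Event level: device differences per task") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

render_figures <- function(results, out_dir) {
  paths <- list()
  save_fig <- function(g, name) {
    p <- file.path(out_dir, name)
    try(suppressMessages(ggplot2::ggsave(p, g, width = 7, height = 5,
                                         dpi = 120)), silent = TRUE)
    p
  }
  if (!is.null(results$signal)) {
    paths$fig_hist <- save_fig(plot_crosscorr_histogram(results$signal),
                               "fig_crosscorr_histogram.png")
  }
  if (!is.null(results$parameter)) {
    for (nm in names(results$parameter$bland_altman)) {
      paths[[paste0("fig_ba_", nm)]] <-
        save_fig(plot_bland_altman(results$parameter$bland_altman[[nm]]),
                 sprintf("fig_bland_altman_%s.png", nm))
    }
  }
  if (!is.null(results$event)) {
    for (nm in names(results$event)) {
      ev <- results$event[[nm]]
      paths[[paste0("fig_tasks_rd_", nm)]] <-
        save_fig(plot_task_lines(ev$rd_summary),
                 sprintf("fig_tasks_rd_%s.png", nm))
      paths[[paste0("fig_tasks_wd_", nm)]] <-
        save_fig(plot_task_lines(ev$wd_summary),
                 sprintf("fig_tasks_wd_%s.png", nm))
      if (length(ev$comparisons) > 0) {
        paths[[paste0("fig_diff_", nm)]] <-
          save_fig(plot_event_differences(ev$comparisons),
                   sprintf("fig_differences_%s.png", nm))
      }
    }
  }
  paths
}
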