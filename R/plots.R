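.lag_labels <- function(lags) {
  frac <- lags / pi
  ifelse(frac == 0, "0", paste0(format(frac, digits = 3), "π"))
}

#' Metric-versus-phase-lag figure
#'
#' One panel per region set, phase lag on the x axis, one line per
#' montage; cohort tables show the across-individual mean with a ribbon
#' of plus/minus one SD.
#'
#' @param records a `tacs_metrics` table.
#' @param metric metric to plot (default the first present).
#' @return a ggplot object.
#' @export
plot_metric_by_lag <- function(records, metric = NULL) {
  if (is.null(metric)) metric <- records$metric[1]
  sub <- dplyr::filter(records, .data$metric == !!metric)
  if (nrow(sub) == 0L) stop("metric '", metric, "' not in records")
  agg <- dplyr::summarise(
    dplyr::group_by(sub, .data$montage_id, .data$region_set,
                    .data$phase_lag),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    .groups = "drop"
  )
  units <- unique(sub$units)[1]
  lab <- if (nzchar(units)) paste0(metric, " (", units, ")") else metric
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$phase_lag, y = .data$mean,
                                    colour = .data$montage_id,
                                    fill = .data$montage_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~region_set, scales = "free_y") +
    ggplot2::scale_x_continuous(
      breaks = sort(unique(agg$phase_lag)),
      labels = .lag_labels(sort(unique(agg$phase_lag)))
    ) +
    ggplot2::labs(x = "phase lag", y = lab, colour = "montage",
                  fill = "montage") +
    ggplot2::theme_minimal()
}

#' @method autoplot tacs_metrics
#' @export
autoplot.tacs_metrics <- function(object, metric = NULL, ...) {
  plot_metric_by_lag(object, metric)
}

#' @method autoplot tacs_phase_tests
#' @export
autoplot.tacs_phase_tests <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$montage_id,
                                    y = .data$p_adjusted,
                                    shape = .data$region_set)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "montage", y = "Holm-adjusted p",
                  shape = "region set") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
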