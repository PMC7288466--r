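#' @export
autoplot.orimin_phases <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phase, y = .data$hours)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f h\n%.3f ccu", .data$hours, .data$ccu)),
      vjust = -0.2, size = 3
    ) +
    ggplot2::labs(
      x = NULL, y = "duration (h)",
      title = sprintf("Cell-cycle phase durations (doubling time %.3g h)",
                      attr(object, "doubling_time"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome minimum origins against chromosome length
#'
#' @param mo_table Output of [genome_mo_table()] (any scenario columns).
#' @return A ggplot object.
#' @export
plot_mo_profile <- function(mo_table) {
  cols <- intersect(c("mo", "mo_mild", "mo_harsh"), names(mo_table))
  if (length(cols) == 0L) {
    abort_domain("`mo_table` has no mo/mo_mild/mo_harsh columns.")
  }
  long <- tidyr::pivot_longer(mo_table, cols = dplyr::all_of(cols),
                              names_to = "scenario", values_to = "origins")
  long$scenario <- factor(long$scenario, levels = c("mo", "mo_mild", "mo_harsh"),
                          labels = c("no stress", "mild stress", "harsh stress"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$length_bp / 1e6, y = .data$origins, colour = .data$scenario
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x,
                         linewidth = 0.5) +
    ggplot2::labs(x = "chromosome length (Mb)", y = "minimum origins",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter and trend lines of origin counts per mapping method
#'
#' Reproduces the method-comparison view: one point per chromosome and
#' method, with an unweighted least-squares trend line per method.  The
#' minimum-origins threshold is drawn like any other method (label it
#' `"MO"` in `data`).
#'
#' @param data A tibble with columns `length_bp`, `count` and `method`.
#' @return A ggplot object.
#' @export
plot_origin_trends <- function(data) {
  needed <- c("length_bp", "count", "method")
  if (!is.data.frame(data) || !all(needed %in% names(data))) {
    abort_domain("`data` must have columns `length_bp`, `count`, `method`.")
  }
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$length_bp / 1e6, y = .data$count, colour = .data$method
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x,
                         linewidth = 0.6) +
    ggplot2::labs(x = "chromosome length (Mb)", y = "origins",
                  colour = "method") +
    ggplot2::theme_minimal()
}
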