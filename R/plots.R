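#' Plot posterior state counts by season
#'
#' Posterior mean and credible ribbon of the imputed number of
#' territories in the chosen state set per season, optionally with the
#' naive count (maximum observed state per territory-year, uncorrected
#' for detection) overlaid as crosses.
#'
#' @param object An `msocc_counts` tibble from [count_states()].
#' @param data Optional survey tibble; when supplied, naive counts are
#'   overlaid.
#' @param level Credible level for the ribbon.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msocc_counts <- function(object, data = NULL, level = 0.9, ...) {
  s <- summarize_counts(object, level = level)
  states <- attr(object, "states")
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Year",
      y = sprintf("Territories in state(s) {%s}",
                  paste(states, collapse = ",")),
      title = sprintf("Imputed territory counts, block %s",
                      attr(object, "block"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    naive <- data |>
      dplyr::group_by(.data$territory, .data$year) |>
      dplyr::summarise(best = max(.data$observed_state), .groups = "drop") |>
      dplyr::filter(.data$best %in% states) |>
      dplyr::count(.data$year)
    p <- p + ggplot2::geom_point(data = naive,
                                 ggplot2::aes(y = .data$n), shape = 4)
  }
  p
}

#' Plot detection probability against date
#'
#' Detection curves for each true state at the posterior means of the
#' detection hyper-parameters: the probability of observing each state as
#' a function of Julian date across the season window.
#'
#' @param fit An `msocc_fit`.
#' @param date_range Julian-date range to display.
#' @return A ggplot.
#' @export
plot_detection <- function(fit, date_range = c(60, 243)) {
  amu <- Reduce(`+`, lapply(fit$chains, function(ch) colMeans(ch$alpha_mu))) /
    length(fit$chains)
  alpha_t <- matrix(amu, 6, 3, byrow = TRUE)
  jd <- seq(date_range[1], date_range[2], by = 2)
  jd_std <- (jd - fit$jd_center) / fit$jd_scale
  rows <- purrr::map_dfr(seq_along(jd), function(i) {
    dpm <- build_dpm(alpha_t, jd_std[i])
    tibble::tibble(
      julian_date = jd[i],
      true_state = rep(2:4, each = 4),
      observed_state = rep(1:4, 3),
      prob = as.vector(t(dpm[2:4, ]))
    )
  })
  rows |>
    dplyr::filter(.data$observed_state <= .data$true_state) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$julian_date, y = .data$prob,
                                 colour = factor(.data$observed_state))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$true_state,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Julian date", y = "Detection probability",
                  colour = "Observed state") +
    ggplot2::theme_minimal()
}
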