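#' Tidy a multistate occupancy fit
#'
#' One row per monitored hyper-level parameter (initial state
#' probabilities, transition hyper-means/SDs, detection hyper-means/SDs)
#' with posterior mean, SD, equal-tailed credible interval, and R-hat
#' (when at least two chains were run).
#'
#' @param x An `msocc_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`, `rhat`.
#' @export
tidy.msocc_fit <- function(x, level = 0.9, ...) {
  nm <- hyper_param_names()
  a <- (1 - level) / 2
  purrr::map_dfr(nm, function(p) {
    d <- as.vector(extract_draws(x, p))
    tibble::tibble(
      parameter = p, mean = mean(d), sd = sd(d),
      lower = unname(quantile(d, a)), upper = unname(quantile(d, 1 - a)),
      rhat = if (length(x$chains) >= 2) gelman_rubin(x, p) else NA_real_
    )
  })
}

#' One-row summary of a multistate occupancy fit
#'
#' @param x An `msocc_fit`.
#' @param ... Unused.
#' @return Tibble with the block label, data and sampler dimensions, the
#'   worst hyper-parameter R-hat, and the Metropolis acceptance rates for
#'   the transition and detection effects.
#' @export
glance.msocc_fit <- function(x, ...) {
  tibble::tibble(
    block = x$block,
    n_territories = length(x$territories),
    n_seasons = length(x$years),
    n_visits = nrow(x$data),
    n_chains = length(x$chains),
    n_draws = nrow(x$chains[[1]]$phi0) * length(x$chains),
    max_rhat = if (length(x$chains) >= 2) max(rhat_table(x)$rhat) else NA_real_,
    accept_beta = mean(vapply(x$chains, `[[`, numeric(1), "accept_beta")),
    accept_alpha = mean(vapply(x$chains, `[[`, numeric(1), "accept_alpha"))
  )
}

#' @export
tidy.trend_estimate <- function(x, ...) {
  tibble::tibble(
    term = sprintf("trend_%d_%d", x$first_year, x$last_year),
    estimate = x$mean, lower = x$lower, upper = x$upper, level = x$level
  )
}
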