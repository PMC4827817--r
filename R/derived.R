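#' Posterior draws of per-season state counts
#'
#' For every retained draw, counts the territories whose imputed latent
#' state falls in `states` in each season — e.g. `states = 4` counts
#' reproducing territories, `states = c(3, 4)` counts all pairs. These
#' counts are the building blocks of the trend estimators and of
#' state-by-year occupancy figures.
#'
#' @param fit An `msocc_fit` fitted with `keep_z = TRUE`.
#' @param states Subset of 1:4 (non-empty).
#' @param years Seasons to include (default: all fitted seasons); must lie
#'   within the fitted range.
#' @return Tibble of class `msocc_counts` with columns `draw`, `year`,
#'   `count`, and attributes `block`, `states`, `n_territories`.
#' @export
count_states <- function(fit, states = 4, years = NULL) {
  states <- as.integer(states)
  if (!length(states) || !all(states %in% 1:4)) {
    stop("states must be a non-empty subset of 1:4", call. = FALSE)
  }
  years <- if (is.null(years)) fit$years else as.integer(years)
  if (!all(years %in% fit$years)) {
    stop("requested years outside the fitted seasons (",
         min(fit$years), "-", max(fit$years), ")", call. = FALSE)
  }
  z <- latent_draws(fit)[, , as.character(years), drop = FALSE]
  hit <- array(z %in% states, dim = dim(z))
  counts <- apply(hit, c(1, 3), sum)
  out <- tibble::tibble(
    draw = rep(seq_len(nrow(counts)), times = length(years)),
    year = rep(years, each = nrow(counts)),
    count = as.vector(counts)
  )
  attr(out, "block") <- fit$block
  attr(out, "states") <- states
  attr(out, "n_territories") <- length(fit$territories)
  class(out) <- c("msocc_counts", class(out))
  out
}

#' Posterior summary of per-season counts
#'
#' @param counts An `msocc_counts` tibble.
#' @param level Credible level for the equal-tailed interval.
#' @return Tibble with one row per year: posterior `mean`, `lower`,
#'   `upper`.
#' @export
summarize_counts <- function(counts, level = 0.9) {
  a <- (1 - level) / 2
  counts |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(mean = mean(.data$count),
                     lower = quantile(.data$count, a),
                     upper = quantile(.data$count, 1 - a),
                     .groups = "drop")
}

trend_window <- function(counts, years) {
  if (is.null(years)) {
    years <- range(counts$year)
  }
  yrs <- sort(unique(counts$year))
  yrs <- yrs[yrs >= min(years) & yrs <= max(years)]
  if (length(yrs) < 2) {
    stop("trend needs at least two seasons in the window", call. = FALSE)
  }
  dplyr::filter(counts, .data$year %in% yrs)
}

#' Posterior linear trend in imputed state counts
#'
#' For each posterior draw s, computes the least-squares slope of the
#' imputed counts on the centred year,
#' `T_L(s) = sum_t N_t(s) (Yr_t - mean(Yr)) / sum_t (Yr_t - mean(Yr))^2`,
#' then summarizes the draws by their mean and equal-tailed credible
#' interval. The estimate is read as the expected average change in the
#' number of territories in the chosen states per one-year interval.
#'
#' @param counts An `msocc_counts` tibble from [count_states()].
#' @param years Length-2 window `(first, last)`, inclusive; default the
#'   full range present in `counts`.
#' @param level Credible level (default 0.9, i.e. 5th/95th percentiles).
#' @return An object of class `trend_estimate`: a one-row tibble with
#'   `mean`, `lower`, `upper`, `level`, `first_year`, `last_year`, and
#'   the per-draw slopes in attribute `draws`.
#' @export
linear_trend <- function(counts, years = NULL, level = 0.9) {
  d <- trend_window(counts, years)
  yrs <- sort(unique(d$year))
  yc <- yrs - mean(yrs)
  denom <- sum(yc^2)
  slopes <- d |>
    dplyr::arrange(.data$draw, .data$year) |>
    dplyr::group_by(.data$draw) |>
    dplyr::summarise(slope = sum(.data$count * yc) / denom, .groups = "drop")
  a <- (1 - level) / 2
  out <- tibble::tibble(
    mean = mean(slopes$slope),
    lower = unname(quantile(slopes$slope, a)),
    upper = unname(quantile(slopes$slope, 1 - a)),
    level = level,
    first_year = min(yrs), last_year = max(yrs)
  )
  attr(out, "draws") <- slopes$slope
  attr(out, "states") <- attr(counts, "states")
  attr(out, "block") <- attr(counts, "block")
  class(out) <- c("trend_estimate", class(out))
  out
}

#' Posterior orthogonal-polynomial trend contrasts
#'
#' Projects each draw's count series onto orthonormal polynomial
#' contrasts of the year ([stats::poly()]). The degree-1 contrast equals
#' the linear slope multiplied by `sqrt(sum((Yr - mean(Yr))^2))` — i.e.
#' [linear_trend()] up to that normalization — and the degree-2 contrast
#' captures curvature orthogonal to the linear component.
#'
#' @inheritParams linear_trend
#' @param degree 1 (linear) or 2 (linear + quadratic contrasts).
#' @return Tibble with one row per contrast (`term` = "linear",
#'   "quadratic"): posterior `mean`, `lower`, `upper`; per-draw contrast
#'   values in attribute `draws` (matrix, draws x terms).
#' @export
polynomial_trend <- function(counts, years = NULL, degree = 1, level = 0.9) {
  stopifnot(degree %in% 1:2)
  d <- trend_window(counts, years)
  yrs <- sort(unique(d$year))
  if (length(yrs) < degree + 1) {
    stop("degree-", degree, " trend needs at least ", degree + 1, " seasons",
         call. = FALSE)
  }
  P <- poly(yrs, degree = degree)  # orthonormal columns
  cmat <- d |>
    dplyr::arrange(.data$draw, .data$year) |>
    (\(x) matrix(x$count, ncol = length(yrs), byrow = TRUE))()
  est <- cmat %*% P  # draws x degree
  a <- (1 - level) / 2
  out <- tibble::tibble(
    term = c("linear", "quadratic")[seq_len(degree)],
    mean = unname(colMeans(est)),
    lower = unname(apply(est, 2, quantile, a)),
    upper = unname(apply(est, 2, quantile, 1 - a)),
    level = level
  )
  attr(out, "draws") <- est
  attr(out, "year_scale") <- sqrt(sum((yrs - mean(yrs))^2))
  out
}

#' Across-year transition probabilities at the hyper-means
#'
#' For each posterior draw, applies the multi-logit transform to the
#' transition hyper-means `mu[m, ]` of row `from`, giving the "average
#' year" transition probability vector, and summarizes the destination
#' probabilities — e.g. `from = 4, to = 4` is the probability of
#' reproducing given reproduction in the previous year, averaged across
#' years of the study.
#'
#' @param fit An `msocc_fit`.
#' @param from Current state (1..4).
#' @param to Destination state(s) to report (default all four).
#' @param level Credible level.
#' @return Tibble with one row per destination: posterior `mean`,
#'   `lower`, `upper`.
#' @export
mean_transition_probs <- function(fit, from, to = 1:4, level = 0.9) {
  stopifnot(from %in% 1:4, all(to %in% 1:4))
  mu <- sapply(2:4, function(n) {
    as.vector(extract_draws(fit, sprintf("beta_mu[%d,%d]", from, n)))
  })
  probs <- t(apply(mu, 1, tpm_row))  # draws x 4
  a <- (1 - level) / 2
  tibble::tibble(
    from = from, to = as.integer(to),
    mean = colMeans(probs)[to],
    lower = apply(probs, 2, quantile, a)[to],
    upper = apply(probs, 2, quantile, 1 - a)[to]
  )
}

#' Trend table across blocks, windows and state sets
#'
#' Builds a publication-style table of posterior linear trends: one row
#' per (block, window, state set), with the posterior mean and
#' equal-tailed credible interval. Windows that extend beyond a block's
#' fitted seasons are reported as NA with a message (e.g. a block whose
#' surveys were discontinued).
#'
#' @param fits A single `msocc_fit` or a list of them.
#' @param windows List of length-2 year windows, e.g.
#'   `list(c(1990, 2002), c(2002, 2014), c(1990, 2014))`.
#' @param state_sets Named list of state subsets, by default
#'   reproductive pairs only (`{4}`) and pairs plus reproductive pairs
#'   (`{3,4}`).
#' @param level Credible level.
#' @return Tibble with columns `block`, `first_year`, `last_year`,
#'   `states`, `mean`, `lower`, `upper`.
#' @export
trend_table <- function(fits,
                        windows = NULL,
                        state_sets = list("reproductive" = 4,
                                          "pairs_and_reproductive" = c(3, 4)),
                        level = 0.9) {
  if (inherits(fits, "msocc_fit")) fits <- list(fits)
  rows <- list()
  for (fit in fits) {
    wins <- windows %||% list(range(fit$years))
    for (nm in names(state_sets)) {
      counts <- count_states(fit, states = state_sets[[nm]])
      for (w in wins) {
        if (min(w) < min(fit$years) || max(w) > max(fit$years)) {
          message("block ", fit$block, ": window ", min(w), "-", max(w),
                  " extends beyond the surveyed seasons; reported as NA")
          rows[[length(rows) + 1L]] <- tibble::tibble(
            block = fit$block, first_year = min(w), last_year = max(w),
            states = nm, mean = NA_real_, lower = NA_real_, upper = NA_real_)
          next
        }
        tr <- linear_trend(counts, years = w, level = level)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          block = fit$block, first_year = tr$first_year,
          last_year = tr$last_year, states = nm,
          mean = tr$mean, lower = tr$lower, upper = tr$upper)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf(
    "Posterior linear trend %d-%d (states {%s}): %.3f (%d%% CRI: %.3f, %.3f) territories/yr\n",
    x$first_year, x$last_year,
    paste(attr(x, "states"), collapse = ","),
    x$mean, round(100 * x$level), x$lower, x$upper))
  invisible(x)
}
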