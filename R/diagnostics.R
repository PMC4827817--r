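#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classic between/within-chain variance ratio on the
#' retained (post-burn-in, thinned) draws: with m chains of n draws,
#' `W` the mean within-chain variance and `B/n` the variance of the chain
#' means, the estimate is `sqrt(((n - 1)/n * W + B/n) / W)`. With
#' `split = TRUE` each chain is first halved, which also detects
#' within-chain trends.
#'
#' @param x An `msocc_fit` or a numeric matrix of draws (iterations in
#'   rows, chains in columns).
#' @param parameter Parameter name (see [extract_draws()]); required for a
#'   fit.
#' @param split Use the split-chain variant.
#' @return The R-hat estimate (numeric scalar).
#' @export
gelman_rubin <- function(x, parameter = NULL, split = FALSE) {
  draws <- if (inherits(x, "msocc_fit")) {
    if (is.null(parameter)) stop("supply a parameter name", call. = FALSE)
    extract_draws(x, parameter)
  } else {
    as.matrix(x)
  }
  if (ncol(draws) < 2) {
    stop("Gelman-Rubin diagnostic needs at least two chains", call. = FALSE)
  }
  if (split) {
    half <- nrow(draws) %/% 2
    draws <- cbind(draws[seq_len(half), , drop = FALSE],
                   draws[nrow(draws) - half + seq_len(half), , drop = FALSE])
  }
  n <- nrow(draws)
  if (n < 2) stop("need at least 2 retained draws per chain", call. = FALSE)
  W <- mean(apply(draws, 2, var))
  B_over_n <- var(colMeans(draws))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' R-hat for all monitored hyper-parameters
#'
#' @param fit An `msocc_fit` with at least two chains.
#' @param split Use split chains.
#' @return Tibble with columns `parameter` and `rhat`, sorted worst first.
#' @export
rhat_table <- function(fit, split = FALSE) {
  nm <- hyper_param_names()
  tibble::tibble(
    parameter = nm,
    rhat = vapply(nm, function(p) gelman_rubin(fit, p, split = split),
                  numeric(1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$rhat))
}
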