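#' Multi-logit (softmax) row with a baseline first category
#'
#' Maps three unconstrained effects for categories 2..4 to a length-4
#' probability vector with category 1 as baseline:
#' `p[n] = exp(b[n]) / (1 + sum(exp(b)))` for n > 1 and
#' `p[1] = 1 / (1 + sum(exp(b)))`. Computed on the log scale
#' (log-sum-exp) so very large or very small effects do not overflow.
#'
#' @param beta Numeric vector of logit-scale effects, one per non-baseline
#'   category.
#' @return Probability vector of length `length(beta) + 1` summing to 1.
#' @export
tpm_row <- function(beta) {
  if (any(!is.finite(beta))) stop("non-finite multi-logit effects", call. = FALSE)
  lp <- c(0, beta)
  m <- max(lp)
  w <- exp(lp - m)
  w / sum(w)
}

#' Build a transition probability matrix from year effects
#'
#' Each row m of the 4x4 matrix is the multi-logit transform of the three
#' effects for destination states 2..4, conditional on current state m.
#'
#' @param beta_t 4x3 numeric matrix of effects; row = current state,
#'   column = destination state 2..4.
#' @return Row-stochastic 4x4 matrix.
#' @export
build_tpm <- function(beta_t) {
  stopifnot(is.matrix(beta_t), nrow(beta_t) == 4, ncol(beta_t) == 3)
  t(apply(beta_t, 1, tpm_row))
}

#' Index of the free detection-matrix entries
#'
#' The detection model has one multi-logit effect (with intercept, linear
#' and quadratic date coefficients) per (true state m, observed state n)
#' pair with 1 < n <= m. This helper enumerates the six pairs in the fixed
#' row order used throughout the package.
#'
#' @return Tibble with columns `pair`, `m`, `n`.
#' @export
dpm_pairs <- function() {
  tibble::tibble(
    pair = 1:6,
    m = c(2L, 3L, 3L, 4L, 4L, 4L),
    n = c(2L, 2L, 3L, 2L, 3L, 4L)
  )
}

#' Build a detection probability matrix for one visit
#'
#' Entry [m, n] is the probability of recording observed state n on a visit
#' to a territory whose true state is m. Row 1 is (1, 0, 0, 0) (nothing can
#' be observed at an unoccupied territory) and entries with n > m are zero:
#' a state higher than the truth cannot be recorded. For m > 1 the row is a
#' multi-logit over observed states 2..m with non-detection (n = 1) as
#' baseline, with linear and quadratic standardized-date terms.
#'
#' @param alpha_t 6x3 numeric matrix of detection effects for one season:
#'   rows follow [dpm_pairs()], columns are (intercept, date, date^2).
#' @param jd_std Standardized Julian date of the visit.
#' @return Row-stochastic 4x4 matrix with zero upper triangle beyond the
#'   true state.
#' @export
build_dpm <- function(alpha_t, jd_std) {
  stopifnot(is.matrix(alpha_t), nrow(alpha_t) == 6, ncol(alpha_t) == 3)
  if (!is.finite(jd_std)) stop("non-finite standardized date", call. = FALSE)
  pairs <- dpm_pairs()
  x <- c(1, jd_std, jd_std^2)
  eta <- as.vector(alpha_t %*% x)
  dpm <- matrix(0, 4, 4)
  dpm[1, 1] <- 1
  for (m in 2:4) {
    idx <- which(pairs$m == m)
    p <- tpm_row(eta[idx])
    dpm[m, c(1L, pairs$n[idx])] <- p
  }
  dpm
}

#' Propagate state probabilities through transition matrices
#'
#' Applies the Chapman-Kolmogorov recursion `phi_t = phi_{t-1} %*% Phi_{t-1}`
#' to obtain the marginal state-probability vector for every season from the
#' initial probabilities and the sequence of yearly transition matrices.
#'
#' @param phi0 Length-4 probability vector of initial state probabilities.
#' @param tpms List of 4x4 row-stochastic transition matrices; `tpms[[t]]`
#'   carries season t to season t + 1.
#' @return Matrix with `length(tpms) + 1` rows; row t is the state
#'   distribution in season t.
#' @export
state_marginals <- function(phi0, tpms) {
  stopifnot(length(phi0) == 4, abs(sum(phi0) - 1) < 1e-8)
  out <- matrix(NA_real_, length(tpms) + 1L, 4L)
  out[1, ] <- phi0
  for (t in seq_along(tpms)) {
    Phi <- tpms[[t]]
    stopifnot(is.matrix(Phi), all(dim(Phi) == 4))
    out[t + 1L, ] <- as.vector(out[t, ] %*% Phi)
  }
  out
}
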