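logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# T x 4 matrix of per-season log detection products for one territory:
# entry [t, m] = sum over that season's visits of log Pr(y | true state m).
# Seasons without visits contribute 0 (log of an empty product).
season_logdet <- function(visits, params, T_) {
  ld <- matrix(0, T_, 4)
  if (!nrow(visits)) return(ld)
  for (r in seq_len(nrow(visits))) {
    t <- visits$season[r]
    dpm <- dpm_at(params, t, visits$jd_std[r])
    ld[t, ] <- ld[t, ] + log(dpm[, visits$y[r]])
  }
  ld
}

#' Marginal log-likelihood of one territory's encounter history
#'
#' Integrates the latent state path out of the state-space model with the
#' forward algorithm: initialize with the initial state probabilities
#' weighted by the first season's detection products, propagate through the
#' yearly transition matrices, and sum the terminal weights. Seasons with no
#' visits contribute transition structure only. All arithmetic is in log
#' space with log-sum-exp, so long histories and extreme detection
#' probabilities do not underflow.
#'
#' @param visits Data frame of the territory's visits with columns
#'   `season` (1-based index into `params$years`), `jd_std`, and `y`
#'   (observed state 1..4). May have zero rows.
#' @param params An [msocc_params()] object.
#' @return Log-likelihood; `-Inf` if every state path is impossible.
#' @export
loglik_territory <- function(visits, params) {
  T_ <- length(params$years)
  ld <- season_logdet(visits, params, T_)
  lf <- log(params$phi0) + ld[1, ]
  if (T_ > 1) {
    for (t in 2:T_) {
      lPhi <- log(build_tpm(matrix(params$beta[t - 1, , ], 4, 3)))
      lf <- vapply(1:4, function(n) logsumexp(lf + lPhi[, n]), numeric(1)) +
        ld[t, ]
    }
  }
  logsumexp(lf)
}

#' Complete-data log-likelihood
#'
#' Joint log-probability of a full latent state trajectory and the observed
#' visit records:
#' the initial-state term, the year-to-year transition terms, and one
#' detection term per visit. Observations that are impossible under the
#' detection constraint (observed state above the latent state) yield
#' `-Inf`.
#'
#' @param z Integer matrix `I x T` of latent states (rows = territories,
#'   in the order of `territories`; columns = seasons of `params$years`).
#' @param data Survey tibble with `jd_std` (see [standardize_dates()]).
#' @param params An [msocc_params()] object.
#' @param territories Character vector giving the row order of `z`;
#'   defaults to the sorted territories present in `data`.
#' @return Log-likelihood (log of the complete-data joint density).
#' @export
loglik_complete <- function(z, data, params,
                            territories = sort(unique(data$territory))) {
  T_ <- length(params$years)
  stopifnot(is.matrix(z), ncol(z) == T_, nrow(z) == length(territories))
  ll <- sum(log(params$phi0[z[, 1]]))
  if (T_ > 1) {
    tpms <- tpm_list(params)
    for (t in 1:(T_ - 1)) {
      ll <- ll + sum(log(tpms[[t]][cbind(z[, t], z[, t + 1])]))
    }
  }
  if (nrow(data)) {
    idx_t <- match(data$territory, territories)
    if (anyNA(idx_t)) stop("data territory missing from z", call. = FALSE)
    seas <- season_index(data$year, params$years)
    for (r in seq_len(nrow(data))) {
      dpm <- dpm_at(params, seas[r], data$jd_std[r])
      ll <- ll + log(dpm[z[idx_t[r], seas[r]], data$observed_state[r]])
    }
  }
  ll
}

#' Marginal log-likelihood of a survey dataset
#'
#' Sum of [loglik_territory()] over all territories in `data`; territories
#' are conditionally independent given the parameters.
#'
#' @param data Survey tibble with `jd_std`.
#' @param params An [msocc_params()] object.
#' @param territories Territories to include (defaults to those in `data`).
#' @return Log-likelihood.
#' @export
loglik_data <- function(data, params,
                        territories = sort(unique(data$territory))) {
  seas <- season_index(data$year, params$years)
  sum(vapply(territories, function(terr) {
    rows <- data$territory == terr
    loglik_territory(
      tibble::tibble(season = seas[rows], jd_std = data$jd_std[rows],
                     y = data$observed_state[rows]),
      params
    )
  }, numeric(1)))
}
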