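#' Draw latent state paths conditional on fixed parameters
#'
#' Exact conditional sampling of each territory's latent state trajectory
#' given the data and a fixed parameter set, by forward-filtering
#' backward-sampling. This is the same latent-state move the Gibbs sampler
#' uses, exposed for simulation studies and model checking.
#'
#' @param params An [msocc_params()] object.
#' @param data Survey tibble with `jd_std`.
#' @param territories Territories to impute (default: those in `data`).
#' @param n Number of independent conditional draws.
#' @return List with `z`, a list of `n` integer matrices
#'   (territories x seasons), and `loglik`, the marginal log-likelihood of
#'   the data under `params` (summed over territories).
#' @export
impute_states <- function(params, data,
                          territories = sort(unique(data$territory)),
                          n = 1) {
  T_ <- length(params$years)
  tpms <- tpm_list(params)
  tpm_flat <- do.call(rbind, lapply(tpms, function(m) as.vector(t(m))))
  if (is.null(tpm_flat)) tpm_flat <- matrix(0, 0, 16)
  seas <- season_index(data$year, params$years)

  logdets <- lapply(territories, function(terr) {
    rows <- data$territory == terr
    season_logdet(
      tibble::tibble(season = seas[rows], jd_std = data$jd_std[rows],
                     y = data$observed_state[rows]),
      params, T_
    )
  })

  loglik <- 0
  z <- replicate(n, matrix(NA_integer_, length(territories), T_,
                           dimnames = list(territories, params$years)),
                 simplify = FALSE)
  for (i in seq_along(territories)) {
    for (s in seq_len(n)) {
      d <- ffbs_cpp(params$phi0, tpm_flat, logdets[[i]])
      if (!length(d$z)) stop("all state paths impossible for territory ",
                             territories[i], call. = FALSE)
      z[[s]][i, ] <- d$z
      if (s == 1) loglik <- loglik + d$loglik
    }
  }
  list(z = z, loglik = loglik)
}
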