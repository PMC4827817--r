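# vectorized multinomial observation draw for visits within one season:
# alpha_t is the season's 6x3 detection-effect matrix, jd the standardized
# dates and m the (common) true state of the visited territories
sim_obs_season <- function(alpha_t, jd, m) {
  n <- length(jd)
  if (m == 1) return(rep(1L, n))
  pairs <- dpm_pairs()
  idx <- which(pairs$m == m)
  X <- cbind(1, jd, jd^2)
  eta <- X %*% t(alpha_t[idx, , drop = FALSE])     # n x (m-1)
  mx <- pmax(0, apply(eta, 1, max))
  w <- cbind(exp(-mx), exp(eta - mx))              # baseline first
  p <- w / rowSums(w)
  cats <- c(1L, pairs$n[idx])
  u <- runif(n)
  pick <- max.col(u < t(apply(p, 1, cumsum)), ties.method = "first")
  cats[pick]
}

#' Simulate a replicated dataset at the observed survey design
#'
#' Draws replicated observed states from the detection model, at exactly
#' the visits (territory, year, date) that occurred in the real data,
#' conditional on a latent state matrix. This is the replication step of a
#' posterior predictive check.
#'
#' @param params An [msocc_params()] object (e.g. one posterior draw).
#' @param z Integer matrix territories x seasons of latent states with
#'   territory rownames covering every surveyed territory.
#' @param design Tibble of visits with columns `territory`, `year`,
#'   `jd_std` (other columns are carried through).
#' @return `design` with a replicated `observed_state` column.
#' @export
simulate_replicate <- function(params, z, design) {
  seas <- season_index(design$year, params$years)
  it <- match(design$territory, rownames(z))
  if (anyNA(it)) stop("design territory missing from z", call. = FALSE)
  zstate <- z[cbind(it, seas)]
  y <- integer(nrow(design))
  for (t in unique(seas)) {
    alpha_t <- matrix(params$alpha[t, , ], 6, 3)
    for (m in unique(zstate[seas == t])) {
      sel <- which(seas == t & zstate == m)
      y[sel] <- sim_obs_season(alpha_t, design$jd_std[sel], m)
    }
  }
  design$observed_state <- y
  design
}

# discrepancy statistics over a survey tibble; each returns a named
# numeric vector of scalar statistics
ppc_statistics <- function(data) {
  per_state <- vapply(1:4, function(n) sum(data$observed_state == n),
                      numeric(1))
  naive <- data |>
    dplyr::group_by(.data$territory, .data$year) |>
    dplyr::summarise(best = max(.data$observed_state), .groups = "drop")
  naive_repro_by_year <- naive |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n4 = sum(.data$best == 4), .groups = "drop")
  c(setNames(per_state, sprintf("visits_state_%d", 1:4)),
    naive_best_repro = sum(naive$best == 4),
    naive_best_pair = sum(naive$best >= 3),
    year_sd_naive_repro = if (nrow(naive_repro_by_year) > 1) {
      sd(naive_repro_by_year$n4)
    } else 0)
}

# rebuild an msocc_params from one retained draw of a fit
params_from_draw <- function(fit, chain, s) {
  ch <- fit$chains[[chain]]
  T_ <- length(fit$years)
  beta <- aperm(array(ch$beta[s, ], dim = c(3, 4, T_ - 1)), c(3, 2, 1))
  alpha <- aperm(array(ch$alpha[s, ], dim = c(3, 6, T_)), c(3, 2, 1))
  msocc_params(ch$phi0[s, ], beta, alpha, fit$years)
}

#' Posterior predictive check of detected-state patterns
#'
#' For each retained posterior draw, simulates a replicated dataset at the
#' observed survey design (conditional on that draw's imputed latent
#' states and detection parameters), computes scalar discrepancy
#' statistics of the detected states on both the replicate and the
#' observed data, and reports posterior predictive p-values
#' `ppp = Pr(T(replicate) >= T(observed))`. Extreme values (outside
#' [0.05, 0.95]) flag disagreement between model and data.
#'
#' The statistic set covers visit-level state frequencies (total visits
#' with each observed state), territory-level aggregation (number of
#' territory-years whose naive best state is a reproducing pair, or any
#' pair), and between-year variability (SD across years of the naive
#' reproducing count).
#'
#' @param fit An `msocc_fit` fitted with `keep_z = TRUE`.
#' @param n_draws Number of posterior draws to use (default: all retained,
#'   pooled over chains; subsampled evenly if fewer are requested).
#' @return Tibble of class `msocc_ppc`: one row per statistic with
#'   `observed`, `rep_mean`, `rep_lower`, `rep_upper`, `ppp`, `flagged`;
#'   the full replicate matrix is in attribute `replicated`.
#' @export
ppc_check <- function(fit, n_draws = NULL) {
  S <- nrow(fit$chains[[1]]$phi0)
  n_chains <- length(fit$chains)
  total <- S * n_chains
  pick <- if (is.null(n_draws) || n_draws >= total) {
    seq_len(total)
  } else {
    round(seq(1, total, length.out = n_draws))
  }
  design <- fit$data[, c("territory", "year", "jd_std")]
  obs <- ppc_statistics(fit$data)
  zd <- latent_draws(fit)
  reps <- matrix(NA_real_, length(pick), length(obs),
                 dimnames = list(NULL, names(obs)))
  for (j in seq_along(pick)) {
    k <- pick[j]
    chain <- (k - 1L) %/% S + 1L
    s <- (k - 1L) %% S + 1L
    params <- params_from_draw(fit, chain, s)
    z <- matrix(zd[k, , ], length(fit$territories), length(fit$years),
                dimnames = list(fit$territories, fit$years))
    rep_data <- simulate_replicate(params, z, design)
    reps[j, ] <- ppc_statistics(rep_data)
  }
  ppp <- vapply(seq_along(obs),
                function(i) mean(reps[, i] >= obs[i]), numeric(1))
  out <- tibble::tibble(
    statistic = names(obs),
    observed = unname(obs),
    rep_mean = colMeans(reps),
    rep_lower = apply(reps, 2, quantile, 0.05),
    rep_upper = apply(reps, 2, quantile, 0.95),
    ppp = ppp,
    flagged = ppp < 0.05 | ppp > 0.95
  )
  attr(out, "replicated") <- reps
  class(out) <- c("msocc_ppc", class(out))
  out
}
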