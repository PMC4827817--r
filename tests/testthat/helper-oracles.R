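# Independent oracles, written from the model definition with plain
# arithmetic (no package internals beyond the parameter container), used
# to check the likelihood and matrix code.

# plain softmax with baseline category first
oracle_softmax <- function(beta) {
  w <- exp(c(0, beta))
  w / sum(w)
}

oracle_tpm <- function(beta_t) {
  t(apply(beta_t, 1, oracle_softmax))
}

# detection row probabilities by direct evaluation of the multi-logit
oracle_dpm <- function(alpha_t, jd) {
  pair_m <- c(2, 3, 3, 4, 4, 4)
  pair_n <- c(2, 2, 3, 2, 3, 4)
  dpm <- matrix(0, 4, 4)
  dpm[1, 1] <- 1
  for (m in 2:4) {
    idx <- which(pair_m == m)
    eta <- alpha_t[idx, 1] + alpha_t[idx, 2] * jd + alpha_t[idx, 3] * jd^2
    p <- oracle_softmax(eta)
    dpm[m, 1] <- p[1]
    dpm[m, pair_n[idx]] <- p[-1]
  }
  dpm
}

# joint probability of one latent path and one territory's visits,
# multiplied out term by term
oracle_path_prob <- function(z_path, visits, params) {
  T_ <- length(params$years)
  p <- params$phi0[z_path[1]]
  if (T_ > 1) {
    for (t in 1:(T_ - 1)) {
      Phi <- oracle_tpm(matrix(params$beta[t, , ], 4, 3))
      p <- p * Phi[z_path[t], z_path[t + 1]]
    }
  }
  if (nrow(visits)) {
    for (r in seq_len(nrow(visits))) {
      dpm <- oracle_dpm(matrix(params$alpha[visits$season[r], , ], 6, 3),
                        visits$jd_std[r])
      p <- p * dpm[z_path[visits$season[r]], visits$y[r]]
    }
  }
  p
}

# marginal likelihood by exhaustive enumeration over all 4^T state paths
oracle_marginal_loglik <- function(visits, params) {
  T_ <- length(params$years)
  paths <- as.matrix(expand.grid(rep(list(1:4), T_)))
  log(sum(apply(paths, 1, oracle_path_prob, visits = visits,
                params = params)))
}

# exact path posterior given the data, for FFBS checks
oracle_path_posterior <- function(visits, params) {
  T_ <- length(params$years)
  paths <- as.matrix(expand.grid(rep(list(1:4), T_)))
  w <- apply(paths, 1, oracle_path_prob, visits = visits, params = params)
  list(paths = paths, prob = w / sum(w))
}

# small random parameter set for property tests
random_params <- function(T_, sd_beta = 1, sd_alpha = 1,
                          first_year = 2001L) {
  phi0 <- as.vector(rgamma(4, 1))
  phi0 <- phi0 / sum(phi0)
  msocc_params(
    phi0 = phi0,
    beta = array(rnorm((T_ - 1) * 12, 0, sd_beta), c(T_ - 1, 4, 3)),
    alpha = array(rnorm(T_ * 18, 0, sd_alpha), c(T_, 6, 3)),
    years = first_year + seq_len(T_) - 1L
  )
}

# random per-territory visit table: up to max_visits in each season
random_visits <- function(T_, max_visits = 3) {
  rows <- list()
  for (t in seq_len(T_)) {
    nv <- sample(0:max_visits, 1)
    if (nv > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        season = t, jd_std = round(rnorm(nv), 3),
        y = sample(1:4, nv, replace = TRUE))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(season = integer(), jd_std = numeric(),
                          y = integer()))
  }
  dplyr::bind_rows(rows)
}

# tiny shared fit used by several test files (cached per test run)
tiny_fit_cache <- new.env()
get_tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    cfg <- sim_config(
      blocks = tibble::tibble(block = "A", n_territories = 12L,
                              first_year = 2001L, last_year = 2006L),
      seed = 99L)
    sim <- simulate_surveys(cfg)
    tiny_fit_cache$sim <- sim
    tiny_fit_cache$fit <- fit_multistate(
      sim$data,
      mcmc = mcmc_config(n_chains = 2, n_iter = 1200, n_burnin = 400,
                         thin = 4, seed = 5),
      rhat_warn = Inf)
  }
  tiny_fit_cache$fit
}
get_tiny_sim <- function() {
  invisible(get_tiny_fit())
  tiny_fit_cache$sim
}
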