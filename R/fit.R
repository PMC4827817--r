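#' Prior specification
#'
#' Priors follow the standard weakly-informative choices for hierarchical
#' multi-logit occupancy models: a flat Dirichlet(1,1,1,1) on the initial
#' state probabilities, normal priors centred at zero on the random-effect
#' hyper-means, and Gamma(2, 0.5) priors on the random-effect spreads.
#'
#' Two conventions in the literature are ambiguous and therefore
#' switchable: `mu_prior` `"variance"` reads "N(0, 2)" as variance 2
#' (SD = sqrt(2), the default) while `"sd"` reads it as SD 2; and
#' `sd_prior_on` places the Gamma(2, 0.5) (shape, rate) prior on the
#' random-effect SD (default) or on its variance.
#'
#' @param phi0_conc Dirichlet concentration for the initial state
#'   probabilities (length 4).
#' @param mu_prior_spread The "2" in N(0, 2).
#' @param mu_prior Whether `mu_prior_spread` is a variance or an SD.
#' @param sd_shape,sd_rate Gamma shape and rate for the spread prior.
#' @param sd_prior_on Whether the Gamma prior sits on the SD or variance.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(phi0_conc = c(1, 1, 1, 1),
                       mu_prior_spread = 2,
                       mu_prior = c("variance", "sd"),
                       sd_shape = 2, sd_rate = 0.5,
                       sd_prior_on = c("sd", "variance")) {
  mu_prior <- match.arg(mu_prior)
  sd_prior_on <- match.arg(sd_prior_on)
  stopifnot(length(phi0_conc) == 4, all(phi0_conc > 0),
            mu_prior_spread > 0, sd_shape > 0, sd_rate > 0)
  structure(list(
    phi0_conc = phi0_conc,
    mu_prior_sd = if (mu_prior == "variance") sqrt(mu_prior_spread) else mu_prior_spread,
    sd_shape = sd_shape, sd_rate = sd_rate,
    sd_on_variance = sd_prior_on == "variance"
  ), class = "prior_spec")
}

#' MCMC configuration
#'
#' The default mirrors the published analysis settings for this model
#' class: three chains of 55,000 iterations with 5,000 burn-in and 1/100
#' thinning, retaining 1,500 draws per chain. Reduced settings are
#' appropriate for simulation studies and tests.
#'
#' @param n_chains Number of chains (run sequentially).
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param thin Thinning interval for retained draws.
#' @param seed Integer base seed; chain c uses `seed + c - 1`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 55000L, n_burnin = 5000L,
                        thin = 100L, seed = 1L) {
  stopifnot(n_chains >= 1, n_burnin < n_iter, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_config")
}

# deterministic latent-state initialization respecting y <= z: the maximum
# state observed in a territory-season, carried forward (then backward)
# through unvisited seasons, defaulting to state 1
init_z <- function(data, territories, years) {
  I_ <- length(territories)
  T_ <- length(years)
  z <- matrix(NA_integer_, I_, T_)
  if (nrow(data)) {
    idx_i <- match(data$territory, territories)
    idx_t <- match(data$year, years)
    for (r in seq_len(nrow(data))) {
      z[idx_i[r], idx_t[r]] <- max(z[idx_i[r], idx_t[r]],
                                   data$observed_state[r], na.rm = TRUE)
    }
  }
  for (i in seq_len(I_)) {
    for (t in seq_len(T_)[-1]) if (is.na(z[i, t])) z[i, t] <- z[i, t - 1]
    for (t in rev(seq_len(T_ - 1))) if (is.na(z[i, t])) z[i, t] <- z[i, t + 1]
    z[i, is.na(z[i, ])] <- 1L
  }
  z
}

#' Fit the dynamic multistate occupancy model to one block
#'
#' Runs the package's Gibbs sampler: forward-filtering backward-sampling
#' for the latent territory states, a conjugate Dirichlet update for the
#' initial state probabilities, adaptive random-walk Metropolis for the
#' season-specific transition and detection effects, conjugate normal
#' updates for the hyper-means, and log-scale random-walk updates for the
#' hyper-SDs. All parameters are block-specific, so one block is fitted
#' per call.
#'
#' @param data Survey tibble (canonical columns). If a `jd_std` column is
#'   absent, dates are standardized here ([standardize_dates()]).
#' @param block Block label to fit; required when `data` spans several
#'   blocks.
#' @param years Seasons to model (default: the block's observed year
#'   range, inclusive). Territories first surveyed after the first season
#'   get latent trajectories from the first season, with earlier seasons
#'   treated as unvisited.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param keep_z Retain posterior draws of the latent states (needed for
#'   state counts, trends and posterior predictive checks).
#' @param rhat_warn Warn if any hyper-parameter R-hat exceeds this value
#'   (set `Inf` to disable).
#' @return An object of class `msocc_fit`.
#' @export
fit_multistate <- function(data, block = NULL, years = NULL,
                           priors = prior_spec(), mcmc = mcmc_config(),
                           keep_z = TRUE, rhat_warn = 1.1) {
  stopifnot(inherits(priors, "prior_spec"), inherits(mcmc, "mcmc_config"))
  blocks_present <- unique(data$block)
  if (is.null(block)) {
    if (length(blocks_present) > 1) {
      stop("data spans blocks ", paste(blocks_present, collapse = ", "),
           "; fit one block per call", call. = FALSE)
    }
    block <- blocks_present
  }
  d <- dplyr::filter(data, .data$block == !!block)
  if (!nrow(d)) stop("no records for block ", block, call. = FALSE)
  if (!"jd_std" %in% names(d)) {
    d <- standardize_dates(d)
  }
  jd_center <- attr(d, "jd_center") %||% attr(data, "jd_center")
  jd_scale <- attr(d, "jd_scale") %||% attr(data, "jd_scale")

  years <- if (is.null(years)) min(d$year):max(d$year) else as.integer(years)
  territories <- sort(unique(d$territory))
  I_ <- length(territories)
  T_ <- length(years)
  if (T_ < 2) stop("need at least two seasons to model dynamics", call. = FALSE)

  z0 <- init_z(d, territories, years)
  terr_idx <- match(d$territory, territories) - 1L
  seas_idx <- season_index(d$year, years) - 1L

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    chains[[ch]] <- run_sampler_cpp(
      terr = terr_idx, seas = seas_idx, y = as.integer(d$observed_state),
      jd = d$jd_std, I = I_, T = T_, z_init = z0,
      n_iter = mcmc$n_iter, n_burn = mcmc$n_burnin, thin = mcmc$thin,
      mu_prior_sd = priors$mu_prior_sd, sd_shape = priors$sd_shape,
      sd_rate = priors$sd_rate, sd_on_variance = priors$sd_on_variance,
      dir_conc = priors$phi0_conc, keep_z = keep_z
    )
  }

  fit <- structure(list(
    chains = chains, block = block, years = years,
    territories = territories, data = d,
    jd_center = jd_center, jd_scale = jd_scale,
    priors = priors, mcmc = mcmc, keep_z = keep_z
  ), class = "msocc_fit")

  if (is.finite(rhat_warn) && mcmc$n_chains >= 2) {
    rt <- rhat_table(fit)
    worst <- rt[which.max(rt$rhat), ]
    if (worst$rhat > rhat_warn) {
      warning(sprintf(
        "possible non-convergence: max R-hat %.3f (%s) exceeds %.2f",
        worst$rhat, worst$parameter, rhat_warn), call. = FALSE)
    }
  }
  fit
}

#' @export
print.msocc_fit <- function(x, ...) {
  S <- nrow(x$chains[[1]]$phi0)
  cat("Dynamic multistate occupancy fit: block", x$block, "\n")
  cat(" ", length(x$territories), "territories,", length(x$years),
      "seasons (", min(x$years), "-", max(x$years), ")\n")
  cat(" ", length(x$chains), "chain(s) x", S, "retained draws",
      sprintf("(thin %d, burn-in %d of %d)\n",
              x$mcmc$thin, x$mcmc$n_burnin, x$mcmc$n_iter))
  invisible(x)
}

# ---- draw extraction ------------------------------------------------------

# map a name like "beta_mu[2,4]" to (matrix-name, column) in the chain output
parse_param <- function(name, T_) {
  m <- regmatches(name, regexec("^([a-z_0]+)\\[([0-9, ]+)\\]$", name))[[1]]
  if (!length(m)) stop("unrecognized parameter name: ", name, call. = FALSE)
  what <- m[2]
  idx <- as.integer(strsplit(gsub(" ", "", m[3]), ",")[[1]])
  pair_of <- function(mm, nn) {
    p <- dpm_pairs()
    hit <- which(p$m == mm & p$n == nn)
    if (!length(hit)) stop("no detection entry for (m=", mm, ", n=", nn, ")",
                           call. = FALSE)
    hit
  }
  col <- switch(what,
    phi0 = {
      stopifnot(length(idx) == 1, idx >= 1, idx <= 4); idx
    },
    beta_mu = ,
    beta_sigma = {
      stopifnot(length(idx) == 2, idx[1] %in% 1:4, idx[2] %in% 2:4)
      (idx[1] - 1L) * 3L + (idx[2] - 1L)
    },
    beta = {
      stopifnot(length(idx) == 3, idx[1] %in% seq_len(T_ - 1),
                idx[2] %in% 1:4, idx[3] %in% 2:4)
      ((idx[1] - 1L) * 4L + (idx[2] - 1L)) * 3L + (idx[3] - 2L) + 1L
    },
    alpha_mu = ,
    alpha_sigma = {
      stopifnot(length(idx) == 3, idx[3] %in% 0:2)
      (pair_of(idx[1], idx[2]) - 1L) * 3L + idx[3] + 1L
    },
    alpha = {
      stopifnot(length(idx) == 4, idx[1] %in% seq_len(T_), idx[4] %in% 0:2)
      ((idx[1] - 1L) * 6L + (pair_of(idx[2], idx[3]) - 1L)) * 3L + idx[4] + 1L
    },
    stop("unrecognized parameter family: ", what, call. = FALSE)
  )
  list(what = what, col = col)
}

#' Extract posterior draws of one scalar parameter
#'
#' Parameter names follow the model's indexing: `"phi0[k]"`;
#' `"beta_mu[m,n]"` and `"beta_sigma[m,n]"` for the transition hyper-mean
#' and hyper-SD from state m to state n (n in 2..4); `"beta[t,m,n]"` for a
#' season-t effect; `"alpha_mu[m,n,k]"`, `"alpha_sigma[m,n,k]"` and
#' `"alpha[t,m,n,k]"` for the detection coefficients (k = 0 intercept,
#' 1 linear date, 2 quadratic date).
#'
#' @param fit An `msocc_fit`.
#' @param parameter Parameter name (see Details).
#' @return Numeric matrix, retained draws x chains.
#' @export
extract_draws <- function(fit, parameter) {
  p <- parse_param(parameter, length(fit$years))
  sapply(fit$chains, function(ch) ch[[p$what]][, p$col])
}

# names of the hyper-level parameters monitored by default
hyper_param_names <- function() {
  pairs <- dpm_pairs()
  c(sprintf("phi0[%d]", 1:4),
    sprintf("beta_mu[%d,%d]", rep(1:4, each = 3), rep(2:4, 4)),
    sprintf("beta_sigma[%d,%d]", rep(1:4, each = 3), rep(2:4, 4)),
    sprintf("alpha_mu[%d,%d,%d]", rep(pairs$m, each = 3),
            rep(pairs$n, each = 3), rep(0:2, 6)),
    sprintf("alpha_sigma[%d,%d,%d]", rep(pairs$m, each = 3),
            rep(pairs$n, each = 3), rep(0:2, 6)))
}

#' Draws of the latent state of every territory-season
#'
#' @param fit An `msocc_fit` fitted with `keep_z = TRUE`.
#' @return Integer array `draws x territories x seasons` pooling chains,
#'   with territory and year dimnames.
#' @export
latent_draws <- function(fit) {
  if (!fit$keep_z) stop("fit was run with keep_z = FALSE", call. = FALSE)
  I_ <- length(fit$territories)
  T_ <- length(fit$years)
  z <- do.call(rbind, lapply(fit$chains, `[[`, "z"))
  # sampler stores season fastest within territory: column (i-1)*T + t
  out <- aperm(array(z, dim = c(nrow(z), T_, I_)), c(1, 3, 2))
  dimnames(out) <- list(NULL, fit$territories, fit$years)
  out
}
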