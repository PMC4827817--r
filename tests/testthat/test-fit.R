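test_that("fits are reproducible given the seed", {
  sim <- get_tiny_sim()
  cfg <- mcmc_config(n_chains = 1, n_iter = 300, n_burnin = 100, thin = 2,
                     seed = 77)
  f1 <- fit_multistate(sim$data, mcmc = cfg, rhat_warn = Inf)
  f2 <- fit_multistate(sim$data, mcmc = cfg, rhat_warn = Inf)
  expect_identical(f1$chains[[1]]$beta_mu, f2$chains[[1]]$beta_mu)
  expect_identical(f1$chains[[1]]$z, f2$chains[[1]]$z)
  f3 <- fit_multistate(sim$data,
                       mcmc = mcmc_config(n_chains = 1, n_iter = 300,
                                          n_burnin = 100, thin = 2, seed = 78),
                       rhat_warn = Inf)
  expect_false(identical(f1$chains[[1]]$beta_mu, f3$chains[[1]]$beta_mu))
})

test_that("unanimous state-4 data dominate the latent states", {
  set.seed(1)
  d <- tidyr::expand_grid(
    territory = sprintf("t%02d", 1:6), year = 2000:2004,
    visit = 1:3) |>
    dplyr::mutate(block = "A", julian_date = 100L + 20L * visit,
                  observed_state = 4L) |>
    dplyr::select(block, territory, year, julian_date, observed_state)
  fit <- fit_multistate(d, mcmc = mcmc_config(n_chains = 1, n_iter = 600,
                                              n_burnin = 200, thin = 2,
                                              seed = 3),
                        rhat_warn = Inf)
  z <- latent_draws(fit)
  expect_gt(mean(z == 4L), 0.999)
})

test_that("posterior-imputed states never fall below an observed state", {
  fit <- get_tiny_fit()
  z <- latent_draws(fit)
  d <- fit$data
  ii <- match(d$territory, fit$territories)
  tt <- match(d$year, fit$years)
  for (r in seq_len(nrow(d))) {
    expect_true(all(z[, ii[r], tt[r]] >= d$observed_state[r]))
  }
})

test_that("fitting refuses multi-block data without a block argument", {
  sim <- simulate_surveys(sim_config(blocks = tibble::tibble(
    block = c("A", "B"), n_territories = c(3L, 3L),
    first_year = 2000L, last_year = 2003L), seed = 8))
  expect_error(fit_multistate(sim$data), "one block per call")
  fit <- fit_multistate(sim$data, block = "B",
                        mcmc = mcmc_config(n_chains = 1, n_iter = 200,
                                           n_burnin = 100, thin = 1, seed = 1),
                        rhat_warn = Inf)
  expect_equal(fit$block, "B")
  expect_equal(length(fit$territories), 3L)
})

test_that("Gelman-Rubin statistic matches the standard formula", {
  # small worked example, hand computation
  draws <- cbind(c(1.1, 0.9, 1.3, 0.7, 1.0), c(1.6, 1.4, 1.8, 1.2, 1.5))
  n <- 5
  W <- mean(apply(draws, 2, var))
  B_over_n <- var(colMeans(draws))
  by_hand <- sqrt(((n - 1) / n * W + B_over_n) / W)
  expect_equal(gelman_rubin(draws), by_hand)

  # coda agrees up to its sampling-variability and d.f. corrections,
  # which vanish for long well-mixed chains
  skip_if_not_installed("coda")
  set.seed(99)
  big <- cbind(rnorm(3000), rnorm(3000))
  ml <- coda::mcmc.list(coda::mcmc(big[, 1, drop = FALSE]),
                        coda::mcmc(big[, 2, drop = FALSE]))
  gd <- coda::gelman.diag(ml, autoburnin = FALSE, transform = FALSE)
  expect_equal(gelman_rubin(big), unname(gd$psrf[1, 1]), tolerance = 0.01)
})

test_that("Gelman-Rubin limits: mixed chains near 1, separated chains large", {
  set.seed(2)
  same <- cbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(gelman_rubin(same) - 1), 0.02)
  apart <- cbind(rnorm(50, 0, 1), rnorm(50, 100, 1))
  expect_gt(gelman_rubin(apart), 10)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "two chains")
  expect_lt(abs(gelman_rubin(same, split = TRUE) - 1), 0.05)
})

test_that("without data the hyper-mean posterior returns the prior", {
  # zero visits anywhere: the sampler should leave mu at its N(0, 2) prior
  set.seed(42)
  out <- territrend:::run_sampler_cpp(
    terr = integer(0), seas = integer(0), y = integer(0), jd = numeric(0),
    I = 5L, T = 3L, z_init = matrix(1L, 5, 3),
    n_iter = 24000L, n_burn = 2000L, thin = 10L,
    mu_prior_sd = sqrt(2), sd_shape = 2, sd_rate = 0.5,
    sd_on_variance = FALSE, dir_conc = rep(1, 4), keep_z = FALSE)
  mu <- as.vector(out$beta_mu)
  expect_lt(abs(mean(mu)), 0.15)
  expect_equal(sd(mu), sqrt(2), tolerance = 0.12)
  amu <- as.vector(out$alpha_mu)
  expect_lt(abs(mean(amu)), 0.15)
  expect_equal(sd(amu), sqrt(2), tolerance = 0.12)
  # hyper-SD marginal should match its Gamma(2, 0.5) prior mean of 4
  expect_equal(mean(out$beta_sigma), 4, tolerance = 0.6)
})

test_that("FFBS draws follow the exact conditional path distribution", {
  set.seed(13)
  p <- random_params(3)
  vis <- tibble::tibble(season = c(1L, 2L, 2L), jd_std = c(0.2, -0.4, 0.9),
                        y = c(2L, 3L, 1L))
  d <- tibble::tibble(block = "A", territory = "t1",
                      year = p$years[vis$season], julian_date = 100L,
                      observed_state = vis$y, jd_std = vis$jd_std)
  exact <- oracle_path_posterior(vis, p)
  n <- 20000
  imp <- impute_states(p, d, territories = "t1", n = n)
  key <- vapply(imp$z, function(zz) paste(zz[1, ], collapse = ""),
                character(1))
  exact_key <- apply(exact$paths, 1, paste, collapse = "")
  obs_counts <- table(factor(key, levels = exact_key))
  keep <- exact$prob * n >= 10
  o <- as.vector(obs_counts[keep])
  e <- exact$prob[keep] * n
  if (any(!keep) && sum(exact$prob[!keep]) * n >= 1) {
    o <- c(o, sum(obs_counts[!keep]))
    e <- c(e, sum(exact$prob[!keep]) * n)
  }
  chi2 <- sum((o - e)^2 / e)
  pval <- stats::pchisq(chi2, df = length(o) - 1, lower.tail = FALSE)
  expect_gt(pval, 1e-3)
})

test_that("non-convergence triggers a warning, not a failure", {
  sim <- get_tiny_sim()
  expect_warning(
    fit_multistate(sim$data, mcmc = mcmc_config(n_chains = 2, n_iter = 60,
                                                n_burnin = 20, thin = 1,
                                                seed = 1),
                   rhat_warn = 1.001),
    "non-convergence")
})

test_that("tidy and glance report the fit at the hyper level", {
  fit <- get_tiny_fit()
  td <- tidy(fit)
  expect_equal(nrow(td), 4 + 12 + 12 + 18 + 18)
  expect_true(all(td$lower <= td$mean & td$mean <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$n_territories, 12L)
  expect_equal(gl$n_chains, 2L)
  expect_true(gl$accept_beta > 0.05 && gl$accept_beta < 0.8)
})
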