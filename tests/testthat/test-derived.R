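# build an msocc_counts tibble by hand for closed-form trend checks
manual_counts <- function(counts_by_draw, years, states = 4L, n_terr = 10L) {
  out <- tibble::tibble(
    draw = rep(seq_len(nrow(counts_by_draw)), times = length(years)),
    year = rep(years, each = nrow(counts_by_draw)),
    count = as.vector(counts_by_draw)
  )
  attr(out, "states") <- states
  attr(out, "block") <- "X"
  attr(out, "n_territories") <- n_terr
  class(out) <- c("msocc_counts", class(out))
  out
}

test_that("state counts partition the territory total", {
  fit <- get_tiny_fit()
  all4 <- count_states(fit, states = 1:4)
  expect_true(all(all4$count == length(fit$territories)))
  parts <- lapply(1:4, function(s) count_states(fit, states = s)$count)
  expect_true(all(Reduce(`+`, parts) == length(fit$territories)))
  expect_error(count_states(fit, states = integer()), "non-empty")
  expect_error(count_states(fit, years = 1800), "outside the fitted")
})

test_that("counts equal a direct count of the latent draws", {
  fit <- get_tiny_fit()
  z <- latent_draws(fit)
  got <- count_states(fit, states = c(3, 4))
  for (yr in sample(fit$years, 2)) {
    direct <- rowSums(matrix(z[, , as.character(yr)] %in% c(3, 4),
                             nrow = dim(z)[1]))
    expect_equal(got$count[got$year == yr], direct)
  }
})

test_that("counts match the generator truth under perfect detection", {
  cfg <- sim_config(blocks = tibble::tibble(
    block = "A", n_territories = 15L, first_year = 2000L, last_year = 2007L),
    alpha_mu = matrix(c(50, 0, 0, -50, 0, 0, 50, 0, 0,
                        -50, 0, 0, -50, 0, 0, 50, 0, 0), 6, 3, byrow = TRUE),
    alpha_sigma = matrix(0, 6, 3), p_surveyed = 1, seed = 17L)
  sim <- simulate_surveys(cfg)
  fit <- fit_multistate(sim$data,
                        mcmc = mcmc_config(n_chains = 1, n_iter = 400,
                                           n_burnin = 200, thin = 2, seed = 2),
                        rhat_warn = Inf)
  truth4 <- colSums(sim$truth$A$z == 4)
  got <- summarize_counts(count_states(fit, 4))
  # with every visit revealing the true state, imputation is pinned in
  # visited territory-years; allow slack only for the unvisited ones
  expect_true(all(abs(got$mean - truth4) <= 2))
})

test_that("linear trend reproduces its closed form", {
  # one draw, counts (5, 4, 3) over three years: slope (-5 + 0 + 3)/2 = -1
  ct <- manual_counts(matrix(c(5, 4, 3), 1), years = 1990:1992)
  tr <- linear_trend(ct)
  expect_identical(tr$mean, -1)
  expect_identical(tr$lower, -1)

  # flat series: exactly zero for every draw
  flat <- manual_counts(matrix(7, 20, 6), years = 2000:2005)
  trf <- linear_trend(flat)
  expect_true(all(attr(trf, "draws") == 0))

  # deterministic arithmetic series with slope k returns exactly k
  for (k in c(-2.5, 0.5, 3)) {
    yrs <- 1995:2004
    ct <- manual_counts(matrix(100 + k * (yrs - 1995), 1), years = yrs)
    expect_equal(linear_trend(ct)$mean, k, tolerance = 1e-12)
  }
  expect_error(linear_trend(manual_counts(matrix(1, 1, 1), 2000)),
               "two seasons")
})

test_that("credible intervals are monotone in the level", {
  set.seed(20)
  ct <- manual_counts(matrix(rpois(50 * 5, 10), 50), years = 2000:2004)
  t80 <- linear_trend(ct, level = 0.8)
  t90 <- linear_trend(ct, level = 0.9)
  t99 <- linear_trend(ct, level = 0.99)
  expect_true(t99$lower <= t90$lower && t90$lower <= t80$lower)
  expect_true(t80$upper <= t90$upper && t90$upper <= t99$upper)
})

test_that("orthogonal-polynomial contrasts nest the linear trend", {
  set.seed(21)
  yrs <- 2000:2008
  ct <- manual_counts(matrix(rpois(30 * length(yrs), 8), 30), years = yrs)
  lin <- linear_trend(ct)
  p1 <- polynomial_trend(ct, degree = 1)
  # degree-1 contrast = slope * sqrt(sum((yr - mean)^2))
  expect_equal(p1$mean, lin$mean * attr(p1, "year_scale"), tolerance = 1e-10)

  # pure quadratic on a symmetric grid: linear contrast zero
  quad <- manual_counts(matrix((yrs - 2004)^2, 1), years = yrs)
  p2 <- polynomial_trend(quad, degree = 2)
  expect_equal(p2$mean[p2$term == "linear"], 0, tolerance = 1e-10)
  expect_gt(abs(p2$mean[p2$term == "quadratic"]), 1)

  # contrasts match brute-force orthogonal polynomial regression
  one <- manual_counts(matrix(rpois(length(yrs), 20), 1), years = yrs)
  p <- polynomial_trend(one, degree = 2)
  fitlm <- lm(count ~ poly(year, 2), data = one)
  # lm coefficients on poly() columns are exactly the projections
  expect_equal(unname(p$mean), unname(coef(fitlm)[2:3]), tolerance = 1e-8)
  expect_error(polynomial_trend(manual_counts(matrix(1:2, 1), 2000:2001),
                                degree = 2), "at least 3 seasons")
})

test_that("hyper-mean transition probabilities transform draw by draw", {
  # fabricate a fit whose beta_mu draws are all zero: probability 1/4 with
  # zero spread
  fake <- structure(list(
    chains = list(list(beta_mu = matrix(0, 50, 12))),
    years = 2000:2004), class = "msocc_fit")
  out <- mean_transition_probs(fake, from = 4)
  expect_equal(out$mean, rep(0.25, 4))
  expect_equal(out$lower, rep(0.25, 4))

  # known non-zero hyper-means: matches direct softmax
  mu <- c(log(2), log(3), log(4))
  bm <- matrix(0, 50, 12)
  bm[, (4 - 1) * 3 + 1:3] <- rep(mu, each = 50)
  fake2 <- structure(list(chains = list(list(beta_mu = bm)),
                          years = 2000:2004), class = "msocc_fit")
  out2 <- mean_transition_probs(fake2, from = 4, to = 4)
  expect_equal(out2$mean, 0.4)
})

test_that("trend tables cover windows, state sets, and refusals", {
  fit <- get_tiny_fit()
  expect_message(
    tb <- trend_table(fit, windows = list(c(2001, 2004), c(2001, 2010))),
    "extends beyond")
  expect_equal(nrow(tb), 4L)  # 2 windows x 2 default state sets
  ok <- tb[tb$last_year == 2004, ]
  expect_true(all(is.finite(ok$mean)))
  na <- tb[tb$last_year == 2010, ]
  expect_true(all(is.na(na$mean)))
  expect_true(all(tb$lower <= tb$mean | is.na(tb$mean)))
})

test_that("count and trend plots build without error", {
  fit <- get_tiny_fit()
  ct <- count_states(fit, 4)
  p <- autoplot(ct, data = fit$data)
  expect_s3_class(p, "ggplot")
  p2 <- plot_detection(fit)
  expect_s3_class(p2, "ggplot")
})
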