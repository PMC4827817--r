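test_that("complete-data likelihood reduces to its single terms", {
  set.seed(3)
  p <- random_params(1)
  d <- tibble::tibble(block = "A", territory = character(), year = integer(),
                      julian_date = integer(), observed_state = integer(),
                      jd_std = numeric())
  z <- matrix(3L, 1, 1)
  expect_equal(loglik_complete(z, d, p, territories = "A001"),
               log(p$phi0[3]))
})

test_that("observations above the latent state are impossible", {
  set.seed(4)
  p <- random_params(1)
  d <- tibble::tibble(block = "A", territory = "A001", year = p$years[1],
                      julian_date = 100L, observed_state = 4L, jd_std = 0.2)
  expect_equal(loglik_complete(matrix(2L, 1, 1), d, p), -Inf)
  # the same observation is fine when the state allows it
  expect_gt(loglik_complete(matrix(4L, 1, 1), d, p), -Inf)
})

test_that("complete-data likelihood equals the hand-summed product of factors", {
  set.seed(5)
  p <- random_params(3)
  d <- tibble::tibble(
    block = "A",
    territory = c("t1", "t1", "t1", "t2", "t2"),
    year = p$years[c(1, 2, 3, 1, 3)],
    julian_date = 100L,
    observed_state = c(1L, 2L, 3L, 2L, 1L),
    jd_std = c(-0.5, 0.1, 0.9, 0.0, 1.2)
  )
  z <- rbind(c(2L, 3L, 3L), c(4L, 4L, 2L))
  got <- loglik_complete(z, d, p, territories = c("t1", "t2"))
  manual <- 0
  for (i in 1:2) {
    terr <- c("t1", "t2")[i]
    vis <- tibble::tibble(season = match(d$year[d$territory == terr], p$years),
                          jd_std = d$jd_std[d$territory == terr],
                          y = d$observed_state[d$territory == terr])
    manual <- manual + log(oracle_path_prob(z[i, ], vis, p))
  }
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("no-visit histories have likelihood one", {
  set.seed(6)
  p <- random_params(1)
  empty <- tibble::tibble(season = integer(), jd_std = numeric(),
                          y = integer())
  expect_equal(loglik_territory(empty, p), 0)
  p3 <- random_params(3)
  expect_equal(loglik_territory(empty, p3), 0, tolerance = 1e-12)
})

test_that("forward algorithm equals exhaustive path enumeration", {
  set.seed(7)
  for (r in 1:40) {
    T_ <- sample(2:4, 1)
    p <- random_params(T_, sd_beta = 2, sd_alpha = 2)
    vis <- random_visits(T_)
    expect_equal(loglik_territory(vis, p),
                 oracle_marginal_loglik(vis, p), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to visit order within a season", {
  set.seed(8)
  p <- random_params(3)
  vis <- tibble::tibble(season = c(1, 1, 1, 2, 2),
                        jd_std = c(0.3, -0.8, 1.1, 0.0, 0.5),
                        y = c(2L, 3L, 1L, 4L, 4L))
  shuffled <- vis[c(3, 1, 2, 5, 4), ]
  expect_equal(loglik_territory(vis, p), loglik_territory(shuffled, p))
})

test_that("with degenerate non-detection the likelihood ignores occupancy", {
  set.seed(9)
  # intercepts of -40 make every detection row (1, 0, 0, 0)
  p <- random_params(3)
  p$alpha[, , 1] <- -40
  p$alpha[, , 2:3] <- 0
  vis <- tibble::tibble(season = c(1, 2, 3), jd_std = c(0, 0.5, -0.5),
                        y = c(1L, 1L, 1L))
  # all-nondetection data carry no information: likelihood is one
  expect_equal(loglik_territory(vis, p), 0, tolerance = 1e-12)
  p2 <- p
  p2$beta[] <- rnorm(length(p2$beta))  # a different TPM changes nothing
  expect_equal(loglik_territory(vis, p2), 0, tolerance = 1e-12)
})

test_that("the sampler's forward filter agrees with the R forward algorithm", {
  set.seed(10)
  for (r in 1:20) {
    T_ <- sample(2:5, 1)
    p <- random_params(T_)
    vis <- random_visits(T_)
    d <- tibble::tibble(block = "A", territory = "t1",
                        year = p$years[vis$season],
                        julian_date = 100L, observed_state = vis$y,
                        jd_std = vis$jd_std)
    imp <- impute_states(p, d, territories = "t1")
    expect_equal(imp$loglik, loglik_territory(vis, p), tolerance = 1e-10)
  }
})

test_that("data-level likelihood sums independent territories", {
  set.seed(11)
  p <- random_params(3)
  d <- tibble::tibble(
    block = "A", territory = c("t1", "t2", "t2"),
    year = p$years[c(1, 2, 3)], julian_date = 100L,
    observed_state = c(2L, 1L, 3L), jd_std = c(0.1, -0.2, 0.4))
  by_hand <- sum(vapply(c("t1", "t2"), function(tt) {
    rows <- d$territory == tt
    loglik_territory(tibble::tibble(season = match(d$year[rows], p$years),
                                    jd_std = d$jd_std[rows],
                                    y = d$observed_state[rows]), p)
  }, numeric(1)))
  expect_equal(loglik_data(d, p), by_hand)
})
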