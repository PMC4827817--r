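#' Configure a synthetic territory-survey simulation
#'
#' Describes a multi-block monitoring design together with the true
#' data-generating parameters of the dynamic multistate model. Defaults
#' give a design in which all four territory states occur with
#' non-negligible frequency; they are synthetic values, not estimates.
#'
#' @param blocks Tibble with columns `block`, `n_territories`,
#'   `first_year`, `last_year`.
#' @param visit_probs Probability weights over 1..15 visits per surveyed
#'   territory-year. The default is an empirical-like distribution with
#'   median 3 and mean about 3.4.
#' @param date_window Integer length-2 Julian-date window for visits
#'   (default 1 March to 31 August).
#' @param phi0 True initial state probabilities (length 4).
#' @param beta_mu,beta_sigma 4x3 matrices of transition hyper-means and
#'   hyper-SDs (rows = current state, cols = destination 2..4).
#' @param alpha_mu,alpha_sigma 6x3 matrices of detection hyper-means and
#'   hyper-SDs (rows = [dpm_pairs()], cols = intercept/date/date^2).
#' @param p_surveyed Probability that a territory receives any daytime
#'   visits in a given year (emulates varying survey effort).
#' @param beta_mu_by_year Optional array `(T - 1) x 4 x 3` of
#'   year-specific transition effect means overriding `beta_mu` (used to
#'   build drifting scenarios); `T` must match the longest block.
#' @param seed Integer seed used by [simulate_surveys()].
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(blocks,
                       visit_probs = default_visit_probs(),
                       date_window = c(60L, 243L),
                       phi0 = c(0.15, 0.15, 0.30, 0.40),
                       beta_mu = default_beta_mu(),
                       beta_sigma = matrix(0.5, 4, 3),
                       alpha_mu = default_alpha_mu(),
                       alpha_sigma = matrix(0.3, 6, 3),
                       p_surveyed = 1,
                       beta_mu_by_year = NULL,
                       seed = 1L) {
  stopifnot(
    all(c("block", "n_territories", "first_year", "last_year") %in%
          names(blocks)),
    all(blocks$n_territories >= 1),
    length(visit_probs) == 15, all(visit_probs >= 0), sum(visit_probs) > 0,
    date_window[1] >= 1, date_window[2] <= 366, date_window[1] < date_window[2],
    length(phi0) == 4, abs(sum(phi0) - 1) < 1e-8,
    all(dim(beta_mu) == c(4, 3)), all(dim(beta_sigma) == c(4, 3)),
    all(beta_sigma >= 0),
    all(dim(alpha_mu) == c(6, 3)), all(dim(alpha_sigma) == c(6, 3)),
    all(alpha_sigma >= 0),
    p_surveyed > 0, p_surveyed <= 1
  )
  structure(
    list(blocks = tibble::as_tibble(blocks), visit_probs = visit_probs,
         date_window = as.integer(date_window), phi0 = phi0,
         beta_mu = beta_mu, beta_sigma = beta_sigma,
         alpha_mu = alpha_mu, alpha_sigma = alpha_sigma,
         p_surveyed = p_surveyed, beta_mu_by_year = beta_mu_by_year,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# visits-per-territory-year weights: support 1..15, median 3
default_visit_probs <- function() {
  p <- c(0.15, 0.20, 0.25, 0.15, 0.10, 0.06, 0.04, 0.02, 0.01,
         0.005, 0.005, 0.002, 0.001, 0.001, 0.001)
  p / sum(p)
}

# transition hyper-means giving persistent pair/reproducing dynamics with
# occasional abandonment; all states reachable
default_beta_mu <- function() {
  matrix(c(
    -1.0, -1.5, -2.5,   # from unoccupied
     0.3, -0.3, -1.0,   # from single
    -0.3,  0.8,  0.3,   # from pair
    -0.5,  0.6,  0.9),  # from reproducing pair
    nrow = 4, byrow = TRUE)
}

# detection hyper-means: reproducing pairs detected well, singles poorly,
# mild seasonal (date) structure
default_alpha_mu <- function() {
  matrix(c(
    -0.5,  0.3, -0.3,   # (2,2)
    -1.2,  0.0,  0.0,   # (3,2)
     0.8,  0.4, -0.3,   # (3,3)
    -1.5,  0.0,  0.0,   # (4,2)
    -0.8,  0.0,  0.0,   # (4,3)
     1.5,  0.5, -0.4),  # (4,4)
    nrow = 6, byrow = TRUE)
}

#' Three-block preset emulating the Mendocino County study design
#'
#' 104 territories split 18/62/24 across blocks A, B and C, seasons
#' 1990-2014 with block C discontinued after 2006, 1-15 daytime visits per
#' surveyed territory-year (median 3) between 1 March and 31 August, and
#' survey effort that skips a territory-year about 15% of the time.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
mendocino_preset <- function(seed = 1L) {
  sim_config(
    blocks = tibble::tibble(
      block = c("A", "B", "C"),
      n_territories = c(18L, 62L, 24L),
      first_year = 1990L,
      last_year = c(2014L, 2014L, 2006L)
    ),
    p_surveyed = 0.85,
    seed = seed
  )
}

#' Single-block scenario with a known linear decline in reproduction
#'
#' Builds a configuration whose expected number of reproducing (state-4)
#' territories declines by exactly `decline` per season: every transition
#' row equals a year-specific target state distribution whose state-4 mass
#' falls linearly (so the chain mixes in one step and the marginal equals
#' the target), transition hyper-SDs are zero (deterministic drift), and
#' detection is strong so imputed states track the truth. Used for trend
#' recovery studies where the estimand is known by construction.
#'
#' @param n_territories Number of territories.
#' @param n_seasons Number of seasons.
#' @param decline Expected loss in reproducing territories per season.
#' @param p4_start Initial probability a territory reproduces.
#' @param first_year First calendar year.
#' @param seed Integer seed.
#' @return A [sim_config()] whose true expected state-4 count has slope
#'   `-decline` per year.
#' @export
drift_config <- function(n_territories = 18, n_seasons = 15, decline = 0.5,
                         p4_start = 0.8, first_year = 2000L, seed = 1L) {
  step <- decline / n_territories
  p4 <- p4_start - step * (seq_len(n_seasons) - 1)
  if (any(p4 <= 0.02) || p4_start >= 0.98) {
    stop("decline too steep for the number of seasons", call. = FALSE)
  }
  target <- function(p) {
    r <- 1 - p
    c(0.15 * r, 0.25 * r, 0.60 * r, p)
  }
  beta_mu_by_year <- array(NA_real_, c(n_seasons - 1, 4, 3))
  for (t in seq_len(n_seasons - 1)) {
    pt <- target(p4[t + 1])
    b <- log(pt[2:4] / pt[1])
    for (m in 1:4) beta_mu_by_year[t, m, ] <- b
  }
  alpha_mu <- matrix(c(
     2.5, 0, 0,    # (2,2)
    -1.0, 0, 0,    # (3,2)
     2.5, 0, 0,    # (3,3)
    -1.0, 0, 0,    # (4,2)
    -1.0, 0, 0,    # (4,3)
     2.5, 0, 0),   # (4,4)
    nrow = 6, byrow = TRUE)
  sim_config(
    blocks = tibble::tibble(block = "D", n_territories = n_territories,
                            first_year = as.integer(first_year),
                            last_year = as.integer(first_year + n_seasons - 1)),
    phi0 = target(p4[1]),
    beta_mu = matrix(0, 4, 3), beta_sigma = matrix(0, 4, 3),
    beta_mu_by_year = beta_mu_by_year,
    alpha_mu = alpha_mu, alpha_sigma = matrix(0.1, 6, 3),
    seed = seed
  )
}

#' Simulate survey data with known truth
#'
#' Generates a complete synthetic dataset from the dynamic multistate
#' model in the generative direction: (1) draw year-specific transition
#' and detection effects from their normal hyper-distributions, per block;
#' (2) draw each territory's initial state from `phi0`; (3) propagate
#' latent states through the yearly transition matrices; (4) draw visit
#' counts and distinct visit dates per surveyed territory-year; (5) draw
#' observed states from the detection matrix rows at the standardized
#' dates. Dates are standardized by the realized pooled mean/SD (the same
#' standardization a fit of the data would use).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An object of class `msocc_sim`: list with `data` (survey tibble
#'   with `jd_std`), `truth` (per block: `params` ([msocc_params()]) and
#'   latent state matrix `z`), and `config`.
#' @export
simulate_surveys <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  blocks <- config$blocks

  # latent structure and visit design first; observations need the pooled
  # date standardization, so they are drawn in a second pass
  truth <- list()
  design <- list()
  for (b in seq_len(nrow(blocks))) {
    blk <- blocks$block[b]
    years <- blocks$first_year[b]:blocks$last_year[b]
    T_ <- length(years)
    I_ <- blocks$n_territories[b]

    beta <- array(rnorm((T_ - 1) * 12,
                        mean = if (is.null(config$beta_mu_by_year)) {
                          aperm(array(config$beta_mu, c(4, 3, T_ - 1)), c(3, 1, 2))
                        } else {
                          config$beta_mu_by_year[seq_len(T_ - 1), , , drop = FALSE]
                        },
                        sd = aperm(array(config$beta_sigma, c(4, 3, T_ - 1)),
                                   c(3, 1, 2))),
                  dim = c(T_ - 1, 4, 3))
    alpha <- array(rnorm(T_ * 18,
                         mean = aperm(array(config$alpha_mu, c(6, 3, T_)),
                                      c(3, 1, 2)),
                         sd = aperm(array(config$alpha_sigma, c(6, 3, T_)),
                                    c(3, 1, 2))),
                   dim = c(T_, 6, 3))
    params <- msocc_params(config$phi0, beta, alpha, years)
    tpms <- tpm_list(params)

    z <- matrix(NA_integer_, I_, T_)
    z[, 1] <- sample.int(4L, I_, replace = TRUE, prob = config$phi0)
    for (t in seq_len(T_ - 1)) {
      for (i in seq_len(I_)) {
        z[i, t + 1] <- sample.int(4L, 1L, prob = tpms[[t]][z[i, t], ])
      }
    }
    terr_ids <- sprintf("%s%03d", blk, seq_len(I_))
    rownames(z) <- terr_ids

    # visit design: which territory-years are surveyed, how often, and when
    vis <- list()
    for (i in seq_len(I_)) {
      for (t in seq_len(T_)) {
        if (runif(1) > config$p_surveyed) next
        nv <- sample.int(15L, 1L, prob = config$visit_probs)
        dates <- sort(sample(config$date_window[1]:config$date_window[2], nv))
        vis[[length(vis) + 1L]] <- tibble::tibble(
          block = blk, territory = terr_ids[i], year = years[t],
          julian_date = dates, season = t, true_state = z[i, t]
        )
      }
    }
    truth[[blk]] <- list(params = params, z = z)
    design[[blk]] <- dplyr::bind_rows(vis)
  }

  all_design <- dplyr::bind_rows(design)
  jd_center <- mean(all_design$julian_date)
  jd_scale <- sd(all_design$julian_date)

  # observation pass: one multinomial draw per visit from the DPM row of
  # the territory's true state
  obs <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    blk <- blocks$block[b]
    d <- design[[blk]]
    params <- truth[[blk]]$params
    y <- integer(nrow(d))
    jd_std <- (d$julian_date - jd_center) / jd_scale
    for (r in seq_len(nrow(d))) {
      dpm <- dpm_at(params, d$season[r], jd_std[r])
      y[r] <- sample.int(4L, 1L, prob = dpm[d$true_state[r], ])
    }
    obs[[b]] <- dplyr::mutate(d, jd_std = jd_std, observed_state = y)
  }
  data <- dplyr::bind_rows(obs) |>
    dplyr::select("block", "territory", "year", "julian_date",
                  "observed_state", "jd_std")
  attr(data, "jd_center") <- jd_center
  attr(data, "jd_scale") <- jd_scale

  structure(list(data = data, truth = truth, config = config),
            class = "msocc_sim")
}

#' @export
print.msocc_sim <- function(x, ...) {
  cat("Synthetic multistate survey dataset:",
      dplyr::n_distinct(x$data$territory), "territories,",
      nrow(x$data), "visits,", nrow(x$config$blocks), "block(s)\n")
  invisible(x)
}

#' Write a simulated dataset and its truth to disk
#'
#' Emits the canonical survey CSV plus a JSON file holding the true
#' parameters and latent states, for use as an external test oracle.
#'
#' @param sim An `msocc_sim` from [simulate_surveys()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_surveys(sim$data, file.path(dir, "surveys.csv"))
  truth <- lapply(sim$truth, function(tr) {
    list(phi0 = tr$params$phi0, beta = tr$params$beta,
         alpha = tr$params$alpha, years = tr$params$years, z = tr$z)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
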