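#' Construct a full parameter set for one block
#'
#' Bundles the realized (year-specific) parameters of the dynamic
#' multistate model for a single block: initial state probabilities,
#' transition effects per between-season interval, and detection effects
#' per season.
#'
#' @param phi0 Length-4 probability vector of initial state probabilities.
#' @param beta Numeric array `(T - 1) x 4 x 3`: transition effects
#'   `beta[t, m, ]` carry season t to t + 1 from state m to states 2..4.
#' @param alpha Numeric array `T x 6 x 3`: detection effects per season
#'   and [dpm_pairs()] row, columns (intercept, date, date^2).
#' @param years Integer vector of the T calendar years (seasons) covered.
#' @return An object of class `msocc_params`.
#' @export
msocc_params <- function(phi0, beta, alpha, years) {
  years <- as.integer(years)
  T_ <- length(years)
  stopifnot(
    length(phi0) == 4, all(phi0 >= 0), abs(sum(phi0) - 1) < 1e-8,
    is.array(beta), all(dim(beta) == c(T_ - 1L, 4L, 3L)),
    is.array(alpha), all(dim(alpha) == c(T_, 6L, 3L))
  )
  structure(list(phi0 = phi0, beta = beta, alpha = alpha, years = years),
            class = "msocc_params")
}

#' @export
print.msocc_params <- function(x, ...) {
  cat("Dynamic multistate occupancy parameters:",
      length(x$years), "seasons (", min(x$years), "-", max(x$years), ")\n")
  cat("  phi0:", paste(sprintf("%.3f", x$phi0), collapse = " "), "\n")
  invisible(x)
}

#' Yearly transition matrices implied by a parameter set
#'
#' @param params An [msocc_params()] object.
#' @return List of `T - 1` row-stochastic 4x4 matrices.
#' @export
tpm_list <- function(params) {
  lapply(seq_len(dim(params$beta)[1]), function(t) {
    build_tpm(matrix(params$beta[t, , ], 4, 3))
  })
}

#' Detection matrix for one visit under a parameter set
#'
#' @param params An [msocc_params()] object.
#' @param season Season index (1-based within `params$years`).
#' @param jd_std Standardized Julian date of the visit.
#' @return 4x4 detection probability matrix.
#' @export
dpm_at <- function(params, season, jd_std) {
  build_dpm(matrix(params$alpha[season, , ], 6, 3), jd_std)
}

# season index for each record's year, validating membership
season_index <- function(years_data, years_model) {
  idx <- match(years_data, years_model)
  if (anyNA(idx)) {
    stop("data years outside the parameter set's seasons: ",
         paste(unique(years_data[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  idx
}
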