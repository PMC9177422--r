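#' Simulate route-level survey counts from the overdispersed Poisson model
#'
#' Counts are drawn from the same hierarchical model the trends module fits:
#' `count[r,t] ~ Poisson(exp(rho_r + beta1 (t - t0) + gamma_t + omega_obs +
#' eta first_year + alpha * H_std[r,t] + eps[r,t]))`, where `H_std` is the
#' standardized (mean 0, sd 1 across route-years) true habitat amount for the
#' species. Every effect draw is recorded in the `"effects"` attribute so
#' parameter-recovery tests can compare estimates against the simulated
#' truth.
#'
#' @param truth A [generate_landscape()] result.
#' @param profile One species-profile row.
#' @param config A [sim_config()] (its `$bbs` block holds the parameters).
#' @param routes Optional [make_routes()] tibble (generated if missing).
#' @param habitat Optional tibble (`route_id`, `year`, `habitat_ha`)
#'   overriding the truth-derived covariate.
#' @param seed Integer seed (default: counts substream of the master seed).
#' @return Tibble (`species`, `route_id`, `year`, `observer_id`,
#'   `first_year`, `count`, `habitat_ha`) with attribute `"effects"`
#'   containing the drawn `rho`, `gamma`, `omega`, `eps`, `beta1`, `alpha`,
#'   `eta` and the habitat standardization used.
#' @export
simulate_bbs_counts <- function(truth, profile, config = truth$config,
                                routes = NULL, habitat = NULL, seed = NULL) {
  p <- config$bbs
  years <- truth$years
  if (length(years) < 2) stop_config("need >= 2 years of counts")
  routes <- routes %||% make_routes(truth, p$n_routes)
  if (nrow(routes) < 2) stop_config("need >= 2 routes")
  habitat <- habitat %||% route_truth_habitat(truth, profile, routes)

  seed <- seed %||% substream_seed(config$seed, "counts")
  nr <- nrow(routes); ny <- length(years)
  df <- tidyr::expand_grid(route_id = routes$route_id, year = years)
  df <- dplyr::left_join(df, habitat, by = c("route_id", "year"))
  if (anyNA(df$habitat_ha)) stop_config("habitat covariate missing route-years")
  h_mu <- mean(df$habitat_ha); h_sd <- stats::sd(df$habitat_ha)
  h_std <- if (h_sd > 0) (df$habitat_ha - h_mu) / h_sd else rep(0, nrow(df))

  withr::with_seed(seed, {
    rho <- stats::rnorm(nr, p$intercept, p$sd_route)
    gamma <- stats::rnorm(ny, 0, p$sd_year)
    gamma <- gamma - mean(gamma)
    omega_pool <- stats::rnorm(p$n_observers, 0, p$sd_obs)
    # observer assignment: each route keeps its observer, switching with
    # obs_change_prob per year to a fresh id from the pool
    next_obs <- 1L
    obs_mat <- matrix(0L, nr, ny)
    for (r in seq_len(nr)) {
      cur <- next_obs; next_obs <- next_obs + 1L
      for (i in seq_len(ny)) {
        if (i > 1L && stats::runif(1) < p$obs_change_prob) {
          cur <- next_obs; next_obs <- next_obs + 1L
        }
        obs_mat[r, i] <- cur
      }
    }
    if (next_obs - 1L > p$n_observers) {
      omega_pool <- c(omega_pool,
                      stats::rnorm(next_obs - 1L - p$n_observers, 0, p$sd_obs))
    }
    obs_id <- as.vector(t(obs_mat))   # route-major, matches expand_grid order
    first_year <- as.integer(!duplicated(obs_id))
    eps <- stats::rnorm(nrow(df), 0, p$sd_eps)
    yr_c <- df$year - years[1]
    log_mu <- rho[rep(seq_len(nr), each = ny)] + p$beta1 * yr_c +
      gamma[match(df$year, years)] + omega_pool[obs_id] +
      p$eta * first_year + p$alpha * h_std + eps
    count <- stats::rpois(nrow(df), exp(log_mu))
  })

  out <- tibble::tibble(
    species = profile$species,
    route_id = df$route_id, year = df$year,
    observer_id = sprintf("O%04d", obs_id),
    first_year = first_year, count = count,
    habitat_ha = df$habitat_ha
  )
  attr(out, "effects") <- list(
    rho = rho, gamma = gamma, omega = omega_pool, eps = eps,
    beta1 = p$beta1, alpha = p$alpha, eta = p$eta,
    habitat_mean = h_mu, habitat_sd = h_sd
  )
  out
}
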