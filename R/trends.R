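#' Fit the hierarchical route-level abundance trend model
#'
#' A route-level variant of the classic hierarchical overdispersed-Poisson
#' survey-trend model. Counts at route r in year t follow
#' `count ~ Poisson(exp(rho_r + beta1 (t - t0) + gamma_t + omega_obs +
#' eta first_year + alphaH H + alphaD dH + eps_rt))` with hierarchical
#' Normal route, observer, year and overdispersion effects; year effects are
#' sum-to-zero constrained to separate them from the linear trend. Habitat
#' covariates are standardized internally (mean 0, sd 1 across route-years).
#' Priors are weakly informative: effects Normal(0, sigma^2) with
#' half-Normal(0, 1) hyper-sds, `beta1 ~ Normal(0, sqrt(10))`.
#'
#' Sampling uses JAGS with >= 3 chains; the fit fails loudly if any
#' monitored parameter has a potential-scale-reduction R-hat above
#' `rhat_max`.
#'
#' @param records Tibble (`route_id`, `year`, `observer_id`, `first_year`,
#'   `count`, and `habitat_ha` when habitat terms are requested).
#' @param trend,habitat,change Include the linear year trend, the
#'   habitat-amount covariate, the year-over-year habitat-change covariate.
#' @param observer,first_year_effect,year_effects,overdispersion Include the
#'   corresponding Sauer-Link nuisance terms (all default TRUE).
#' @param chains,draws,warmup,adapt,thin MCMC profile (defaults 3 chains x
#'   2000 draws after 1000 warmup).
#' @param seed Integer seed for the samplers.
#' @param rhat_max Convergence gate (default 1.05).
#' @param rhat_scope Apply the gate to the reported effect parameters
#'   (`"effects"`: trend, habitat, habitat-change and first-year terms; the
#'   default) or to `"all"` monitored parameters. Variance hyperparameters
#'   of deep random effects mix slowly under any Gibbs scheme and are
#'   nuisance quantities; their R-hats are always reported in the summary.
#' @param check_convergence Raise an error when the gate fails (default
#'   TRUE).
#' @return A `trend_fit`: posterior summary tibble, `coda::mcmc.list`
#'   draws, term flags, data/standardization info, diagnostics.
#' @export
fit_trend_model <- function(records,
                            trend = TRUE, habitat = FALSE, change = FALSE,
                            observer = TRUE, first_year_effect = TRUE,
                            year_effects = TRUE, overdispersion = TRUE,
                            chains = 3, draws = 2000, warmup = 1000,
                            adapt = 500, thin = 1, seed = 1L,
                            rhat_max = 1.05, rhat_scope = c("effects", "all"),
                            check_convergence = TRUE) {
  rhat_scope = match.arg(rhat_scope)
  validate_count_records(records, need_habitat = habitat || change)
  if (chains < 3) stop_config("need >= 3 chains")

  routes <- sort(unique(records$route_id))
  years <- sort(unique(records$year))
  if (length(routes) < 2 || length(years) < 2) {
    stop_validation("need >= 2 routes and >= 2 years")
  }
  observers <- sort(unique(records$observer_id))
  t0 <- years[1]

  dat <- list(
    count = as.integer(records$count),
    route = match(records$route_id, routes),
    N = nrow(records), R = length(routes)
  )
  terms <- character(0)
  if (trend) {
    dat$yrc <- records$year - t0
    terms <- c(terms, "beta1 * yrc[i]")
  }
  if (year_effects) {
    dat$yearidx <- match(records$year, years)
    dat$TY <- length(years)
    terms <- c(terms, "gamma[yearidx[i]]")
  }
  if (observer) {
    dat$obs <- match(records$observer_id, observers)
    dat$O <- length(observers)
    terms <- c(terms, "omega[obs[i]]")
  }
  if (first_year_effect) {
    dat$first <- as.numeric(records$first_year)
    terms <- c(terms, "eta * first[i]")
  }
  h_info <- list()
  if (habitat) {
    h_mu <- mean(records$habitat_ha); h_sd <- stats::sd(records$habitat_ha)
    if (h_sd == 0) stop_validation("habitat covariate has zero variance")
    dat$H <- (records$habitat_ha - h_mu) / h_sd
    terms <- c(terms, "alphaH * H[i]")
    h_info <- list(habitat_mean = h_mu, habitat_sd = h_sd,
                   h_std_range = range(dat$H))
  }
  if (change) {
    dh <- records |>
      dplyr::group_by(.data$route_id) |>
      dplyr::arrange(.data$year, .by_group = TRUE) |>
      dplyr::mutate(dh = .data$habitat_ha - dplyr::lag(.data$habitat_ha)) |>
      dplyr::ungroup() |>
      dplyr::pull(.data$dh)
    dh[is.na(dh)] <- 0
    dh_sd <- stats::sd(dh)
    dat$dH <- if (dh_sd > 0) (dh - mean(dh)) / dh_sd else dh
    terms <- c(terms, "alphaD * dH[i]")
    h_info$dh_sd <- dh_sd
  }
  if (overdispersion) terms <- c(terms, "eps[i]")

  model_code <- trend_model_code(trend, habitat, change, observer,
                                 first_year_effect, year_effects,
                                 overdispersion, terms)
  monitors <- c(
    "mu_rho", "sigma_rho",
    if (trend) "beta1",
    if (year_effects) "sigma_gamma",
    if (observer) "sigma_omega",
    if (first_year_effect) "eta",
    if (habitat) "alphaH",
    if (change) "alphaD",
    if (overdispersion) "sigma_eps"
  )
  inits <- lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (substream_seed(seed, "mcmc") + k) %% 2147483587)
  })
  # block samplers for Poisson GLM nodes
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  jm <- rjags::jags.model(textConnection(model_code), data = dat,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = TRUE)
  if (warmup > 0) update(jm, warmup, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitors, n.iter = draws, thin = thin,
                                 progress.bar = "none")
  summary <- summarize_posterior(samples)

  gate_terms <- if (rhat_scope == "all") summary$term else {
    intersect(summary$term, c("beta1", "alphaH", "alphaD", "eta"))
  }
  bad <- summary$rhat > rhat_max & summary$term %in% gate_terms
  if (any(bad, na.rm = TRUE) && check_convergence) {
    abort(sprintf("MCMC did not converge: R-hat > %.2f for %s",
                  rhat_max,
                  paste(summary$term[which(bad)], collapse = ", ")),
          class = "birdhab_convergence_error")
  }

  structure(list(
    summary = summary, samples = samples,
    terms = list(trend = trend, habitat = habitat, change = change,
                 observer = observer, first_year_effect = first_year_effect,
                 year_effects = year_effects, overdispersion = overdispersion),
    data_info = c(list(n_routes = length(routes), n_years = length(years),
                       years = years, t0 = t0, n_obs = nrow(records)), h_info),
    mcmc = list(chains = chains, draws = draws, warmup = warmup, thin = thin,
                seed = seed)
  ), class = "trend_fit")
}

validate_count_records <- function(records, need_habitat = FALSE) {
  need <- c("route_id", "year", "observer_id", "first_year", "count")
  if (need_habitat) need <- c(need, "habitat_ha")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_validation("count records missing columns: %s",
                    paste(miss, collapse = ", "))
  }
  cnt <- records$count
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt))
    stop_validation("counts must be non-negative integers (rows %s)",
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(records)
}

trend_model_code <- function(trend, habitat, change, observer, first_year,
                             year_effects, overdispersion, terms) {
  lp <- paste(c("rho[route[i]]", terms[terms != "eps[i]"],
                if (overdispersion) "eps[i]"), collapse = " + ")
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    count[i] ~ dpois(mu[i])\n",
    "    log(mu[i]) <- ", lp, "\n",
    if (overdispersion) "    eps[i] ~ dnorm(0, tau_eps)\n" else "",
    "  }\n",
    "  for (r in 1:R) { rho[r] ~ dnorm(mu_rho, tau_rho) }\n",
    "  mu_rho ~ dnorm(0, 0.01)\n",
    "  sigma_rho ~ dnorm(0, 1) T(0,)\n",
    "  tau_rho <- pow(sigma_rho, -2)\n",
    if (trend) "  beta1 ~ dnorm(0, 0.1)\n" else "",
    if (year_effects) paste0(
      "  for (t in 1:TY) { gamma_raw[t] ~ dnorm(0, tau_gamma) }\n",
      "  for (t in 1:TY) { gamma[t] <- gamma_raw[t] - mean(gamma_raw[]) }\n",
      "  sigma_gamma ~ dnorm(0, 1) T(0,)\n",
      "  tau_gamma <- pow(sigma_gamma, -2)\n") else "",
    if (observer) paste0(
      "  for (o in 1:O) { omega[o] ~ dnorm(0, tau_omega) }\n",
      "  sigma_omega ~ dnorm(0, 1) T(0,)\n",
      "  tau_omega <- pow(sigma_omega, -2)\n") else "",
    if (first_year) "  eta ~ dnorm(0, 1)\n" else "",
    if (habitat) "  alphaH ~ dnorm(0, 0.1)\n" else "",
    if (change) "  alphaD ~ dnorm(0, 0.1)\n" else "",
    if (overdispersion) paste0(
      "  sigma_eps ~ dnorm(0, 1) T(0,)\n",
      "  tau_eps <- pow(sigma_eps, -2)\n") else "",
    "}\n"
  )
}

# Posterior moments, quantiles, sign probabilities and diagnostics for every
# monitored parameter of an mcmc.list.
summarize_posterior <- function(samples) {
  mat <- as.matrix(samples)
  terms <- colnames(mat)
  rhat <- tryCatch({
    gd <- coda::gelman.diag(samples, autoburnin = FALSE, multivariate = FALSE)
    gd$psrf[, 1]
  }, error = function(e) rep(NA_real_, length(terms)))
  ess <- tryCatch(coda::effectiveSize(samples),
                  error = function(e) rep(NA_real_, length(terms)))
  tibble::tibble(
    term = terms,
    mean = colMeans(mat),
    median = apply(mat, 2, stats::median),
    sd = apply(mat, 2, stats::sd),
    q2.5 = apply(mat, 2, stats::quantile, 0.025),
    q97.5 = apply(mat, 2, stats::quantile, 0.975),
    p_negative = colMeans(mat < 0),
    rhat = unname(rhat[terms]),
    ess = unname(ess[terms])
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %d routes x %d years, %d records\n",
              x$data_info$n_routes, x$data_info$n_years, x$data_info$n_obs))
  print(x$summary)
  invisible(x)
}

#' Posterior fold change in abundance across the observed habitat range
#'
#' For each posterior draw of the habitat coefficient, computes
#' `exp(alphaH * (Hmax - Hmin))` on the standardized habitat scale and
#' reports the posterior median: the multiplicative abundance difference
#' between the highest- and lowest-habitat landscapes.
#'
#' @param fit A `trend_fit` with the habitat term.
#' @param range Standardized habitat range (defaults to the observed
#'   `max - min` of the fit's standardized covariate).
#' @return List: `median`, `q2.5`, `q97.5`, `draws`.
#' @export
habitat_fold_change <- function(fit, range = NULL) {
  if (!isTRUE(fit$terms$habitat)) {
    stop_validation("fit has no habitat term")
  }
  range <- range %||% diff(fit$data_info$h_std_range)
  draws <- exp(as.matrix(fit$samples)[, "alphaH"] * range)
  list(median = stats::median(draws),
       q2.5 = unname(stats::quantile(draws, 0.025)),
       q97.5 = unname(stats::quantile(draws, 0.975)),
       draws = draws)
}

#' Convert a log-scale trend coefficient to annual percent change
#'
#' @param beta1 Trend coefficient(s).
#' @param convention `"proportion"` (default; `100 * beta1`, matching the
#'   usual labelling where -0.05 is read as -5% per year) or `"log-linear"`
#'   (`100 * (exp(beta1) - 1)`).
#' @return Annual percent change.
#' @export
#' @examples
#' trend_to_percent(-0.05)                # -5
#' trend_to_percent(-0.05, "log-linear")  # -4.877
trend_to_percent <- function(beta1, convention = c("proportion", "log-linear")) {
  convention <- match.arg(convention)
  if (convention == "proportion") 100 * beta1 else 100 * (exp(beta1) - 1)
}

#' Classify a population trend from its posterior credible interval
#'
#' Declining if the 95% credible interval for the trend lies below zero,
#' increasing if above, uncertain otherwise.
#'
#' @param fit A `trend_fit` (or its summary tibble).
#' @return `"declining"`, `"increasing"` or `"uncertain"`.
#' @export
classify_decline <- function(fit) {
  s <- if (inherits(fit, "trend_fit")) fit$summary else fit
  row <- dplyr::filter(s, .data$term == "beta1")
  if (nrow(row) == 0) stop_validation("no trend coefficient in fit")
  if (row$q97.5 < 0) "declining" else if (row$q2.5 > 0) "increasing" else {
    "uncertain"
  }
}

#' Ten-year population trend with threatened-listing flag
#'
#' Refits the trend model on the last `window` years of data and converts
#' the annual trend to a cumulative percent change
#' `100 * ((1 + beta1)^window - 1)` (proportion convention). A cumulative
#' decline steeper than 30% over ten years meets the usual "threatened"
#' listing criterion.
#'
#' @param records Count records as for [fit_trend_model()].
#' @param window Number of most recent years (default 10).
#' @param ... Passed to [fit_trend_model()].
#' @return List: `fit`, `cumulative_pct` (posterior median), `q2.5`,
#'   `q97.5`, `flagged` (median decline > 30%).
#' @export
ten_year_trend <- function(records, window = 10, ...) {
  years <- sort(unique(records$year))
  if (length(years) < window) {
    stop_validation("need >= %d years of data, got %d", window, length(years))
  }
  keep <- utils::tail(years, window)
  fit <- fit_trend_model(dplyr::filter(records, .data$year %in% keep), ...)
  b <- as.matrix(fit$samples)[, "beta1"]
  cum <- 100 * ((1 + b)^window - 1)
  list(fit = fit,
       cumulative_pct = stats::median(cum),
       q2.5 = unname(stats::quantile(cum, 0.025)),
       q97.5 = unname(stats::quantile(cum, 0.975)),
       flagged = stats::median(cum) < -30)
}
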