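#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted trend model
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return The posterior summary as a tibble (`term`, `mean`, `median`,
#'   `sd`, `q2.5`, `q97.5`, `p_negative`, `rhat`, `ess`).
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) x$summary

#' One-row summary of a fitted trend model
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble with data size, sampler settings and worst diagnostics.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    n_routes = x$data_info$n_routes, n_years = x$data_info$n_years,
    n_obs = x$data_info$n_obs, chains = x$mcmc$chains,
    draws = x$mcmc$draws,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    min_ess = min(x$summary$ess, na.rm = TRUE)
  )
}

#' Tidy a Maxent model's non-zero feature weights
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`, `penalty`), active features only.
#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(term = names(x$lambda), estimate = unname(x$lambda),
                 penalty = unname(x$beta_j)) |>
    dplyr::filter(.data$estimate != 0)
}

#' One-row summary of a Maxent model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with beta, feature counts, entropy and normalizer.
#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, n_features = length(x$lambda),
    n_active = sum(x$lambda != 0), n_presences = x$n_presences,
    n_background = x$n_background, entropy = x$h, log_z = x$log_z,
    objective = x$objective, iterations = x$iterations
  )
}

#' Tidy an association regression
#'
#' @param x An `association_regression`.
#' @param ... Unused.
#' @return Posterior summary tibble.
#' @method tidy association_regression
#' @export
tidy.association_regression <- function(x, ...) x$summary

#' Tidy a clear-cut/habitat-loss regression
#'
#' @param x A `clearcut_regression`.
#' @param ... Unused.
#' @return Coefficient tibble with 95% confidence limits.
#' @method tidy clearcut_regression
#' @export
tidy.clearcut_regression <- function(x, ...) x$coef
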