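#' Simulation configuration for synthetic forest landscapes
#'
#' Bundles every knob of the synthetic-data generator: grid size, simulated
#' years, disturbance rates, reflectance sampling, and the parameters of the
#' route-count (BBS-style) simulator. All downstream randomness derives from
#' the single `seed` via fixed per-component substreams, so any stage can be
#' re-simulated independently and reproducibly.
#'
#' @param seed Integer master seed.
#' @param rows,cols Grid dimensions (30 m pixels).
#' @param years Integer vector of contiguous simulated years.
#' @param p_clearcut Annual per-pixel clear-cut probability for forest pixels.
#' @param plantation_fraction Probability a clear-cut pixel is replanted as a
#'   single-species plantation rather than regenerating naturally.
#' @param p_deforest Annual per-pixel probability of permanent conversion to
#'   non-forest.
#' @param revisit_days Interval (days) between satellite observations.
#' @param noise_sd Standard deviation of i.i.d. Gaussian reflectance noise
#'   (reflectance units).
#' @param old_age Stand age (years) at which naturally regenerated forest is
#'   classed as shade-tolerant old forest.
#' @param init_age_max Maximum initial stand age (years); initial ages are
#'   uniform on `0:init_age_max`.
#' @param harmonic_library Tibble of per-class, per-band harmonic coefficients
#'   (columns `class`, `band`, `A0`, `B0`, `A1`, `B1`, `A2`, `B2`, `A3`,
#'   `B3`). Defaults to [default_harmonic_library()].
#' @param bbs Named list of route-count simulator parameters: `n_routes`,
#'   `intercept` (log expected count at the reference year), `beta1` (log-scale
#'   annual trend), `alpha` (habitat coefficient on the standardized habitat
#'   covariate), `sd_route`, `sd_obs`, `eta` (first-year observer effect),
#'   `sd_year`, `sd_eps` (overdispersion), `n_observers`, `obs_change_prob`.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, rows = 20, cols = 20, years = 2000:2005)
#' cfg$p_clearcut
sim_config <- function(seed = 1L,
                       rows = 100L,
                       cols = 100L,
                       years = 1985:2020,
                       p_clearcut = 0.02,
                       plantation_fraction = 0.5,
                       p_deforest = 0.001,
                       revisit_days = 16,
                       noise_sd = 0.02,
                       old_age = 60L,
                       init_age_max = 120L,
                       harmonic_library = default_harmonic_library(),
                       bbs = list()) {
  bbs_default <- list(
    n_routes = 10L, intercept = log(5), beta1 = -0.02, alpha = 0.3,
    sd_route = 0.2, sd_obs = 0.15, eta = -0.15, sd_year = 0.1,
    sd_eps = 0.1, n_observers = 200L, obs_change_prob = 0.1
  )
  bbs <- utils::modifyList(bbs_default, bbs)

  cfg <- list(
    seed = as.integer(seed), rows = as.integer(rows), cols = as.integer(cols),
    years = as.integer(years), p_clearcut = p_clearcut,
    plantation_fraction = plantation_fraction, p_deforest = p_deforest,
    revisit_days = revisit_days, noise_sd = noise_sd,
    old_age = as.integer(old_age), init_age_max = as.integer(init_age_max),
    harmonic_library = harmonic_library, bbs = bbs
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(
    p_clearcut = cfg$p_clearcut,
    plantation_fraction = cfg$plantation_fraction,
    p_deforest = cfg$p_deforest,
    obs_change_prob = cfg$bbs$obs_change_prob
  )
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop_config("probabilities must lie in [0, 1]: %s",
                paste(names(probs)[bad], collapse = ", "))
  }
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (cfg$revisit_days <= 0) stop_config("revisit_days must be > 0")
  if (length(cfg$years) < 2) stop_config("at least 2 simulated years required")
  if (any(diff(cfg$years) != 1L)) stop_config("years must be contiguous")
  sds <- unlist(cfg$bbs[c("sd_route", "sd_obs", "sd_year", "sd_eps")])
  if (any(sds < 0)) stop_config("BBS effect sds must be >= 0")
  invisible(cfg)
}

#' Per-class harmonic reflectance coefficient library
#'
#' One row per (cover class, band) giving the eight harmonic coefficients
#' (`A0` intercept, `B0` inter-annual slope per day, `A1..A3`/`B1..B3`
#' intra-annual terms, period 365.25 d) that generate noiseless reflectance
#' for that class. The defaults encode the broad spectral behaviour the
#' simulator needs: bright aseasonal non-forest, dark moderately seasonal
#' old mixed forest, bright strongly seasonal young regenerating forest, and
#' dark weakly seasonal (evergreen) plantations.
#'
#' @return Tibble with columns `class`, `band`, `A0`, `B0`, `A1`, `B1`,
#'   `A2`, `B2`, `A3`, `B3`.
#' @export
default_harmonic_library <- function() {
  classes <- cover_classes()
  base <- c(tolerant_old = 0.06, regenerating = 0.14, plantation = 0.08,
            non_forest = 0.30)
  amp <- c(tolerant_old = 0.05, regenerating = 0.10, plantation = 0.015,
           non_forest = 0.01)
  grid <- tidyr::expand_grid(class = classes, band = 1:6)
  dplyr::mutate(
    grid,
    A0 = base[.data$class] + 0.025 * (.data$band - 1),
    B0 = 0,
    A1 = amp[.data$class] * (1 + 0.1 * (.data$band - 3)),
    B1 = 0.5 * .data$A1,
    A2 = 0.15 * .data$A1,
    B2 = -0.1 * .data$A1,
    A3 = 0.05 * .data$A1,
    B3 = 0.02 * .data$A1
  )
}

cover_classes <- function() {
  c("tolerant_old", "regenerating", "plantation", "non_forest")
}

coef_names <- function() c("A0", "B0", "A1", "B1", "A2", "B2", "A3", "B3")

# Evaluate the harmonic model for a coefficient matrix whose rows align with t.
eval_harmonic <- function(coefs, t) {
  stopifnot(ncol(coefs) == 8)
  w <- 2 * pi * t / DAYS_PER_YEAR
  coefs[, 1] + coefs[, 2] * t +
    coefs[, 3] * cos(w) + coefs[, 4] * sin(w) +
    coefs[, 5] * cos(2 * w) + coefs[, 6] * sin(2 * w) +
    coefs[, 7] * cos(3 * w) + coefs[, 8] * sin(3 * w)
}

#' Read a simulation configuration from a YAML file
#'
#' The file may contain any subset of [sim_config()]'s arguments (with a
#' nested `bbs` block); unspecified values take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_config("unknown configuration fields: %s",
                paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$years)) vals$years <- as.integer(vals$years)
  do.call(sim_config, vals)
}
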