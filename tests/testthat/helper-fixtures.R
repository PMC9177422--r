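# Shared small fixtures, built in code.

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, rows = 12, cols = 12, years = 2000:2005,
         p_clearcut = 0.05, revisit_days = 16),
    list(...))
  do.call(sim_config, args)
}

# A flat-occupancy profile: occupancy identically plogis(logit_p).
flat_profile <- function(p, species = "flat") {
  species_profile(species, intercept = stats::qlogis(p), age_slope = 0,
                  class_effects = c(tolerant_old = 0, regenerating = 0,
                                    plantation = 0, non_forest = 0))
}

# Homogeneous-Poisson BBS parameter block: all effects off.
bbs_flat <- function(...) {
  utils::modifyList(
    list(beta1 = 0, alpha = 0, sd_route = 0, sd_obs = 0, eta = 0,
         sd_year = 0, sd_eps = 0),
    list(...))
}

# Random raw 54-feature table for maxent tests.
random_features <- function(n, p = 54, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * p), n, p)
  })
  colnames(m) <- paste0("f", seq_len(p))
  tibble::as_tibble(m)
}
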