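#' Define a synthetic species occupancy profile
#'
#' Occupancy probability is a logistic function of stand age and cover class:
#' `logit(p) = intercept + age_slope * age + class_effect[class]`, so it is
#' strictly inside (0, 1) everywhere. The mature-forest association score is
#' the continuous axis used by the impact module's association regression;
#' territory sizes bound breeding-pair density per hectare of habitat.
#'
#' @param species Species identifier.
#' @param intercept,age_slope Logit-scale intercept and per-year age slope.
#' @param class_effects Named numeric vector of logit offsets, one per cover
#'   class (`tolerant_old`, `regenerating`, `plantation`, `non_forest`).
#' @param mature_association Continuous mature-forest association score.
#' @param territory_min_ha,territory_max_ha Territory size range (ha/pair).
#' @param successional_class One of `"R"` (regenerating), `"I"` (immature),
#'   `"M"` (mature).
#' @return A one-row tibble of class `species_profile`.
#' @export
#' @examples
#' species_profile("old_forest_specialist", intercept = -5, age_slope = 0.08)
species_profile <- function(species,
                            intercept = 0,
                            age_slope = 0,
                            class_effects = c(tolerant_old = 0,
                                              regenerating = 0,
                                              plantation = 0,
                                              non_forest = 0),
                            mature_association = 0,
                            territory_min_ha = 1,
                            territory_max_ha = 2,
                            successional_class = "M") {
  missing_cls <- setdiff(cover_classes(), names(class_effects))
  if (length(missing_cls)) {
    stop_config("class_effects missing classes: %s",
                paste(missing_cls, collapse = ", "))
  }
  if (!(territory_min_ha > 0 && territory_min_ha <= territory_max_ha)) {
    stop_config("need 0 < territory_min_ha <= territory_max_ha")
  }
  if (!successional_class %in% c("R", "I", "M")) {
    stop_config("successional_class must be R, I or M")
  }
  out <- tibble::tibble(
    species = species, intercept = intercept, age_slope = age_slope,
    class_effects = list(class_effects[cover_classes()]),
    mature_association = mature_association,
    territory_min_ha = territory_min_ha, territory_max_ha = territory_max_ha,
    successional_class = successional_class
  )
  class(out) <- c("species_profile", class(out))
  out
}

#' Example species pool: an old-forest specialist and an early-seral species
#'
#' @return A tibble of stacked [species_profile()] rows.
#' @export
example_profiles <- function() {
  dplyr::bind_rows(
    species_profile(
      "oldforest_specialist",
      intercept = -4.5, age_slope = 0.07,
      class_effects = c(tolerant_old = 1.0, regenerating = 0,
                        plantation = -2.0, non_forest = -8),
      mature_association = 0.9,
      territory_min_ha = 1, territory_max_ha = 3,
      successional_class = "M"
    ),
    species_profile(
      "earlyseral_generalist",
      intercept = 1.2, age_slope = -0.10,
      class_effects = c(tolerant_old = -1.0, regenerating = 0.5,
                        plantation = -0.5, non_forest = -5),
      mature_association = -0.6,
      territory_min_ha = 0.5, territory_max_ha = 1.5,
      successional_class = "R"
    )
  )
}

#' Occupancy probability for one species over pixels
#'
#' @param profile One row of a species-profile tibble.
#' @param age Numeric vector of stand ages.
#' @param class_id Integer vector of cover-class codes aligned with `age`.
#' @return Probabilities in (0, 1).
#' @export
occupancy_prob <- function(profile, age, class_id) {
  eff <- profile$class_effects[[1]]
  stats::plogis(profile$intercept + profile$age_slope * age + eff[class_id])
}
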