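#' Convert net habitat change into breeding-pairs-lost bounds
#'
#' For each species with a net habitat loss, territory sizes bound the
#' number of displaced breeding pairs: `pairs_min = loss_ha /
#' territory_max_ha`, `pairs_max = loss_ha / territory_min_ha`, and
#' individuals are exactly twice the pairs. Within-species gains offset
#' losses before conversion (net accounting); species with net gains
#' contribute zero loss. The calculation assumes available habitat is
#' consistently occupied by territories.
#'
#' @param habitat_change Tibble (`species`, `net_change_ha`); negative
#'   values are losses. With `mode = "loss_only"` supply a `loss_ha` column
#'   of gross losses instead.
#' @param territories Tibble (`species`, `territory_min_ha`,
#'   `territory_max_ha`).
#' @param mode `"net"` (default) or `"loss_only"`.
#' @return A `pairs_lost` list: `by_species` tibble (`species`, `loss_ha`,
#'   `pairs_min`, `pairs_max`, `individuals_min`, `individuals_max`) and
#'   `total` (one-row tibble of sums, including `total_loss_ha` and
#'   `total_loss_km2`).
#' @export
#' @examples
#' pairs_lost(
#'   tibble::tibble(species = "sp1", net_change_ha = -100),
#'   tibble::tibble(species = "sp1", territory_min_ha = 2,
#'                  territory_max_ha = 5)
#' )$by_species
pairs_lost <- function(habitat_change, territories, mode = c("net", "loss_only")) {
  mode <- match.arg(mode)
  if (any(territories$territory_min_ha <= 0) ||
      any(territories$territory_min_ha > territories$territory_max_ha)) {
    stop_config("territory sizes must satisfy 0 < min <= max")
  }
  missing_sp <- setdiff(habitat_change$species, territories$species)
  if (length(missing_sp)) {
    abort(sprintf("no territory entry for species: %s",
                  paste(missing_sp, collapse = ", ")),
          class = "birdhab_coverage_error")
  }
  df <- dplyr::left_join(habitat_change, territories, by = "species")
  loss <- if (mode == "net") pmax(-df$net_change_ha, 0) else df$loss_ha
  by_species <- tibble::tibble(
    species = df$species,
    loss_ha = loss,
    pairs_min = loss / df$territory_max_ha,
    pairs_max = loss / df$territory_min_ha,
    individuals_min = 2 * loss / df$territory_max_ha,
    individuals_max = 2 * loss / df$territory_min_ha
  )
  total <- dplyr::summarise(
    by_species,
    total_loss_ha = sum(.data$loss_ha),
    total_loss_km2 = sum(.data$loss_ha) / 100,
    pairs_min = sum(.data$pairs_min), pairs_max = sum(.data$pairs_max),
    individuals_min = sum(.data$individuals_min),
    individuals_max = sum(.data$individuals_max)
  )
  structure(list(by_species = by_species, total = total),
            class = "pairs_lost")
}

#' @export
print.pairs_lost <- function(x, ...) {
  cat("<pairs_lost>\n")
  print(x$total)
  invisible(x)
}

#' Bayesian regression of habitat change on mature-forest association
#'
#' Fits, per species record, `habitat_change_pct ~ Normal(a +
#' b * association, sigma)` by MCMC, optionally with a separate intercept
#' per successional class (R/I/M). Reports the slope posterior and a 95%
#' credible band for the fitted line.
#'
#' @param records Tibble (`species`, `mature_association`,
#'   `habitat_change_pct`, optionally `successional_class`).
#' @param class_intercepts Add per-successional-class intercepts.
#' @param chains,draws,warmup,seed MCMC profile.
#' @return An `association_regression` list: `summary` tibble (includes the
#'   `slope` term), `samples`, `band` function (`x -> tibble(fit, lower,
#'   upper)`).
#' @export
association_regression <- function(records, class_intercepts = FALSE,
                                   chains = 3, draws = 2000, warmup = 1000,
                                   seed = 1L) {
  if (nrow(records) < 5) stop_validation("need >= 5 species with scores")
  x <- records$mature_association
  if (stats::sd(x) == 0) {
    abort("constant association score; regression undefined",
          class = "birdhab_regression_error")
  }
  y <- records$habitat_change_pct
  dat <- list(x = x, y = y, N = length(y))
  if (class_intercepts) {
    cls <- factor(records$successional_class, levels = c("R", "I", "M"))
    if (anyNA(cls)) stop_validation("successional_class must be R, I or M")
    dat$cls <- as.integer(cls)
    dat$C <- nlevels(cls)
  }
  code <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    if (class_intercepts) {
      "    y[i] ~ dnorm(a[cls[i]] + b * x[i], tau)\n"
    } else {
      "    y[i] ~ dnorm(a + b * x[i], tau)\n"
    },
    "  }\n",
    if (class_intercepts) {
      "  for (c in 1:C) { a[c] ~ dnorm(0, 1e-4) }\n"
    } else {
      "  a ~ dnorm(0, 1e-4)\n"
    },
    "  b ~ dnorm(0, 1e-4)\n",
    "  sigma ~ dnorm(0, 0.001) T(0.001,)\n",   # bounded away from 0 so exact-fit data cannot overflow the precision

    "  tau <- pow(sigma, -2)\n",
    "}\n"
  )
  inits <- lapply(seq_len(chains), function(k) {
    list(sigma = 1,   # keep the truncated half-Normal off its boundary
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (substream_seed(seed, "mcmc") + k) %% 2147483587)
  })
  jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                          n.chains = chains, n.adapt = 500, quiet = TRUE)
  update(jm, warmup, progress.bar = "none")
  samples <- rjags::coda.samples(jm, c("a", "b", "sigma"), n.iter = draws,
                                 progress.bar = "none")
  summary <- summarize_posterior(samples)
  summary$term[summary$term == "b"] <- "slope"
  mat <- as.matrix(samples)
  a_cols <- grep("^a", colnames(mat), value = TRUE)
  band <- function(xs) {
    a_draw <- if (length(a_cols) == 1) mat[, a_cols] else {
      rowMeans(mat[, a_cols])
    }
    purrr::map_dfr(xs, function(x0) {
      f <- a_draw + mat[, "b"] * x0
      tibble::tibble(x = x0, fit = stats::median(f),
                     lower = unname(stats::quantile(f, 0.025)),
                     upper = unname(stats::quantile(f, 0.975)))
    })
  }
  structure(list(summary = summary, samples = samples, band = band),
            class = "association_regression")
}

#' @export
print.association_regression <- function(x, ...) {
  cat("<association_regression>\n")
  print(dplyr::filter(x$summary, .data$term == "slope"))
  invisible(x)
}
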