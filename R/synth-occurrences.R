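#' Simulate presence-only species occurrence points
#'
#' Sampling locations are drawn uniformly over the grid (and uniformly over
#' `years`); presence at a point is a Bernoulli draw with probability given
#' by the species occupancy curve at that pixel-year.
#'
#' @param truth A [generate_landscape()] result.
#' @param profiles Tibble of [species_profile()] rows.
#' @param n_points Number of survey points per species.
#' @param years Years to sample from (default: the landscape's final year).
#' @param seed Integer seed (default: the occurrences substream of the
#'   landscape's master seed).
#' @return Tibble (`species`, `x`, `y`, `row`, `col`, `year`, `p_occ`,
#'   `present`); `x`/`y` are pixel-centre planar metres, origin at the
#'   top-left corner, `y` increasing downwards.
#' @export
simulate_occurrences <- function(truth, profiles, n_points,
                                 years = max(truth$years), seed = NULL) {
  if (nrow(profiles) == 0) stop_config("empty species profile list")
  if (n_points < 1) stop_config("n_points must be >= 1")
  if (!all(years %in% truth$years)) {
    stop_config("requested years outside the simulated range")
  }
  seed <- seed %||% substream_seed(truth$config$seed, "occurrences")
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
      prof <- profiles[i, ]
      row <- sample.int(truth$rows, n_points, replace = TRUE)
      col <- sample.int(truth$cols, n_points, replace = TRUE)
      yr <- if (length(years) == 1L) rep(years, n_points) else {
        sample(years, n_points, replace = TRUE)
      }
      yi <- match(yr, truth$years)
      idx <- cbind(row, col, yi)
      p <- occupancy_prob(prof, truth$age[idx], truth$class_id[idx])
      tibble::tibble(
        species = prof$species,
        x = (col - 0.5) * PIXEL_M, y = (row - 0.5) * PIXEL_M,
        row = row, col = col, year = yr, p_occ = p,
        present = as.integer(stats::runif(n_points) < p)
      )
    })
  })
  out
}
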