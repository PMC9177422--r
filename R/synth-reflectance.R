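#' Simulate per-pixel multi-band reflectance time series
#'
#' Each pixel-band series is its cover class's harmonic curve evaluated at
#' regular revisit dates plus i.i.d. Gaussian noise; when a pixel's class
#' changes (disturbance, succession), the coefficients switch abruptly at the
#' first observation of the new class's year.
#'
#' @param truth A [generate_landscape()] result.
#' @param config A [sim_config()] (defaults to the one stored in `truth`).
#' @param pixels Optional tibble with `row`, `col` restricting which pixels
#'   are simulated (all pixels otherwise).
#' @param bands Integer vector of bands to simulate (default 1:6).
#' @return Tibble with columns `pixel_id`, `row`, `col`, `band`, `t`
#'   (days since Jan 1 of the first simulated year), `year`, `value`.
#' @export
#' @examples
#' truth <- generate_landscape(sim_config(seed = 1, rows = 10, cols = 10,
#'                                        years = 2000:2002))
#' head(simulate_reflectance(truth, pixels = tibble::tibble(row = 1, col = 1)))
simulate_reflectance <- function(truth, config = truth$config, pixels = NULL,
                                 bands = 1:6) {
  lib <- config$harmonic_library
  missing_cls <- setdiff(cover_classes(), unique(lib$class))
  if (length(missing_cls)) {
    stop_config("harmonic library missing classes: %s",
                paste(missing_cls, collapse = ", "))
  }
  if (config$revisit_days <= 0) stop_config("revisit interval must be > 0")

  if (is.null(pixels)) {
    pixels <- tidyr::expand_grid(row = seq_len(truth$rows),
                                 col = seq_len(truth$cols))
  }
  ny <- length(truth$years)
  t_obs <- seq(config$revisit_days / 2, ny * DAYS_PER_YEAR,
               by = config$revisit_days)
  year_idx <- pmin(floor(t_obs / DAYS_PER_YEAR) + 1L, ny)

  # coefficient lookup: [class_id, band] -> row of 8 coefficients
  lib <- dplyr::arrange(lib, match(.data$class, cover_classes()), .data$band)
  coef_mat <- as.matrix(lib[, coef_names()])

  pixels <- dplyr::mutate(pixels,
                          pixel_id = (.data$row - 1L) * truth$cols + .data$col)
  np <- nrow(pixels); nt <- length(t_obs)

  # class id per (pixel, obs): rows are obs, cols pixels
  cls <- matrix(0L, nt, np)
  for (j in seq_len(np)) {
    cls[, j] <- truth$class_id[pixels$row[j], pixels$col[j], year_idx]
  }

  out <- tidyr::expand_grid(
    pixels[, c("pixel_id", "row", "col")],
    band = as.integer(bands)
  )
  out <- tidyr::expand_grid(out, tibble::tibble(t = t_obs,
                                                year = truth$years[year_idx]))
  # expand_grid order: pixel varies slowest, then band, then t
  cls_full <- as.vector(vapply(seq_len(np), function(j) {
    rep(cls[, j], times = length(bands))
  }, numeric(nt * length(bands))))
  band_full <- rep(rep(as.integer(bands), each = nt), times = np)
  lib_row <- (cls_full - 1L) * 6L + band_full
  mu <- eval_harmonic(coef_mat[lib_row, , drop = FALSE], out$t)

  withr::with_seed(substream_seed(config$seed, "reflectance"), {
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(length(mu), 0, config$noise_sd)
    } else 0
  })
  out$value <- mu + noise
  out
}
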