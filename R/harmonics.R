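#' Harmonic regression on reflectance time series
#'
#' Fits, by ordinary least squares, the eight-term harmonic model
#' `R_t = A0 + B0 t + sum_{k=1..3} [ A_k cos(2 pi k t / T) + B_k sin(2 pi k t / T) ]`
#' with period `T = 365.25` days, where `t` is days since the start of the
#' epoch. `A0` is the intercept, `B0` the inter-annual trend (per day), and
#' the `A_k`/`B_k` capture intra-annual (phenological) reflectance change.
#'
#' @param series Tibble with columns `t` (days, strictly increasing) and
#'   `value` (reflectance); extra columns are ignored.
#' @param interval Optional `c(t_start, t_end)`; observations with
#'   `t_start <= t < t_end` are used (all observations otherwise).
#' @param rmse_denom `"n"` (default) or `"n-p"`; normalization of the
#'   root-mean-squared residual.
#' @return A `harmonic_segment`: tibble row with `t_start`, `t_end`,
#'   the eight coefficients `A0`, `B0`, `A1`, `B1`, `A2`, `B2`, `A3`, `B3`,
#'   `rmse` and `n_obs`.
#' @export
#' @examples
#' tt <- seq(8, 2000, by = 16)
#' fit_harmonic(tibble::tibble(t = tt, value = 0.3))
fit_harmonic <- function(series, interval = NULL, rmse_denom = c("n", "n-p")) {
  rmse_denom <- match.arg(rmse_denom)
  t <- series$t; y <- series$value
  if (!is.null(interval)) {
    keep <- t >= interval[1] & t < interval[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 8 || length(unique(t)) < 8) {
    abort(sprintf("insufficient data for harmonic fit: %d observations (%d distinct times), need >= 8",
                  length(t), length(unique(t))),
          class = "birdhab_insufficient_data")
  }
  if (any(!is.finite(y))) stop_validation("non-finite reflectance values")
  X <- harmonic_design(t)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("rank-deficient harmonic design matrix (collinear observation times)",
          class = "birdhab_degenerate_fit")
  }
  beta <- qr.coef(qrX, y)
  resid <- y - as.vector(X %*% beta)
  denom <- if (rmse_denom == "n") length(y) else max(length(y) - ncol(X), 1)
  seg <- tibble::tibble(
    t_start = if (is.null(interval)) min(t) else interval[1],
    t_end = if (is.null(interval)) max(t) + 1e-9 else interval[2],
    !!!stats::setNames(as.list(beta), coef_names()),
    rmse = sqrt(sum(resid^2) / denom),
    n_obs = length(y)
  )
  class(seg) <- c("harmonic_segment", class(seg))
  seg
}

harmonic_design <- function(t) {
  w <- 2 * pi * t / DAYS_PER_YEAR
  cbind(1, t, cos(w), sin(w), cos(2 * w), sin(2 * w), cos(3 * w), sin(3 * w))
}

#' Predict reflectance from a fitted harmonic segment
#'
#' @param object A `harmonic_segment` (one row).
#' @param t Times (days since epoch).
#' @param ... Unused.
#' @return Numeric vector of fitted reflectance.
#' @export
predict.harmonic_segment <- function(object, t, ...) {
  b <- as.numeric(object[1, coef_names()])
  as.vector(harmonic_design(t) %*% b)
}

#' Detect abrupt spectral-trajectory breaks across bands
#'
#' Scans a multi-band pixel series for times where `window` consecutive
#' observations deviate from the running harmonic fit by more than
#' `threshold_multiplier` times the segment RMSE in a majority of bands; a
#' break is declared at the first observation of such a run and segments are
#' refit after each break. This is a compact variant of continuous
#' change-detection on harmonic residuals.
#'
#' @param series Tibble (`band`, `t`, `value`) for one pixel; all bands must
#'   share observation times.
#' @param window Consecutive exceedances required (default 3).
#' @param threshold_multiplier Residual threshold in RMSE units (default 3;
#'   `Inf` disables detection).
#' @param min_stable Observations used to initialise each segment's running
#'   fit (default 12; must be >= 8).
#' @param min_span Minimum time span (days) of each segment's running fit;
#'   default two years, so the annual harmonics are constrained before
#'   residuals are screened.
#' @return Numeric vector of break times (empty if none).
#' @export
detect_breaks <- function(series, window = 3, threshold_multiplier = 3,
                          min_stable = 12, min_span = 2 * DAYS_PER_YEAR) {
  w <- series_to_wide(series)
  detect_breaks_mat(w$tt, w$Y, window, threshold_multiplier, min_stable,
                    min_span)
}

# Common time axis + band matrix from a long (band, t, value) tibble.
series_to_wide <- function(series) {
  bands <- sort(unique(series$band))
  wide <- tidyr::pivot_wider(series, id_cols = "t", names_from = "band",
                             values_from = "value", names_prefix = "b")
  wide <- dplyr::arrange(wide, .data$t)
  Y <- as.matrix(wide[, paste0("b", bands), drop = FALSE])
  if (anyNA(Y)) {
    stop_validation("bands must share observation times within a pixel")
  }
  list(tt = wide$t, Y = Y, bands = bands)
}

#' Fit break-delimited harmonic segments for one pixel
#'
#' Runs [detect_breaks()] and then fits one harmonic segment per band within
#' each break-delimited interval. Segments with fewer than 8 observations
#' inherit the previous segment's coefficients and are flagged.
#'
#' @inheritParams detect_breaks
#' @param t_range Overall `c(t_start, t_end)` (defaults to the series span).
#' @return Tibble of `harmonic_segment` rows with added `band`, `segment`
#'   and `inherited` columns.
#' @export
fit_segments <- function(series, window = 3, threshold_multiplier = 3,
                         min_stable = 12, t_range = NULL,
                         min_span = 2 * DAYS_PER_YEAR) {
  w <- series_to_wide(series)
  segs <- fit_segments_mat(w$tt, w$Y, window, threshold_multiplier,
                           min_stable, t_range, min_span)
  ns <- length(segs$edges) - 1L
  purrr::map_dfr(seq_len(ns), function(s) {
    purrr::map_dfr(seq_along(w$bands), function(j) {
      row <- tibble::tibble(
        t_start = segs$edges[s], t_end = segs$edges[s + 1],
        !!!stats::setNames(as.list(segs$coefs[s, j, ]), coef_names()),
        rmse = segs$rmse[s, j], n_obs = segs$n_obs[s, j],
        inherited = segs$inherited[s, j],
        band = w$bands[j], segment = s
      )
      class(row) <- c("harmonic_segment", class(row))
      row
    })
  })
}

#' Assemble the 54-variable SDM feature vector for a query year
#'
#' Concatenates, for each of six bands, the eight harmonic coefficients of
#' the segment covering the query year (interleaved `A0, B0, A1, B1, A2, B2,
#' A3, B3`), followed by the six per-band segment RMSEs: 54 variables in all.
#'
#' @param segments A [fit_segments()] tibble covering 6 bands.
#' @param query_year Calendar year to evaluate.
#' @param year0 First year of the epoch (so `t` of mid-`query_year` can be
#'   located inside a segment).
#' @return A one-row tibble with columns `b<band>_<coef>` (48) then
#'   `rmse_b1..rmse_b6`, plus `year`.
#' @export
build_features <- function(segments, query_year, year0) {
  t_q <- year_mid_t(query_year, year0)
  bands <- 1:6
  vals <- purrr::map(bands, function(b) {
    seg <- dplyr::filter(segments, .data$band == b,
                         .data$t_start <= t_q, t_q < .data$t_end)
    if (nrow(seg) == 0) {
      abort(sprintf("no band-%d segment covers year %d", b, query_year),
            class = "birdhab_coverage_error")
    }
    seg <- seg[1, ]
    stats::setNames(
      as.numeric(seg[1, c(coef_names(), "rmse")]),
      c(paste0("b", b, "_", coef_names()), paste0("rmse_b", b))
    )
  })
  coefs <- unlist(purrr::map(vals, ~ .x[1:8]))
  rmses <- unlist(purrr::map(vals, ~ .x[9]))
  out <- tibble::as_tibble(as.list(c(coefs, rmses)))
  stopifnot(ncol(out) == 54)
  out$year <- query_year
  out
}

#' Per-pixel, per-year feature table from a reflectance series table
#'
#' Convenience wrapper: for each pixel in `series`, fits break-delimited
#' harmonic segments across bands and evaluates the 54-variable feature
#' vector at each requested year.
#'
#' @param series Tibble from [simulate_reflectance()] (columns `pixel_id`,
#'   `row`, `col`, `band`, `t`, `value`).
#' @param years Years at which to evaluate features.
#' @param year0 First epoch year.
#' @inheritParams detect_breaks
#' @return Tibble keyed by `pixel_id`, `row`, `col`, `year` with 54 feature
#'   columns.
#' @export
pixel_features <- function(series, years, year0, window = 3,
                           threshold_multiplier = 3, min_stable = 12) {
  # fast matrix path: requires a complete band x time grid per pixel (as the
  # reflectance simulator produces)
  ord <- order(series$pixel_id, series$band, series$t)
  pid <- series$pixel_id[ord]
  idx_by_pixel <- split(ord, pid)
  keys <- series[!duplicated(series$pixel_id),
                 c("pixel_id", "row", "col")]
  keys <- keys[match(names(idx_by_pixel), as.character(keys$pixel_id)), ]
  ny <- length(years)
  rows <- vector("list", length(idx_by_pixel))
  for (k in seq_along(idx_by_pixel)) {
    ii <- idx_by_pixel[[k]]
    b <- series$band[ii]
    nb <- length(unique(b))
    nt <- length(ii) / nb
    if (nt != round(nt)) {
      stop_validation("bands must share observation times within a pixel")
    }
    tt <- series$t[ii][seq_len(nt)]
    if (!identical(rep(tt, nb), series$t[ii])) {
      stop_validation("bands must share observation times within a pixel")
    }
    Y <- matrix(series$value[ii], nrow = nt, ncol = nb)
    segs <- fit_segments_mat(tt, Y, window, threshold_multiplier, min_stable)
    rows[[k]] <- features_from_segments(segs, years, year0)
  }
  feat <- do.call(rbind, rows)
  out <- tibble::tibble(
    pixel_id = rep(keys$pixel_id, each = ny),
    row = rep(keys$row, each = ny),
    col = rep(keys$col, each = ny),
    year = rep(years, times = nrow(keys))
  )
  dplyr::bind_cols(out, tibble::as_tibble(feat))
}
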