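#' Back-cast a fitted SDM across yearly feature tables
#'
#' Applies a fitted Maxent model to per-pixel, per-year feature tables
#' (clamping to the model's training feature range), returning one
#' suitability value per pixel-year. Deterministic given model and features.
#'
#' @param model A `maxent_model`.
#' @param features Tibble keyed by `row`, `col`, `year` (and optionally
#'   `pixel_id`) with the model's raw feature columns.
#' @param type Output transform (`"cloglog"` default).
#' @return `features`' key columns plus `suitability`.
#' @export
backcast <- function(model, features, type = "cloglog") {
  key_cols <- intersect(c("pixel_id", "row", "col", "year"), names(features))
  if (!all(c("row", "col", "year") %in% key_cols)) {
    abort("features must carry row, col and year columns",
          class = "birdhab_geometry_error")
  }
  feat_cols <- setdiff(names(features), key_cols)
  need <- model$scaling$names
  if (!is.null(need) && !all(need %in% feat_cols)) {
    abort(sprintf("feature table lacks model features: %s",
                  paste(setdiff(need, feat_cols), collapse = ", ")),
          class = "birdhab_geometry_error")
  }
  if (!is.null(need)) feat_cols <- need
  out <- dplyr::select(features, dplyr::all_of(key_cols))
  out$suitability <- predict(model, features[, feat_cols], type = type)
  out
}

#' Select the suitability cut point equalizing the two error rates
#'
#' Over the grid of observed scores, returns the cut minimizing
#' `|FNR - FPR|` (sensitivity = specificity criterion, the operational
#' reading of "minimize false positive and negative error"); ties break
#' toward higher sensitivity. `method = "youden"` instead maximizes
#' sensitivity + specificity.
#'
#' @param presence_scores,background_scores Suitability at validation
#'   presences / background points.
#' @param method `"sens_spec"` (default) or `"youden"`.
#' @return The selected cut point (scalar).
#' @export
select_threshold <- function(presence_scores, background_scores,
                             method = c("sens_spec", "youden")) {
  method <- match.arg(method)
  if (!length(presence_scores) || !length(background_scores)) {
    stop_validation("both validation score sets must be non-empty")
  }
  grid <- sort(unique(c(presence_scores, background_scores)))
  if (length(grid) < 2) {
    abort("degenerate scores: all values identical, no threshold exists",
          class = "birdhab_threshold_error")
  }
  fnr <- vapply(grid, function(c) mean(presence_scores < c), numeric(1))
  fpr <- vapply(grid, function(c) mean(background_scores >= c), numeric(1))
  sens <- 1 - fnr
  crit <- if (method == "sens_spec") -abs(fnr - fpr) else sens + (1 - fpr)
  best <- which(crit == max(crit))
  best <- best[which.max(sens[best])]
  grid[best]
}

#' Build an annual binary habitat series from suitability values
#'
#' @param suitability Tibble (`row`, `col`, `year`, `suitability`).
#' @param threshold Cut point; pixels with `suitability >= threshold` are
#'   habitat.
#' @param species Optional species label.
#' @return A `habitat_series`: list with `pixels` (adds logical `habitat`),
#'   `areas` (per-year `habitat_ha`; pixel = 0.09 ha), `threshold`,
#'   `species`, `years`.
#' @export
habitat_series <- function(suitability, threshold, species = NA_character_) {
  px <- dplyr::mutate(suitability, habitat = .data$suitability >= threshold)
  areas <- px |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(habitat_ha = sum(.data$habitat) * PIXEL_HA,
                     .groups = "drop") |>
    dplyr::arrange(.data$year)
  structure(list(pixels = px, areas = areas, threshold = threshold,
                 species = species, years = sort(unique(px$year))),
            class = "habitat_series")
}

#' @export
print.habitat_series <- function(x, ...) {
  cat(sprintf("<habitat_series> %s: years %d-%d, threshold %.4f\n",
              x$species, min(x$years), max(x$years), x$threshold))
  rng <- range(x$areas$habitat_ha)
  cat(sprintf("  habitat area %.1f-%.1f ha\n", rng[1], rng[2]))
  invisible(x)
}

#' Habitat change between two years: per-pixel transitions and net percent
#'
#' @param series A [habitat_series()].
#' @param y0,y1 Baseline and comparison years.
#' @return List: `change` (tibble `row`, `col`, `transition` in
#'   loss/gain/stable-habitat/stable-nonhabitat), `net_pct`
#'   (`100 * (area(y1) - area(y0)) / area(y0)`), `area_y0`, `area_y1` (ha).
#' @export
habitat_change <- function(series, y0, y1) {
  if (!all(c(y0, y1) %in% series$years)) {
    stop_validation("years %d/%d not in series", y0, y1)
  }
  a0 <- series$pixels |> dplyr::filter(.data$year == y0) |>
    dplyr::select("row", "col", h0 = "habitat")
  a1 <- series$pixels |> dplyr::filter(.data$year == y1) |>
    dplyr::select("row", "col", h1 = "habitat")
  ch <- dplyr::inner_join(a0, a1, by = c("row", "col")) |>
    dplyr::mutate(transition = dplyr::case_when(
      .data$h0 & !.data$h1 ~ "loss",
      !.data$h0 & .data$h1 ~ "gain",
      .data$h0 & .data$h1 ~ "stable_habitat",
      TRUE ~ "stable_nonhabitat"
    ))
  area0 <- sum(ch$h0) * PIXEL_HA
  area1 <- sum(ch$h1) * PIXEL_HA
  if (area0 == 0) {
    abort("baseline habitat area is zero; percent change undefined",
          class = "birdhab_undefined_percent")
  }
  list(change = dplyr::select(ch, "row", "col", "transition"),
       net_pct = 100 * (area1 - area0) / area0,
       area_y0 = area0, area_y1 = area1)
}

#' Habitat area within route buffers, per route and year
#'
#' Sums the areas of habitat pixels whose centres fall inside each route's
#' buffer polygon (pixel-centre-in-polygon rasterization; no partial-pixel
#' weighting).
#'
#' @param series A [habitat_series()].
#' @param buffers A [make_routes()] tibble.
#' @param extent `c(rows, cols)` of the raster grid.
#' @return Tibble (`route_id`, `year`, `habitat_ha`).
#' @export
route_habitat <- function(series, buffers, extent) {
  rows <- extent[1]; cols <- extent[2]
  width <- cols * PIXEL_M; height <- rows * PIXEL_M
  bad <- buffers$xmin < 0 | buffers$xmax > width |
    buffers$ymin < 0 | buffers$ymax > height
  if (any(bad)) {
    abort(sprintf("route buffer(s) outside raster extent: %s",
                  paste(buffers$route_id[bad], collapse = ", ")),
          class = "birdhab_geometry_error")
  }
  purrr::map_dfr(seq_len(nrow(buffers)), function(r) {
    px <- buffer_pixels(buffers[r, ], rows, cols)
    sub <- dplyr::semi_join(series$pixels, px, by = c("row", "col"))
    sub |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(habitat_ha = sum(.data$habitat) * PIXEL_HA,
                       .groups = "drop") |>
      dplyr::mutate(route_id = buffers$route_id[r], .before = 1)
  })
}

#' Attribute habitat-loss pixels to disturbance causes
#'
#' Each loss pixel is assigned to `clearcut` or `deforestation` if the truth
#' disturbance schedule records such an event at that pixel in `(y0, y1]`
#' (deforestation takes precedence), and to `other` otherwise.
#'
#' @param change The `change` tibble from [habitat_change()].
#' @param truth A [generate_landscape()] result (aligned grid).
#' @param y0,y1 Change interval.
#' @return Tibble (`cause`, `n_pixels`, `fraction`); fractions sum to 1
#'   (all-zero when there are no loss pixels).
#' @export
attribute_loss <- function(change, truth, y0, y1) {
  loss <- dplyr::filter(change, .data$transition == "loss")
  causes <- c("clearcut", "deforestation", "other")
  if (nrow(loss) == 0) {
    return(tibble::tibble(cause = causes, n_pixels = 0L, fraction = 0))
  }
  ev <- dplyr::filter(truth$events, .data$year > y0, .data$year <= y1)
  key <- function(d) paste(d$row, d$col)
  cut_px <- key(dplyr::filter(ev, .data$type == "clearcut"))
  def_px <- key(dplyr::filter(ev, .data$type == "deforestation"))
  k <- key(loss)
  cause <- ifelse(k %in% def_px, "deforestation",
                  ifelse(k %in% cut_px, "clearcut", "other"))
  tibble::tibble(cause = causes) |>
    dplyr::left_join(
      tibble::tibble(cause = cause) |> dplyr::count(.data$cause, name = "n_pixels"),
      by = "cause") |>
    dplyr::mutate(n_pixels = dplyr::coalesce(.data$n_pixels, 0L),
                  fraction = .data$n_pixels / nrow(loss))
}

#' Regression of habitat loss on clear-cut area across routes
#'
#' Ordinary least squares of per-route habitat loss (ha) on per-route
#' clear-cut area within the species' habitat (ha), with normal-theory 95%
#' confidence intervals.
#'
#' @param data Tibble with columns `clearcut_ha` and `habitat_loss_ha`
#'   (one row per route).
#' @return A `clearcut_regression` list: `fit` (the `lm`), `coef` tibble
#'   (`term`, `estimate`, `conf.low`, `conf.high`).
#' @export
clearcut_regression <- function(data) {
  if (nrow(data) < 3) stop_validation("need >= 3 routes")
  if (stats::sd(data$clearcut_ha) == 0) {
    abort("zero variance in clear-cut area; regression undefined",
          class = "birdhab_regression_error")
  }
  fit <- stats::lm(habitat_loss_ha ~ clearcut_ha, data = data)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  coef_tbl <- tibble::tibble(
    term = names(stats::coef(fit)),
    estimate = as.numeric(stats::coef(fit)),
    conf.low = ci[, 1], conf.high = ci[, 2]
  )
  structure(list(fit = fit, coef = coef_tbl),
            class = "clearcut_regression")
}

#' @export
print.clearcut_regression <- function(x, ...) {
  cat("<clearcut_regression>\n")
  print(x$coef)
  invisible(x)
}
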