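#' Generate straight survey-route transects with rectangular buffers
#'
#' Routes are axis-aligned horizontal transects with uniform random vertical
#' placement and horizontal offset, buffered 100 m each side (200 m diameter),
#' mirroring roadside survey-route landscapes. A nominal 40 km route is
#' clipped to the grid width if the grid is smaller.
#'
#' @param truth A [generate_landscape()] result (or any list with `rows`,
#'   `cols`).
#' @param n_routes Number of routes.
#' @param length_m Route length in metres (default 40 km, clipped to grid).
#' @param half_width Buffer half width in metres (default 100).
#' @param seed Integer seed (default: routes substream of the master seed).
#' @return Tibble (`route_id`, `x0`, `x1`, `y`, `xmin`, `xmax`, `ymin`,
#'   `ymax`, `length_m`, `buffer_area_ha`).
#' @export
make_routes <- function(truth, n_routes = truth$config$bbs$n_routes,
                        length_m = 40000, half_width = 100, seed = NULL) {
  if (n_routes < 2) stop_config("need at least 2 routes")
  width <- truth$cols * PIXEL_M
  height <- truth$rows * PIXEL_M
  len <- min(length_m, width)
  if (height < 2 * half_width) {
    stop_config("grid too short for a %g m buffer half-width", half_width)
  }
  seed <- seed %||% substream_seed(truth$config$seed, "routes")
  withr::with_seed(seed, {
    y <- stats::runif(n_routes, half_width, height - half_width)
    x0 <- stats::runif(n_routes, 0, width - len)
  })
  tibble::tibble(
    route_id = sprintf("R%03d", seq_len(n_routes)),
    x0 = x0, x1 = x0 + len, y = y,
    xmin = x0, xmax = x0 + len, ymin = y - half_width, ymax = y + half_width,
    length_m = len,
    buffer_area_ha = len * 2 * half_width / 1e4
  )
}

# Pixel centres falling inside one rectangular buffer.
buffer_pixels <- function(route, rows, cols) {
  cx <- (seq_len(cols) - 0.5) * PIXEL_M
  cy <- (seq_len(rows) - 0.5) * PIXEL_M
  in_col <- which(cx >= route$xmin & cx <= route$xmax)
  in_row <- which(cy >= route$ymin & cy <= route$ymax)
  tidyr::expand_grid(row = in_row, col = in_col)
}

#' True expected suitable area per route-year
#'
#' Sums the species occupancy probability over pixels whose centres fall in
#' each route buffer, scaled by pixel area (0.09 ha): the ground-truth
#' habitat covariate used when simulating route counts.
#'
#' @param truth A [generate_landscape()] result.
#' @param profile One species-profile row.
#' @param routes A [make_routes()] tibble.
#' @return Tibble (`route_id`, `year`, `habitat_ha`).
#' @export
route_truth_habitat <- function(truth, profile, routes) {
  ny <- length(truth$years)
  purrr::map_dfr(seq_len(nrow(routes)), function(r) {
    px <- buffer_pixels(routes[r, ], truth$rows, truth$cols)
    if (nrow(px) == 0) {
      return(tibble::tibble(route_id = routes$route_id[r],
                            year = truth$years, habitat_ha = 0))
    }
    hab <- vapply(seq_len(ny), function(i) {
      idx <- cbind(px$row, px$col, i)
      sum(occupancy_prob(profile, truth$age[idx], truth$class_id[idx])) *
        PIXEL_HA
    }, numeric(1))
    tibble::tibble(route_id = routes$route_id[r], year = truth$years,
                   habitat_ha = hab)
  })
}
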