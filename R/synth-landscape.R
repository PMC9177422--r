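#' Generate a synthetic forest landscape with disturbance ground truth
#'
#' Simulates per-pixel, per-year forest age and cover class on a 30 m grid.
#' Each year, forest pixels are independently clear-cut (age resets to zero;
#' the pixel becomes a plantation with the configured probability, otherwise
#' it regenerates naturally) or permanently deforested. Naturally regenerated
#' forest is classed as shade-tolerant old forest once its age reaches
#' `old_age`. The full disturbance schedule is returned as ground truth for
#' recovery tests.
#'
#' @param config A [sim_config()].
#' @return An object of class `landscape_truth`: a list with
#'   * `age`: integer array `[rows, cols, years]` of stand age;
#'   * `class_id`: integer array of cover-class codes (see `$classes`);
#'   * `classes`: code-to-name lookup;
#'   * `events`: tibble of disturbances (`row`, `col`, `year`, `type`);
#'   * `years`, `rows`, `cols`, `config`.
#' @export
#' @examples
#' truth <- generate_landscape(sim_config(seed = 1, rows = 15, cols = 15,
#'                                        years = 2000:2004))
#' dplyr::count(truth$events, type)
generate_landscape <- function(config) {
  validate_sim_config(config)
  if (config$rows < 10 || config$cols < 10) {
    stop_config("grid must be at least 10 x 10 (got %d x %d)",
                config$rows, config$cols)
  }
  rows <- config$rows; cols <- config$cols
  years <- config$years; ny <- length(years)
  n <- rows * cols

  withr::with_seed(substream_seed(config$seed, "landscape"), {
    age0 <- sample.int(config$init_age_max + 1L, n, replace = TRUE) - 1L
    age <- array(0L, dim = c(rows, cols, ny))
    plantation <- rep(FALSE, n)   # last cut replanted?
    deforested <- rep(FALSE, n)
    cur_age <- age0
    class_id <- array(0L, dim = c(rows, cols, ny))
    events <- vector("list", ny)

    for (i in seq_len(ny)) {
      if (i > 1L) {
        cur_age <- cur_age + 1L
        forest <- !deforested
        u_cc <- stats::runif(n)
        u_df <- stats::runif(n)
        cut <- forest & (u_cc < config$p_clearcut)
        defo <- forest & !cut & (u_df < config$p_deforest)
        if (any(cut)) {
          cur_age[cut] <- 0L
          plantation[cut] <- stats::runif(sum(cut)) < config$plantation_fraction
        }
        if (any(defo)) {
          deforested[defo] <- TRUE
          cur_age[defo] <- 0L
        }
        ev <- NULL
        if (any(cut) || any(defo)) {
          idx <- c(which(cut), which(defo))
          ev <- tibble::tibble(
            row = ((idx - 1L) %% rows) + 1L,
            col = ((idx - 1L) %/% rows) + 1L,
            year = years[i],
            type = rep(c("clearcut", "deforestation"), c(sum(cut), sum(defo)))
          )
        }
        events[[i]] <- ev
      }
      age[, , i] <- cur_age
      class_id[, , i] <- classify_pixels(cur_age, plantation, deforested,
                                         config$old_age)
    }
  })

  structure(
    list(
      age = age, class_id = class_id,
      classes = stats::setNames(seq_along(cover_classes()), cover_classes()),
      events = dplyr::bind_rows(events) %||% tibble::tibble(),
      years = years, rows = rows, cols = cols, config = config
    ),
    class = "landscape_truth"
  )
}

# Cover class is a deterministic function of (age, disturbance history).
classify_pixels <- function(age, plantation, deforested, old_age) {
  cls <- ifelse(deforested, 4L,
         ifelse(plantation, 3L,
         ifelse(age >= old_age, 1L, 2L)))
  as.integer(cls)
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat(sprintf("<landscape_truth> %d x %d pixels (30 m), years %d-%d\n",
              x$rows, x$cols, min(x$years), max(x$years)))
  cat(sprintf("  disturbance events: %d clearcut, %d deforestation\n",
              sum(x$events$type == "clearcut"),
              sum(x$events$type == "deforestation")))
  invisible(x)
}

#' Per-year cover-class and cumulative clear-cut summary of a landscape
#'
#' @param truth A `landscape_truth`.
#' @return Tibble with one row per year: pixel counts per cover class,
#'   `cum_clearcut` (pixels cut at least once so far) and
#'   `cum_clearcut_frac`.
#' @export
landscape_summary <- function(truth) {
  ny <- length(truth$years)
  n <- truth$rows * truth$cols
  cut_events <- dplyr::filter(truth$events, .data$type == "clearcut")
  ever_cut <- matrix(FALSE, truth$rows, truth$cols)
  purrr::map_dfr(seq_len(ny), function(i) {
    yr <- truth$years[i]
    ev <- dplyr::filter(cut_events, .data$year == yr)
    if (nrow(ev)) ever_cut[cbind(ev$row, ev$col)] <<- TRUE
    cls <- truth$class_id[, , i]
    tibble::tibble(
      year = yr,
      tolerant_old = sum(cls == 1L), regenerating = sum(cls == 2L),
      plantation = sum(cls == 3L), non_forest = sum(cls == 4L),
      cum_clearcut = sum(ever_cut),
      cum_clearcut_frac = sum(ever_cut) / n
    )
  })
}
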