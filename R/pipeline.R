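#' Run the full synthetic-landscape analysis pipeline
#'
#' Orchestrates every stage end to end on simulated inputs: landscape and
#' disturbance generation, reflectance simulation, harmonic feature
#' extraction with break detection, presence-only SDM fitting with
#' spatial-block validation and beta tuning, annual habitat back-casting and
#' thresholding, route-buffer habitat accounting, clear-cut association
#' regression, route-count simulation, hierarchical trend/habitat models,
#' and pairs-lost impact summaries. Identical seeds reproduce identical
#' outputs at every stage.
#'
#' @param config A [sim_config()].
#' @param profiles Species-profile tibble (default [example_profiles()]).
#' @param seed Optional master seed overriding `config$seed`.
#' @param sdm_years Years of occurrence data used to fit SDMs (default: the
#'   2006-2010 window when simulated, else the middle five years).
#' @param n_points Survey points per species (default 1500).
#' @param n_background Background sample size (default: a quarter of the
#'   grid, capped at 10,000).
#' @param beta_grid Regularization multipliers to tune over (default
#'   `c(0.5, 1, 2)` for pipeline runs; see [tune_beta()] for the full
#'   convention grid).
#' @param block_edge Spatial-block edge in metres (default: a quarter of the
#'   grid width, so small synthetic grids still yield several blocks).
#' @param threshold_method Passed to [select_threshold()].
#' @param mcmc Named list overriding the reduced trend-model MCMC profile.
#' @param run_trends Fit the hierarchical count models (default TRUE).
#' @return A `pipeline_run` list: `truth`, `routes`, per-species results
#'   (`sdm`, `auc_test`, `threshold`, `series` areas, `net_change`,
#'   `route_habitat`, `clearcut`, `counts`, `trend_fit`, summaries),
#'   `impact`, and a `manifest` recording seeds, hashes, thresholds and
#'   selected betas.
#' @export
run_pipeline <- function(config = sim_config(),
                         profiles = example_profiles(),
                         seed = NULL,
                         sdm_years = NULL,
                         n_points = 1500,
                         n_background = NULL,
                         beta_grid = c(0.5, 1, 2),
                         block_edge = NULL,
                         threshold_method = "sens_spec",
                         mcmc = list(),
                         run_trends = TRUE) {
  t_start <- Sys.time()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_sim_config(config)
  mcmc <- utils::modifyList(
    list(chains = 3, draws = 1000, warmup = 500, adapt = 300), mcmc)

  truth <- generate_landscape(config)
  routes <- make_routes(truth)
  years <- truth$years
  sdm_years <- sdm_years %||% {
    if (all(2006:2010 %in% years)) 2006:2010 else {
      years[pmax(1, floor(length(years) / 2) - 2) + 0:4]
    }
  }

  series <- simulate_reflectance(truth, config)
  features <- pixel_features(series, years, year0 = years[1])
  feat_cols <- setdiff(names(features), c("pixel_id", "row", "col", "year"))

  all_pixels <- tidyr::expand_grid(row = seq_len(truth$rows),
                                   col = seq_len(truth$cols))
  n_background <- n_background %||% min(10000, nrow(all_pixels) %/% 4)
  bg <- sample_background(all_pixels, n_background,
                          seed = substream_seed(config$seed, "background"))
  withr::with_seed(substream_seed(config$seed, "background") + 1L, {
    bg$year <- sample(sdm_years, nrow(bg), replace = TRUE)
  })
  bg <- dplyr::mutate(bg, x = (.data$col - 0.5) * PIXEL_M,
                      y = (.data$row - 0.5) * PIXEL_M)
  bg_feat <- dplyr::inner_join(bg, features, by = c("row", "col", "year"))

  occ <- simulate_occurrences(truth, profiles, n_points, years = sdm_years)
  block_edge <- block_edge %||% (truth$cols * PIXEL_M / 4)

  species_results <- list()
  net_changes <- list()
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    sp <- prof$species
    pres <- dplyr::filter(occ, .data$species == sp, .data$present == 1L)
    pres_feat <- dplyr::inner_join(pres, features,
                                   by = c("row", "col", "year"))
    if (nrow(pres_feat) < 10) {
      abort(sprintf("species %s: only %d presences; cannot fit SDM",
                    sp, nrow(pres_feat)), class = "birdhab_validation_error")
    }
    # shared spatial blocks for presences and background
    pts <- dplyr::bind_rows(
      dplyr::mutate(pres_feat[, c("x", "y")], role = "pres"),
      dplyr::mutate(bg_feat[, c("x", "y")], role = "bg")
    )
    split <- spatial_block_split(pts, block_edge, train_fraction = 0.8,
                                 seed = substream_seed(config$seed, "split"))
    pres_fold <- split$fold[split$role == "pres"]
    bg_fold <- split$fold[split$role == "bg"]
    tr_pres <- pres_feat[pres_fold == "train", feat_cols]
    te_pres <- pres_feat[pres_fold == "test", feat_cols]
    tr_bg <- bg_feat[bg_fold == "train", feat_cols]
    te_bg <- bg_feat[bg_fold == "test", feat_cols]

    tuned <- tune_beta(tr_pres, tr_bg, grid = beta_grid,
                       tol = 1e-6, max_iter = 5000)
    model <- tuned$model
    auc_test <- if (nrow(te_pres) && nrow(te_bg)) {
      auc(predict(model, te_pres), predict(model, te_bg))
    } else NA_real_
    thr_pres <- if (nrow(te_pres)) te_pres else tr_pres
    thr_bg <- if (nrow(te_bg)) te_bg else tr_bg
    threshold <- select_threshold(predict(model, thr_pres),
                                  predict(model, thr_bg),
                                  method = threshold_method)

    suit <- features |>
      dplyr::group_split(.data$year) |>
      purrr::map_dfr(~ backcast(model, .x))
    serie <- habitat_series(suit, threshold, species = sp)
    y0 <- min(years); y1 <- max(years)
    change <- habitat_change(serie, y0, y1)
    attribution <- attribute_loss(change$change, truth, y0, y1)
    rh <- route_habitat(serie, routes, c(truth$rows, truth$cols))

    # per-route clear-cut area inside the species' baseline habitat
    hab0 <- dplyr::filter(serie$pixels, .data$year == y0, .data$habitat)
    cuts <- dplyr::filter(truth$events, .data$type == "clearcut") |>
      dplyr::semi_join(hab0, by = c("row", "col")) |>
      dplyr::distinct(.data$row, .data$col)
    cc_route <- purrr::map_dfr(seq_len(nrow(routes)), function(r) {
      px <- buffer_pixels(routes[r, ], truth$rows, truth$cols)
      tibble::tibble(
        route_id = routes$route_id[r],
        clearcut_ha = nrow(dplyr::semi_join(cuts, px,
                                            by = c("row", "col"))) * PIXEL_HA)
    })
    loss_route <- rh |>
      dplyr::filter(.data$year %in% c(y0, y1)) |>
      tidyr::pivot_wider(names_from = "year", values_from = "habitat_ha",
                         names_prefix = "y") |>
      dplyr::mutate(habitat_loss_ha = .data[[paste0("y", y0)]] -
                      .data[[paste0("y", y1)]])
    cc_df <- dplyr::inner_join(cc_route, loss_route, by = "route_id")
    cc_reg <- tryCatch(clearcut_regression(cc_df), error = function(e) NULL)

    counts <- simulate_bbs_counts(truth, prof, config, routes = routes)
    trend <- habitat_fit <- NULL
    if (run_trends) {
      recs <- counts |>
        dplyr::select(-"habitat_ha") |>
        dplyr::inner_join(rh, by = c("route_id", "year"))
      habitat_fit <- fit_trend_model(
        recs, trend = TRUE, habitat = TRUE,
        chains = mcmc$chains, draws = mcmc$draws, warmup = mcmc$warmup,
        adapt = mcmc$adapt, seed = substream_seed(config$seed, "mcmc") + i)
      trend <- list(
        classification = classify_decline(habitat_fit),
        fold_change = habitat_fold_change(habitat_fit)
      )
    }

    net_changes[[sp]] <- tibble::tibble(
      species = sp, net_change_ha = change$area_y1 - change$area_y0,
      net_pct = change$net_pct)
    species_results[[sp]] <- list(
      profile = prof, model = model, beta = tuned$beta,
      beta_results = tuned$results, auc_test = auc_test,
      threshold = threshold, areas = serie$areas, series = serie,
      net_change = net_changes[[sp]], attribution = attribution,
      route_habitat = rh, clearcut = list(data = cc_df, regression = cc_reg),
      counts = counts, habitat_fit = habitat_fit, trend = trend
    )
  }

  net_tbl <- dplyr::bind_rows(net_changes)
  territories <- profiles[, c("species", "territory_min_ha",
                              "territory_max_ha")]
  impact <- pairs_lost(net_tbl, territories)
  assoc <- NULL
  if (nrow(profiles) >= 5) {
    assoc <- association_regression(
      dplyr::inner_join(
        net_tbl,
        profiles[, c("species", "mature_association", "successional_class")],
        by = "species") |>
        dplyr::rename(habitat_change_pct = "net_pct"))
  }

  manifest <- tibble::tibble(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    species = names(species_results),
    beta = unname(purrr::map_dbl(species_results, "beta")),
    threshold = unname(purrr::map_dbl(species_results, "threshold")),
    auc_test = unname(purrr::map_dbl(species_results, "auc_test")),
    net_pct = net_tbl$net_pct,
    started = t_start, finished = Sys.time()
  )
  structure(list(truth = truth, routes = routes, species = species_results,
                 impact = impact, association = assoc, manifest = manifest,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> seed %d, %d species, grid %d x %d\n",
              x$config$seed, length(x$species), x$truth$rows, x$truth$cols))
  print(dplyr::select(x$manifest, "species", "beta", "threshold",
                      "auc_test", "net_pct"))
  invisible(x)
}

#' Markdown report for a pipeline run
#'
#' @param run A `pipeline_run`.
#' @return Character vector of markdown lines (invisibly writes nothing).
#' @export
report_run <- function(run) {
  m <- run$manifest
  lines <- c(
    "# Synthetic pipeline run",
    sprintf("- seed: %d; config hash: %s", run$config$seed, m$config_hash[1]),
    sprintf("- grid: %d x %d pixels; years %d-%d", run$truth$rows,
            run$truth$cols, min(run$truth$years), max(run$truth$years)),
    "", "## Species results", "",
    "| species | beta | threshold | test AUC | net habitat change (%) |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.2f | %.4f | %.3f | %.1f |",
            m$species, m$beta, m$threshold, m$auc_test, m$net_pct),
    "", "## Impact",
    sprintf("- total net loss: %.1f ha (%.2f km^2)",
            run$impact$total$total_loss_ha, run$impact$total$total_loss_km2),
    sprintf("- breeding pairs lost: %.0f-%.0f (%.0f-%.0f individuals)",
            run$impact$total$pairs_min, run$impact$total$pairs_max,
            run$impact$total$individuals_min, run$impact$total$individuals_max)
  )
  for (sp in names(run$species)) {
    tr <- run$species[[sp]]$trend
    if (!is.null(tr)) {
      lines <- c(lines, sprintf(
        "- %s: trend %s; habitat fold change (median) %.2f",
        sp, tr$classification, tr$fold_change$median))
    }
  }
  lines
}

#' Validate analysis input tables before running
#'
#' Schema and geometry checks for the pipeline's tabular inputs: required
#' columns, non-negative integer counts, finite coordinates, routes inside
#' the raster extent and year coverage. Fatal problems abort (listing the
#' offending rows) unless `action = "report"`.
#'
#' @param counts Optional route-count tibble.
#' @param presences Optional presence-point tibble (`x`, `y`, `year`).
#' @param routes Optional [make_routes()] tibble.
#' @param extent Optional `c(rows, cols)` grid extent for geometry checks.
#' @param action `"error"` (default) aborts on fatal issues; `"report"`
#'   returns the issue table.
#' @return Tibble (`severity`, `message`) of all issues (empty when clean).
#' @export
validate_inputs <- function(counts = NULL, presences = NULL, routes = NULL,
                            extent = NULL, action = c("error", "report")) {
  action <- match.arg(action)
  issues <- list()
  add <- function(severity, msg) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(severity = severity,
                                                     message = msg)
  }
  if (!is.null(counts)) {
    need <- c("route_id", "year", "observer_id", "first_year", "count")
    miss <- setdiff(need, names(counts))
    if (length(miss)) {
      add("fatal", sprintf("count table missing columns: %s",
                           paste(miss, collapse = ", ")))
    } else {
      bad <- which(!is.finite(counts$count) | counts$count < 0 |
                     counts$count != round(counts$count))
      if (length(bad)) {
        add("fatal", sprintf("non-integer or negative counts at rows: %s",
                             paste(utils::head(bad, 10), collapse = ", ")))
      }
      if (length(unique(counts$year)) < 2) {
        add("warning", "fewer than 2 survey years")
      }
    }
  }
  if (!is.null(presences)) {
    miss <- setdiff(c("x", "y", "year"), names(presences))
    if (length(miss)) {
      add("fatal", sprintf("presence table missing columns: %s",
                           paste(miss, collapse = ", ")))
    } else if (any(!is.finite(presences$x) | !is.finite(presences$y))) {
      add("fatal", "non-finite presence coordinates")
    }
  }
  if (!is.null(routes) && !is.null(extent)) {
    width <- extent[2] * PIXEL_M; height <- extent[1] * PIXEL_M
    bad <- which(routes$xmin < 0 | routes$xmax > width |
                   routes$ymin < 0 | routes$ymax > height)
    if (length(bad)) {
      add("fatal", sprintf("routes outside raster extent: %s",
                           paste(routes$route_id[bad], collapse = ", ")))
    }
  }
  report <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(severity = character(0), message = character(0))
  }
  fatal <- report$message[report$severity == "fatal"]
  if (action == "error" && length(fatal)) {
    stop_validation("input validation failed:\n%s",
                    paste("-", fatal, collapse = "\n"))
  }
  report
}
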