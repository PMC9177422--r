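make_suit_tbl <- function(rows, cols, years, value_fn) {
  tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols),
                     year = years) |>
    dplyr::mutate(suitability = value_fn(row, col, year))
}

test_that("back-casting is deterministic and matches pointwise prediction", {
  withr::with_seed(1, {
    P <- random_features(30, p = 6, seed = 1)
    B <- random_features(50, p = 6, seed = 2)
  })
  m <- maxent_fit(P, B, beta = 0.5)
  feats <- dplyr::bind_cols(
    tidyr::expand_grid(row = 1:5, col = 1:4, year = c(2000, 2001)),
    random_features(40, p = 6, seed = 3))
  bc <- backcast(m, feats)
  expect_identical(nrow(bc), 40L)
  # identical features in two years -> identical suitability
  f2 <- feats; f2$year <- f2$year + 10
  expect_equal(backcast(m, f2)$suitability, bc$suitability)
  # pointwise oracle: direct predict on one row
  i <- 17L
  direct <- predict(m, feats[i, paste0("f", 1:6)])
  expect_equal(bc$suitability[i], direct, tolerance = 1e-12)
  # uniform model -> constant raster
  mu <- maxent_fit(P, B, beta = 1e6)
  expect_equal(diff(range(backcast(mu, feats)$suitability)), 0,
               tolerance = 1e-10)
})

test_that("threshold selection equalizes error rates and matches the oracle", {
  # perfectly separated scores: zero error at the returned cut
  thr <- select_threshold(c(0.8, 0.9, 0.95), c(0.1, 0.2, 0.3))
  expect_equal(mean(c(0.8, 0.9, 0.95) < thr), 0)   # FNR
  expect_equal(mean(c(0.1, 0.2, 0.3) >= thr), 0)   # FPR
  # symmetric overlapping Gaussians: cut near the midpoint of the means
  withr::with_seed(31, {
    pres <- rnorm(4000, 0.7, 0.1); bg <- rnorm(4000, 0.3, 0.1)
  })
  thr2 <- select_threshold(pres, bg)
  expect_lt(abs(thr2 - 0.5), 0.02)
  expect_identical(thr2, threshold_oracle(pres, bg))
  expect_error(select_threshold(rep(0.5, 5), rep(0.5, 3)),
               class = "birdhab_threshold_error")
})

test_that("threshold selection equals exhaustive search on random score sets", {
  withr::with_seed(37, {
    for (r in 1:25) {
      pres <- runif(sample(5:40, 1))
      bg <- runif(sample(5:40, 1))
      expect_identical(select_threshold(pres, bg), threshold_oracle(pres, bg))
    }
  })
})

test_that("habitat change accounting is exact and complete", {
  suit <- make_suit_tbl(10, 10, c(2000, 2010), function(r, c, y) {
    # habitat = upper half in 2000; in 2010 only the upper quarter remains
    ifelse(y == 2000, ifelse(r <= 5, 1, 0),
           ifelse(r <= 2.5, 1, 0))
  })
  hs <- habitat_series(suit, threshold = 0.5, species = "toy")
  ch <- habitat_change(hs, 2000, 2010)
  expect_equal(ch$net_pct, -60)   # 50 -> 20 pixels
  tab <- table(ch$change$transition)
  expect_identical(sum(tab), 100L)                 # every pixel classified once
  expect_identical(unname(tab["loss"]), 30L)
  # identical years -> all stable, 0%
  ch0 <- habitat_change(hs, 2000, 2000)
  expect_equal(ch0$net_pct, 0)
  expect_true(all(grepl("stable", ch0$change$transition)))
  # half of habitat pixels flipped off, none gained -> -50% by direct count
  suit2 <- make_suit_tbl(10, 10, c(2000, 2001), function(r, c, y) {
    ifelse(y == 2000, ifelse(r <= 4, 1, 0), ifelse(r <= 2, 1, 0))
  })
  hs2 <- habitat_series(suit2, 0.5)
  expect_equal(habitat_change(hs2, 2000, 2001)$net_pct, -50)
  # zero baseline -> undefined percent
  suit3 <- make_suit_tbl(10, 10, c(2000, 2001), function(r, c, y) {
    ifelse(y == 2001 & r == 1, 1, 0)
  })
  expect_error(habitat_change(habitat_series(suit3, 0.5), 2000, 2001),
               class = "birdhab_undefined_percent")
})

test_that("raising the threshold never increases habitat area", {
  suit <- make_suit_tbl(15, 15, 2000:2003,
                        function(r, c, y) (r * c + y %% 7) %% 100 / 100)
  areas <- purrr::map(c(0.2, 0.5, 0.8),
                      ~ habitat_series(suit, .x)$areas$habitat_ha)
  expect_true(all(areas[[1]] >= areas[[2]]))
  expect_true(all(areas[[2]] >= areas[[3]]))
})

test_that("a 40 km route over full habitat returns about 800 ha", {
  rows <- 12; cols <- 1340
  truth_stub <- list(rows = rows, cols = cols,
                     config = list(bbs = list(n_routes = 2), seed = 1))
  routes <- make_routes(truth_stub, n_routes = 2, seed = 5)
  expect_equal(routes$length_m[1], 40000)
  expect_equal(routes$buffer_area_ha[1], 800)
  suit <- make_suit_tbl(rows, cols, 2000, function(r, c, y) 1)
  hs <- habitat_series(suit, 0.5)
  rh <- route_habitat(hs, routes, c(rows, cols))
  # within one pixel-row of the nominal 800 ha (a row is ~1334 pixels)
  row_ha <- 0.09 * (40000 / 30)
  expect_true(all(abs(rh$habitat_ha - 800) <= row_ha))
  expect_true(all(rh$habitat_ha <= routes$buffer_area_ha + row_ha))
  # no-habitat raster -> 0 ha
  hs0 <- habitat_series(dplyr::mutate(suit, suitability = 0), 0.5)
  expect_true(all(route_habitat(hs0, routes, c(rows, cols))$habitat_ha == 0))
})

test_that("route habitat equals brute-force point-in-polygon accumulation", {
  rows <- 20; cols <- 60
  suit <- make_suit_tbl(rows, cols, 2000,
                        function(r, c, y) ((r * 7 + c * 13) %% 10) / 10)
  hs <- habitat_series(suit, 0.5)
  routes <- tibble::tibble(route_id = "R001", x0 = 100, x1 = 1500, y = 300,
                           xmin = 100, xmax = 1500, ymin = 200, ymax = 400,
                           length_m = 1400, buffer_area_ha = 28)
  rh <- route_habitat(hs, routes, c(rows, cols))
  oracle <- route_habitat_oracle(dplyr::filter(hs$pixels, year == 2000),
                                 routes[1, ], rows, cols)
  expect_equal(rh$habitat_ha, oracle)
  # a route outside the extent is a geometry error
  bad <- dplyr::mutate(routes, xmax = 1e6)
  expect_error(route_habitat(hs, bad, c(rows, cols)),
               class = "birdhab_geometry_error")
})

test_that("loss attribution matches direct cross-tabulation", {
  cfg <- tiny_config(seed = 41, p_clearcut = 0.15, p_deforest = 0.01)
  truth <- generate_landscape(cfg)
  y0 <- min(truth$years); y1 <- max(truth$years)
  # habitat lost exactly where age dropped below a cutoff
  suit <- make_suit_tbl(truth$rows, truth$cols, c(y0, y1), function(r, c, y) {
    i <- match(y, truth$years)
    as.numeric(truth$age[cbind(r, c, i)] >= 3)
  })
  hs <- habitat_series(suit, 0.5)
  ch <- habitat_change(hs, y0, y1)
  attr_tbl <- attribute_loss(ch$change, truth, y0, y1)
  expect_equal(sum(attr_tbl$fraction), 1)
  # contingency oracle
  loss <- dplyr::filter(ch$change, transition == "loss")
  ev <- dplyr::filter(truth$events, year > y0, year <= y1)
  k <- paste(loss$row, loss$col)
  kc <- paste(ev$row[ev$type == "clearcut"], ev$col[ev$type == "clearcut"])
  kd <- paste(ev$row[ev$type == "deforestation"],
              ev$col[ev$type == "deforestation"])
  n_def <- sum(k %in% kd)
  n_cut <- sum(k %in% kc & !(k %in% kd))
  expect_identical(attr_tbl$n_pixels[attr_tbl$cause == "clearcut"], n_cut)
  expect_identical(attr_tbl$n_pixels[attr_tbl$cause == "deforestation"], n_def)
  # all-clearcut and no-disturbance limiting cases
  ch_cut <- ch$change[paste(ch$change$row, ch$change$col) %in% kc &
                        ch$change$transition == "loss", ]
  if (nrow(ch_cut) > 0) {
    a2 <- attribute_loss(ch_cut, truth, y0, y1)
    expect_equal(a2$fraction[a2$cause %in% c("clearcut", "deforestation")] |>
                   sum(), 1)
  }
  no_events <- truth; no_events$events <- truth$events[0, ]
  a3 <- attribute_loss(ch$change, no_events, y0, y1)
  expect_equal(a3$fraction[a3$cause == "other"], 1)
})

test_that("clear-cut regression recovers exact and noisy slopes", {
  d <- tibble::tibble(clearcut_ha = c(1, 2, 3, 4),
                      habitat_loss_ha = c(2, 4, 6, 8))
  r <- clearcut_regression(d)
  sl <- dplyr::filter(tidy(r), term == "clearcut_ha")
  expect_equal(sl$estimate, 2, tolerance = 1e-12)
  expect_lt(sl$conf.high - sl$conf.low, 1e-8)
  expect_error(clearcut_regression(d[1:2, ]),
               class = "birdhab_validation_error")
  expect_error(clearcut_regression(
    tibble::tibble(clearcut_ha = c(1, 1, 1), habitat_loss_ha = 1:3)),
    class = "birdhab_regression_error")
  # normal-theory CI covers a known slope in >= 93 of 100 simulations
  withr::with_seed(43, {
    cover <- vapply(1:100, function(r) {
      x <- runif(20, 0, 10)
      y <- 1 + 3 * x + rnorm(20, 0, 2)
      ci <- dplyr::filter(
        tidy(clearcut_regression(
          tibble::tibble(clearcut_ha = x, habitat_loss_ha = y))),
        term == "clearcut_ha")
      ci$conf.low <= 3 && 3 <= ci$conf.high
    }, logical(1))
  })
  expect_gte(sum(cover), 93)
})
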