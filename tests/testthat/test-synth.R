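test_that("invalid configurations are rejected", {
  expect_error(sim_config(p_clearcut = -0.1), class = "birdhab_config_error")
  expect_error(sim_config(p_clearcut = 1.2), class = "birdhab_config_error")
  expect_error(sim_config(noise_sd = -1), class = "birdhab_config_error")
  expect_error(sim_config(years = 2000), class = "birdhab_config_error")
  expect_error(generate_landscape(sim_config(rows = 5, cols = 5)),
               class = "birdhab_config_error")
})

test_that("clearcut probability limits behave as constructed", {
  # p = 0: no pixel's age ever resets
  t0 <- generate_landscape(tiny_config(p_clearcut = 0, p_deforest = 0))
  for (i in 2:length(t0$years)) {
    expect_true(all(t0$age[, , i] == t0$age[, , i - 1] + 1L))
  }
  expect_identical(nrow(t0$events), 0L)

  # p = 1 over 2 years: every forest pixel has age 0 in year 2
  t1 <- generate_landscape(tiny_config(p_clearcut = 1, p_deforest = 0,
                                       years = 2000:2001))
  expect_true(all(t1$age[, , 2] == 0L))
})

test_that("clearcut rate matches a direct Bernoulli tally", {
  cfg <- sim_config(seed = 42, rows = 100, cols = 100, years = 1985:2019,
                    p_clearcut = 0.02, p_deforest = 0)
  truth <- generate_landscape(cfg)
  ny <- length(truth$years)
  n <- truth$rows * truth$cols
  # oracle: count reset events directly from the age array
  resets <- vapply(2:ny, function(i) sum(truth$age[, , i] == 0L), numeric(1))
  expect_equal(sum(resets), nrow(truth$events))
  frac <- mean(resets / n)
  se <- sqrt(0.02 * 0.98 / n) / sqrt(ny - 1)
  expect_lt(abs(frac - 0.02), 3 * se)
})

test_that("cumulative clearcut area is monotone non-decreasing", {
  truth <- generate_landscape(tiny_config(seed = 9, p_clearcut = 0.1))
  s <- landscape_summary(truth)
  expect_true(all(diff(s$cum_clearcut) >= 0))
})

test_that("identical seeds give bit-identical outputs across generators", {
  cfg <- tiny_config(seed = 7)
  a <- generate_landscape(cfg); b <- generate_landscape(cfg)
  expect_identical(a$age, b$age)
  expect_identical(a$events, b$events)
  px <- tibble::tibble(row = 1:3, col = 1:3)
  expect_identical(simulate_reflectance(a, cfg, pixels = px),
                   simulate_reflectance(b, cfg, pixels = px))
  prof <- example_profiles()[1, ]
  expect_identical(simulate_occurrences(a, prof, 100),
                   simulate_occurrences(b, prof, 100))
  r <- make_routes(a, 3); r2 <- make_routes(b, 3)
  expect_identical(r, r2)
  expect_identical(simulate_bbs_counts(a, prof, cfg, routes = r),
                   simulate_bbs_counts(b, prof, cfg, routes = r2))
})

test_that("noiseless reflectance reproduces the class curve exactly", {
  cfg <- tiny_config(noise_sd = 0, p_clearcut = 0, p_deforest = 0)
  truth <- generate_landscape(cfg)
  px <- tibble::tibble(row = 2, col = 2)
  sr <- simulate_reflectance(truth, cfg, pixels = px)
  expect_identical(sort(unique(sr$band)), 1:6)
  expect_equal(dplyr::n_distinct(sr$band), 6L)
  # residuals against the class curve are identically zero
  cls <- truth$class_id[2, 2, 1]
  lib <- cfg$harmonic_library
  for (b in 1:6) {
    sub <- dplyr::filter(sr, band == b)
    coefs <- as.matrix(lib[lib$class == cover_classes()[cls] &
                             lib$band == b,
                           c("A0","B0","A1","B1","A2","B2","A3","B3")])
    mu <- harmonic_truth_eval(as.numeric(coefs), sub$t)
    expect_equal(sub$value, mu, tolerance = 1e-12)
  }
})

test_that("disturbance produces a detectable residual shift", {
  cfg <- sim_config(seed = 3, rows = 10, cols = 10, years = 2000:2009,
                    p_clearcut = 0, p_deforest = 0, noise_sd = 0.005,
                    plantation_fraction = 0)
  truth <- generate_landscape(cfg)
  # force a clearcut at a known pixel/year midway
  brk_year <- 2005L
  i_brk <- match(brk_year, truth$years)
  truth$age[5, 5, i_brk:length(truth$years)] <-
    0:(length(truth$years) - i_brk)
  truth$class_id[5, 5, i_brk:length(truth$years)] <- 2L  # regenerating
  truth$class_id[5, 5, 1:(i_brk - 1)] <- 1L              # old before
  sr <- simulate_reflectance(truth, cfg,
                             pixels = tibble::tibble(row = 5, col = 5))
  t_brk <- (i_brk - 1) * 365.25
  b1 <- dplyr::filter(sr, band == 1)
  pre <- dplyr::filter(b1, t < t_brk)
  post <- dplyr::filter(b1, t >= t_brk)
  fit <- fit_harmonic(pre)
  resid_post <- abs(post$value - predict(fit, post$t))
  expect_gt(mean(resid_post), 3 * fit$rmse)
})

test_that("occurrence sampling follows the occupancy curve", {
  truth <- generate_landscape(tiny_config(seed = 5))
  # occupancy ~ 1 everywhere
  occ1 <- simulate_occurrences(truth, flat_profile(1 - 1e-12), 500)
  expect_true(all(occ1$present == 1L))
  # occupancy = 0.5: binomial check at n = 10,000
  occ5 <- simulate_occurrences(truth, flat_profile(0.5), 10000)
  expect_lt(abs(mean(occ5$present) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(simulate_occurrences(truth, flat_profile(0.5)[0, ], 10),
               class = "birdhab_config_error")
})

test_that("an old-forest specialist is rarer where old forest is absent", {
  prof <- example_profiles()[1, ]
  # all-young landscape: no pixel ever reaches old age
  cfg_young <- tiny_config(seed = 21, p_clearcut = 0, p_deforest = 0,
                           init_age_max = 10, old_age = 1000L)
  # all-old landscape
  cfg_old <- tiny_config(seed = 21, p_clearcut = 0, p_deforest = 0,
                         init_age_max = 120, old_age = 0L)
  occ_young <- simulate_occurrences(generate_landscape(cfg_young), prof, 3000)
  occ_old <- simulate_occurrences(generate_landscape(cfg_old), prof, 3000)
  expect_lt(sum(occ_young$present), sum(occ_old$present))
})

test_that("homogeneous Poisson counts have the configured mean", {
  cfg <- sim_config(seed = 31, rows = 10, cols = 40, years = 1990:2019,
                    p_clearcut = 0, p_deforest = 0,
                    bbs = bbs_flat(n_routes = 60, intercept = log(5)))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, flat_profile(0.5), cfg)
  se <- sqrt(5 / nrow(cc))
  expect_lt(abs(mean(cc$count) - 5), 4 * se)
})

test_that("habitat coefficient induces rank correlation with counts", {
  cfg <- sim_config(seed = 32, rows = 20, cols = 40, years = 1990:2019,
                    p_clearcut = 0.05,
                    bbs = bbs_flat(n_routes = 25, alpha = 0.8, intercept = log(5)))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, example_profiles()[1, ], cfg)
  by_route <- cc |>
    dplyr::group_by(route_id) |>
    dplyr::summarise(count = mean(count), habitat = mean(habitat_ha))
  expect_gt(stats::cor(by_route$habitat, by_route$count,
                       method = "spearman"), 0)
})

test_that("first-year observer effect shows in grouped count means", {
  cfg <- sim_config(seed = 33, rows = 10, cols = 40, years = 1985:2019,
                    p_clearcut = 0, p_deforest = 0,
                    bbs = bbs_flat(n_routes = 300, intercept = log(5),
                                   eta = -0.3, obs_change_prob = 0.5,
                                   n_observers = 8000L))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, flat_profile(0.5), cfg)
  expect_gte(nrow(cc), 1e4)
  m1 <- mean(cc$count[cc$first_year == 1])
  m0 <- mean(cc$count[cc$first_year == 0])
  ratio <- m1 / m0
  expect_lt(abs(ratio - exp(-0.3)), 0.05)
})

test_that("counts are overdispersed when the extra-Poisson sd is positive", {
  cfg <- sim_config(seed = 34, rows = 10, cols = 40, years = 1985:2019,
                    p_clearcut = 0, p_deforest = 0,
                    bbs = bbs_flat(n_routes = 60, intercept = log(10),
                                   sd_eps = 0.3))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, flat_profile(0.5), cfg)
  disp <- cc |>
    dplyr::group_by(route_id) |>
    dplyr::summarise(ratio = stats::var(count) / mean(count))
  expect_gt(mean(disp$ratio), 1)
})

test_that("YAML configuration files round-trip through sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "rows: 15", "cols: 18",
               "years: [2000, 2001, 2002]",
               "p_clearcut: 0.03",
               "bbs:", "  n_routes: 4", "  alpha: 0.2"), path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$rows, 15L)
  expect_identical(cfg$years, 2000:2002)
  expect_equal(cfg$p_clearcut, 0.03)
  expect_identical(cfg$bbs$n_routes, 4L)
  expect_equal(cfg$bbs$alpha, 0.2)
  expect_equal(cfg$bbs$sd_obs, sim_config()$bbs$sd_obs)
  writeLines("bogus_field: 1", path)
  expect_error(read_sim_config(path), class = "birdhab_config_error")
})
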