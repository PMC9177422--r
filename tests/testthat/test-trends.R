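# Reduced sampler profile used throughout these tests; the model default is
# 3 x 2000 draws after 1000 warmup.
fast_mcmc <- list(chains = 3, draws = 400, warmup = 300, adapt = 200)

fit_fast <- function(records, ...) {
  do.call(fit_trend_model,
          c(list(records = records, check_convergence = FALSE), fast_mcmc,
            list(...)))
}

flat_records <- function(n_routes = 5, n_years = 12, count = 5) {
  tidyr::expand_grid(route_id = sprintf("R%02d", 1:n_routes),
                     year = 2000 + seq_len(n_years) - 1) |>
    dplyr::mutate(observer_id = route_id, first_year = 0L, count = count)
}

test_that("count records are validated", {
  bad <- flat_records(); bad$count[3] <- -1
  expect_error(fit_trend_model(bad), class = "birdhab_validation_error")
  bad2 <- flat_records(); bad2$count[5] <- 2.5
  expect_error(fit_trend_model(bad2), class = "birdhab_validation_error")
  expect_error(fit_trend_model(dplyr::select(flat_records(), -count)),
               class = "birdhab_validation_error")
  expect_error(fit_trend_model(flat_records(n_routes = 1)),
               class = "birdhab_validation_error")
  expect_error(fit_trend_model(flat_records(), habitat = TRUE),
               class = "birdhab_validation_error")
})

test_that("a flat count series concentrates the trend near zero", {
  fit <- fit_fast(flat_records(count = 5))
  b <- dplyr::filter(tidy(fit), term == "beta1")
  expect_lt(abs(b$mean), 0.01)
  expect_true(b$q2.5 < 0 && b$q97.5 > 0)
  expect_identical(classify_decline(fit), "uncertain")
  g <- glance(fit)
  expect_identical(g$n_routes, 5L)
})

test_that("trend-to-percent conversions follow both conventions", {
  expect_equal(trend_to_percent(-0.05), -5)
  expect_equal(trend_to_percent(0), 0)
  expect_equal(trend_to_percent(0, "log-linear"), 0)
  expect_equal(trend_to_percent(-0.05, "log-linear"), -4.877058, tolerance = 1e-6)
})

test_that("decline classification applies the credible-interval rule", {
  mk <- function(lo, hi) tibble::tibble(term = "beta1", q2.5 = lo, q97.5 = hi)
  expect_identical(classify_decline(mk(-0.08, -0.02)), "declining")
  expect_identical(classify_decline(mk(-0.01, 0.03)), "uncertain")
  expect_identical(classify_decline(mk(0.01, 0.05)), "increasing")
})

fake_habitat_fit <- function(draws, range = 1) {
  structure(list(
    terms = list(habitat = TRUE),
    data_info = list(h_std_range = c(0, range)),
    samples = coda::mcmc.list(coda::mcmc(matrix(draws,
                                                dimnames = list(NULL, "alphaH"))))
  ), class = "trend_fit")
}

test_that("habitat fold change has its closed forms", {
  expect_equal(habitat_fold_change(fake_habitat_fit(rep(0, 11)))$median, 1)
  expect_equal(habitat_fold_change(fake_habitat_fit(rep(log(2), 11),
                                                    range = 1))$median, 2)
  # log-normal draws: median fold = exp(median(alpha) * range)
  withr::with_seed(51, draws <- rnorm(4001, 0.4, 0.1))
  fc <- habitat_fold_change(fake_habitat_fit(draws, range = 2))
  expect_equal(fc$median, exp(stats::median(draws) * 2), tolerance = 1e-10)
  expect_lt(abs(fc$median - exp(0.4 * 2)), 0.1)
})

test_that("habitat effect is recovered on one simulated dataset", {
  cfg <- sim_config(seed = 61, rows = 20, cols = 40, years = 1995:2014,
                    bbs = list(n_routes = 20, alpha = 0.5, beta1 = -0.03))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, example_profiles()[1, ], cfg)
  fit <- fit_fast(cc, habitat = TRUE)
  a <- dplyr::filter(tidy(fit), term == "alphaH")
  expect_lt(abs(a$mean - 0.5), 0.2)
  b <- dplyr::filter(tidy(fit), term == "beta1")
  expect_lt(abs(b$mean - (-0.03)), 0.02)
  # every monitored parameter carries a reported R-hat and ordered quantiles
  s <- tidy(fit)
  expect_true(all(is.finite(s$rhat)))
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
})

test_that("posterior contracts as the number of routes grows", {
  sds <- vapply(c(10, 30, 100), function(nr) {
    cfg <- sim_config(seed = 62, rows = 20, cols = 40, years = 2001:2015,
                      bbs = list(n_routes = nr, alpha = 0.4, beta1 = -0.02))
    truth <- generate_landscape(cfg)
    cc <- simulate_bbs_counts(truth, example_profiles()[1, ], cfg)
    fit <- fit_fast(cc, habitat = TRUE)
    dplyr::filter(tidy(fit), term == "alphaH")$sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("consistent observer relabelling leaves inference unchanged", {
  cfg <- sim_config(seed = 63, rows = 20, cols = 40, years = 2001:2012,
                    bbs = list(n_routes = 10))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, example_profiles()[1, ], cfg)
  relabel <- stats::setNames(
    sprintf("Z%04d", rev(seq_along(unique(cc$observer_id)))),
    unique(cc$observer_id))
  cc2 <- dplyr::mutate(cc, observer_id = relabel[observer_id])
  f1 <- fit_fast(cc)
  f2 <- fit_fast(cc2)
  b1 <- dplyr::filter(tidy(f1), term == "beta1")
  b2 <- dplyr::filter(tidy(f2), term == "beta1")
  expect_lt(abs(b1$mean - b2$mean), 3 * sqrt(b1$sd^2 / b1$ess + b2$sd^2 / b2$ess) + 1e-3)
})

test_that("without overdispersion the fit agrees with a frequentist GLMM", {
  cfg <- sim_config(seed = 64, rows = 20, cols = 40, years = 1996:2015,
                    bbs = list(n_routes = 25, sd_eps = 0, beta1 = -0.03,
                               alpha = 0))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, example_profiles()[1, ], cfg)
  fit <- fit_fast(cc, overdispersion = FALSE)
  b <- dplyr::filter(tidy(fit), term == "beta1")
  glmm <- lme4::glmer(
    count ~ yrc + first_year + (1 | route_id) + (1 | observer_id) +
      (1 | year_f),
    data = dplyr::mutate(cc, yrc = year - min(year), year_f = factor(year)),
    family = stats::poisson())
  est <- unname(lme4::fixef(glmm)["yrc"])
  se <- sqrt(diag(as.matrix(stats::vcov(glmm))))[["yrc"]]
  # credible and confidence intervals overlap
  expect_lt(max(b$q2.5, est - 1.96 * se), min(b$q97.5, est + 1.96 * se))
})

test_that("ten-year trends flag steep declines and respect the window", {
  expect_error(ten_year_trend(flat_records(n_years = 6)),
               class = "birdhab_validation_error")
  # flat data: ~0% cumulative change, no flag
  flat <- ten_year_trend(flat_records(n_years = 12), window = 10,
                         chains = 3, draws = 400, warmup = 300, adapt = 200,
                         check_convergence = FALSE)
  expect_lt(abs(flat$cumulative_pct), 10)
  expect_false(flat$flagged)
  expect_identical(length(flat$fit$data_info$years), 10L)
  # boundary arithmetic: -3.5%/yr compounds to almost exactly -30% over 10 yr
  expect_equal(100 * ((1 - 0.035)^10 - 1), -29.97176, tolerance = 1e-5)
  # simulated steep decline is flagged
  cfg <- sim_config(seed = 65, rows = 20, cols = 40, years = 2005:2014,
                    bbs = list(n_routes = 20, beta1 = -0.05, alpha = 0,
                               intercept = log(20)))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, example_profiles()[1, ], cfg)
  tt <- ten_year_trend(cc, window = 10, chains = 3, draws = 400,
                       warmup = 300, adapt = 200, check_convergence = FALSE)
  expect_true(tt$flagged)
})

test_that("prior predictive draws are valid non-negative counts", {
  # draw from the generative model at the prior means of the hyper-sds
  cfg <- sim_config(seed = 66, rows = 10, cols = 20, years = 2010:2014,
                    bbs = list(n_routes = 5))
  truth <- generate_landscape(cfg)
  cc <- simulate_bbs_counts(truth, example_profiles()[2, ], cfg)
  expect_true(all(cc$count >= 0))
  expect_true(all(cc$count == round(cc$count)))
  expect_true(is.finite(mean(cc$count)))
})
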