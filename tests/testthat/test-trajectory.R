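obs_days <- c(seq(4, 24, by = 2), 25)

test_that("constant series smooth to constant daily values", {
  out <- smooth_interpolate(obs_days, rep(3.5, length(obs_days)))
  expect_equal(out$day, 4:25)
  expect_equal(out$value, rep(3.5, 22), tolerance = 1e-10)
})

test_that("cubic polynomials pass through smoothing and interpolation exactly", {
  # polynomial reproduction by the filter requires evenly spaced observations
  unif_days <- seq(4, 24, by = 2)
  f <- function(t) 2 + 0.5 * t - 0.03 * t^2 + 0.001 * t^3
  out <- smooth_interpolate(unif_days, f(unif_days),
                            smoothing_spec(7, 3, days = 4:24))
  expect_equal(out$value, f(4:24), tolerance = 1e-8)
  # degree-5 polynomials are reproduced exactly at the observation days by
  # the order-5 filter
  g <- function(t) 1 + 1e-4 * (t - 14)^5 - 1e-3 * (t - 10)^3
  out5 <- smooth_interpolate(unif_days, g(unif_days),
                             smoothing_spec(7, 5, days = 4:24))
  expect_equal(out5$value[out5$day %in% unif_days], g(unif_days),
               tolerance = 1e-8)
})

test_that("smoothing reduces observation noise on a logistic curve", {
  truth <- function(t) 1 / (1 + exp(-(t - 12) / 3))
  withr::with_seed(10, {
    rmse_raw <- rmse_sm <- numeric(20)
    for (i in 1:20) {
      noisy <- truth(obs_days) * (1 + rnorm(length(obs_days), 0, 0.05))
      sm <- smooth_interpolate(obs_days, noisy, smoothing_spec(7, 3))
      rmse_raw[i] <- sqrt(mean((noisy - truth(obs_days))^2))
      rmse_sm[i] <- sqrt(mean((sm$value - truth(sm$day))^2))
    }
  })
  expect_lt(mean(rmse_sm), mean(rmse_raw))
})

test_that("too few observations for the window raise an advisory error", {
  expect_error(smooth_interpolate(1:5, 1:5), "smaller window")
  expect_error(smoothing_spec(6, 3), "odd")
  expect_error(smoothing_spec(7, 7), "polyorder")
})

test_that("daily phenotypes cover every plant, feature and day", {
  daily <- fixture_daily(1)
  expect_setequal(unique(daily$feature),
                  c("root_px", "shoot_px", "health", "ndvi"))
  counts <- table(daily$plant_id, daily$feature)
  expect_true(all(counts == 22))
})

test_that("an exactly linear feature gives r = -1 with a zero-width CI", {
  plants <- tibble::tibble(plant_id = sprintf("P%02d", 1:10),
                           dose_uM = seq(0, 450, by = 50))
  daily <- tidyr::expand_grid(plant_id = plants$plant_id, day = 11:13) %>%
    dplyr::inner_join(plants, by = "plant_id") %>%
    dplyr::mutate(feature = "root_px", value = -dose_uM) %>%
    dplyr::select(plant_id, feature, day, value)
  dc <- daily_correlation(daily, plants, n_boot = 200, seed = 1)
  expect_true(all(abs(dc$r + 1) < 1e-12))
  expect_true(all(abs(dc$ci_hi - dc$ci_lo) < 1e-9))
})

test_that("null features give CIs covering zero on most days", {
  plants <- tibble::tibble(plant_id = sprintf("P%02d", 1:40),
                           dose_uM = rep(c(0, 50, 200, 500), each = 10))
  covers <- vapply(1:10, function(s) {
    withr::with_seed(20 + s, {
      daily <- tidyr::expand_grid(plant_id = plants$plant_id, day = 11:20) %>%
        dplyr::mutate(feature = "root_px", value = rnorm(dplyr::n())) %>%
        dplyr::select(plant_id, feature, day, value)
    })
    dc <- daily_correlation(daily, plants, n_boot = 2000, seed = s)
    mean(dc$ci_lo <= 0 & dc$ci_hi >= 0)
  }, numeric(1))
  expect_gte(mean(covers), 0.9)
})

test_that("root correlations turn negative before health correlations", {
  daily <- fixture_daily(1)
  study <- fixture_study(1)
  dc <- daily_correlation(daily, study$plants, n_boot = 300, seed = 3)
  first_neg <- function(feat) {
    d <- dc[dc$feature == feat & dc$day >= 11, ]
    min(d$day[d$ci_hi < 0])
  }
  expect_lt(first_neg("root_px"), first_neg("health"))
})

test_that("the dose screen flags huge separations and spares the control", {
  plants <- tibble::tibble(plant_id = sprintf("P%02d", 1:12),
                           dose_uM = rep(c(0, 500), each = 6))
  withr::with_seed(30, {
    daily <- tidyr::expand_grid(plant_id = plants$plant_id, day = 11:12) %>%
      dplyr::inner_join(plants, by = "plant_id") %>%
      dplyr::mutate(feature = "root_px",
                    value = rnorm(dplyr::n(), ifelse(dose_uM == 0, 0, -10))) %>%
      dplyr::select(plant_id, feature, day, value)
  })
  tests <- daily_dose_tests(daily, plants)
  expect_true(all(tests$significant))
  expect_false(0 %in% tests$dose_uM)     # control never compared to itself
  expect_error(
    daily_dose_tests(daily, dplyr::mutate(plants, dose_uM = dose_uM + 1)),
    "control"
  )
})

test_that("type-I rate of the screen is near nominal under the null", {
  flagged <- vapply(1:6, function(s) {
    plants <- tibble::tibble(plant_id = sprintf("P%02d", 1:24),
                             dose_uM = rep(c(0, 100, 300, 500), each = 6))
    withr::with_seed(400 + s, {
      daily <- tidyr::expand_grid(plant_id = plants$plant_id,
                                  day = 11:20) %>%
        dplyr::mutate(feature = "root_px", value = rnorm(dplyr::n())) %>%
        dplyr::select(plant_id, feature, day, value)
    })
    mean(daily_dose_tests(daily, plants)$significant)
  }, numeric(1))
  expect_lte(mean(flagged), 0.05 + 0.03)
})

test_that("trajectory matrices are scaled, complete and idempotent", {
  daily <- fixture_daily(1)
  m <- build_trajectory_matrix(daily)
  expect_equal(ncol(m), 45)
  expect_equal(nrow(m), 42)
  expect_true(all(m >= 0 & m <= 1))
  for (f in c("root_px", "shoot_px", "health")) {
    cols <- grepl(paste0("^", f, "_"), colnames(m))
    expect_equal(min(m[, cols]), 0)
    expect_equal(max(m[, cols]), 1)
  }
  # rescaling already-scaled values changes nothing
  long <- tibble::as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE))
  names(long) <- c("plant_id", "col", "value")
  long <- long %>%
    tidyr::separate_wider_regex(col, c(feature = ".*", "_d", day = "\\d+")) %>%
    dplyr::mutate(day = as.integer(day))
  m2 <- build_trajectory_matrix(long)
  expect_equal(m2, m, tolerance = 1e-12)
  # two plants with constant distinct levels scale to all-0 / all-1 rows
  small <- tidyr::expand_grid(
    plant_id = c("A", "B"),
    feature = c("root_px", "shoot_px", "health"), day = 11:25
  ) %>% dplyr::mutate(value = ifelse(plant_id == "A", 1, 5))
  ms <- build_trajectory_matrix(small)
  expect_equal(unname(ms["A", ]), rep(0, 45))
  expect_equal(unname(ms["B", ]), rep(1, 45))
  expect_error(build_trajectory_matrix(small[-1, ]), "missing")
})
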