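test_that("round-1 design yields 42 plants with a full imaging record", {
  study <- fixture_study(1)
  expect_equal(nrow(study$plants), 42)
  expect_setequal(unique(study$plants$dose_uM),
                  c(0, 25, 50, 100, 200, 300, 500))
  per_plant <- table(study$observations$plant_id)
  n_days <- length(unique(study$observations$day))
  expect_gte(n_days, 10)
  expect_true(all(per_plant == n_days * 4))
  # every (plant, day) has one root scan and three shoot views
  combos <- with(study$observations, table(plant_id, day, modality))
  expect_true(all(combos == 1))
})

test_that("zero-noise replicates reproduce the noiseless logistic solution", {
  p <- sim_params(plant_cv = 0, obs_noise_cv = 0, fw_noise_cv = 0,
                  health_noise_sd = 0, ndvi_noise_sd = 0)
  study <- simulate_experiment(dose_design(0, 6), p, seed = 3)
  root <- subset(study$observations, modality == "root_scan")
  wide <- tapply(root$pixel_count, list(root$plant_id, root$day), identity)
  # all 6 plants identical
  expect_true(all(apply(wide, 2, function(col) diff(range(col)) == 0)))
  expected <- p$gain_root * latent_size(
    sort(unique(root$day)), 0, p$growth_rate, p$k_root,
    p$s0_frac * p$k_root, p$ec50_root, p$hill_root, p$onset_lag_root,
    p$amendment_day
  )
  expect_equal(unname(wide[1, ]), expected, tolerance = 1e-12)
})

test_that("closed-form growth matches numeric integration of the ODE", {
  skip_if_not_installed("deSolve")
  p <- sim_params()
  for (dose in c(0, 50, 300, 10000)) {
    ode_fn <- function(t, state, parms) {
      i_inf <- 1 / (1 + (dose / p$ec50_root)^p$hill_root)
      w <- if (t <= p$amendment_day) 0 else {
        min((t - p$amendment_day) / p$onset_lag_root, 1)
      }
      I <- 1 - w * (1 - i_inf)
      list(p$growth_rate * state[1] * (1 - state[1] / p$k_root) * I)
    }
    num <- deSolve::ode(c(S = p$s0_frac * p$k_root), seq(0, 25, 0.25), ode_fn,
                        NULL, method = "rk4")
    closed <- latent_size(seq(0, 25, 0.25), dose, p$growth_rate, p$k_root,
                          p$s0_frac * p$k_root, p$ec50_root, p$hill_root,
                          p$onset_lag_root, p$amendment_day)
    expect_equal(unname(num[, "S"]), closed, tolerance = 1e-5)
  }
})

test_that("a saturating dose freezes post-amendment growth", {
  p <- sim_params()
  args <- function(dose, t) latent_size(t, dose, p$growth_rate, p$k_root,
                                        p$s0_frac * p$k_root, p$ec50_root,
                                        p$hill_root, p$onset_lag_root,
                                        p$amendment_day)
  t0 <- p$amendment_day + p$onset_lag_root
  incr_high <- args(10000, 25) - args(10000, t0)
  incr_ctrl <- args(0, 25) - args(0, t0)
  expect_lte(incr_high / incr_ctrl, 0.01)
})

test_that("mean final latent size is non-increasing in dose for every phenotype", {
  p <- sim_params(plant_cv = 0, obs_noise_cv = 0, fw_noise_cv = 0)
  doses <- c(0, 10, 25, 50, 100, 200, 300, 400, 500)
  study <- simulate_experiment(dose_design(doses, 1), p, seed = 1)
  fin <- study$truth[study$truth$day == 25, ]
  fin <- fin[match(study$plants$plant_id, fin$plant_id), ]
  ord <- order(study$plants$dose_uM)
  for (col in c("s_root", "s_shoot", "health")) {
    expect_true(all(diff(fin[[col]][ord]) <= 1e-12), info = col)
  }
})

test_that("identical (design, params, seed) gives identical studies", {
  a <- simulate_experiment(dose_design(), sim_params(), seed = 42)
  b <- simulate_experiment(dose_design(), sim_params(), seed = 42)
  expect_identical(a$plants, b$plants)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
})

test_that("final root pixels and root fresh weight are realistically correlated", {
  # calibration target: Pearson r in [0.75, 0.95] over >= 60 plants at
  # default noise, bracketing observed imaging/harvest agreement
  a <- fixture_study(1)
  b <- simulate_experiment(
    dose_design(c(0, 137, 263, 349, 406, 458, 500), 6, round_id = 2),
    sim_params(), seed = 101
  )
  plants <- rbind(a$plants, b$plants)
  obs <- rbind(a$observations, b$observations)
  fin <- subset(obs, day == 25 & modality == "root_scan")
  m <- merge(plants, fin[, c("plant_id", "pixel_count")])
  expect_gte(nrow(m), 60)
  r <- cor(m$pixel_count, m$fw_root_g)
  expect_gte(r, 0.75)
  expect_lte(r, 0.95)
})

test_that("studies carry their generating parameters as ground truth", {
  study <- fixture_study(1)
  expect_s3_class(study$params, "sim_params")
  expect_equal(study$params$ec50_root, sim_params()$ec50_root)
  expect_true(all(c("s_root", "s_shoot", "health") %in% names(study$truth)))
})

test_that("invalid designs and schedules are rejected", {
  expect_error(dose_design(c(0, 600)), "doses")
  expect_error(dose_design(0, 0), "n_replicates")
  expect_error(sim_params(schedule = c(2, 10)), "schedule")
  expect_error(sim_params(ec50_root = 400), "ordering")
  expect_error(sim_params(growth_rate = -1), "positive")
})

test_that("dropout flags plants with a reason", {
  study <- simulate_experiment(dose_design(), sim_params(dropout_rate = 0.3),
                               seed = 9)
  expect_gt(sum(study$plants$excluded), 0)
  expect_true(all(nzchar(study$plants$reason[study$plants$excluded])))
})

test_that("make_cube honours the green fraction exactly and is seed-stable", {
  cube <- make_cube(64, 64, 0.5, seed = 4)
  expect_equal(sum(cube$w == 1, na.rm = TRUE), 2048)
  em <- default_endmembers()
  p0 <- sim_params(cube_noise_sd = 0)
  pure <- make_cube(8, 8, 1, p0, seed = 1)
  expect_equal(as.numeric(pure$cube[3, 5, ]), em$green, tolerance = 1e-12)
  expect_error(make_cube(4, 4, 0.5, mask = matrix(FALSE, 4, 4)), "mask")
  expect_error(make_cube(4, 4, 1.4), "green_fraction")
  expect_identical(make_cube(8, 8, 0.3, seed = 7)$cube,
                   make_cube(8, 8, 0.3, seed = 7)$cube)
})

test_that("sim_params round-trips through YAML", {
  p <- sim_params(ec50_root = 40, seed = 5L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_params(p, path)
  q <- read_sim_params(path)
  expect_equal(q$ec50_root, 40)
  expect_equal(q$endmembers, p$endmembers, tolerance = 1e-5)
  expect_equal(q$view_gains, p$view_gains)
})
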