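test_that("two-point posterior matches a hand-built 2x2 oracle", {
  m <- gp_model(signal_var = 2, lengthscales = 30, noise_var = 0.1,
                X = c(10, 60), y = c(1, -0.5), prior_mean = 0.25)
  xs <- c(0, 10, 35, 100)
  pr <- predict(m, xs)
  orc <- gp_oracle(m, xs)
  expect_equal(pr$mean, orc$mean, tolerance = 1e-8)
  expect_equal(pr$sd_epistemic, orc$sd, tolerance = 1e-8)
  expect_equal(pr$sd_with_noise, sqrt(orc$sd^2 + 0.1), tolerance = 1e-8)
})

test_that("posterior interpolates a near-noiseless training point", {
  m <- gp_model(1, 20, 1e-12, X = 50, y = 3, prior_mean = 0)
  pr <- predict(m, 50)
  expect_equal(pr$mean, 3, tolerance = 1e-4)
  expect_lt(pr$sd_epistemic, 1e-3)
})

test_that("an empty model predicts from the prior", {
  m <- gp_model(4, 50, 0.01, prior_mean = 1.5)
  pr <- predict(m, c(0, 250, 500))
  expect_equal(pr$mean, rep(1.5, 3))
  expect_equal(pr$sd_epistemic, rep(2, 3))
})

test_that("adding a training point never increases epistemic sd", {
  base <- gp_model(1, 60, 0.05, X = c(0, 100, 300), y = c(1, 0.5, 0.2))
  more <- gp_model(1, 60, 0.05, X = c(0, 100, 300, 200),
                   y = c(1, 0.5, 0.2, 0.3))
  g <- seq(0, 500, by = 25)
  expect_true(all(predict(more, g)$sd_epistemic <=
                    predict(base, g)$sd_epistemic + 1e-10))
})

test_that("fit_gp is deterministic and beats random hyperparameter draws", {
  study <- fixture_study(1)
  cfg <- gp_config(max_iterations = 500, seed = 7)
  f1 <- fit_gp(study$plants$dose_uM, study$plants$fw_root_g, cfg)
  f2 <- fit_gp(study$plants$dose_uM, study$plants$fw_root_g, cfg)
  expect_identical(f1$theta, f2$theta)
  expect_gte(f1$log_marginal, f1$log_marginal_init)
  # fitted optimum at least as good as 100 random in-bounds draws
  lo <- f1$bounds[, "lower"]; hi <- f1$bounds[, "upper"]
  X <- matrix(study$plants$dose_uM, ncol = 1)
  withr::with_seed(99, {
    rand_nll <- vapply(1:100, function(i) {
      lt <- lo + runif(length(lo)) * (hi - lo)
      phenoloop:::gp_nll_cpp(lt, X, study$plants$fw_root_g,
                             mean(study$plants$fw_root_g), 0L)
    }, numeric(1))
  })
  expect_true(all(-f1$log_marginal <= rand_nll + 1e-9))
})

test_that("hyperparameters are recovered from a known GP draw", {
  true_ell <- 80
  withr::with_seed(5, {
    x <- sort(runif(40, 0, 500))
    K <- 1.5 * exp(-0.5 * outer(x, x, "-")^2 / true_ell^2) + diag(1e-8, 40)
    y <- drop(chol(K + diag(1e-6, 40)) %*% rnorm(40))
  })
  f <- fit_gp(x, y, gp_config(max_iterations = 2000, seed = 11))
  ratio <- unname(f$theta["lengthscale_x"]) / true_ell
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})

test_that("constant targets drive the signal variance to its lower bound", {
  f <- fit_gp(c(0, 100, 200, 300), rep(2, 4),
              gp_config(max_iterations = 200, seed = 1))
  expect_lt(f$theta[["signal_var"]], 1e-10)
  pr <- predict(f, c(50, 250))
  expect_equal(pr$mean, c(2, 2), tolerance = 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_gp(rep(5, 4), 1:4, gp_config(max_iterations = 10)),
               "constant")
  expect_error(fit_gp(1, 1), "at least 2")
  expect_error(fit_gp(c(1, 2), c(1, Inf)), "finite")
})

test_that("crps_gaussian matches its closed-form reference points", {
  # mu = y, sigma = 1: numeric integration gives 0.2336949...
  expect_equal(crps_gaussian(0, 1, 0), 2 / sqrt(2 * pi) - 1 / sqrt(pi),
               tolerance = 1e-10)
  expect_equal(crps_gaussian(0, 1, 0), 0.23370, tolerance = 1e-4)
  expect_equal(crps_gaussian(3, 0, 1), 2)          # point mass -> |y - mu|
  # far-tail asymptote: |y - mu| - sigma/sqrt(pi), checked against the
  # integral definition
  crps_num <- stats::integrate(function(t) {
    (pnorm(t) - as.numeric(t >= 10))^2
  }, -15, 30, rel.tol = 1e-10)$value
  expect_equal(crps_gaussian(0, 1, 10), crps_num, tolerance = 1e-6)
  expect_equal(crps_gaussian(0, 1, 10), 10 - 1 / sqrt(pi), tolerance = 1e-4)
  expect_error(crps_gaussian(0, -1, 0), "nonnegative")
})

test_that("nrmse matches hand arithmetic and is affine invariant", {
  expect_equal(nrmse(c(1, 1), c(0, 2)), 0.5)
  expect_equal(nrmse(c(0, 2), c(0, 2)), 0)
  withr::with_seed(2, {
    obs <- rnorm(20); prd <- obs + rnorm(20, 0, 0.3)
    a <- 3.7; b <- -1.2
    expect_equal(nrmse(prd, obs), nrmse(a * prd + b, a * obs + b),
                 tolerance = 1e-12)
  })
  expect_error(nrmse(1:3, rep(1, 3)), "positive")
  expect_error(nrmse(1:3, 1:4), "equal length")
})

test_that("GP models round-trip through JSON", {
  study <- fixture_study(1)
  f <- fit_gp(study$plants$dose_uM, study$plants$fw_root_g,
              gp_config(max_iterations = 200, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_gp_model(f, path)
  g <- read_gp_model(path)
  grid <- seq(0, 500, by = 50)
  expect_equal(predict(g, grid)$mean, predict(f, grid)$mean,
               tolerance = 1e-10)
  expect_equal(predict(g, grid)$sd_with_noise,
               predict(f, grid)$sd_with_noise, tolerance = 1e-10)
})

test_that("tidiers expose hyperparameters and model summaries", {
  m <- gp_model(1, 50, 0.01, X = c(0, 100), y = c(1, 0))
  td <- tidy(m)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(m)
  expect_equal(gl$n, 2)
  expect_equal(gl$kernel, "sqexp")
})

test_that("the Matern kernel option matches its oracle too", {
  m <- gp_model(1.2, 40, 0.02, X = c(20, 150, 340), y = c(0.5, -0.2, 0.1),
                config = gp_config(kernel = "matern32"))
  xs <- c(0, 90, 480)
  pr <- predict(m, xs)
  orc <- gp_oracle(m, xs)
  expect_equal(pr$mean, orc$mean, tolerance = 1e-8)
  expect_equal(pr$sd_epistemic, orc$sd, tolerance = 1e-8)
})
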