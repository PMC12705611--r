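test_that("stratified splits balance dose bins across folds", {
  doses <- rep(c(0, 25, 50, 100, 200, 300, 500), each = 6)
  splits <- stratified_splits(doses, cv_scheme(seed = 3))
  expect_length(splits, 30)
  bin <- attr(splits, "bin")
  for (s in splits) {
    expect_length(s$test, 7)
    expect_setequal(c(s$train, s$test), seq_along(doses))
    counts <- table(factor(bin[s$test], levels = sort(unique(bin))))
    # per-fold bin composition within one of the proportional share
    for (b in sort(unique(bin))) {
      expect_lte(abs(counts[[as.character(b)]] - sum(bin == b) / 6), 1)
    }
  }
  # every sample appears in exactly one test fold per repeat
  for (r in 1:5) {
    tests <- unlist(lapply(splits, function(s) {
      if (s$repeat_id == r) s$test
    }))
    expect_setequal(tests, seq_along(doses))
    expect_length(tests, length(doses))
  }
})

test_that("six samples with k = 6 degenerate to leave-one-out", {
  splits <- stratified_splits(c(0, 10, 20, 30, 40, 50),
                              cv_scheme(k = 6, repeats = 1, seed = 1))
  expect_length(splits, 6)
  expect_true(all(vapply(splits, function(s) length(s$test), 0L) == 1))
})

test_that("degenerate stratification inputs error", {
  expect_error(stratified_splits(rep(100, 12), cv_scheme()), "distinct")
  expect_error(stratified_splits(c(0, 1), cv_scheme(k = 6)), "fewer samples")
})

test_that("a smooth dose-response is fit with low cross-validated NRMSE", {
  withr::with_seed(8, {
    dose <- rep(c(0, 25, 50, 100, 200, 300, 500), each = 6)
    y <- 1 / (1 + (dose / 120)^2) + rnorm(length(dose), 0, 0.02)
  })
  ev <- evaluate_model(tibble::tibble(dose_uM = dose, y = y), "y",
                       scheme = cv_scheme(seed = 1),
                       config = gp_config(max_iterations = 500, seed = 1))
  expect_lt(ev$mean_nrmse, 0.15)
  expect_lt(ev$null_ratio, 1)
  expect_equal(nrow(ev$splits), 30)
  expect_true(ev$ci95[1] <= ev$mean_nrmse && ev$mean_nrmse <= ev$ci95[2])
})

test_that("dose-independent targets give a null ratio near one", {
  ratios <- vapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      dose <- rep(c(0, 25, 50, 100, 200, 300, 500), each = 6)
      y <- rnorm(length(dose))
    })
    ev <- evaluate_model(
      tibble::tibble(dose_uM = dose, y = y), "y",
      scheme = cv_scheme(k = 2, repeats = 1, seed = s),
      config = gp_config(max_iterations = 300, seed = s)
    )
    ev$null_ratio
  }, numeric(1))
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.2)
})

test_that("bootstrap CI is stable when resamples increase tenfold", {
  study <- fixture_study(1)
  ev1 <- evaluate_model(study$plants, "fw_root_g",
                        scheme = cv_scheme(seed = 2),
                        config = gp_config(max_iterations = 300, seed = 2),
                        n_boot = 1000)
  ev2 <- evaluate_model(study$plants, "fw_root_g",
                        scheme = cv_scheme(seed = 2),
                        config = gp_config(max_iterations = 300, seed = 2),
                        n_boot = 10000)
  width <- diff(ev1$ci95)
  expect_lt(max(abs(ev1$ci95 - ev2$ci95)), width / 10)
})

test_that("missing target columns are reported by name", {
  expect_error(evaluate_model(tibble::tibble(dose_uM = 1:6), "fw"),
               "fw")
})

test_that("compare_models is null for identical inputs and flags real shifts", {
  withr::with_seed(3, v <- runif(30, 0.1, 0.3))
  cmp <- compare_models(list(a = v, b = v))
  expect_equal(cmp$p_value, 1, tolerance = 1e-9)
  expect_equal(cmp$improvement_pct, 0)
  expect_equal(attr(cmp, "method"), "t-test")
  # three variants, one shifted
  withr::with_seed(4, {
    x <- rnorm(30, 0.25, 0.02)
    y <- rnorm(30, 0.25, 0.02)
    z <- rnorm(30, 0.15, 0.02)
  })
  cmp3 <- compare_models(list(r1 = x, r2 = y, comb = z))
  expect_equal(attr(cmp3, "method"), "anova+tukey")
  expect_lt(attr(cmp3, "anova_p"), 0.05)
  p_shift <- cmp3$p_value[cmp3$b == "comb" | cmp3$a == "comb"]
  p_null <- cmp3$p_value[cmp3$a == "r1" & cmp3$b == "r2"]
  expect_true(all(p_shift < 0.05))
  expect_gt(p_null, 0.05)
  # improvement computed from unrounded means
  imp <- cmp3$improvement_pct[cmp3$a == "r1" & cmp3$b == "comb"]
  expect_equal(imp, (mean(x) - mean(z)) / mean(x) * 100, tolerance = 1e-12)
  expect_error(compare_models(list(a = 1:5, b = 1:6)), "mismatched")
})

test_that("endpoint_comparison handles two-group and multi-group designs", {
  df2 <- tibble::tibble(g = rep(c("ctrl", "t"), each = 6),
                        v = rep(c(1, 2, 3, 4, 5, 6), 2))
  out <- endpoint_comparison(df2, "v", "g", control = "ctrl")
  expect_equal(out$cohens_d, 0)
  expect_gt(out$p_adj, 0.99)
  # N(0,1) vs N(-2,1) at n = 4: d near -2 and usually significant
  hits <- 0; ds <- numeric(10)
  for (s in 1:10) {
    withr::with_seed(200 + s, {
      df <- tibble::tibble(
        g = rep(c("ctrl", "lo"), each = 4),
        v = c(rnorm(4, 0, 1), rnorm(4, -2, 1))
      )
    })
    out <- endpoint_comparison(df, "v", "g", control = "ctrl")
    ds[s] <- out$cohens_d
    hits <- hits + (out$p_adj < 0.1)
  }
  expect_equal(mean(ds), -2, tolerance = 0.75)
  expect_gte(hits, 6)
  # multi-group: a knockout group stands out from control
  withr::with_seed(6, {
    df <- tibble::tibble(
      g = rep(c("ctrl", paste0("t", 1:8), "ko"), each = 4),
      v = c(rnorm(36, 1, 0.1), rnorm(4, 0.3, 0.1))
    )
  })
  out <- endpoint_comparison(df, "v", "g", control = "ctrl")
  expect_equal(attr(out, "method"), "anova+tukey")
  expect_lt(out$p_adj[out$group == "ko"], 0.05)
  expect_true(all(out$p_adj[!out$group %in% "ko"] > 0.05))
  expect_error(endpoint_comparison(df, "v", "g", control = "none"), "control")
  expect_error(
    endpoint_comparison(tibble::tibble(g = c("a", "a", "b"), v = 1:3),
                        "v", "g", control = "a"),
    "fewer than 2"
  )
})

test_that("minmax_scale matches its definition and cancels in NRMSE", {
  expect_equal(minmax_scale(c(0, 5, 10)), c(0, 0.5, 1))
  g <- rep(c("a", "b"), each = 3)
  sc <- minmax_scale(c(1, 2, 3, 10, 20, 30), groups = g)
  expect_equal(range(sc[g == "a"]), c(0, 1))
  expect_equal(range(sc[g == "b"]), c(0, 1))
  expect_error(minmax_scale(rep(2, 4)), "zero range")
  # global scaling of the target leaves GP CV NRMSE unchanged
  study <- fixture_study(1)
  tab <- study$plants
  tab$fw_scaled <- minmax_scale(tab$fw_root_g)
  cfg <- gp_config(max_iterations = 300, seed = 4)
  ev_raw <- evaluate_model(tab, "fw_root_g", scheme = cv_scheme(seed = 4),
                           config = cfg)
  ev_sc <- evaluate_model(tab, "fw_scaled", scheme = cv_scheme(seed = 4),
                          config = cfg)
  expect_equal(ev_sc$mean_nrmse, ev_raw$mean_nrmse, tolerance = 0.02)
})
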