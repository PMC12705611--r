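#' Stratified repeated k-fold cross-validation scheme
#'
#' The default mirrors the study protocol: 5 repeats of 6-fold
#' cross-validation (30 train/test splits), stratifying on dose via 3
#' equal-frequency (quantile) bins, with a fresh seeded shuffle between
#' repeats.
#'
#' @param k Folds per repeat (default 6).
#' @param repeats Number of repeats (default 5).
#' @param n_bins Equal-frequency dose bins for stratification (default 3).
#' @param seed Integer seed.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(k = 6, repeats = 5, n_bins = 3, seed = 1L) {
  stopifnot(k >= 2, repeats >= 1, n_bins >= 1)
  structure(
    list(k = as.integer(k), repeats = as.integer(repeats),
         n_bins = as.integer(n_bins), seed = as.integer(seed)),
    class = "cv_scheme"
  )
}

#' Build stratified train/test splits over doses
#'
#' Doses are binned into `n_bins` equal-frequency bins (quantile cut); within
#' each repeat every bin is shuffled and dealt round-robin into the k folds,
#' so per-fold bin counts differ by at most one. Every sample appears in
#' exactly one test fold per repeat.
#'
#' @param doses Numeric dose per sample.
#' @param scheme A [cv_scheme()].
#' @return A list of `k * repeats` splits, each a list with `train`, `test`
#'   integer indices and `repeat_id`, `fold` labels.
#' @export
stratified_splits <- function(doses, scheme = cv_scheme()) {
  n <- length(doses)
  if (n < scheme$k) stop("stratified_splits: fewer samples than folds",
                         call. = FALSE)
  if (length(unique(doses)) < scheme$n_bins) {
    stop("stratified_splits: fewer distinct doses than stratification bins",
         call. = FALSE)
  }
  br <- unique(quantile(doses, probs = seq(0, 1, length.out = scheme$n_bins + 1)))
  bin <- if (length(br) > 2) {
    as.integer(cut(doses, br, include.lowest = TRUE))
  } else {
    rep(1L, n)
  }
  k <- scheme$k
  splits <- list()
  withr::with_seed(scheme$seed, {
    for (r in seq_len(scheme$repeats)) {
      fold <- integer(n)
      load <- integer(k)
      for (b in sort(unique(bin))) {
        idx <- sample(which(bin == b))
        # deal round-robin over folds ordered by current load (random ties):
        # keeps per-fold bin counts within 1 and total fold sizes balanced
        fold_order <- order(load, sample.int(k))
        fold[idx] <- fold_order[((seq_along(idx) - 1L) %% k) + 1L]
        load <- load + tabulate(fold[idx], k)
      }
      for (f in seq_len(k)) {
        splits[[length(splits) + 1]] <- list(
          train = which(fold != f), test = which(fold == f),
          repeat_id = r, fold = f
        )
      }
    }
  })
  attr(splits, "bin") <- bin
  splits
}

#' Evaluate a GP dose-response model by stratified repeated CV
#'
#' For every split the model is fitted on the training fold and scored on the
#' test fold: NRMSE normalised by that test set's own target range, and the
#' mean Gaussian CRPS using the predictive standard deviation with noise.
#' Split-level NRMSE values are summarised by their mean and a percentile
#' bootstrap 95% interval. A full-data fit gives `full_nrmse`, and the
#' scrambled-target null ratio `full_nrmse / nrmse(scrambled)` measures how
#' much better the model fits real targets than shuffled ones (< 1 means
#' genuine signal). Test folds with zero target range are flagged and
#' excluded from the summaries, never silently dropped.
#'
#' @param data A data frame of samples.
#' @param target Name of the target column.
#' @param inputs Character vector of input columns (first one is the dose
#'   used for stratification). Default `"dose_uM"`.
#' @param scheme A [cv_scheme()].
#' @param config A [gp_config()]; each split uses a seed derived from it.
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param n_scrambles Scrambled-target refits averaged in the null ratio
#'   (default 1, seeded).
#' @return An object of class `pl_evaluation`.
#' @export
evaluate_model <- function(data, target, inputs = "dose_uM",
                           scheme = cv_scheme(), config = gp_config(),
                           n_boot = 1000, n_scrambles = 1) {
  missing_cols <- setdiff(c(target, inputs), names(data))
  if (length(missing_cols) > 0) {
    stop("evaluate_model: column(s) not found in `data`: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as_input_matrix(data[, inputs, drop = FALSE])
  y <- as.numeric(data[[target]])
  splits <- stratified_splits(data[[inputs[1]]], scheme)

  score_one <- function(s, i) {
    cfg <- config
    cfg$seed <- config$seed + i
    test_range <- diff(range(y[s$test]))
    if (test_range <= 0) {
      return(tibble::tibble(
        repeat_id = s$repeat_id, fold = s$fold, n_test = length(s$test),
        nrmse = NA_real_, crps = NA_real_, excluded = TRUE
      ))
    }
    fit <- fit_gp(X[s$train, , drop = FALSE], y[s$train], cfg)
    pr <- predict(fit, X[s$test, , drop = FALSE])
    tibble::tibble(
      repeat_id = s$repeat_id, fold = s$fold, n_test = length(s$test),
      nrmse = nrmse(pr$mean, y[s$test], test_range),
      crps = mean(crps_gaussian(pr$mean, pr$sd_with_noise, y[s$test])),
      excluded = FALSE
    )
  }
  per_split <- dplyr::bind_rows(purrr::imap(splits, score_one))

  valid <- per_split$nrmse[!per_split$excluded]
  mean_nrmse <- mean(valid)
  ci95 <- withr::with_seed(config$seed + 10000L, {
    boot_means <- vapply(seq_len(n_boot), function(b) {
      mean(sample(valid, replace = TRUE))
    }, numeric(1))
    unname(quantile(boot_means, c(0.025, 0.975)))
  })

  full_fit <- fit_gp(X, y, config)
  full_pred <- predict(full_fit, X)
  full_nrmse <- nrmse(full_pred$mean, y)

  null_nrmse <- withr::with_seed(config$seed + 20000L, {
    vapply(seq_len(n_scrambles), function(j) {
      ys <- sample(y)
      cfg <- config
      cfg$seed <- config$seed + 20000L + j
      f <- fit_gp(X, ys, cfg)
      pr <- predict(f, X)
      nrmse(pr$mean, ys)
    }, numeric(1))
  })
  null_ratio <- full_nrmse / mean(null_nrmse)

  structure(
    list(
      splits = per_split, mean_nrmse = mean_nrmse,
      mean_crps = mean(per_split$crps[!per_split$excluded]),
      ci95 = ci95, full_nrmse = full_nrmse,
      null_nrmse = mean(null_nrmse), null_ratio = null_ratio,
      n_excluded = sum(per_split$excluded),
      target = target, inputs = inputs, scheme = scheme, config = config,
      full_fit = full_fit
    ),
    class = "pl_evaluation"
  )
}

#' @export
print.pl_evaluation <- function(x, ...) {
  cat("<pl_evaluation>", x$target, "-", nrow(x$splits), "splits",
      sprintf("(%d excluded)\n", x$n_excluded))
  cat(sprintf("  mean NRMSE %.4f (95%% CI %.4f - %.4f), mean CRPS %.4g\n",
              x$mean_nrmse, x$ci95[1], x$ci95[2], x$mean_crps))
  cat(sprintf("  full NRMSE %.4f, scrambled-null ratio %.3f\n",
              x$full_nrmse, x$null_ratio))
  invisible(x)
}

#' Broom-style tidiers for evaluation reports
#'
#' `tidy()` returns the per-split scores; `glance()` the one-row summary.
#'
#' @param x A `pl_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.pl_evaluation <- function(x, ...) x$splits

#' @rdname tidy.pl_evaluation
#' @exportS3Method generics::glance
glance.pl_evaluation <- function(x, ...) {
  tibble::tibble(
    target = x$target, mean_nrmse = x$mean_nrmse, ci_lo = x$ci95[1],
    ci_hi = x$ci95[2], mean_crps = x$mean_crps, full_nrmse = x$full_nrmse,
    null_ratio = x$null_ratio, n_splits = nrow(x$splits),
    n_excluded = x$n_excluded
  )
}

#' Compare model variants on per-split NRMSE values
#'
#' Two variants are compared with a Student's t-test; three or more with a
#' one-way ANOVA plus Tukey HSD pairwise adjusted p-values. Percent
#' improvement is computed from the unrounded means as
#' `(mean_A - mean_B) / mean_A * 100` for each ordered pair (positive means
#' B improves on A).
#'
#' @param reports A named list of `pl_evaluation` objects or numeric vectors
#'   of per-split NRMSE values (equal lengths).
#' @return A tibble of class `pl_comparison`, one row per ordered pair, with
#'   attributes `method` and `anova_p` (for 3+ variants).
#' @export
compare_models <- function(reports) {
  vals <- lapply(reports, function(r) {
    if (inherits(r, "pl_evaluation")) r$splits$nrmse[!r$splits$excluded]
    else as.numeric(r)
  })
  if (length(vals) < 2) stop("compare_models: need >= 2 variants", call. = FALSE)
  if (length(unique(lengths(vals))) != 1) {
    stop("compare_models: variants have mismatched split counts", call. = FALSE)
  }
  if (is.null(names(vals))) names(vals) <- paste0("model", seq_along(vals))
  nm <- names(vals)
  means <- vapply(vals, mean, numeric(1))

  pairs <- utils::combn(nm, 2, simplify = FALSE)
  if (length(vals) == 2) {
    method <- "t-test"
    anova_p <- NA_real_
    pw <- purrr::map(pairs, function(p) {
      tt <- t.test(vals[[p[1]]], vals[[p[2]]])
      tibble::tibble(a = p[1], b = p[2], statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    })
  } else {
    method <- "anova+tukey"
    df <- data.frame(
      value = unlist(vals),
      variant = factor(rep(nm, lengths(vals)), levels = nm)
    )
    fit <- aov(value ~ variant, data = df)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$variant
    pw <- purrr::map(pairs, function(p) {
      row <- paste0(p[2], "-", p[1])
      alt <- paste0(p[1], "-", p[2])
      hit <- if (row %in% rownames(tk)) tk[row, ] else tk[alt, ]
      tibble::tibble(a = p[1], b = p[2], statistic = unname(hit["diff"]),
                     p_value = unname(hit["p adj"]))
    })
  }
  out <- dplyr::bind_rows(pw) %>%
    dplyr::mutate(
      mean_a = unname(means[.data$a]), mean_b = unname(means[.data$b]),
      improvement_pct = unname((means[.data$a] - means[.data$b]) /
        means[.data$a] * 100)
    )
  attr(out, "method") <- method
  attr(out, "anova_p") <- anova_p
  class(out) <- c("pl_comparison", class(out))
  out
}

#' Endpoint comparison across treatment groups
#'
#' One-way ANOVA over groups, Tukey HSD pairs against the control group, and
#' standardised mean differences (Cohen's d with pooled sd) of each treatment
#' versus control. With exactly two groups the test falls back to a Student's
#' t-test.
#'
#' @param data A data frame.
#' @param value Name of the response column.
#' @param group Name of the grouping column.
#' @param control Control group label.
#' @return A tibble (class `pl_comparison`) with one row per treatment
#'   group: n, mean, difference vs control, adjusted p, Cohen's d. Attributes
#'   `method` and `anova_p`.
#' @export
endpoint_comparison <- function(data, value, group, control) {
  missing_cols <- setdiff(c(value, group), names(data))
  if (length(missing_cols) > 0) {
    stop("endpoint_comparison: column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (!control %in% g) {
    stop("endpoint_comparison: control group not present", call. = FALSE)
  }
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop("endpoint_comparison: group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  lv <- c(control, setdiff(sort(unique(g)), control))
  gf <- factor(g, levels = lv)
  cohen_d <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    if (sp == 0) return(0)
    (mean(a) - mean(b)) / sp
  }
  ctrl_v <- v[g == control]
  treats <- lv[-1]

  if (length(lv) == 2) {
    tv <- v[g == treats]
    tt <- t.test(tv, ctrl_v)
    out <- tibble::tibble(
      group = treats, n = length(tv), mean = mean(tv),
      diff = mean(tv) - mean(ctrl_v), p_adj = tt$p.value,
      cohens_d = cohen_d(tv, ctrl_v)
    )
    attr(out, "method") <- "t-test"
    attr(out, "anova_p") <- NA_real_
  } else {
    fit <- aov(v ~ gf)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$gf
    rows <- purrr::map(treats, function(tr) {
      nm1 <- paste0(tr, "-", control); nm2 <- paste0(control, "-", tr)
      hit <- if (nm1 %in% rownames(tk)) tk[nm1, ] else {
        h <- tk[nm2, ]; h["diff"] <- -h["diff"]; h
      }
      tv <- v[g == tr]
      tibble::tibble(
        group = tr, n = length(tv), mean = mean(tv),
        diff = unname(hit["diff"]), p_adj = unname(hit["p adj"]),
        cohens_d = cohen_d(tv, ctrl_v)
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "method") <- "anova+tukey"
    attr(out, "anova_p") <- anova_p
  }
  attr(out, "control") <- control
  class(out) <- c("pl_comparison", class(out))
  out
}

#' MinMax scaling to the unit interval
#'
#' `(v - min) / (max - min)` computed globally or within groups.
#'
#' @param values Numeric vector.
#' @param groups Optional grouping vector of the same length; when supplied,
#'   scaling is performed within each group.
#' @return Scaled values in \[0, 1\].
#' @export
#' @examples
#' minmax_scale(c(0, 5, 10)) # 0, 0.5, 1
minmax_scale <- function(values, groups = NULL) {
  scale_one <- function(v) {
    rg <- range(v)
    if (diff(rg) <= 0) {
      stop("minmax_scale: zero range within a scaling scope", call. = FALSE)
    }
    (v - rg[1]) / diff(rg)
  }
  if (is.null(groups)) return(scale_one(values))
  out <- values
  for (g in unique(groups)) {
    sel <- groups == g
    out[sel] <- scale_one(values[sel])
  }
  out
}
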