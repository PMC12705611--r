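#' Smoothing and interpolation settings for daily series
#'
#' Savitzky-Golay smoothing on the observation sequence followed by cubic
#' spline interpolation onto integer days. The study defaults are window 7
#' with polyorder 3 for pixel-count features and polyorder 5 for health
#' fraction and NDVI.
#'
#' @param window_length Odd filter window (default 7).
#' @param polyorder Polynomial order, less than `window_length`.
#' @param days Integer days of the output series (default 4:25).
#' @return A list of class `smoothing_spec`.
#' @export
smoothing_spec <- function(window_length = 7, polyorder = 3, days = 4:25) {
  if (window_length %% 2 != 1) {
    stop("smoothing_spec: window_length must be odd", call. = FALSE)
  }
  if (polyorder >= window_length) {
    stop("smoothing_spec: polyorder must be < window_length", call. = FALSE)
  }
  structure(
    list(window_length = as.integer(window_length),
         polyorder = as.integer(polyorder), days = as.integer(days)),
    class = "smoothing_spec"
  )
}

#' Smooth irregular observations and interpolate to daily values
#'
#' Applies a Savitzky-Golay filter along the observation sequence, then a
#' cubic spline through the smoothed points evaluated at integer days. Days
#' outside the observed range are clamped to the first/last smoothed value
#' (no extrapolation).
#'
#' @param day Observation days (need not be consecutive).
#' @param value Observed values, same length as `day`.
#' @param spec A [smoothing_spec()].
#' @return A tibble with columns `day`, `value` (one row per day in
#'   `spec$days`).
#' @export
smooth_interpolate <- function(day, value, spec = smoothing_spec()) {
  if (length(day) != length(value)) {
    stop("smooth_interpolate: day and value must have equal length",
         call. = FALSE)
  }
  if (length(value) < spec$window_length) {
    stop("smooth_interpolate: fewer observations (", length(value),
         ") than the filter window (", spec$window_length,
         "); use a smaller window", call. = FALSE)
  }
  ord <- order(day)
  day <- day[ord]; value <- value[ord]
  sm <- signal::sgolayfilt(value, p = spec$polyorder, n = spec$window_length)
  f <- splinefun(day, sm, method = "fmm")
  d_out <- spec$days
  clamped <- pmin(pmax(d_out, min(day)), max(day))
  tibble::tibble(day = d_out, value = f(clamped))
}

#' Daily phenotype series for every plant
#'
#' Reduces the raw imaging observations to one value per plant, feature and
#' day -- `root_px` (root-scan pixel count), `shoot_px` (Euclidean norm of
#' the three shoot views), `health` (pixel-count-weighted mean health
#' fraction) and `ndvi` (mean over views) -- then smooths and interpolates
#' each series to integer days. Pixel features use polyorder 3; health and
#' NDVI use polyorder 5.
#'
#' @param observations Observation tibble (see [simulate_experiment()]).
#' @param window_length,days Passed to [smoothing_spec()].
#' @return A long tibble: `plant_id`, `feature`, `day`, `value`.
#' @export
daily_phenotypes <- function(observations, window_length = 7, days = 4:25) {
  per_day <- observations %>%
    dplyr::group_by(.data$plant_id, .data$day) %>%
    dplyr::summarise(
      root_px = .data$pixel_count[.data$modality == "root_scan"][1],
      shoot_px = euclidean_size(
        .data$pixel_count[.data$modality != "root_scan"]
      ),
      health = weighted_health(
        .data$health_fraction[.data$modality != "root_scan"],
        .data$pixel_count[.data$modality != "root_scan"]
      ),
      ndvi = mean(.data$mean_ndvi[.data$modality != "root_scan"]),
      .groups = "drop"
    ) %>%
    tidyr::pivot_longer(c("root_px", "shoot_px", "health", "ndvi"),
                        names_to = "feature", values_to = "value")

  polyorders <- c(root_px = 3, shoot_px = 3, health = 5, ndvi = 5)
  per_day %>%
    dplyr::group_by(.data$plant_id, .data$feature) %>%
    dplyr::group_modify(function(df, key) {
      spec <- smoothing_spec(window_length, polyorders[[key$feature]], days)
      smooth_interpolate(df$day, df$value, spec)
    }) %>%
    dplyr::ungroup()
}

#' Per-day Pearson correlation between dose and a daily feature
#'
#' For each feature and day, computes the Pearson correlation between dose
#' and the daily value across plants, with a percentile bootstrap confidence
#' interval obtained by resampling plants.
#'
#' @param daily Long daily tibble from [daily_phenotypes()].
#' @param plants Plant tibble with `plant_id` and `dose_uM`.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A tibble: `feature`, `day`, `r`, `ci_lo`, `ci_hi`.
#' @export
daily_correlation <- function(daily, plants, n_boot = 10000, seed = 1L,
                              conf = 0.95) {
  joined <- dplyr::inner_join(daily, plants[, c("plant_id", "dose_uM")],
                              by = "plant_id")
  alpha <- (1 - conf) / 2
  withr::with_seed(as.integer(seed), {
    joined %>%
      dplyr::group_by(.data$feature, .data$day) %>%
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        if (n < 3) stop("daily_correlation: need >= 3 plants per day",
                        call. = FALSE)
        if (sd(df$dose_uM) == 0 || sd(df$value) == 0) {
          stop("daily_correlation: zero variance on day ", key$day,
               call. = FALSE)
        }
        r <- cor(df$dose_uM, df$value)
        idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
        rb <- boot_cor(df$dose_uM, df$value, idx)
        tibble::tibble(
          r = r,
          ci_lo = unname(quantile(rb, alpha, na.rm = TRUE)),
          ci_hi = unname(quantile(rb, 1 - alpha, na.rm = TRUE))
        )
      }) %>%
      dplyr::ungroup()
  })
}

# vectorised bootstrap Pearson correlation; idx is n_boot x n
boot_cor <- function(x, y, idx) {
  xb <- matrix(x[idx], nrow = nrow(idx))
  yb <- matrix(y[idx], nrow = nrow(idx))
  n <- ncol(idx)
  mx <- rowMeans(xb); my <- rowMeans(yb)
  sxy <- rowSums(xb * yb) / n - mx * my
  sxx <- rowSums(xb * xb) / n - mx^2
  syy <- rowSums(yb * yb) / n - my^2
  out <- sxy / sqrt(sxx * syy)
  out[sxx <= 0 | syy <= 0] <- NA_real_
  out
}

#' Per-day dose-versus-control significance screen
#'
#' For each feature and day runs a one-way ANOVA across dose groups followed
#' by Tukey HSD; only contrasts involving the control dose are retained, and
#' Benjamini-Hochberg correction is applied across the retained
#' (day x dose) family within each feature. Comparisons are flagged at
#' `p_adj < alpha`.
#'
#' @param daily Long daily tibble from [daily_phenotypes()].
#' @param plants Plant tibble with `plant_id`, `dose_uM`.
#' @param control_dose Control dose (default 0).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @param day_window Days screened; defaults to the post-amendment window
#'   c(11, 25), where dose effects can exist.
#' @return A tibble: `feature`, `day`, `dose_uM`, `diff`, `p_tukey`,
#'   `p_adj`, `significant`.
#' @export
daily_dose_tests <- function(daily, plants, control_dose = 0, alpha = 0.05,
                             day_window = c(11, 25)) {
  joined <- dplyr::inner_join(daily, plants[, c("plant_id", "dose_uM")],
                              by = "plant_id") %>%
    dplyr::filter(.data$day >= day_window[1], .data$day <= day_window[2])
  if (!control_dose %in% joined$dose_uM) {
    stop("daily_dose_tests: control dose arm missing", call. = FALSE)
  }
  res <- joined %>%
    dplyr::group_by(.data$feature, .data$day) %>%
    dplyr::group_modify(function(df, key) {
      gf <- factor(df$dose_uM)
      if (nlevels(gf) < 2) return(tibble::tibble())
      fit <- aov(df$value ~ gf)
      tk <- TukeyHSD(fit)$gf
      prs <- strsplit(rownames(tk), "-", fixed = TRUE)
      keep <- vapply(prs, function(p) control_dose %in% as.numeric(p),
                     logical(1))
      if (!any(keep)) return(tibble::tibble())
      other <- vapply(prs[keep], function(p) {
        setdiff(as.numeric(p), control_dose)[1]
      }, numeric(1))
      tibble::tibble(
        dose_uM = other,
        diff = unname(tk[keep, "diff"]),
        p_tukey = unname(tk[keep, "p adj"])
      )
    }) %>%
    dplyr::ungroup()
  res %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::mutate(p_adj = p.adjust(.data$p_tukey, method = "BH")) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(significant = .data$p_adj < alpha)
}

#' First day a dose becomes significantly different from control
#'
#' @param tests Output of [daily_dose_tests()].
#' @return A tibble `feature`, `dose_uM`, `first_day` (NA if never
#'   significant).
#' @export
first_significant_day <- function(tests) {
  tests %>%
    dplyr::group_by(.data$feature, .data$dose_uM) %>%
    dplyr::summarise(
      first_day = if (any(.data$significant)) {
        min(.data$day[.data$significant])
      } else NA_integer_,
      .groups = "drop"
    )
}

#' Assemble the plants x (feature x day) trajectory matrix
#'
#' Each feature is MinMax-scaled globally across all plants and days in the
#' window, then the per-day columns of the features are concatenated. With
#' the default 3 features and days 11--25 the matrix has 45 columns. Row
#' order is stable by `plant_id`.
#'
#' @param daily Long daily tibble from [daily_phenotypes()].
#' @param day_window Two-element day window (default c(11, 25), the exposure
#'   period).
#' @param features Features to include.
#' @return A numeric matrix in \[0, 1\] with plants as (named) rows.
#' @export
build_trajectory_matrix <- function(daily, day_window = c(11, 25),
                                    features = c("root_px", "shoot_px",
                                                 "health")) {
  sub <- daily %>%
    dplyr::filter(.data$feature %in% features,
                  .data$day >= day_window[1], .data$day <= day_window[2])
  counts <- sub %>%
    dplyr::count(.data$plant_id, .data$feature)
  expected <- day_window[2] - day_window[1] + 1
  bad <- counts$plant_id[counts$n != expected]
  full <- table(counts$plant_id)
  missing_feat <- names(full)[full != length(features)]
  if (length(missing_feat) > 0 || length(bad) > 0) {
    stop("build_trajectory_matrix: plant(s) missing a feature or days: ",
         paste(unique(c(missing_feat, bad)), collapse = ", "), call. = FALSE)
  }
  scaled <- sub %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::mutate(value = minmax_scale(.data$value)) %>%
    dplyr::ungroup()
  wide <- scaled %>%
    dplyr::mutate(col = paste0(.data$feature, "_d", .data$day)) %>%
    dplyr::select("plant_id", "col", "value") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "value") %>%
    dplyr::arrange(.data$plant_id)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$plant_id
  ord <- as.vector(outer(day_window[1]:day_window[2], features,
                         function(d, f) paste0(f, "_d", d)))
  m[, ord, drop = FALSE]
}
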