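#' Latent logistic growth under ramped dose inhibition
#'
#' Solves dS/dt = r S (1 - S/K) I(d, t) in closed form. The inhibition factor
#' I equals 1 before the amendment day, ramps linearly over `lag` days to its
#' Hill asymptote 1 / (1 + (d / ec50)^hill), and stays there. Writing the
#' logistic in logit form makes S depend only on the time-integral of I, which
#' is piecewise polynomial, so no numerical integration is needed.
#'
#' @param t Numeric vector of days.
#' @param dose Dose in uM.
#' @param r Growth rate (1/day).
#' @param K Carrying capacity.
#' @param s0 Initial size at day 0.
#' @param ec50,hill Hill inhibition parameters.
#' @param lag Ramp duration in days.
#' @param t0 Amendment day.
#' @return Latent sizes at `t`.
#' @export
#' @examples
#' latent_size(0:25, dose = 0, r = 0.4, K = 1, s0 = 0.001,
#'             ec50 = 50, hill = 1.5, lag = 1, t0 = 10)
latent_size <- function(t, dose, r, K, s0, ec50, hill, lag, t0) {
  i_inf <- 1 / (1 + (dose / ec50)^hill)
  J <- integrated_inhibition(t, i_inf, lag, t0)
  K / (1 + (K / s0 - 1) * exp(-r * J))
}

# time-integral of the ramped inhibition factor
integrated_inhibition <- function(t, i_inf, lag, t0) {
  drop_ <- 1 - i_inf
  vapply(t, function(tt) {
    if (tt <= t0) return(tt)
    if (lag > 0 && tt <= t0 + lag) {
      u <- tt - t0
      return(t0 + u - drop_ * u^2 / (2 * lag))
    }
    ramp_area <- if (lag > 0) t0 + lag * (1 + i_inf) / 2 else t0
    ramp_area + i_inf * (tt - t0 - lag)
  }, numeric(1))
}

# health fraction: saturating decline after amendment + lag, with its own
# Hill dose dependence
latent_health <- function(t, dose, baseline, ec50, hill, lag, t0, tau) {
  level <- 1 - 1 / (1 + (dose / ec50)^hill)
  g <- 1 - exp(-pmax(0, t - t0 - lag) / tau)
  baseline * (1 - level * g)
}

#' Simulate a virtual dose-stress phenotyping experiment
#'
#' Generates one experimental round: per-plant harvest fresh weights and a
#' full imaging record (one root scan plus three shoot views per scheduled
#' day), driven by dose-inhibited logistic growth with per-plant lognormal
#' size multipliers and multiplicative observation noise. The generating
#' parameters and the noiseless daily latent trajectories are returned so
#' parameter-recovery tests need no re-derivation.
#'
#' @param design A [dose_design()] tibble.
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical (design, params, seed) give identical
#'   studies.
#' @return An object of class `ecobot_study`: a list with tibbles `plants`
#'   (plant_id, round_id, dose_uM, fw_root_g, fw_shoot_g, excluded, reason),
#'   `observations` (plant_id, round_id, dose_uM, day, modality, pixel_count,
#'   health_fraction, mean_ndvi) and `truth` (noiseless daily latent root and
#'   shoot sizes and health per plant), plus the `params`, `design` and
#'   `seed` used.
#' @export
#' @examples
#' study <- simulate_experiment(dose_design(c(0, 100)), sim_params(), seed = 1)
#' nrow(study$plants)
simulate_experiment <- function(design, params = sim_params(), seed = 1L) {
  stopifnot(inherits(design, "dose_design"))
  validate_sim_params(params)
  if (any(design$n_replicates < 1)) {
    stop("simulate_experiment: replicate counts must be positive", call. = FALSE)
  }
  if (any(params$schedule < 4 | params$schedule > 25)) {
    stop("simulate_experiment: imaging schedule must lie within [4, 25]",
         call. = FALSE)
  }

  p <- params
  doses <- rep(design$dose_uM, design$n_replicates)
  round_id <- rep(design$round_id, design$n_replicates)
  n <- length(doses)
  plant_id <- sprintf("R%d_P%02d", round_id, seq_len(n))
  days <- sort(unique(p$schedule))
  truth_days <- 4:25

  em <- p$endmembers
  bands <- band_windows()
  ndvi_green <- ndvi_pixel(em$green, em$wavelength, bands)
  ndvi_brown <- ndvi_pixel(em$brown, em$wavelength, bands)

  withr::with_seed(as.integer(seed), {
    mult <- exp(rnorm(n, 0, p$plant_cv))
    excluded <- runif(n) < p$dropout_rate
    reason <- ifelse(excluded, "failed germination", "")

    traj <- purrr::map(seq_len(n), function(i) {
      s_root <- mult[i] * latent_size(
        truth_days, doses[i], p$growth_rate, p$k_root, p$s0_frac * p$k_root,
        p$ec50_root, p$hill_root, p$onset_lag_root, p$amendment_day
      )
      s_shoot <- mult[i] * latent_size(
        truth_days, doses[i], p$growth_rate, p$k_shoot, p$s0_frac * p$k_shoot,
        p$ec50_shoot, p$hill_shoot, p$onset_lag_shoot, p$amendment_day
      )
      health <- latent_health(
        truth_days, doses[i], p$health_baseline, p$ec50_health, p$hill_health,
        p$onset_lag_health, p$amendment_day, p$health_tau
      )
      tibble::tibble(
        plant_id = plant_id[i], day = truth_days,
        s_root = s_root, s_shoot = s_shoot, health = health
      )
    })
    truth <- dplyr::bind_rows(traj)

    obs <- purrr::map(seq_len(n), function(i) {
      tr <- traj[[i]]
      idx <- match(days, tr$day)
      s_root <- tr$s_root[idx]
      s_shoot <- tr$s_shoot[idx]
      health <- tr$health[idx]
      nd <- length(days)

      root_px <- p$gain_root * s_root * exp(rnorm(nd, 0, p$obs_noise_cv))
      views <- names(p$view_gains)
      shoot <- purrr::map(views, function(v) {
        px <- p$view_gains[[v]] * s_shoot * exp(rnorm(nd, 0, p$obs_noise_cv))
        hf <- pmin(pmax(health + rnorm(nd, 0, p$health_noise_sd), 0), 1)
        nv <- ndvi_brown + health * (ndvi_green - ndvi_brown) +
          rnorm(nd, 0, p$ndvi_noise_sd)
        tibble::tibble(
          plant_id = plant_id[i], day = days,
          modality = paste0("shoot_", v),
          pixel_count = px, health_fraction = hf, mean_ndvi = nv
        )
      })
      dplyr::bind_rows(
        tibble::tibble(
          plant_id = plant_id[i], day = days, modality = "root_scan",
          pixel_count = root_px, health_fraction = NA_real_,
          mean_ndvi = NA_real_
        ),
        dplyr::bind_rows(shoot)
      )
    })
    observations <- dplyr::bind_rows(obs) %>%
      dplyr::mutate(
        round_id = rep(round_id, each = length(days) * 4)[seq_len(dplyr::n())],
        dose_uM = rep(doses, each = length(days) * 4)[seq_len(dplyr::n())]
      ) %>%
      dplyr::select("plant_id", "round_id", "dose_uM", "day", "modality",
                    "pixel_count", "health_fraction", "mean_ndvi")

    s_root_final <- vapply(traj, function(tr) tr$s_root[tr$day == 25], 0)
    s_shoot_final <- vapply(traj, function(tr) tr$s_shoot[tr$day == 25], 0)
    fw_root <- p$a_root * s_root_final * exp(rnorm(n, 0, p$fw_noise_cv))
    fw_shoot <- p$a_shoot * s_shoot_final * exp(rnorm(n, 0, p$fw_noise_cv))

    plants <- tibble::tibble(
      plant_id = plant_id, round_id = round_id, dose_uM = doses,
      fw_root_g = fw_root, fw_shoot_g = fw_shoot,
      excluded = excluded, reason = reason
    )

    structure(
      list(
        plants = plants, observations = observations, truth = truth,
        params = p, design = design, seed = as.integer(seed)
      ),
      class = "ecobot_study"
    )
  })
}

#' @export
print.ecobot_study <- function(x, ...) {
  cat("<ecobot_study> round(s)", paste(unique(x$plants$round_id), collapse = ","),
      "-", nrow(x$plants), "plants,", nrow(x$observations), "observations\n")
  cat("  doses (uM):", paste(sort(unique(x$plants$dose_uM)), collapse = ", "), "\n")
  invisible(x)
}

#' Build a small synthetic hyperspectral cube with a plant mask
#'
#' Each in-mask pixel is either green-dominant (mixture weight w = 1) or
#' brown-dominant (w = 0); its spectrum is w * green + (1 - w) * brown plus
#' Gaussian spectral noise. The number of green-dominant pixels equals
#' `round(green_fraction * n_mask)` exactly, with positions shuffled under
#' the seed. Wavelengths are restricted to the retained 430--800 nm grid.
#'
#' @param n_rows,n_cols Spatial dimensions.
#' @param green_fraction Target fraction of green-dominant in-mask pixels.
#' @param params A [sim_params()] object (endmembers, `cube_noise_sd`).
#' @param seed Integer seed.
#' @param mask Logical matrix of in-mask pixels; defaults to all `TRUE`.
#' @return A list of class `hs_cube`: `cube` (rows x cols x bands array),
#'   `wavelengths`, `mask`, and `w` (the per-pixel mixture weights, `NA`
#'   off-mask).
#' @export
#' @examples
#' cube <- make_cube(8, 8, green_fraction = 0.5, seed = 1)
#' dim(cube$cube)
make_cube <- function(n_rows, n_cols, green_fraction, params = sim_params(),
                      seed = 1L, mask = NULL) {
  if (green_fraction < 0 || green_fraction > 1) {
    stop("make_cube: green_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, n_rows, n_cols)
  if (!any(mask)) stop("make_cube: mask is empty", call. = FALSE)
  em <- params$endmembers
  wl <- em$wavelength
  idx <- which(mask)
  n_in <- length(idx)
  n_green <- round(green_fraction * n_in)

  withr::with_seed(as.integer(seed), {
    green_idx <- sample(idx, n_green)
    w <- matrix(NA_real_, n_rows, n_cols)
    w[idx] <- 0
    w[green_idx] <- 1

    cube <- array(0, dim = c(n_rows, n_cols, length(wl)))
    noise <- array(rnorm(n_rows * n_cols * length(wl), 0, params$cube_noise_sd),
                   dim = dim(cube))
    for (b in seq_along(wl)) {
      plane <- w * em$green[b] + (1 - w) * em$brown[b]
      plane[is.na(plane)] <- 0
      cube[, , b] <- pmin(pmax(plane + noise[, , b] * as.numeric(mask), 0), 1)
    }
    structure(
      list(cube = cube, wavelengths = wl, mask = mask, w = w),
      class = "hs_cube"
    )
  })
}
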