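#' Default reflectance endmembers on the retained wavelength grid
#'
#' Smooth parametric reflectance curves for photosynthetically active
#' ("green") and senescent ("brown") shoot tissue on the 430--800 nm grid the
#' imaging pipeline retains. The green endmember has the classic green-peak /
#' red-trough / red-edge shape; the brown endmember rises gently with
#' wavelength and lacks the red edge.
#'
#' @param step Grid spacing in nm (default 5).
#' @return A tibble with columns `wavelength`, `green`, `brown`.
#' @export
#' @examples
#' em <- default_endmembers()
#' range(em$wavelength)
default_endmembers <- function(step = 5) {
  wl <- seq(430, 800, by = step)
  # green: low blue, bump at 550, chlorophyll trough at 675, steep red edge
  green <- 0.04 +
    0.11 * exp(-((wl - 552) / 38)^2) -
    0.025 * exp(-((wl - 675) / 22)^2) +
    0.46 / (1 + exp(-(wl - 715) / 14))
  # brown: monotone rise, no red edge
  brown <- 0.08 + 0.28 / (1 + exp(-(wl - 630) / 90))
  tibble::tibble(
    wavelength = wl,
    green = pmin(pmax(green, 0), 1),
    brown = pmin(pmax(brown, 0), 1)
  )
}

#' Simulation parameters for a virtual dose-stress phenotyping experiment
#'
#' Bundles the generative parameters of the virtual experiment: logistic
#' growth, dose-dependent growth-rate inhibition (Hill curves with phenotype
#' specific EC50s, onset lags ramping in after the amendment day), per-plant
#' size variability, multiplicative observation noise, pixel/weight
#' conversion gains and the imaging schedule.
#'
#' The default parameterisation mirrors the phenomenology of copper-stressed
#' *Brachypodium distachyon* in fabricated-ecosystem chambers: roots are the
#' most sensitive phenotype (EC50 50 uM), shoot size intermediate (105 uM),
#' shoot health least sensitive (300 uM); the stressor is amended on day 10
#' and imaging runs roughly every other day from day 4 to day 25.
#'
#' @param growth_rate Logistic growth rate r (1/day).
#' @param k_root,k_shoot Carrying capacities in latent size units.
#' @param s0_frac Initial size at day 0 as a fraction of capacity.
#' @param ec50_root,ec50_shoot,ec50_health Half-maximal inhibition doses (uM).
#' @param hill_root,hill_shoot,hill_health Hill exponents of the inhibition
#'   curves.
#' @param onset_lag_root,onset_lag_shoot,onset_lag_health Days over which the
#'   inhibition ramps in linearly after the amendment day.
#' @param amendment_day Day the stressor is added (default 10).
#' @param health_tau Time constant (days) of the saturating health decline.
#' @param plant_cv Log-scale standard deviation of the per-plant lognormal
#'   growth multiplier.
#' @param obs_noise_cv Relative standard deviation of pixel-count
#'   observation noise (multiplicative lognormal).
#' @param fw_noise_cv Relative standard deviation of harvest fresh-weight
#'   noise (blot-dry weighing of mg-scale tissue is noisier than imaging).
#' @param a_root,a_shoot Grams of fresh weight per latent size unit.
#' @param gain_root Root-scan pixels per latent size unit.
#' @param view_gains Named numeric vector of shoot pixels per latent size
#'   unit for the `top`, `side` and `front` camera views.
#' @param schedule Integer imaging days, all within day 4 to 25.
#' @param health_baseline Health fraction of an unstressed plant.
#' @param health_noise_sd Additive noise sd of per-view health fractions.
#' @param ndvi_noise_sd Additive noise sd of per-view mean NDVI.
#' @param cube_noise_sd Spectral noise sd used by [make_cube()].
#' @param endmembers Tibble from [default_endmembers()] (wavelength, green,
#'   brown).
#' @param dropout_rate Probability a plant is excluded (failed germination
#'   etc.); 0 by default.
#' @param seed Default seed carried with the parameter set.
#' @return An object of class `sim_params` (a named list).
#' @seealso [simulate_experiment()], [make_cube()]
#' @export
#' @examples
#' p <- sim_params()
#' p$ec50_root < p$ec50_shoot
sim_params <- function(growth_rate = 0.4,
                       k_root = 1,
                       k_shoot = 1.2,
                       s0_frac = 0.001,
                       ec50_root = 50,
                       ec50_shoot = 105,
                       ec50_health = 300,
                       hill_root = 1.5,
                       hill_shoot = 3.5,
                       hill_health = 5,
                       onset_lag_root = 1,
                       onset_lag_shoot = 3,
                       onset_lag_health = 5,
                       amendment_day = 10,
                       health_tau = 3,
                       plant_cv = 0.2,
                       obs_noise_cv = 0.15,
                       fw_noise_cv = 0.40,
                       a_root = 0.025,
                       a_shoot = 0.06,
                       gain_root = 25000,
                       view_gains = c(top = 20000, side = 12000, front = 12000),
                       schedule = c(seq(4, 24, by = 2), 25),
                       health_baseline = 0.97,
                       health_noise_sd = 0.03,
                       ndvi_noise_sd = 0.02,
                       cube_noise_sd = 0.01,
                       endmembers = default_endmembers(),
                       dropout_rate = 0,
                       seed = 1L) {
  p <- list(
    growth_rate = growth_rate, k_root = k_root, k_shoot = k_shoot,
    s0_frac = s0_frac,
    ec50_root = ec50_root, ec50_shoot = ec50_shoot, ec50_health = ec50_health,
    hill_root = hill_root, hill_shoot = hill_shoot, hill_health = hill_health,
    onset_lag_root = onset_lag_root, onset_lag_shoot = onset_lag_shoot,
    onset_lag_health = onset_lag_health,
    amendment_day = amendment_day, health_tau = health_tau,
    plant_cv = plant_cv, obs_noise_cv = obs_noise_cv,
    fw_noise_cv = fw_noise_cv,
    a_root = a_root, a_shoot = a_shoot, gain_root = gain_root,
    view_gains = view_gains, schedule = as.integer(schedule),
    health_baseline = health_baseline, health_noise_sd = health_noise_sd,
    ndvi_noise_sd = ndvi_noise_sd, cube_noise_sd = cube_noise_sd,
    endmembers = endmembers, dropout_rate = dropout_rate,
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

#' @rdname sim_params
#' @export
default_params <- function() sim_params()

validate_sim_params <- function(p) {
  pos <- c(
    "growth_rate", "k_root", "k_shoot", "s0_frac", "ec50_root", "ec50_shoot",
    "ec50_health", "hill_root", "hill_shoot", "hill_health", "a_root",
    "a_shoot", "gain_root", "health_tau"
  )
  for (f in pos) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
      stop("sim_params: `", f, "` must be strictly positive", call. = FALSE)
    }
  }
  if (any(p$view_gains <= 0)) stop("sim_params: view_gains must be positive",
                                   call. = FALSE)
  if (p$plant_cv < 0 || p$obs_noise_cv < 0 || p$fw_noise_cv < 0) {
    stop("sim_params: noise scales must be nonnegative", call. = FALSE)
  }
  if (!(p$ec50_root < p$ec50_shoot && p$ec50_shoot < p$ec50_health)) {
    stop("sim_params: expected sensitivity ordering ec50_root < ec50_shoot < ec50_health",
         call. = FALSE)
  }
  if (any(p$schedule < 4) || any(p$schedule > 25)) {
    stop("sim_params: schedule days must lie within [4, 25]", call. = FALSE)
  }
  em <- p$endmembers
  if (any(em$green < 0 | em$green > 1 | em$brown < 0 | em$brown > 1)) {
    stop("sim_params: endmember reflectances must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Dose design for one experimental round
#'
#' @param doses Numeric doses in uM, each in \[0, 500\].
#' @param n_replicates Replicates per dose arm; recycled to `length(doses)`.
#' @param round_id Integer round identifier.
#' @return A tibble with class `dose_design` and columns `round_id`,
#'   `dose_uM`, `n_replicates`.
#' @export
#' @examples
#' dose_design() # the standard 7-dose round-1 design
dose_design <- function(doses = c(0, 25, 50, 100, 200, 300, 500),
                        n_replicates = 6,
                        round_id = 1L) {
  if (any(doses < 0 | doses > 500)) {
    stop("dose_design: doses must lie in [0, 500] uM", call. = FALSE)
  }
  n_replicates <- rep_len(as.integer(n_replicates), length(doses))
  if (any(n_replicates < 1)) {
    stop("dose_design: n_replicates must be >= 1", call. = FALSE)
  }
  out <- tibble::tibble(
    round_id = as.integer(round_id),
    dose_uM = as.numeric(doses),
    n_replicates = n_replicates
  )
  class(out) <- c("dose_design", class(out))
  out
}

#' Serialize simulation parameters to YAML
#'
#' Endmember spectra are stored as parallel lists so the file round-trips.
#'
#' @param params A [sim_params()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_sim_params <- function(params, path) {
  p <- unclass(params)
  p$endmembers <- as.list(params$endmembers)
  p$view_gains <- as.list(params$view_gains)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  p <- yaml::read_yaml(path)
  p$endmembers <- tibble::as_tibble(lapply(p$endmembers, unlist))
  p$view_gains <- unlist(p$view_gains)
  do.call(sim_params, p)
}
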