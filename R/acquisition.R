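#' Acquisition request for variance-based Bayesian optimisation
#'
#' @param n_points Number of new doses to propose (default 5).
#' @param domain Dose domain in uM (default \[0, 500\]).
#' @param grid_step Grid resolution in uM (default 1; proposals are
#'   grid-aligned integers).
#' @param min_separation Minimum distance between proposed doses in uM
#'   (default 20, to avoid replicate-adjacent proposals).
#' @param seed Carried for provenance; the acquisition itself is
#'   deterministic.
#' @return A list of class `acquisition_request`.
#' @export
acquisition_request <- function(n_points = 5, domain = c(0, 500),
                                grid_step = 1, min_separation = 20,
                                seed = 1L) {
  if (n_points < 1) stop("acquisition_request: n_points must be >= 1",
                         call. = FALSE)
  if (min_separation < grid_step) {
    stop("acquisition_request: min_separation must be >= grid_step",
         call. = FALSE)
  }
  structure(
    list(n_points = as.integer(n_points), domain = domain,
         grid_step = grid_step, min_separation = min_separation,
         seed = as.integer(seed)),
    class = "acquisition_request"
  )
}

#' Propose new doses by greedy posterior-variance acquisition
#'
#' Greedy sequential selection on the prediction grid: pick the grid point
#' with maximal posterior epistemic variance, excise its `min_separation`
#' neighbourhood, and repeat `n_points` times. The posterior is not
#' re-conditioned between picks. Exact variance ties break toward the lower
#' dose, so a data-free prior model yields the successive lowest admissible
#' grid points.
#'
#' @param model A fitted `pl_gp` model (or a prior [gp_model()]).
#' @param request An [acquisition_request()].
#' @return Sorted numeric vector of proposed doses with attribute
#'   `variance_grid`, a tibble of the full (dose, sd_epistemic) audit grid.
#' @export
#' @examples
#' m <- gp_model(1, 50, 0.01) # prior model, flat variance
#' propose_doses(m, acquisition_request(n_points = 3))
propose_doses <- function(model, request = acquisition_request()) {
  dom <- request$domain
  if (diff(dom) < request$n_points * request$min_separation) {
    stop("propose_doses: domain narrower than n_points * min_separation",
         call. = FALSE)
  }
  grid <- seq(dom[1], dom[2], by = request$grid_step)
  post <- predict(model, grid)
  v <- signif(post$sd_epistemic^2, 10)  # blunt float dust so ties are exact
  admissible <- rep(TRUE, length(grid))
  picks <- numeric(request$n_points)
  for (j in seq_len(request$n_points)) {
    if (!any(admissible)) {
      stop("propose_doses: admissible grid exhausted", call. = FALSE)
    }
    idx <- which(admissible)[which.max(v[admissible])]  # first max = lower dose
    picks[j] <- grid[idx]
    admissible <- admissible & abs(grid - grid[idx]) >= request$min_separation
  }
  out <- sort(picks)
  attr(out, "variance_grid") <- tibble::tibble(
    dose = grid, sd_epistemic = post$sd_epistemic
  )
  out
}
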