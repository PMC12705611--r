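#' Configuration for Gaussian-process dose-response fits
#'
#' The model uses a stationary ARD kernel (one lengthscale per input
#' dimension) with a single fitted constant noise variance. Hyperparameters
#' are chosen by maximising the log marginal likelihood with a seeded
#' stochastic search over log-hyperparameters (greedy acceptance, annealed
#' step size, occasional uniform restarts) followed by box-constrained
#' local refinement. Lengthscale bounds per dimension are
#' `[0.01 * span, 5 * span]` of the observed input values.
#'
#' @param kernel `"sqexp"` (squared exponential, default) or `"matern32"`.
#' @param max_iterations Stochastic-search iterations. 2000 by default for
#'   desk-scale runs; raise to 10000--25000 for production fits.
#' @param seed Integer seed; fits are reproducible given the seed.
#' @param lengthscale_rule Multipliers of the per-dimension input span giving
#'   the lower and upper lengthscale bounds.
#' @param grid Default prediction grid (doses 0--500 uM in steps of 1).
#' @return A list of class `gp_config`.
#' @export
gp_config <- function(kernel = c("sqexp", "matern32"),
                      max_iterations = 2000,
                      seed = 1L,
                      lengthscale_rule = c(0.01, 5),
                      grid = seq(0, 500, by = 1)) {
  kernel <- match.arg(kernel)
  if (max_iterations < 1) stop("gp_config: max_iterations must be >= 1",
                               call. = FALSE)
  if (any(lengthscale_rule <= 0) || lengthscale_rule[1] >= lengthscale_rule[2]) {
    stop("gp_config: lengthscale_rule must be increasing and positive",
         call. = FALSE)
  }
  structure(
    list(kernel = kernel, max_iterations = as.integer(max_iterations),
         seed = as.integer(seed), lengthscale_rule = lengthscale_rule,
         grid = grid),
    class = "gp_config"
  )
}

kernel_code <- function(kernel) if (kernel == "matern32") 1L else 0L

as_input_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Fit a Gaussian-process regression of a phenotype on dose
#'
#' Maximises the log marginal likelihood of an ARD-kernel GP with constant
#' noise over (signal variance, per-dimension lengthscales, noise variance),
#' within bounds derived from the data: lengthscales within
#' `lengthscale_rule` times the observed span of each input, variances
#' relative to the target variance. The prior mean is the training-target
#' mean. The seeded search guarantees the fitted log marginal likelihood is
#' at least that of its starting point.
#'
#' @param X Inputs: numeric vector, matrix or data frame (dose in uM, plus
#'   optional covariates).
#' @param y Numeric targets (fresh weight in g, or scaled pixel counts).
#' @param config A [gp_config()].
#' @return An object of class `pl_gp` with elements `theta` (named natural
#'   scale hyperparameters), `logtheta`, `bounds`, `X`, `y`, `prior_mean`,
#'   `log_marginal`, `config`.
#' @export
#' @examples
#' fit <- fit_gp(c(0, 100, 200, 400), c(1, 0.8, 0.4, 0.1),
#'               gp_config(max_iterations = 200))
#' fit$theta
fit_gp <- function(X, y, config = gp_config()) {
  X <- as_input_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("fit_gp: nrow(X) != length(y)", call. = FALSE)
  if (nrow(X) < 2) stop("fit_gp: need at least 2 training points", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("fit_gp: inputs and targets must be finite", call. = FALSE)
  }
  d <- ncol(X)
  spans <- apply(X, 2, function(v) diff(range(v)))
  if (any(spans == 0)) {
    stop("fit_gp: input column(s) ",
         paste(colnames(X)[spans == 0], collapse = ", "),
         " are constant; the lengthscale bounds rule degenerates",
         call. = FALSE)
  }
  vy <- max(var(y), 1e-12)
  lower <- log(c(1e-3 * vy, config$lengthscale_rule[1] * spans, 1e-6 * vy))
  upper <- log(c(1e2 * vy, config$lengthscale_rule[2] * spans, 2 * vy))
  prior_mean <- mean(y)
  kc <- kernel_code(config$kernel)
  nll <- function(lt) gp_nll_cpp(lt, X, y, prior_mean, kc)

  start <- (lower + upper) / 2
  init_nll <- nll(start)
  sr <- withr::with_seed(config$seed, {
    gp_search_cpp(start, lower, upper, config$max_iterations, X, y,
                  prior_mean, kc)
  })
  best <- as.numeric(sr$par)
  best_nll <- sr$value
  ref <- tryCatch(
    optim(best, nll, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 200)),
    error = function(e) NULL
  )
  if (!is.null(ref) && is.finite(ref$value) && ref$value < best_nll) {
    best <- ref$par
    best_nll <- ref$value
  }

  theta <- exp(best)
  names(theta) <- c("signal_var", paste0("lengthscale_", colnames(X)),
                    "noise_var")
  structure(
    list(theta = theta, logtheta = best,
         bounds = cbind(lower = lower, upper = upper),
         X = X, y = y, prior_mean = prior_mean,
         log_marginal = -best_nll, log_marginal_init = -init_nll,
         config = config),
    class = "pl_gp"
  )
}

#' Construct a GP model directly from hyperparameters
#'
#' Useful for prior models (no training data) and for tests against
#' closed-form oracles at fixed hyperparameters.
#'
#' @param signal_var,lengthscales,noise_var Natural-scale hyperparameters.
#' @param X,y Optional training data (may be empty for a prior model).
#' @param prior_mean Constant prior mean.
#' @param config A [gp_config()].
#' @return A `pl_gp` object.
#' @export
gp_model <- function(signal_var, lengthscales, noise_var,
                     X = NULL, y = NULL, prior_mean = 0,
                     config = gp_config()) {
  d <- length(lengthscales)
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = 0, ncol = d,
                dimnames = list(NULL, paste0("x", seq_len(d))))
    y <- numeric(0)
  } else {
    X <- as_input_matrix(X)
    y <- as.numeric(y)
  }
  theta <- c(signal_var, lengthscales, noise_var)
  names(theta) <- c("signal_var", paste0("lengthscale_", colnames(X)),
                    "noise_var")
  structure(
    list(theta = theta, logtheta = log(theta), bounds = NULL,
         X = X, y = y, prior_mean = prior_mean, log_marginal = NA_real_,
         config = config),
    class = "pl_gp"
  )
}

#' Posterior summary of a fitted GP on a dose grid
#'
#' Returns the posterior mean, the epistemic standard deviation (without
#' observation noise) and the predictive standard deviation with noise,
#' `sqrt(sd_epistemic^2 + noise_var)`, at each grid point.
#'
#' @param object A `pl_gp` model.
#' @param grid Numeric vector (single input) or matrix/data frame of new
#'   inputs; defaults to the config grid (0--500 uM step 1).
#' @param ... Unused.
#' @return A tibble of class `pl_gp_posterior` with the grid columns plus
#'   `mean`, `sd_epistemic`, `sd_with_noise`.
#' @export
predict.pl_gp <- function(object, grid = NULL, ...) {
  d <- ncol(object$X)
  if (is.null(grid)) {
    if (d != 1) stop("predict.pl_gp: supply a grid for multi-input models",
                     call. = FALSE)
    grid <- object$config$grid
  }
  Xs <- as_input_matrix(grid)
  if (ncol(Xs) != d) stop("predict.pl_gp: grid has wrong number of columns",
                          call. = FALSE)
  if (!all(is.finite(Xs))) stop("predict.pl_gp: grid outside numeric range",
                                call. = FALSE)
  pr <- gp_predict_cpp(object$logtheta, object$X, object$y,
                       object$prior_mean, Xs, kernel_code(object$config$kernel))
  out <- tibble::as_tibble(as.data.frame(Xs))
  colnames(out) <- colnames(object$X)[seq_len(d)]
  out$mean <- as.numeric(pr$mean)
  out$sd_epistemic <- sqrt(pmax(as.numeric(pr$var), 0))
  out$sd_with_noise <- sqrt(pmax(as.numeric(pr$var), 0) + pr$noise_var)
  class(out) <- c("pl_gp_posterior", class(out))
  out
}

#' @export
print.pl_gp <- function(x, ...) {
  cat("<pl_gp>", x$config$kernel, "ARD kernel,", nrow(x$X), "training points\n")
  print(signif(x$theta, 4))
  if (is.finite(x$log_marginal)) {
    cat("log marginal likelihood:", format(x$log_marginal, digits = 6), "\n")
  }
  invisible(x)
}

#' Broom-style tidiers for GP models
#'
#' `tidy()` returns one row per hyperparameter; `glance()` a one-row model
#' summary.
#'
#' @param x A `pl_gp` model.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.pl_gp <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @rdname tidy.pl_gp
#' @exportS3Method generics::glance
glance.pl_gp <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$X), kernel = x$config$kernel,
    log_marginal = x$log_marginal,
    noise_sd = sqrt(unname(x$theta["noise_var"]))
  )
}

#' Continuous ranked probability score of a Gaussian predictive
#'
#' Closed form: `CRPS = sigma * (z * (2 * Phi(z) - 1) + 2 * phi(z) -
#' 1/sqrt(pi))` with `z = (y - mu)/sigma`; for `sigma = 0` the score reduces
#' to the absolute error. Vectorised over its arguments.
#'
#' @param mu,sigma Predictive mean and standard deviation (`sigma >= 0`).
#' @param y Observed value.
#' @return CRPS values (lower is better).
#' @export
#' @examples
#' crps_gaussian(0, 1, 0) # 0.2336949...
crps_gaussian <- function(mu, sigma, y) {
  n <- max(length(mu), length(sigma), length(y))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); y <- rep_len(y, n)
  if (any(sigma < 0)) stop("crps_gaussian: sigma must be nonnegative",
                           call. = FALSE)
  out <- abs(y - mu)
  pos <- sigma > 0
  z <- (y[pos] - mu[pos]) / sigma[pos]
  out[pos] <- sigma[pos] *
    (z * (2 * pnorm(z) - 1) + 2 * stats::dnorm(z) - 1 / sqrt(pi))
  out
}

#' Range-normalised root-mean-square error
#'
#' RMSE divided by the range of the evaluated target values (by default the
#' range of `observed`, i.e. each test set normalises its own RMSE).
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @param normalizing_range Positive scalar; defaults to
#'   `diff(range(observed))`.
#' @return Scalar NRMSE.
#' @export
#' @examples
#' nrmse(c(1, 1), c(0, 2)) # 0.5
nrmse <- function(predicted, observed, normalizing_range = NULL) {
  if (length(predicted) != length(observed)) {
    stop("nrmse: predicted and observed must have equal length", call. = FALSE)
  }
  if (is.null(normalizing_range)) {
    normalizing_range <- diff(range(observed))
  }
  if (normalizing_range <= 0) {
    stop("nrmse: normalizing range must be positive (constant test targets?)",
         call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2)) / normalizing_range
}

#' Dose at which the posterior mean crosses a fraction of its control value
#'
#' Finds the first downward crossing of `fraction` times the posterior mean
#' at `reference_dose`, interpolating linearly between grid points. Used to
#' read effective doses (e.g. an EC50-like half-response dose) off a fitted
#' dose-response posterior.
#'
#' @param posterior A `pl_gp_posterior` on an increasing dose grid.
#' @param fraction Fraction of the reference response (default 0.5).
#' @param reference_dose Dose whose prediction anchors the reference
#'   (default 0).
#' @return The interpolated crossing dose, or `NA` if the mean never drops
#'   below the threshold.
#' @export
dose_at_fraction <- function(posterior, fraction = 0.5, reference_dose = 0) {
  x <- posterior[[1]]
  mu <- posterior$mean
  i0 <- which.min(abs(x - reference_dose))
  thr <- fraction * mu[i0]
  i <- which(mu <= thr)
  i <- i[i > i0]
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  if (i == 1) return(x[1])
  x[i - 1] + (thr - mu[i - 1]) * (x[i] - x[i - 1]) / (mu[i] - mu[i - 1])
}

#' Serialize a GP model to JSON
#'
#' Stores hyperparameters, bounds, training data, prior mean, kernel and the
#' seed, plus a digest of the training data for provenance.
#'
#' @param model A `pl_gp` model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gp_model <- function(model, path) {
  obj <- list(
    kernel = model$config$kernel,
    theta = as.list(model$theta),
    logtheta = model$logtheta,
    bounds = if (!is.null(model$bounds)) {
      list(lower = model$bounds[, "lower"], upper = model$bounds[, "upper"])
    },
    prior_mean = model$prior_mean,
    log_marginal = model$log_marginal,
    seed = model$config$seed,
    max_iterations = model$config$max_iterations,
    X = as.data.frame(model$X),
    y = model$y,
    data_digest = rlang::hash(list(model$X, model$y))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp_model
#' @export
read_gp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- as.matrix(obj$X)
  theta <- unlist(obj$theta)
  d <- ncol(X)
  gp_model(
    signal_var = theta[["signal_var"]],
    lengthscales = unname(theta[seq(2, d + 1)]),
    noise_var = theta[["noise_var"]],
    X = X, y = obj$y, prior_mean = obj$prior_mean,
    config = gp_config(kernel = obj$kernel, seed = obj$seed,
                       max_iterations = obj$max_iterations)
  )
}
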