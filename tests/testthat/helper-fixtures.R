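# shared fixtures, built once per test run and cached
.fixture_env <- new.env(parent = emptyenv())

fixture_study <- function(seed = 1) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_experiment(dose_design(), sim_params(),
                                               seed = seed)
  }
  .fixture_env[[key]]
}

fixture_daily <- function(seed = 1) {
  key <- paste0("daily_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- daily_phenotypes(fixture_study(seed)$observations)
  }
  .fixture_env[[key]]
}

# exact mixtures of the default endmembers (rows = spectra)
mixture_spectra <- function(weights, noise_sd = 0, seed = 1) {
  em <- default_endmembers()
  withr::with_seed(seed, {
    t(vapply(weights, function(w) {
      w * em$green + (1 - w) * em$brown + rnorm(nrow(em), 0, noise_sd)
    }, numeric(nrow(em))))
  })
}

# dense linear-algebra GP posterior oracle, independent of the compiled path
gp_oracle <- function(model, xstar) {
  th <- model$theta
  d <- ncol(model$X)
  ell <- unname(th[seq(2, d + 1)])
  kern <- function(A, B) {
    D2 <- matrix(0, nrow(A), nrow(B))
    for (j in seq_len(d)) {
      D2 <- D2 + outer(A[, j] / ell[j], B[, j] / ell[j], "-")^2
    }
    if (model$config$kernel == "sqexp") {
      th[["signal_var"]] * exp(-0.5 * D2)
    } else {
      r <- sqrt(3) * sqrt(D2)
      th[["signal_var"]] * (1 + r) * exp(-r)
    }
  }
  Xs <- matrix(xstar, ncol = d)
  K <- kern(model$X, model$X) +
    diag(th[["noise_var"]] + 1e-10 * th[["signal_var"]], nrow(model$X))
  Ks <- kern(model$X, Xs)
  Ki <- solve(K)
  mu <- model$prior_mean + drop(t(Ks) %*% Ki %*% (model$y - model$prior_mean))
  v <- th[["signal_var"]] - diag(t(Ks) %*% Ki %*% Ks)
  list(mean = mu, sd = sqrt(pmax(v, 0)))
}
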