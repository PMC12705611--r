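#' Plot a GP posterior over dose
#'
#' Mean line with epistemic (inner) and with-noise (outer) standard
#' deviation bands, plus the training points.
#'
#' @param object A `pl_gp_posterior` from [predict.pl_gp()].
#' @param model Optional `pl_gp` supplying training points.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pl_gp_posterior <- function(object, model = NULL, ...) {
  xcol <- names(object)[1]
  g <- ggplot2::ggplot(object, ggplot2::aes(.data[[xcol]])) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd_with_noise,
                   ymax = .data$mean + .data$sd_with_noise),
      fill = "firebrick", alpha = 0.15
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd_epistemic,
                   ymax = .data$mean + .data$sd_epistemic),
      fill = "goldenrod", alpha = 0.35
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::labs(x = xcol, y = "posterior", title = "GP posterior") +
    ggplot2::theme_minimal()
  if (!is.null(model) && nrow(model$X) > 0) {
    pts <- tibble::tibble(x = model$X[, 1], y = model$y)
    g <- g + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(.data$x, .data$y),
                                 inherit.aes = FALSE, size = 1)
  }
  g
}

#' Plot per-split NRMSE summaries of one or more evaluations
#'
#' @param object A `pl_evaluation` (or pass several via `more`).
#' @param more Optional named list of further `pl_evaluation` objects.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pl_evaluation <- function(object, more = NULL, ...) {
  evs <- c(list(object), more)
  if (is.null(names(evs)) || names(evs)[1] == "") {
    names(evs)[1] <- object$target
  }
  df <- purrr::imap_dfr(evs, function(e, nm) {
    dplyr::mutate(glance(e), variant = nm, .before = 1)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$variant, .data$mean_nrmse)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "mean NRMSE (95% bootstrap CI)") +
    ggplot2::theme_minimal()
}

#' Plot the 2-D trajectory embedding coloured by cluster
#'
#' @param object A `pl_clusters` tibble from [embed_cluster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pl_clusters <- function(object, ...) {
  df <- dplyr::mutate(object,
                      cluster = factor(.data$cluster,
                                       labels = ifelse(sort(unique(.data$cluster)) == -1,
                                                       "noise",
                                                       sort(unique(.data$cluster)))))
  ggplot2::ggplot(df, ggplot2::aes(.data$umap1, .data$umap2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-day dose correlations with bootstrap bands
#'
#' @param dc Output of [daily_correlation()].
#' @return A ggplot object.
#' @export
plot_daily_correlation <- function(dc) {
  ggplot2::ggplot(dc, ggplot2::aes(.data$day, .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = "day", y = "Pearson r (dose vs value)") +
    ggplot2::theme_minimal()
}
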