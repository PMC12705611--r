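#' Run the two-round closed experimental loop
#'
#' Simulates round 1, fits a GP of root fresh weight on dose, proposes new
#' doses by variance acquisition, simulates round 2 on the proposals plus the
#' 0 and 500 uM anchors, then fits and cross-validates round-1, round-2 and
#' combined models for every requested target, compares them, and (optionally)
#' runs the daily trajectory pipeline on the combined observations. All
#' stage seeds derive deterministically from the master seed, so identical
#' configurations give identical artifacts.
#'
#' @param params A [sim_params()] generator configuration.
#' @param round1 Round-1 [dose_design()].
#' @param request An [acquisition_request()].
#' @param config A [gp_config()] used for every model fit.
#' @param scheme A [cv_scheme()] for the evaluations.
#' @param targets Targets to model and evaluate; any of `"fw_root"`,
#'   `"fw_shoot"`, `"root_px_scaled"`, `"shoot_px_scaled"` (final-day pixel
#'   sizes, MinMax-scaled over both rounds).
#' @param n_replicates_round2 Replicates per round-2 arm (default 6).
#' @param run_trajectory Run the daily-series + clustering pipeline
#'   (default TRUE).
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, all artifacts are written
#'   as CSV/JSON with a run log.
#' @return An object of class `pl_loop`: designs, plant tables, the
#'   acquisition model and proposals, per-target evaluations
#'   (round1/round2/combined), comparisons with percent improvements, and
#'   the trajectory outputs.
#' @export
run_loop <- function(params = sim_params(),
                     round1 = dose_design(),
                     request = acquisition_request(),
                     config = gp_config(),
                     scheme = cv_scheme(),
                     targets = c("fw_root", "fw_shoot",
                                 "root_px_scaled", "shoot_px_scaled"),
                     n_replicates_round2 = 6,
                     run_trajectory = TRUE,
                     seed = 1L,
                     out_dir = NULL) {
  targets <- match.arg(targets, several.ok = TRUE)
  stage_seeds <- withr::with_seed(as.integer(seed), sample.int(2^30, 12))
  log_lines <- c(
    sprintf("phenoloop run_loop | master seed %d", as.integer(seed)),
    sprintf("config digest %s",
            rlang::hash(list(params, round1, request, config, scheme, targets)))
  )
  stage <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  stage(sprintf("[simulate] round 1: %d arms, seed %d",
                nrow(round1), stage_seeds[1]))
  study1 <- simulate_experiment(round1, params, stage_seeds[1])

  stage("[fit] round-1 root fresh-weight model for acquisition")
  cfg_ask <- config
  cfg_ask$seed <- stage_seeds[2]
  ask_model <- fit_gp(study1$plants$dose_uM, study1$plants$fw_root_g, cfg_ask)
  proposals <- propose_doses(ask_model, request)
  stage(sprintf("[ask] proposed doses (uM): %s",
                paste(proposals, collapse = ", ")))

  round2 <- dose_design(sort(unique(c(0, proposals, 500))),
                        n_replicates_round2, round_id = 2L)
  stage(sprintf("[simulate] round 2: %d arms, seed %d",
                nrow(round2), stage_seeds[3]))
  study2 <- simulate_experiment(round2, params, stage_seeds[3])

  tabs <- analysis_tables(study1, study2)

  evaluations <- list()
  comparisons <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    stage(sprintf("[evaluate] target %s (round1 / round2 / combined)", tg))
    ev <- purrr::imap(tabs, function(tab, variant) {
      cfg <- config
      cfg$seed <- stage_seeds[4] + ti * 100L +
        match(variant, names(tabs)) * 10L
      sch <- scheme
      sch$seed <- stage_seeds[5] + ti * 100L +
        match(variant, names(tabs)) * 10L
      evaluate_model(tab, tg, scheme = sch, config = cfg)
    })
    evaluations[[tg]] <- ev
    comparisons[[tg]] <- compare_models(ev)
  }
  improvement <- purrr::imap_dfr(evaluations, function(ev, tg) {
    tibble::tibble(
      target = tg,
      round1_nrmse = ev$round1$mean_nrmse,
      round2_nrmse = ev$round2$mean_nrmse,
      combined_nrmse = ev$combined$mean_nrmse,
      improvement_pct = (ev$round1$mean_nrmse - ev$combined$mean_nrmse) /
        ev$round1$mean_nrmse * 100
    )
  })

  trajectory <- NULL
  if (run_trajectory) {
    stage("[trajectories] daily series, embedding, clustering")
    obs <- dplyr::bind_rows(study1$observations, study2$observations)
    plants <- dplyr::bind_rows(study1$plants, study2$plants) %>%
      dplyr::filter(!.data$excluded)
    obs <- obs[obs$plant_id %in% plants$plant_id, ]
    daily <- daily_phenotypes(obs)
    mat <- build_trajectory_matrix(daily)
    clusters <- embed_cluster(mat, seed = stage_seeds[6], plants = plants)
    cl_stats <- if (length(unique(clusters$cluster[clusters$cluster != -1])) >= 2) {
      cluster_statistics(clusters, plants, daily)
    }
    trajectory <- list(daily = daily, matrix = mat, clusters = clusters,
                       cluster_statistics = cl_stats)
  }

  out <- structure(
    list(
      designs = list(round1 = round1, round2 = round2),
      studies = list(round1 = study1, round2 = study2),
      tables = tabs,
      ask_model = ask_model, proposals = proposals,
      evaluations = evaluations, comparisons = comparisons,
      improvement = improvement, trajectory = trajectory,
      seed = as.integer(seed), stage_seeds = stage_seeds,
      log = log_lines
    ),
    class = "pl_loop"
  )
  if (!is.null(out_dir)) write_loop_artifacts(out, out_dir)
  out
}

# per-variant analysis tables with final-day pixel sizes (scaled over both
# rounds, as the study scales pixel data across experiments)
analysis_tables <- function(study1, study2) {
  one <- function(study) {
    final <- study$observations %>%
      dplyr::filter(.data$day == max(.data$day)) %>%
      dplyr::group_by(.data$plant_id) %>%
      dplyr::summarise(
        root_px = .data$pixel_count[.data$modality == "root_scan"][1],
        shoot_px = euclidean_size(
          .data$pixel_count[.data$modality != "root_scan"]
        ),
        .groups = "drop"
      )
    study$plants %>%
      dplyr::filter(!.data$excluded) %>%
      dplyr::inner_join(final, by = "plant_id") %>%
      dplyr::rename(fw_root = "fw_root_g", fw_shoot = "fw_shoot_g")
  }
  t1 <- one(study1); t2 <- one(study2)
  both <- dplyr::bind_rows(t1, t2) %>%
    dplyr::mutate(
      root_px_scaled = minmax_scale(.data$root_px),
      shoot_px_scaled = minmax_scale(.data$shoot_px)
    )
  list(
    round1 = both[both$round_id == unique(t1$round_id), ],
    round2 = both[both$round_id == unique(t2$round_id), ],
    combined = both
  )
}

#' @export
print.pl_loop <- function(x, ...) {
  cat("<pl_loop> master seed", x$seed, "\n")
  cat("  proposals (uM):", paste(x$proposals, collapse = ", "), "\n")
  print(as.data.frame(x$improvement), row.names = FALSE)
  if (!is.null(x$trajectory)) {
    k <- length(unique(x$trajectory$clusters$cluster
                       [x$trajectory$clusters$cluster != -1]))
    cat("  trajectory clusters:", k, "\n")
  }
  invisible(x)
}

write_loop_artifacts <- function(loop, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- loop$log[2]
  for (r in names(loop$studies)) {
    write_study(loop$studies[[r]], file.path(out_dir, r))
  }
  write_gp_model(loop$ask_model, file.path(out_dir, "ask_model.json"))
  jsonlite::write_json(
    list(proposals_uM = as.numeric(loop$proposals), seed = loop$seed,
         config_digest = sub("config digest ", "", hdr)),
    file.path(out_dir, "proposals.json"), auto_unbox = TRUE, digits = NA
  )
  glances <- purrr::imap_dfr(loop$evaluations, function(ev, tg) {
    purrr::imap_dfr(ev, function(e, variant) {
      dplyr::mutate(glance(e), variant = variant, .before = 1)
    })
  })
  write.csv(glances, file.path(out_dir, "evaluation_summary.csv"),
            row.names = FALSE)
  write.csv(loop$improvement, file.path(out_dir, "improvement.csv"),
            row.names = FALSE)
  if (!is.null(loop$trajectory)) {
    write.csv(loop$trajectory$daily, file.path(out_dir, "daily_series.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(loop$trajectory$clusters),
              file.path(out_dir, "clusters.csv"), row.names = FALSE)
  }
  writeLines(loop$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
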