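#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates simulate -> respond -> tune -> map -> cluster -> stability
#' -> report on one synthetic experiment, writing tidy CSV outputs and a
#' JSON run manifest (configs, seed, file digests, stage timings, package
#' version) to `out_dir`. Stages execute in dependency order; when
#' `resume = TRUE`, stages whose outputs already exist are skipped unless
#' explicitly listed in `stages`. Each stage draws from a stage-scoped RNG
#' stream derived from the master seed, so reruns with the same seed are
#' byte-identical and no stage consumes another's stream.
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run (default: all).
#' @param config An [analysis_config()].
#' @param sim A [sim_config()].
#' @param seed Master integer seed.
#' @param resume Skip stages whose outputs exist.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("simulate", "respond", "tune", "map",
                                    "cluster", "stability", "report"),
                         config = analysis_config(),
                         sim = sim_config(),
                         seed = 1L, resume = TRUE) {
  all_stages <- c("simulate", "respond", "tune", "map", "cluster",
                  "stability", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, paste0(...))
  stage_seed <- function(stage) {
    (seed * 131L + match(stage, all_stages) * 7919L) %% .Machine$integer.max
  }
  timings <- list()
  ran <- character(0)
  run_stage <- function(stage, outputs, fun) {
    need <- stage %in% stages || !all(file.exists(outputs))
    if (resume && !(stage %in% stages) && all(file.exists(outputs))) {
      need <- FALSE
    }
    if (!need) return(invisible(NULL))
    t0 <- Sys.time()
    message("[whiskermap] stage ", stage)
    tryCatch(fun(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ran <<- c(ran, stage)
  }

  session_files <- function() pth("trials_s", sprintf("%02d", seq_len(sim$n_sessions)), ".csv")

  run_stage("simulate",
            c(pth("barrel_map.json"), pth("roster.csv"), session_files()),
            function() {
    exp <- simulate_experiment(sim, seed = stage_seed("simulate"))
    write_barrel_map(exp$map, pth("barrel_map.json"))
    readr::write_csv(exp$roster, pth("roster.csv"), progress = FALSE)
    truth_flat <- purrr::imap(exp$truth, function(tr, s) {
      surf <- do.call(rbind, tr$surface)
      colnames(surf) <- paste0("true_", whisker_labels())
      dplyr::bind_cols(
        tibble::tibble(session = s),
        tr[c("roi_id", "ref_whisker", "responsive", "base_peak", "peak")],
        tibble::as_tibble(surf))
    })
    readr::write_csv(dplyr::bind_rows(truth_flat), pth("ground_truth.csv"),
                     progress = FALSE)
    readr::write_csv(exp$change_log, pth("change_log.csv"), progress = FALSE)
    for (s in seq_len(sim$n_sessions)) {
      write_trial_table(exp$tables[[s]], session_files()[s])
    }
  })

  profile_files <- function() pth("profiles_s", sprintf("%02d", seq_len(sim$n_sessions)), ".csv")
  run_stage("respond", profile_files(), function() {
    for (s in seq_len(sim$n_sessions)) {
      tab <- filter_analysis_trials(read_trial_table(session_files()[s]),
                                    config = config)
      prof <- response_profiles(tab, config,
                                seed = stage_seed("respond") + s)
      readr::write_csv(prof, profile_files()[s], progress = FALSE)
    }
  })

  run_stage("tune", pth("tuning_s01.csv"), function() {
    map <- read_barrel_map(pth("barrel_map.json"))
    roster <- readr::read_csv(pth("roster.csv"), show_col_types = FALSE)
    for (s in seq_len(sim$n_sessions)) {
      tab <- filter_analysis_trials(read_trial_table(session_files()[s]),
                                    config = config)
      prof <- readr::read_csv(profile_files()[s], show_col_types = FALSE)
      tsum <- with_seed_maybe(stage_seed("tune") + s,
        tuning_summaries(tab, prof, roster, map, config, seed = NULL))
      flat <- tsum
      flat$ebw <- vapply(flat$ebw, paste, character(1), collapse = ";")
      readr::write_csv(flat, pth("tuning_s", sprintf("%02d", s), ".csv"),
                       progress = FALSE)
    }
  })

  run_stage("map", c(pth("ensemble.csv"), pth("gradient.csv")), function() {
    map <- read_barrel_map(pth("barrel_map.json"))
    roster <- readr::read_csv(pth("roster.csv"), show_col_types = FALSE)
    tsum <- readr::read_csv(pth("tuning_s01.csv"), show_col_types = FALSE)
    ens <- ensemble_topography(tsum, roster, map)
    ens$radii <- NULL
    readr::write_csv(ens, pth("ensemble.csv"), progress = FALSE)
    # subcolumnar gradient: sharpness vs distance to BW column center
    loc <- purrr::map_dfr(seq_len(nrow(tsum)), function(i) {
      np <- normalize_position(roster[roster$roi_id == tsum$roi_id[i], ],
                               tsum$bw[i], map)
      tibble::tibble(radius = np$radius, bw_response = tsum$bw_response[i],
                     sharpness = tsum$sharpness[i])
    })
    grad <- dplyr::bind_rows(
      dplyr::mutate(gradient_regression(loc$radius, loc$bw_response),
                    measure = "bw_response"),
      dplyr::mutate(gradient_regression(loc$radius, loc$sharpness),
                    measure = "sharpness"))
    readr::write_csv(grad, pth("gradient.csv"), progress = FALSE)
  })

  run_stage("cluster", c(pth("pairs.csv"), pth("binned_profile.csv"),
                         pth("cluster_flags.csv")), function() {
    map <- read_barrel_map(pth("barrel_map.json"))
    roster <- readr::read_csv(pth("roster.csv"), show_col_types = FALSE)
    prof <- readr::read_csv(profile_files()[1], show_col_types = FALSE)
    tsum <- readr::read_csv(pth("tuning_s01.csv"), show_col_types = FALSE)
    pairs <- pairwise_similarity(prof, tsum, roster)
    readr::write_csv(pairs, pth("pairs.csv"), progress = FALSE)
    bp <- binned_profile(pairs, "signal_correlation", config)
    readr::write_csv(bp, pth("binned_profile.csv"), progress = FALSE)
    flags <- cluster_excess_test(pairs, "signal_correlation",
                                 n_boot = config$n_bootstrap,
                                 config = config,
                                 seed = stage_seed("cluster"))
    readr::write_csv(flags, pth("cluster_flags.csv"), progress = FALSE)
    ci <- cluster_index(pairs, config)
    readr::write_csv(ci, pth("cluster_index.csv"), progress = FALSE)
  })

  run_stage("stability", c(pth("stability_records.csv"),
                           pth("interval_estimates.csv")), function() {
    map <- read_barrel_map(pth("barrel_map.json"))
    roster <- readr::read_csv(pth("roster.csv"), show_col_types = FALSE)
    tabs <- lapply(session_files(), function(f) {
      filter_analysis_trials(read_trial_table(f), config = config)
    })
    ci <- if (file.exists(pth("cluster_index.csv"))) {
      readr::read_csv(pth("cluster_index.csv"), show_col_types = FALSE)
    } else NULL
    recs <- stability_records(tabs, roster, map, cluster_indices = ci,
                              config = config,
                              seed = stage_seed("stability"))
    readr::write_csv(recs, pth("stability_records.csv"), progress = FALSE)
    est <- interval_subsample(recs, config = config,
                              seed = stage_seed("stability") + 1L)
    readr::write_csv(est, pth("interval_estimates.csv"), progress = FALSE)
    fit <- tryCatch(
      predict_change(recs, "tuning_change", config = config,
                     seed = stage_seed("stability") + 2L),
      error = function(e) NULL)
    if (!is.null(fit)) {
      readr::write_csv(tidy(fit), pth("model_coefficients.csv"),
                       progress = FALSE)
    }
  })

  run_stage("report", pth("report_summary.csv"), function() {
    cls <- readr::read_csv(profile_files()[1], show_col_types = FALSE) |>
      classify_responsiveness()
    tsum <- readr::read_csv(pth("tuning_s01.csv"), show_col_types = FALSE)
    recs <- readr::read_csv(pth("stability_records.csv"),
                            show_col_types = FALSE)
    columnar <- tsum[!tsum$column %in% c("septal", "excluded"), ]
    sr <- recs[recs$transition == "stable_responsive", ]
    summary <- tibble::tibble(
      quantity = c("fraction_responsive", "fraction_cw_tuned_columnar",
                   "fraction_in_bw_column", "fraction_tuning_changed"),
      value = c(
        mean(cls$responsive),
        mean(columnar$column_class == "CW_tuned"),
        mean(columnar$bw == columnar$column),
        mean(sr$tuning_class %in% c("delta_bw", "delta_com"))
      )
    )
    readr::write_csv(summary, pth("report_summary.csv"), progress = FALSE)
  })

  outputs <- list.files(out_dir, pattern = "\\.(csv|json)$",
                        full.names = TRUE)
  outputs <- setdiff(outputs, pth("manifest.json"))
  manifest <- list(
    package = "whiskermap",
    version = as.character(utils::packageVersion("whiskermap")),
    seed = seed,
    stages_run = ran,
    analysis_config = unclass(config),
    sim_config = unclass(sim),
    timings_sec = timings,
    files = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
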