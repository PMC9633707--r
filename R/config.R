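#' Analysis configuration
#'
#' Bundles the fixed constants used across the pipeline. Defaults follow the
#' study conventions: 10,000-iteration permutation and bootstrap nulls,
#' alpha = 0.05, Benjamini-Hochberg FDR q = 0.05, a 0-1000 ms post-stimulus
#' response window against a 0-500 ms pre-stimulus baseline, a 1.25
#' column-radius inclusion zone around stimulated columns, 10 um distance
#' bins, a 30-200 um range for the subcolumnar gradient regression, a 20 um
#' window for local cluster tests, and 1000 subsampling repetitions.
#'
#' The configuration (including `seed`) is attached to every result object
#' so any output can be traced to the settings that produced it.
#'
#' @param n_permutations Iterations for permutation nulls.
#' @param n_bootstrap Iterations for bootstrap nulls.
#' @param alpha Significance level for single tests.
#' @param fdr_q Benjamini-Hochberg false discovery rate.
#' @param response_window Evoked window, seconds after stimulus onset.
#' @param baseline_window Baseline window, seconds (negative = pre-stimulus).
#' @param inclusion_radius Max distance from a stimulated column centroid, in
#'   normalized column radii, for a cell to enter analysis.
#' @param bin_width Distance bin width in um (bins half-open `[k*w, (k+1)*w)`).
#' @param fit_range Distance range (um) for the cluster-test linear regression.
#' @param cluster_window Neighborhood radius (um) for cluster tests and the
#'   per-cell cluster index.
#' @param subsample_reps Repetitions for interval/spatial subsampling.
#' @param stim_duration,delay_duration Stimulus and delay period lengths (s),
#'   used for lick exclusion in the delayed-response task.
#' @param seed Integer seed recorded with results; stochastic operations use
#'   it when no explicit seed is given.
#' @return A list of class `"wm_config"`.
#' @examples
#' cfg <- analysis_config(n_permutations = 2000, seed = 1)
#' cfg$alpha
#' @export
analysis_config <- function(n_permutations = 10000,
                            n_bootstrap = 10000,
                            alpha = 0.05,
                            fdr_q = 0.05,
                            response_window = c(0, 1),
                            baseline_window = c(-0.5, 0),
                            inclusion_radius = 1.25,
                            bin_width = 10,
                            fit_range = c(30, 200),
                            cluster_window = 20,
                            subsample_reps = 1000,
                            stim_duration = 0.5,
                            delay_duration = 1,
                            seed = NULL) {
  cfg <- list(
    n_permutations = as.integer(n_permutations),
    n_bootstrap = as.integer(n_bootstrap),
    alpha = alpha, fdr_q = fdr_q,
    response_window = response_window, baseline_window = baseline_window,
    inclusion_radius = inclusion_radius, bin_width = bin_width,
    fit_range = fit_range, cluster_window = cluster_window,
    subsample_reps = as.integer(subsample_reps),
    stim_duration = stim_duration, delay_duration = delay_duration,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  stopifnot(
    cfg$n_permutations > 0, cfg$n_bootstrap > 0,
    cfg$alpha > 0, cfg$alpha < 1, cfg$fdr_q > 0, cfg$fdr_q < 1,
    diff(cfg$response_window) > 0, diff(cfg$baseline_window) > 0,
    cfg$inclusion_radius > 0, cfg$bin_width > 0,
    diff(cfg$fit_range) > 0, cfg$cluster_window > 0,
    cfg$subsample_reps > 0
  )
  structure(cfg, class = "wm_config")
}

#' @export
print.wm_config <- function(x, ...) {
  cat("<whiskermap analysis config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# Run `code` under `seed` if one is available, else in the current RNG state.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Attach config (and so the seed) to a result, for provenance.
carry_config <- function(x, config) {
  attr(x, "wm_config") <- config
  x
}

#' Retrieve the configuration attached to a result object
#' @param x A result produced by a whiskermap function.
#' @return The `wm_config` used, or `NULL`.
#' @export
result_config <- function(x) attr(x, "wm_config")
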