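# Shared fixtures, built in code.

# Exhaustive permutation oracle: exact one/two-sided p-values for the
# difference-of-means test over all C(n, n1) splits. Independent of the
# Monte-Carlo engine (uses utils::combn directly).
enum_perm_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  obs <- mean(a) - mean(b)
  idx <- utils::combn(length(x), n1)
  stats <- apply(idx, 2, function(ix) mean(x[ix]) - mean(x[-ix]))
  list(
    p_greater = mean(stats >= obs - 1e-12),
    p_less = mean(stats <= obs + 1e-12),
    p_two = mean(abs(stats) >= abs(obs) - 1e-12)
  )
}

# Tiny wide trial table with explicit per-trial evoked values.
# stimuli: character vector (whisker label, "blank", or "all"); evoked:
# named list of per-roi numeric vectors, one value per trial.
toy_table <- function(stimuli, evoked, lick = rep(FALSE, length(stimuli)),
                      lick_times = NULL) {
  kind <- ifelse(stimuli == "blank", "blank",
                 ifelse(stimuli == "all", "all_whisker",
                        ifelse(stimuli == "tone", "tone", "single_whisker")))
  tab <- tibble::tibble(
    session_id = "s01",
    trial_index = seq_along(stimuli) - 1L,
    stimulus_kind = kind,
    whisker = ifelse(kind == "single_whisker", stimuli, NA_character_),
    lick = lick
  )
  if (!is.null(lick_times)) tab$lick_times <- lick_times
  trial_table(dplyr::bind_cols(tab, tibble::as_tibble(evoked)))
}

# Trial table for one cell with given per-whisker trial vectors + blanks.
cell_table <- function(trials, blanks, roi = "roi_1") {
  stimuli <- c(rep(names(trials), lengths(trials)), rep("blank", length(blanks)))
  ev <- c(unlist(trials, use.names = FALSE), blanks)
  toy_table(stimuli, stats::setNames(list(ev), roi))
}

# Fast test configs.
quick_config <- function(...) {
  args <- list(n_permutations = 500, n_bootstrap = 500, subsample_reps = 200)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(analysis_config, args)
}

# Small noiseless simulation for exact-recovery checks.
noiseless_sim <- function(n_cells = 40, seed = 11, ...) {
  sim_config(n_cells = n_cells, noise_sd = 0, gain_sdlog = 0,
             wavering_drop = 0, suppressed_fraction = 0,
             n_sessions = 1, seed = seed, ...)
}
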