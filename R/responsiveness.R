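#' Stimulus-evoked dF/F from a frame-resolved trace
#'
#' Evoked response = mean dF/F over the response window (0-1000 ms after
#' stimulus onset by default) minus mean dF/F over the baseline window
#' (0-500 ms pre-stimulus). Window edges map to frames by
#' `floor(onset + t * rate)` with half-open windows, so at 7.5 Hz with
#' onset frame 10 the response frames are 10..17 and the baseline frames
#' 6..9.
#'
#' @param trace Numeric vector of frame dF/F values (1-based indexing).
#' @param onset Stimulus-onset frame index.
#' @param frame_rate Frames per second.
#' @param config An [analysis_config()] supplying the windows.
#' @return A single evoked dF/F value.
#' @examples
#' compute_evoked(c(rep(0.1, 9), rep(0.6, 8)), onset = 10, frame_rate = 7.5)
#' @export
compute_evoked <- function(trace, onset, frame_rate,
                           config = analysis_config()) {
  window_frames <- function(w) {
    lo <- floor(onset + w[1] * frame_rate)
    hi <- ceiling(onset + w[2] * frame_rate) - 1
    if (lo < 1 || hi > length(trace) || hi < lo) {
      stop("trace does not cover frames ", lo, "..", hi, call. = FALSE)
    }
    seq(lo, hi)
  }
  resp <- window_frames(config$response_window)
  base <- window_frames(config$baseline_window)
  mean(trace[resp]) - mean(trace[base])
}

#' Permutation test for a whisker-evoked response against blank trials
#'
#' Tests whether single-trial evoked dF/F on one whisker's trials differs
#' from blank trials by shuffling trials between the two sets and
#' recomputing the difference of means. Monte-Carlo p-values use the
#' add-one convention `(1 + k) / (1 + N)`, which avoids p = 0 and makes the
#' test slightly conservative.
#'
#' @param whisker_trials,blank_trials Numeric vectors of single-trial
#'   evoked dF/F.
#' @param n_permutations Number of shuffles (>= 100).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `observed` (mean difference), `p_pos`
#'   (one-sided, response above blanks), `p_neg` (below blanks), `p_two`
#'   (two-sided on |difference|), and trial counts.
#' @examples
#' set.seed(1)
#' permutation_response_test(rnorm(20, 0.5, 0.1), rnorm(40, 0, 0.1),
#'                           n_permutations = 500)
#' @export
permutation_response_test <- function(whisker_trials, blank_trials,
                                      n_permutations = 10000, seed = NULL) {
  if (length(whisker_trials) == 0 || length(blank_trials) == 0) {
    stop("both trial sets must be non-empty", call. = FALSE)
  }
  if (n_permutations < 100) {
    stop("n_permutations must be at least 100", call. = FALSE)
  }
  res <- with_seed_maybe(seed, .perm_diff_engine(
    c(whisker_trials, blank_trials), length(whisker_trials),
    as.integer(n_permutations)
  ))
  tibble::tibble(
    observed = res$observed,
    p_pos = (1 + res$n_ge) / (1 + res$n_perm),
    p_neg = (1 + res$n_le) / (1 + res$n_perm),
    p_two = (1 + res$n_abs_ge) / (1 + res$n_perm),
    n_whisker = length(whisker_trials),
    n_blank = length(blank_trials)
  )
}

# Two-sample permutation difference test between two whiskers' trial sets.
# Same engine, exposed for eBW / best-whisker-change testing.
perm_two_sample <- function(a, b, n_permutations, seed = NULL) {
  res <- with_seed_maybe(seed, .perm_diff_engine(
    c(a, b), length(a), as.integer(n_permutations)
  ))
  list(observed = res$observed,
       p_greater = (1 + res$n_ge) / (1 + res$n_perm),
       p_less = (1 + res$n_le) / (1 + res$n_perm),
       p_two = (1 + res$n_abs_ge) / (1 + res$n_perm))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR control across a cell's stimuli, via [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate.
#' @return Logical vector of significance flags (monotone in p).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Single-trial response criterion
#'
#' A single trial counts as responsive when its evoked dF/F strictly
#' exceeds the blank-trial mean plus one blank-trial standard deviation.
#'
#' @param evoked Numeric vector of single-trial evoked dF/F.
#' @param blank_mean,blank_sd Blank-trial statistics (SD uses n - 1).
#' @return Logical vector.
#' @export
single_trial_responsive <- function(evoked, blank_mean, blank_sd) {
  stopifnot(blank_sd >= 0)
  evoked > blank_mean + blank_sd
}

#' Per-cell, per-whisker response profiles
#'
#' The core responsiveness computation. For every ROI and every single
#' whisker, tests the whisker's trials against blank trials with the
#' trial-shuffling permutation test, then applies Benjamini-Hochberg
#' correction across the nine single whiskers within each cell. Positive
#' and negative responses are tested as two one-sided tests pooled into one
#' two-sided decision per stimulus (the smaller tail doubled, sign
#' recorded), so each stimulus yields a single significance call whose
#' family-wise behaviour the FDR step can control.
#'
#' @param table A filtered `trial_table` (see [filter_analysis_trials()]).
#' @param config An [analysis_config()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return A tibble with one row per ROI x whisker: `roi_id`, `whisker`,
#'   `mean_evoked`, `n_trials`, `p_pos`, `p_neg`, `p` (pooled two-sided),
#'   `sig` (after FDR), `sign` (+1/-1 for significant calls, 0 otherwise),
#'   `blank_mean`, `blank_sd`, `n_blank`, and `trial_frac` (fraction of
#'   single trials passing the single-trial criterion).
#' @seealso [classify_responsiveness()]
#' @export
response_profiles <- function(table, config = analysis_config(),
                              seed = config$seed) {
  table <- trial_table(table)
  pc <- trial_pieces(table)
  if (!any(pc$is_blank)) stop("no blank trials in table", call. = FALSE)
  labels <- whisker_labels()
  with_seed_maybe(seed, {
    out <- purrr::map(pc$rois, function(roi) {
      ev <- pc$evoked[, roi]
      blanks <- ev[pc$is_blank]
      bm <- mean(blanks)
      bs <- stats::sd(blanks)
      rows <- purrr::map(labels, function(w) {
        tw <- ev[pc$is_single & pc$whisker == w]
        if (length(tw) == 0) {
          return(tibble::tibble(
            whisker = w, mean_evoked = NA_real_, n_trials = 0L,
            p_pos = NA_real_, p_neg = NA_real_, p = NA_real_,
            trial_frac = NA_real_
          ))
        }
        pt <- permutation_response_test(tw, blanks, config$n_permutations)
        tibble::tibble(
          whisker = w,
          mean_evoked = pt$observed,
          n_trials = length(tw),
          p_pos = pt$p_pos, p_neg = pt$p_neg,
          p = min(1, 2 * min(pt$p_pos, pt$p_neg)),
          trial_frac = mean(single_trial_responsive(tw, bm, bs))
        )
      })
      res <- dplyr::bind_rows(rows)
      res$sig <- FALSE
      tested <- !is.na(res$p)
      res$sig[tested] <- fdr_correct(res$p[tested], config$fdr_q)
      res$sign <- ifelse(res$sig, ifelse(res$mean_evoked > 0, 1L, -1L), 0L)
      res$roi_id <- roi
      res$blank_mean <- bm
      res$blank_sd <- bs
      res$n_blank <- sum(pc$is_blank)
      res
    })
    out <- dplyr::bind_rows(out)
  })
  out <- dplyr::relocate(out, "roi_id")
  carry_config(out, config)
}

#' Classify cells by responsiveness
#'
#' A cell is whisker-responsive when at least one whisker drove a
#' significant positive response. Cells with only significant negative
#' responses are flagged `negative_only` and, like wholly non-significant
#' cells, are excluded from receptive-field analyses.
#'
#' @param profiles Output of [response_profiles()].
#' @return One row per ROI: `roi_id`, `responsive`, `negative_only`, and
#'   `class` (`responsive` / `negative_only` / `non_responsive`).
#' @export
classify_responsiveness <- function(profiles) {
  out <- profiles |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(
      responsive = any(.data$sign == 1L, na.rm = TRUE),
      negative_only = !any(.data$sign == 1L, na.rm = TRUE) &
        any(.data$sign == -1L, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$responsive ~ "responsive",
      .data$negative_only ~ "negative_only",
      TRUE ~ "non_responsive"
    ))
  carry_config(out, result_config(profiles))
}
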