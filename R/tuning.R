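#' Per-whisker single-trial evoked values for one ROI
#'
#' @param table A filtered `trial_table`.
#' @param roi ROI column name.
#' @return Named list (one element per whisker) of evoked dF/F vectors.
#' @export
whisker_trial_list <- function(table, roi) {
  pc <- trial_pieces(table)
  ev <- pc$evoked[, roi]
  out <- lapply(whisker_labels(), function(w) {
    unname(ev[pc$is_single & pc$whisker == w])
  })
  names(out) <- whisker_labels()
  out
}


# One-pass version: per-ROI named lists of per-whisker trial vectors.
all_whisker_trials <- function(table, rois = roi_columns(table)) {
  pc <- trial_pieces(table)
  labs <- whisker_labels()
  idx <- lapply(labs, function(w) which(pc$is_single & pc$whisker == w))
  names(idx) <- labs
  out <- lapply(rois, function(roi) {
    ev <- pc$evoked[, roi]
    lapply(idx, function(ix) unname(ev[ix]))
  })
  names(out) <- rois
  out
}

# Named per-whisker mean vector from a profiles tibble, one ROI.
profile_means <- function(profiles, roi) {
  p <- profiles[profiles$roi_id == roi, ]
  stats::setNames(p$mean_evoked, p$whisker)[whisker_labels()]
}

#' Best whisker and equivalent best whiskers
#'
#' The best whisker (BW) is the significant-positive whisker with the
#' largest mean evoked dF/F (ties broken by smaller p, then fixed whisker
#' order). Equivalent best whiskers (eBWs) are significant-positive
#' whiskers whose trial sets are statistically indistinguishable from the
#' BW's by a two-sided permutation difference-of-means test at `alpha`
#' (uncorrected across candidates). A cell with more than one eBW is
#' broadly tuned.
#'
#' @param trials Named list of per-whisker single-trial evoked vectors
#'   (see [whisker_trial_list()]).
#' @param profile The [response_profiles()] rows for this ROI.
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @return A list with `bw` (label), `ebw` (character vector, contains
#'   `bw`), and `broadly_tuned`.
#' @export
find_bw_and_ebw <- function(trials, profile, config = analysis_config(),
                            seed = config$seed) {
  pos <- profile$sign == 1L & !is.na(profile$mean_evoked)
  if (!any(pos)) {
    stop("find_bw_and_ebw() requires a responsive profile", call. = FALSE)
  }
  cand <- profile[pos, ]
  ord <- order(-cand$mean_evoked, cand$p, match(cand$whisker, whisker_labels()))
  bw <- cand$whisker[ord[1]]
  others <- setdiff(cand$whisker, bw)
  ebw <- bw
  with_seed_maybe(seed, {
    for (w in others) {
      pt <- perm_two_sample(trials[[bw]], trials[[w]], config$n_permutations)
      if (pt$p_two > config$alpha) ebw <- c(ebw, w)
    }
  })
  ebw <- whisker_labels()[whisker_labels() %in% ebw]
  list(bw = bw, ebw = ebw, broadly_tuned = length(ebw) > 1)
}

#' Tuning sharpness
#'
#' `(R_BW - R_W) / (R_BW + R_W)` where `R_BW` is the mean evoked dF/F to
#' the best whisker and `R_W` the average over the other eight whiskers
#' with negative per-whisker means replaced by zero. Ranges over `[0, 1]`:
#' 1 when only the BW responds, 0 when all whiskers respond equally.
#'
#' @param means Named per-whisker mean evoked vector (9 values).
#' @param bw Best-whisker label; defaults to the max-mean whisker.
#' @return Sharpness, or `NA` when `R_BW <= 0` (undefined).
#' @examples
#' m <- c(D2 = 0.8, D1 = 0.4, D3 = 0.2, C2 = -0.1, C1 = 0, C3 = 0,
#'        E1 = 0, E2 = 0, E3 = 0)
#' tuning_sharpness(m)  # 0.725 / 0.875
#' @export
tuning_sharpness <- function(means, bw = names(which.max(means))) {
  r_bw <- means[[bw]]
  if (is.na(r_bw) || r_bw <= 0) return(NA_real_)
  others <- means[setdiff(names(means), bw)]
  r_w <- mean(pmax(others, 0), na.rm = TRUE)
  (r_bw - r_w) / (r_bw + r_w)
}

#' Columnar whisker dominance index
#'
#' `(R_CW - R_SW) / |R_CW + R_SW|` where `R_CW` is the mean response to the
#' whisker matching the cell's anatomical column and `R_SW` the strongest
#' of the other eight (surround) whiskers, both on raw (un-zeroed) means.
#' A cell responding only to its CW has CWDI = 1; equal CW and strongest-SW
#' responses give CWDI = 0; values above 1 or below 0 arise when the
#' strongest SW or the CW response is negative.
#'
#' @param means Named per-whisker mean evoked vector.
#' @param column Columnar-whisker label (cell must be non-septal).
#' @return CWDI, or `NA` when the denominator is zero.
#' @examples
#' m <- stats::setNames(rep(0, 9), whisker_labels())
#' m["D2"] <- 0.5
#' cw_dominance_index(m, "D2")  # 1
#' @export
cw_dominance_index <- function(means, column) {
  r_cw <- means[[column]]
  r_sw <- max(means[setdiff(names(means), column)], na.rm = TRUE)
  den <- abs(r_cw + r_sw)
  if (is.na(den) || den == 0) return(NA_real_)
  (r_cw - r_sw) / den
}

#' Columnar whisker preference
#'
#' As [tuning_sharpness()] but centred on the columnar whisker:
#' `(R_CW - R_W) / (R_CW + R_W)` with negative surround means zeroed in
#' `R_W`. Negative when the cell prefers a surround whisker.
#'
#' @inheritParams cw_dominance_index
#' @return CW preference, or `NA` when `R_CW + R_W <= 0`.
#' @export
cw_preference <- function(means, column) {
  r_cw <- means[[column]]
  others <- means[setdiff(names(means), column)]
  r_w <- mean(pmax(others, 0), na.rm = TRUE)
  den <- r_cw + r_w
  if (is.na(den) || den <= 0) return(NA_real_)
  (r_cw - r_w) / den
}

#' Tuning center of mass
#'
#' Response-weighted centroid of the 3x3 whisker grid (arc on x, row on y,
#' unit spacing; see [whisker_grid()]), with negative per-whisker means
#' zeroed.
#'
#' @param means Named per-whisker mean evoked vector.
#' @return Named numeric `c(x, y)`, or `c(NA, NA)` when no mean is positive.
#' @examples
#' m <- stats::setNames(rep(0, 9), whisker_labels())
#' m["D2"] <- 0.6; m["D3"] <- 0.2
#' tuning_com(m)  # x = 1.25, y = 1
#' @export
tuning_com <- function(means) {
  g <- whisker_grid()
  w <- pmax(means[g$whisker], 0)
  w[is.na(w)] <- 0
  tot <- sum(w)
  if (tot <= 0) return(c(x = NA_real_, y = NA_real_))
  c(x = sum(w * g$gx) / tot, y = sum(w * g$gy) / tot)
}

#' Columnar vs non-columnar tuning class
#'
#' Cells inside a column are labelled `nonCW_tuned` only when their best
#' whisker differs from the columnar whisker *and* the BW's trials are
#' significantly stronger than the CW's trials by a one-sided permutation
#' test at `alpha` (equivalently, the CW is not an eBW). Otherwise they are
#' `CW_tuned` - a deliberately conservative rule. Cells outside every
#' column are `septal`.
#'
#' @param trials Named per-whisker trial list for the cell.
#' @param bw Best-whisker label.
#' @param column Columnar whisker label, or `NA`/`"septal"` for septal cells.
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @return `"CW_tuned"`, `"nonCW_tuned"`, or `"septal"`.
#' @export
classify_column_tuning <- function(trials, bw, column,
                                   config = analysis_config(),
                                   seed = config$seed) {
  if (is.na(column) || identical(column, "septal")) return("septal")
  if (bw == column) return("CW_tuned")
  pt <- with_seed_maybe(seed,
    perm_two_sample(trials[[bw]], trials[[column]], config$n_permutations))
  if (pt$p_greater <= config$alpha) "nonCW_tuned" else "CW_tuned"
}

#' Mean rank-ordered tuning curves
#'
#' Each included cell's nine per-whisker means are sorted strongest to
#' weakest (negative responses retained), normalized, and averaged across
#' cells. Only cells whose BW is the center whisker or a center-edge
#' whisker of the 3x3 array are included, so the BW plus at least its five
#' immediate neighbours were sampled.
#'
#' @param summaries A [tuning_summaries()] tibble (needs `roi_id`, `bw`).
#' @param profiles A [response_profiles()] tibble.
#' @param normalize `"to_blank"` (divide by the cell's blank-trial standard
#'   deviation, expressing responses in units of the blank noise floor) or
#'   `"to_max"` (divide by the cell's strongest response).
#' @return A tibble with `rank`, `mean`, `sem`, `n_cells`.
#' @export
rank_ordered_curves <- function(summaries, profiles,
                                normalize = c("to_blank", "to_max")) {
  normalize <- match.arg(normalize)
  g <- whisker_grid()
  center_or_edge <- g$whisker[(g$gx == 1) | (g$gy == 1)]
  keep <- summaries$roi_id[summaries$bw %in% center_or_edge]
  if (length(keep) == 0) {
    return(tibble::tibble(rank = integer(0), mean = numeric(0),
                          sem = numeric(0), n_cells = integer(0)))
  }
  curves <- purrr::map(keep, function(roi) {
    m <- sort(profile_means(profiles, roi), decreasing = TRUE)
    if (normalize == "to_max") {
      m <- m / m[1]
    } else {
      bs <- profiles$blank_sd[profiles$roi_id == roi][1]
      if (!is.na(bs) && bs > 0) m <- m / bs
    }
    unname(m)
  })
  mat <- do.call(rbind, curves)
  tibble::tibble(
    rank = seq_len(ncol(mat)),
    mean = colMeans(mat),
    sem = apply(mat, 2, stats::sd) / sqrt(nrow(mat)),
    n_cells = nrow(mat)
  )
}

#' Per-cell tuning summaries
#'
#' Runs the full tuning characterization for every responsive cell in a
#' trial table: BW and eBW set, broad-tuning flag, sharpness, tuning
#' center of mass, and - when a barrel map and ROI roster are supplied -
#' CWDI, CW preference, and the columnar tuning class.
#'
#' @param table A filtered `trial_table`.
#' @param profiles Output of [response_profiles()] for the same table.
#' @param rois Optional roster tibble (`roi_id`, `x`, `y`).
#' @param map Optional [barrel_map()].
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @return A tibble, one row per responsive ROI: `roi_id`, `bw`, `ebw`
#'   (list-column), `broadly_tuned`, `bw_response`, `sharpness`, `com_x`,
#'   `com_y`, and with map: `column`, `column_class`, `cwdi`,
#'   `cw_preference`.
#' @export
tuning_summaries <- function(table, profiles, rois = NULL, map = NULL,
                             config = analysis_config(), seed = config$seed) {
  cls <- classify_responsiveness(profiles)
  responsive <- cls$roi_id[cls$responsive]
  assignment <- NULL
  if (!is.null(rois) && !is.null(map)) {
    assignment <- assign_column(rois, map, config)
  }
  trials_all <- all_whisker_trials(table, responsive)
  rows <- with_seed_maybe(seed, purrr::map(responsive, function(roi) {
    prof <- profiles[profiles$roi_id == roi, ]
    trials <- trials_all[[roi]]
    bwres <- find_bw_and_ebw(trials, prof, config, seed = NULL)
    means <- stats::setNames(prof$mean_evoked, prof$whisker)[whisker_labels()]
    com <- tuning_com(means)
    out <- tibble::tibble(
      roi_id = roi, bw = bwres$bw, ebw = list(bwres$ebw),
      broadly_tuned = bwres$broadly_tuned,
      bw_response = means[[bwres$bw]],
      sharpness = tuning_sharpness(means, bwres$bw),
      com_x = com[["x"]], com_y = com[["y"]]
    )
    if (!is.null(assignment)) {
      a <- assignment[assignment$roi_id == roi, ]
      col <- if (nrow(a) == 1) a$column else NA_character_
      in_column <- !is.na(col) && !col %in% c("septal", "excluded")
      out$column <- col
      out$column_class <- classify_column_tuning(
        trials, bwres$bw, if (in_column) col else NA_character_,
        config, seed = NULL)
      out$cwdi <- if (in_column) cw_dominance_index(means, col) else NA_real_
      out$cw_preference <- if (in_column) cw_preference(means, col) else NA_real_
    }
    out
  }))
  carry_config(dplyr::bind_rows(rows), config)
}
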