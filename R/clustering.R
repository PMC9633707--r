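# Zero-negative 9-vector of per-whisker means for one ROI.
zeroed_means <- function(profiles, roi) {
  m <- profile_means(profiles, roi)
  m[is.na(m)] <- 0
  pmax(m, 0)
}

#' Pairwise tuning similarity of co-columnar neurons
#'
#' For every pair of responsive cells sharing a column, computes the three
#' tuning-similarity measures - signal correlation (Pearson correlation of
#' the per-whisker mean response vectors with negative responses zeroed),
#' Euclidean distance between tuning centers of mass, and whether the two
#' cells share the same BW - plus the response-magnitude similarity
#' `|R_a - R_b| / |R_a + R_b|` of the two BW response magnitudes.
#'
#' @param profiles A [response_profiles()] tibble.
#' @param summaries A [tuning_summaries()] tibble with a `column` column
#'   (i.e. computed with a map); only non-septal responsive cells pair.
#' @param rois Roster tibble (`roi_id`, `x`, `y`, optional `field_id`; pairs
#'   never span imaging fields).
#' @return A tibble, one row per unordered pair: `roi_a`, `roi_b`,
#'   `column`, `distance` (um), `signal_correlation`, `delta_com`,
#'   `same_bw`, `magnitude_similarity`. Zero-variance response vectors give
#'   `NA` correlation.
#' @export
pairwise_similarity <- function(profiles, summaries, rois) {
  stopifnot("column" %in% names(summaries))
  s <- summaries[!summaries$column %in% c("septal", "excluded") &
                   !is.na(summaries$column), ]
  s <- dplyr::left_join(s, rois, by = "roi_id")
  fields <- if ("field_id" %in% names(s)) s$field_id else rep("f", nrow(s))
  groups <- split(seq_len(nrow(s)), paste(s$column, fields))
  out <- purrr::map(groups, function(ix) {
    m <- length(ix)
    if (m < 2) return(NULL)
    V <- do.call(rbind, lapply(s$roi_id[ix],
                               function(r) zeroed_means(profiles, r)))
    sds <- apply(V, 1, stats::sd)
    C <- suppressWarnings(stats::cor(t(V)))
    C[sds == 0, ] <- NA_real_
    C[, sds == 0] <- NA_real_
    pr <- which(upper.tri(C), arr.ind = TRUE)
    i <- ix[pr[, 1]]; j <- ix[pr[, 2]]
    tibble::tibble(
      roi_a = s$roi_id[i], roi_b = s$roi_id[j], column = s$column[i],
      distance = sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2),
      signal_correlation = C[pr],
      delta_com = sqrt((s$com_x[i] - s$com_x[j])^2 +
                         (s$com_y[i] - s$com_y[j])^2),
      same_bw = s$bw[i] == s$bw[j],
      magnitude_similarity = abs(s$bw_response[i] - s$bw_response[j]) /
        abs(s$bw_response[i] + s$bw_response[j])
    )
  })
  dplyr::bind_rows(out)
}

#' Distance-binned similarity profile
#'
#' Bins pairwise similarities by inter-soma distance into half-open bins
#' `[k*w, (k+1)*w)` (default 10 um) and reports per-bin mean, SEM, and
#' pair count. Bins with no pairs are absent.
#'
#' @param pairs A [pairwise_similarity()] tibble.
#' @param metric Column to profile, e.g. `"signal_correlation"`.
#' @param config An [analysis_config()].
#' @return A tibble `bin_lo`, `bin_hi`, `bin_mid`, `mean`, `sem`, `n_pairs`.
#' @export
binned_profile <- function(pairs, metric = "signal_correlation",
                           config = analysis_config()) {
  stopifnot(nrow(pairs) >= 1)
  w <- config$bin_width
  v <- pairs[[metric]]
  keep <- is.finite(v) & is.finite(pairs$distance)
  b <- floor(pairs$distance[keep] / w)
  v <- v[keep]
  out <- tibble::tibble(bin = b, value = v) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_lo = .data$bin * w, bin_hi = (.data$bin + 1) * w,
                  bin_mid = .data$bin_lo + w / 2) |>
    dplyr::select("bin_lo", "bin_hi", "bin_mid", "mean", "sem", "n_pairs") |>
    dplyr::arrange(.data$bin_lo)
  class(out) <- unique(c("wm_binned_profile", class(out)))
  carry_config(out, config)
}

#' Within-column spatial-shuffle null for the binned profile
#'
#' Null model of completely random intermixing of tuning within each
#' column: cell locations are permuted among the cells of each column, the
#' pairwise profile is re-binned, and the per-bin distribution over
#' iterations gives the null mean and percentile 95% CI. The multiset of
#' positions and of tuning vectors per column is preserved exactly, so
#' only the pairing of tuning to location is randomized.
#'
#' @param pairs A [pairwise_similarity()] tibble (observed pairs).
#' @param metric Similarity column to profile.
#' @param n_iter Number of shuffles.
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @return A tibble `bin_lo`, `bin_hi`, `null_mean`, `null_lo`, `null_hi`
#'   (2.5 and 97.5 percentiles), `n_iter`.
#' @export
spatial_shuffle_null <- function(pairs, metric = "signal_correlation",
                                 n_iter = 10000,
                                 config = analysis_config(),
                                 seed = config$seed) {
  w <- config$bin_width
  cols <- split(pairs, pairs$column)
  # per column: slot pairs with fixed distances and a similarity lookup
  prep <- purrr::map(cols, function(pc) {
    ids <- sort(unique(c(pc$roi_a, pc$roi_b)))
    m <- length(ids)
    S <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
    S[cbind(match(pc$roi_a, ids), match(pc$roi_b, ids))] <- pc[[metric]]
    S[cbind(match(pc$roi_b, ids), match(pc$roi_a, ids))] <- pc[[metric]]
    list(i = match(pc$roi_a, ids), j = match(pc$roi_b, ids),
         bin = floor(pc$distance / w), S = S, m = m)
  })
  bins <- sort(unique(unlist(purrr::map(prep, "bin"))))
  acc <- matrix(NA_real_, n_iter, length(bins))
  with_seed_maybe(seed, {
    for (it in seq_len(n_iter)) {
      sums <- stats::setNames(numeric(length(bins)), bins)
      counts <- stats::setNames(numeric(length(bins)), bins)
      for (pcp in prep) {
        perm <- sample.int(pcp$m)
        vals <- pcp$S[cbind(perm[pcp$i], perm[pcp$j])]
        ok <- is.finite(vals)
        if (!any(ok)) next
        t1 <- tapply(vals[ok], pcp$bin[ok], sum)
        t2 <- tapply(rep(1, sum(ok)), pcp$bin[ok], sum)
        sums[names(t1)] <- sums[names(t1)] + t1
        counts[names(t2)] <- counts[names(t2)] + t2
      }
      acc[it, ] <- ifelse(counts > 0, sums / counts, NA_real_)
    }
  })
  out <- tibble::tibble(
    bin_lo = bins * w, bin_hi = (bins + 1) * w,
    null_mean = colMeans(acc, na.rm = TRUE),
    null_lo = apply(acc, 2, stats::quantile, 0.025, na.rm = TRUE),
    null_hi = apply(acc, 2, stats::quantile, 0.975, na.rm = TRUE),
    n_iter = n_iter
  )
  carry_config(out, config)
}

#' Sub-20 um cluster-excess test
#'
#' Tests whether tuning similarity of near neighbours exceeds the general
#' subcolumnar gradient. An ordinary least-squares line is fitted to
#' pair-level (distance, similarity) points over 30-200 um and
#' extrapolated to the centers of the bins at or below the cluster window
#' (20 um). For each such bin, the within-bin pairs are resampled with
#' replacement `n_boot` times; the one-sided p-value is the add-one
#' fraction of bootstrap bin means on or beyond the *expected* side of the
#' extrapolated value (direction `"greater"` for metrics where clustering
#' raises similarity, `"less"` where it lowers, e.g. `delta_com`).
#' Benjamini-Hochberg correction is applied across the tested bins.
#'
#' @param pairs A [pairwise_similarity()] tibble.
#' @param metric Similarity column.
#' @param direction `"greater"` or `"less"`: side of the regression line on
#'   which clustering is expected.
#' @param n_boot Bootstrap iterations per bin.
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @param fit_on `"pairs"` (default; pair-level regression) or `"bins"`
#'   (regression on bin means).
#' @return A tibble, one row per tested bin: `bin_lo`, `bin_hi`,
#'   `observed_mean`, `expected`, `n_pairs`, `p`, `flag`; plus the fitted
#'   `slope`/`intercept` as attributes.
#' @export
cluster_excess_test <- function(pairs, metric = "signal_correlation",
                                direction = c("greater", "less"),
                                n_boot = 10000, config = analysis_config(),
                                seed = config$seed, fit_on = c("pairs", "bins")) {
  direction <- match.arg(direction)
  fit_on <- match.arg(fit_on)
  v <- pairs[[metric]]
  keep <- is.finite(v) & is.finite(pairs$distance)
  d <- pairs$distance[keep]; v <- v[keep]
  rng <- config$fit_range
  in_fit <- d >= rng[1] & d < rng[2]
  w <- config$bin_width
  if (length(unique(floor(d[in_fit] / w))) < 2) {
    stop("need >= 2 occupied bins in the fit range", call. = FALSE)
  }
  if (fit_on == "pairs") {
    fit <- stats::lm(v[in_fit] ~ d[in_fit])
  } else {
    bp <- binned_profile(tibble::tibble(distance = d[in_fit],
                                        m = v[in_fit], column = "x"),
                         metric = "m", config = config)
    fit <- stats::lm(bp$mean ~ bp$bin_mid)
  }
  slope <- stats::coef(fit)[[2]]; intercept <- stats::coef(fit)[[1]]

  test_bins <- sort(unique(floor(d[d < config$cluster_window] / w)))
  rows <- with_seed_maybe(seed, purrr::map(test_bins, function(b) {
    vb <- v[floor(d / w) == b]
    expected <- intercept + slope * (b * w + w / 2)
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(vb[sample.int(length(vb), replace = TRUE)])
    }, numeric(1))
    k <- if (direction == "greater") sum(boots <= expected)
         else sum(boots >= expected)
    tibble::tibble(
      bin_lo = b * w, bin_hi = (b + 1) * w,
      observed_mean = mean(vb), expected = expected,
      n_pairs = length(vb), p = (1 + k) / (1 + n_boot)
    )
  }))
  out <- dplyr::bind_rows(rows)
  out$flag <- fdr_correct(out$p, config$fdr_q)
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  carry_config(out, config)
}

#' Per-cell cluster index
#'
#' Mean signal correlation between a responsive neuron and its responsive
#' neighbours within the cluster window (20 um). Cells with no such
#' neighbour get `NA`.
#'
#' @param pairs A [pairwise_similarity()] tibble.
#' @param config An [analysis_config()].
#' @return Tibble `roi_id`, `cluster_index`, `n_neighbors`.
#' @export
cluster_index <- function(pairs, config = analysis_config()) {
  near <- pairs[pairs$distance < config$cluster_window &
                  is.finite(pairs$signal_correlation), ]
  both <- dplyr::bind_rows(
    tibble::tibble(roi_id = near$roi_a, sc = near$signal_correlation),
    tibble::tibble(roi_id = near$roi_b, sc = near$signal_correlation)
  )
  out <- both |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(cluster_index = mean(.data$sc),
                     n_neighbors = dplyr::n(), .groups = "drop")
  carry_config(out, config)
}
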