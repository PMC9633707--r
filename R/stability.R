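# means over a per-whisker trial list (NA for unsampled whiskers)
trial_means <- function(trials) {
  vapply(trials, function(v) if (length(v) == 0) NA_real_ else mean(v),
         numeric(1))
}

#' Best-whisker change test between two sessions
#'
#' A cell's BW is considered changed when, in the later session, some
#' whisker evokes a significantly stronger mean dF/F than the prior BW by
#' a one-sided permutation test at `alpha` - equivalently, when the prior
#' BW is no longer an equivalent best whisker. Candidate whiskers are
#' tested uncorrected by default (`correct = TRUE` applies
#' Benjamini-Hochberg across candidates).
#'
#' @param trials_s1,trials_s2 Named per-whisker trial lists for the two
#'   sessions (see [whisker_trial_list()]).
#' @param prior_bw BW label from the first session; defaults to the
#'   max-mean whisker of `trials_s1`.
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @param correct Apply FDR correction across candidate whiskers.
#' @return A list: `changed`, `new_bw` (session-2 max-mean whisker when
#'   changed, else `NA`), `prior_bw`, `p_min`.
#' @export
delta_bw_test <- function(trials_s1, trials_s2, prior_bw = NULL,
                          config = analysis_config(), seed = config$seed,
                          correct = FALSE) {
  m1 <- trial_means(trials_s1)
  m2 <- trial_means(trials_s2)
  if (is.null(prior_bw)) prior_bw <- names(which.max(m1))
  if (length(trials_s2[[prior_bw]]) == 0) {
    stop("prior BW ", prior_bw, " was not sampled in the second session",
         call. = FALSE)
  }
  cand <- names(trials_s2)[!is.na(m2) & names(trials_s2) != prior_bw &
                             m2 > m2[[prior_bw]]]
  if (length(cand) == 0) {
    return(list(changed = FALSE, new_bw = NA_character_,
                prior_bw = prior_bw, p_min = NA_real_))
  }
  ps <- with_seed_maybe(seed, vapply(cand, function(w) {
    perm_two_sample(trials_s2[[w]], trials_s2[[prior_bw]],
                    config$n_permutations)$p_greater
  }, numeric(1)))
  sig <- if (correct) fdr_correct(ps, config$alpha) else ps <= config$alpha
  if (any(sig)) {
    list(changed = TRUE, new_bw = names(which.max(m2)),
         prior_bw = prior_bw, p_min = min(ps))
  } else {
    list(changed = FALSE, new_bw = NA_character_,
         prior_bw = prior_bw, p_min = min(ps))
  }
}

#' Tuning center-of-mass change test between two sessions
#'
#' The observed shift is the Euclidean distance between the two sessions'
#' tuning centers of mass (negative means zeroed). The null distribution
#' is built by shuffling single trials of the same whisker between the two
#' sessions (preserving per-session trial counts) and recomputing the
#' shift; the cell is flagged changed when the observed shift exceeds the
#' null's `1 - alpha` percentile (or `1 - alpha/2` with
#' `two_sided = TRUE`). Whiskers sampled in only one session are excluded
#' from both CoMs.
#'
#' @inheritParams delta_bw_test
#' @param two_sided Use the `1 - alpha/2` percentile threshold.
#' @return A one-row tibble: `changed`, `observed`, `null_q` (threshold
#'   percentile of the null), `n_iter`.
#' @export
delta_com_bootstrap <- function(trials_s1, trials_s2,
                                config = analysis_config(),
                                seed = config$seed, two_sided = FALSE) {
  labels <- whisker_labels()
  shared <- labels[vapply(labels, function(w) {
    length(trials_s1[[w]]) > 0 && length(trials_s2[[w]]) > 0
  }, logical(1))]
  if (length(shared) == 0) stop("no whisker sampled in both sessions",
                                call. = FALSE)
  g <- whisker_grid()
  gx <- g$gx[match(shared, g$whisker)]
  gy <- g$gy[match(shared, g$whisker)]
  com_of <- function(m) {
    w <- pmax(m, 0)
    tot <- sum(w)
    if (tot <= 0) return(c(NA_real_, NA_real_))
    c(sum(w * gx) / tot, sum(w * gy) / tot)
  }
  c1 <- com_of(trial_means(trials_s1[shared]))
  c2 <- com_of(trial_means(trials_s2[shared]))
  observed <- sqrt(sum((c1 - c2)^2))
  null <- with_seed_maybe(seed, .com_shuffle_engine(
    unname(trials_s1[shared]), unname(trials_s2[shared]),
    gx, gy, config$n_bootstrap))
  prob <- if (two_sided) 1 - config$alpha / 2 else 1 - config$alpha
  thr <- stats::quantile(null, prob, na.rm = TRUE, names = FALSE)
  tibble::tibble(
    changed = is.finite(observed) && observed > thr,
    observed = observed, null_q = thr, n_iter = config$n_bootstrap
  )
}

#' Classify one cell's stability across a session pair
#'
#' The responsiveness transition comes from the per-session responsive
#' flags (`stable_nonresponsive`, `gained`, `lost`, `stable_responsive`).
#' For cells responsive in both sessions, tuning is classed by first
#' testing for a BW change ([delta_bw_test()]) and, only when the BW is
#' stable, for a CoM change ([delta_com_bootstrap()]); a cell with neither
#' has stable tuning.
#'
#' @inheritParams delta_bw_test
#' @param responsive_s1,responsive_s2 Per-session responsive flags.
#' @return One-row tibble: `transition`, `tuning_class` (`stable`,
#'   `delta_bw`, `delta_com`, or `NA` unless stably responsive),
#'   `delta_com_magnitude`, `prior_bw`, `new_bw`.
#' @export
classify_stability <- function(trials_s1, trials_s2,
                               responsive_s1, responsive_s2,
                               prior_bw = NULL,
                               config = analysis_config(),
                               seed = config$seed) {
  transition <- if (responsive_s1 && responsive_s2) "stable_responsive"
    else if (responsive_s1) "lost"
    else if (responsive_s2) "gained"
    else "stable_nonresponsive"
  if (transition != "stable_responsive") {
    return(tibble::tibble(transition = transition,
                          tuning_class = NA_character_,
                          delta_com_magnitude = NA_real_,
                          prior_bw = NA_character_, new_bw = NA_character_))
  }
  with_seed_maybe(seed, {
    bwres <- delta_bw_test(trials_s1, trials_s2, prior_bw, config, seed = NULL)
    if (bwres$changed) {
      # report the realized CoM shift for magnitude bookkeeping
      cm <- delta_com_observed(trials_s1, trials_s2)
      tibble::tibble(transition = transition, tuning_class = "delta_bw",
                     delta_com_magnitude = cm,
                     prior_bw = bwres$prior_bw, new_bw = bwres$new_bw)
    } else {
      cres <- delta_com_bootstrap(trials_s1, trials_s2, config, seed = NULL)
      tibble::tibble(
        transition = transition,
        tuning_class = if (cres$changed) "delta_com" else "stable",
        delta_com_magnitude = cres$observed,
        prior_bw = bwres$prior_bw, new_bw = NA_character_
      )
    }
  })
}

# Observed CoM shift without the null (shared whiskers, zeroed negatives).
delta_com_observed <- function(trials_s1, trials_s2) {
  labels <- whisker_labels()
  shared <- labels[vapply(labels, function(w) {
    length(trials_s1[[w]]) > 0 && length(trials_s2[[w]]) > 0
  }, logical(1))]
  g <- whisker_grid()
  gx <- g$gx[match(shared, g$whisker)]
  gy <- g$gy[match(shared, g$whisker)]
  com_of <- function(m) {
    w <- pmax(m, 0); tot <- sum(w)
    if (tot <= 0) return(c(NA_real_, NA_real_))
    c(sum(w * gx) / tot, sum(w * gy) / tot)
  }
  c1 <- com_of(trial_means(trials_s1[shared]))
  c2 <- com_of(trial_means(trials_s2[shared]))
  sqrt(sum((c1 - c2)^2))
}

#' Stability records for all cells across all session pairs
#'
#' Runs per-session responsiveness and tuning, then classifies every cell
#' across every ordered session pair. The interval class is the session
#' index difference (`delta = j - i`). Initial covariates (session-i BW
#' response magnitude, sharpness, columnar class, distance from the cell
#' to its BW column center in column radii, cluster index) are attached
#' when a map/roster/cluster-index table is supplied.
#'
#' @param tables List of filtered `trial_table`s, one per session, sharing
#'   the same ROI columns (the cross-session identity link).
#' @param rois,map Optional roster and [barrel_map()] for covariates.
#' @param cluster_indices Optional tibble `roi_id`, `cluster_index`
#'   (session-1 based).
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @return A tibble, one row per cell x session pair: `roi_id`, `s_i`,
#'   `s_j`, `delta`, `transition`, `tuning_class`, `delta_com_magnitude`,
#'   `prior_bw`, `new_bw`, and covariate columns where available.
#' @export
stability_records <- function(tables, rois = NULL, map = NULL,
                              cluster_indices = NULL,
                              config = analysis_config(),
                              seed = config$seed) {
  n_sessions <- length(tables)
  stopifnot(n_sessions >= 2)
  shared_rois <- Reduce(intersect, lapply(tables, roi_columns))
  with_seed_maybe(seed, {
    profiles <- lapply(tables, response_profiles, config = config, seed = NULL)
    classes <- lapply(profiles, classify_responsiveness)
    summaries <- lapply(seq_len(n_sessions), function(s) {
      tuning_summaries(tables[[s]], profiles[[s]], rois = rois, map = map,
                       config = config, seed = NULL)
    })
    trials_all <- lapply(tables, all_whisker_trials, rois = shared_rois)
    recs <- list()
    for (i in seq_len(n_sessions - 1)) {
      for (j in seq(i + 1, n_sessions)) {
        for (roi in shared_rois) {
          ri <- classes[[i]]$responsive[classes[[i]]$roi_id == roi]
          rj <- classes[[j]]$responsive[classes[[j]]$roi_id == roi]
          si <- summaries[[i]][summaries[[i]]$roi_id == roi, ]
          prior_bw <- if (nrow(si) == 1) si$bw else NULL
          rec <- classify_stability(
            trials_all[[i]][[roi]], trials_all[[j]][[roi]],
            ri, rj, prior_bw = prior_bw, config = config, seed = NULL)
          rec$roi_id <- roi
          rec$s_i <- i; rec$s_j <- j; rec$delta <- j - i
          if (nrow(si) == 1) {
            rec$bw_response <- si$bw_response
            rec$sharpness <- si$sharpness
            if ("column_class" %in% names(si)) {
              rec$column_class <- si$column_class
            }
            if (!is.null(map) && !is.null(rois)) {
              rr <- rois[rois$roi_id == roi, ]
              np <- normalize_position(rr, si$bw, map)
              rec$location <- np$radius
            }
          }
          recs[[length(recs) + 1]] <- rec
        }
      }
    }
    out <- dplyr::bind_rows(recs)
  })
  out <- dplyr::relocate(out, "roi_id", "s_i", "s_j", "delta")
  if (!is.null(cluster_indices)) {
    out <- dplyr::left_join(out, cluster_indices[c("roi_id", "cluster_index")],
                            by = "roi_id")
  }
  carry_config(out, config)
}

#' Within-session false-positive control
#'
#' Splits one session into two pseudo-sessions - alternate trials or first
#' vs second half, per whisker - and runs the across-session tuning-change
#' tests between them. Because both halves sample the same stationary
#' tuning, the flagged fraction estimates the tests' false-positive rate
#' and should sit near `alpha`.
#'
#' @param table A filtered `trial_table`.
#' @param mode `"alternate_trials"` or `"halves"`.
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @param min_trials Minimum trials per whisker per split; cells below it
#'   are skipped and counted.
#' @return A list: `fraction_changed`, `n_cells`, `n_skipped`, and the
#'   per-cell tibble `records`.
#' @export
within_session_control <- function(table,
                                   mode = c("alternate_trials", "halves"),
                                   config = analysis_config(),
                                   seed = config$seed, min_trials = 4) {
  mode <- match.arg(mode)
  with_seed_maybe(seed, {
    profiles <- response_profiles(table, config, seed = NULL)
    cls <- classify_responsiveness(profiles)
    responsive <- cls$roi_id[cls$responsive]
    n_skipped <- 0L
    trials_all <- all_whisker_trials(table, responsive)
    recs <- list()
    for (roi in responsive) {
      trials <- trials_all[[roi]]
      split1 <- list(); split2 <- list()
      for (w in names(trials)) {
        v <- trials[[w]]
        if (length(v) == 0) { split1[[w]] <- v; split2[[w]] <- v; next }
        idx <- seq_along(v)
        sel <- if (mode == "alternate_trials") idx %% 2 == 1
               else idx <= length(v) / 2
        split1[[w]] <- v[sel]; split2[[w]] <- v[!sel]
      }
      sampled <- names(trials)[lengths(trials) > 0]
      if (any(lengths(split1[sampled]) < min_trials) ||
          any(lengths(split2[sampled]) < min_trials)) {
        n_skipped <- n_skipped + 1L
        next
      }
      prior_bw <- names(which.max(trial_means(split1)))
      rec <- classify_stability(split1, split2, TRUE, TRUE,
                                prior_bw = prior_bw, config = config,
                                seed = NULL)
      rec$roi_id <- roi
      recs[[length(recs) + 1]] <- rec
    }
    records <- dplyr::bind_rows(recs)
  })
  changed <- records$tuning_class %in% c("delta_bw", "delta_com")
  out <- list(
    fraction_changed = mean(changed),
    n_cells = nrow(records), n_skipped = n_skipped,
    records = records
  )
  carry_config(out, config)
}

#' Unbiased interval subsampling
#'
#' Cells imaged across four sessions contribute three different 1-interval
#' records, two 2-interval records, and one 3-interval record. To avoid
#' overcounting, each repetition draws one record per cell per interval
#' class, computes the summary quantity, and the mean and percentile 95%
#' CI over repetitions are reported.
#'
#' @param records A [stability_records()] tibble.
#' @param quantity Function of a records tibble returning one number.
#'   Default: fraction of stably responsive cells whose tuning changed.
#' @param config An [analysis_config()] (`subsample_reps` repetitions).
#' @param seed Optional integer seed.
#' @return One row per interval class: `delta`, `mean`, `ci_lo`, `ci_hi`,
#'   `reps`.
#' @export
interval_subsample <- function(records, quantity = fraction_tuning_changed,
                               config = analysis_config(),
                               seed = config$seed) {
  reps <- config$subsample_reps
  out <- with_seed_maybe(seed, purrr::map(sort(unique(records$delta)),
    function(dlt) {
      rd <- records[records$delta == dlt, ]
      groups <- split(seq_len(nrow(rd)), rd$roi_id)
      vals <- vapply(seq_len(reps), function(r) {
        take <- vapply(groups, function(ix) {
          if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
        }, integer(1))
        quantity(rd[take, , drop = FALSE])
      }, numeric(1))
      tibble::tibble(
        delta = dlt, mean = mean(vals),
        ci_lo = stats::quantile(vals, 0.025, names = FALSE),
        ci_hi = stats::quantile(vals, 0.975, names = FALSE),
        reps = reps
      )
    }))
  carry_config(dplyr::bind_rows(out), config)
}

#' @rdname interval_subsample
#' @param x A records tibble.
#' @export
fraction_tuning_changed <- function(x) {
  sr <- x$transition == "stable_responsive"
  if (!any(sr)) return(NA_real_)
  mean(x$tuning_class[sr] %in% c("delta_bw", "delta_com"))
}

#' Two-group comparisons
#'
#' Standard two-sided tests used for group contrasts: Fisher's exact test
#' or a chi-squared test on 2x2 counts (given as `c(successes, total)` per
#' group), or Wilcoxon rank-sum / Kolmogorov-Smirnov tests on samples.
#'
#' @param a,b For `fisher_exact`/`chi2`: `c(n_success, n_total)`; for
#'   `ranksum`/`ks`: numeric samples.
#' @param test One of `"fisher_exact"`, `"chi2"`, `"ranksum"`, `"ks"`.
#' @return One-row tibble: `test`, `statistic`, `p`, plus a `warning`
#'   column when a chi-squared expected count fell below 1.
#' @examples
#' group_compare(c(122, 258), c(307, 710), "fisher_exact")  # p = 0.273
#' @export
group_compare <- function(a, b, test = c("fisher_exact", "chi2",
                                         "ranksum", "ks")) {
  test <- match.arg(test)
  warn <- NA_character_
  if (test %in% c("fisher_exact", "chi2")) {
    stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
    tab <- matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]), nrow = 2,
                  byrow = TRUE)
    if (test == "fisher_exact") {
      ht <- stats::fisher.test(tab, alternative = "two.sided")
      stat <- unname(ht$estimate)
    } else {
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_counts < 1)) warn <- "expected cell count below 1"
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ht$statistic)
    }
  } else if (test == "ranksum") {
    ht <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
    stat <- unname(ht$statistic)
  } else {
    ht <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
    stat <- unname(ht$statistic)
  }
  tibble::tibble(test = test, statistic = stat, p = ht$p.value,
                 warning = warn)
}

#' Logistic model of tuning- or responsiveness-change predictors
#'
#' Fits a binomial GLM with logit link predicting whether a cell changed
#' tuning (stably responsive cells; predictors: map location, tuning
#' sharpness, BW response magnitude, cluster index) or changed
#' responsiveness (all cells responsive in session i or j; predictors
#' exclude the cluster index), with stratified 10-fold cross-validation.
#' Predictors are standardized so coefficient magnitudes are comparable.
#' Cells lacking a cluster index (no neighbour within 20 um) receive the
#' population median plus a missingness indicator.
#'
#' @param records A [stability_records()] tibble with covariate columns.
#' @param outcome `"tuning_change"` or `"responsiveness_change"`.
#' @param folds Cross-validation folds.
#' @param config An [analysis_config()].
#' @param seed Optional integer seed.
#' @return An object of class `wm_change_fit` with [tidy()]/[glance()]
#'   methods: the glm fit, standardized coefficients, and per-fold
#'   deviance and AUC.
#' @export
predict_change <- function(records,
                           outcome = c("tuning_change",
                                       "responsiveness_change"),
                           folds = 10, config = analysis_config(),
                           seed = config$seed) {
  outcome <- match.arg(outcome)
  if (outcome == "tuning_change") {
    d <- records[records$transition == "stable_responsive", ]
    y <- d$tuning_class %in% c("delta_bw", "delta_com")
    covars <- c("location", "sharpness", "bw_response", "cluster_index")
  } else {
    d <- records[records$transition != "stable_nonresponsive", ]
    y <- d$transition %in% c("gained", "lost")
    covars <- c("location", "sharpness", "bw_response")
  }
  covars <- intersect(covars, names(d))
  X <- d[covars]
  if ("cluster_index" %in% covars) {
    miss <- is.na(X$cluster_index)
    X$cluster_index[miss] <- stats::median(X$cluster_index, na.rm = TRUE)
    X$cluster_index_missing <- as.numeric(miss)
  }
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; model is unidentifiable", call. = FALSE)
  }
  scale_cols <- setdiff(names(X), "cluster_index_missing")
  for (v in scale_cols) {
    if (stats::sd(X[[v]]) > 0) X[[v]] <- as.numeric(scale(X[[v]]))
  }
  df <- cbind(data.frame(y = y), X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  probs <- stats::fitted(fit)
  if (!fit$converged || any(probs > 1 - 1e-8) || any(probs < 1e-8)) {
    stop("(quasi-)complete separation detected; coefficients unreliable",
         call. = FALSE)
  }
  cv <- with_seed_maybe(seed, {
    fold_of <- integer(nrow(df))
    for (cls in c(TRUE, FALSE)) {
      ix <- which(y == cls)
      fold_of[ix] <- sample(rep(seq_len(folds), length.out = length(ix)))
    }
    purrr::map(seq_len(folds), function(f) {
      train <- df[fold_of != f, , drop = FALSE]
      test <- df[fold_of == f, , drop = FALSE]
      m <- suppressWarnings(
        stats::glm(y ~ ., data = train, family = stats::binomial()))
      p <- stats::predict(m, newdata = test, type = "response")
      eps <- 1e-12
      dev <- -2 * sum(test$y * log(pmax(p, eps)) +
                        (1 - test$y) * log(pmax(1 - p, eps)))
      tibble::tibble(fold = f, n = nrow(test), deviance = dev,
                     auc = rank_auc(p, test$y))
    }) |> dplyr::bind_rows()
  })
  structure(list(fit = fit, cv = cv, outcome = outcome, n = nrow(df),
                 config = config),
            class = "wm_change_fit")
}

# AUC via the rank-sum identity.
rank_auc <- function(p, y) {
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.wm_change_fit <- function(x, ...) {
  cat("<whiskermap change-prediction model>\n")
  cat("outcome:", x$outcome, " n =", x$n, "\n")
  cat("mean CV AUC:", round(mean(x$cv$auc, na.rm = TRUE), 3), "\n")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a change-prediction fit
#'
#' @param x A [predict_change()] result.
#' @param ... Unused.
#' @return One row per model term with standardized `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy wm_change_fit
#' @export
tidy.wm_change_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co), estimate = co[, 1], std.error = co[, 2],
    statistic = co[, 3], p.value = co[, 4]
  )
}

#' @rdname tidy.wm_change_fit
#' @method glance wm_change_fit
#' @export
glance.wm_change_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n = x$n,
    null.deviance = x$fit$null.deviance, deviance = x$fit$deviance,
    AIC = stats::AIC(x$fit),
    cv_deviance = sum(x$cv$deviance),
    cv_auc = mean(x$cv$auc, na.rm = TRUE),
    folds = nrow(x$cv)
  )
}
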