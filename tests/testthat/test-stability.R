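mk_trials <- function(...) {
  out <- stats::setNames(vector("list", 9), whisker_labels())
  for (w in whisker_labels()) out[[w]] <- numeric(0)
  v <- list(...)
  for (w in names(v)) out[[w]] <- v[[w]]
  out
}

test_that("delta BW test detects swaps and respects the eBW rule", {
  cfg <- quick_config(n_permutations = 1000, seed = 51)
  s1 <- mk_trials(D2 = rep(c(0.8, 0.9), 10), D1 = rep(c(0.2, 0.25), 10))
  # identical sessions: stable
  r0 <- delta_bw_test(s1, s1, config = cfg)
  expect_false(r0$changed)
  expect_equal(r0$prior_bw, "D2")

  # responses swap D2 <-> D1 with a large margin: changed, new BW D1
  s2 <- mk_trials(D2 = rep(c(0.2, 0.25), 10), D1 = rep(c(0.8, 0.9), 10))
  r1 <- delta_bw_test(s1, s2, config = cfg)
  expect_true(r1$changed)
  expect_equal(r1$new_bw, "D1")

  # two statistically equivalent top whiskers incl. the prior BW: stable
  s3 <- mk_trials(D2 = c(0.80, 0.85, 0.82, 0.78, 0.81, 0.84),
                  D1 = c(0.81, 0.84, 0.80, 0.79, 0.83, 0.82))
  r2 <- delta_bw_test(s1, s3, config = cfg)
  expect_false(r2$changed)

  # prior BW unsampled in session 2 is a contract error
  s4 <- mk_trials(D1 = rep(0.5, 8))
  expect_error(delta_bw_test(s1, s4, config = cfg), "not sampled")
})

test_that("delta CoM bootstrap is calibrated and detects injected jitter", {
  cfg <- quick_config(n_bootstrap = 1000, seed = 52)
  s1 <- mk_trials(D2 = rep(c(0.8, 0.9, 0.7), 8),
                  D1 = rep(c(0.3, 0.4, 0.2), 8),
                  D3 = rep(c(0.1, 0.2, 0.15), 8))
  r0 <- delta_com_bootstrap(s1, s1, config = cfg)
  expect_equal(r0$observed, 0)
  expect_false(r0$changed)

  # null calibration: alternate halves of one noisy session flag ~ alpha
  set.seed(99)
  n_cells <- 120
  flags <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    full <- mk_trials(D2 = 0.6 + rnorm(40, 0, 0.15),
                      D1 = 0.3 + rnorm(40, 0, 0.15),
                      C2 = 0.2 + rnorm(40, 0, 0.15))
    h1 <- lapply(full, function(v) v[seq_along(v) %% 2 == 1])
    h2 <- lapply(full, function(v) v[seq_along(v) %% 2 == 0])
    flags[i] <- delta_com_bootstrap(h1, h2, config = cfg, seed = NULL)$changed
  }
  expect_lt(abs(mean(flags) - 0.05), 0.06)

  # injected CoM jitter above measurement noise is detected
  s_shift <- mk_trials(D2 = rep(c(0.8, 0.9, 0.7), 8),
                       D1 = rep(c(0.05, 0.1, 0.0), 8),
                       D3 = rep(c(0.55, 0.6, 0.5), 8))
  r1 <- delta_com_bootstrap(s1, s_shift, config = cfg)
  expect_true(r1$changed)
  expect_gt(r1$observed, r1$null_q)

  # a whisker sampled in one session only is excluded from both CoMs
  s_extra <- s1; s_extra$E3 <- rep(10, 8)
  r2 <- delta_com_bootstrap(s1, s_extra, config = cfg)
  expect_equal(r2$observed, 0)
})

test_that("stability classification composes transitions and tuning classes", {
  cfg <- quick_config(seed = 53)
  s1 <- mk_trials(D2 = rep(c(0.8, 0.9), 8), D1 = rep(c(0.2, 0.3), 8))
  r <- classify_stability(s1, s1, FALSE, FALSE, config = cfg)
  expect_equal(r$transition, "stable_nonresponsive")
  expect_true(is.na(r$tuning_class))
  expect_equal(classify_stability(s1, s1, TRUE, FALSE, config = cfg)$transition,
               "lost")
  expect_equal(classify_stability(s1, s1, FALSE, TRUE, config = cfg)$transition,
               "gained")
  rs <- classify_stability(s1, s1, TRUE, TRUE, config = cfg)
  expect_equal(rs$transition, "stable_responsive")
  expect_equal(rs$tuning_class, "stable")

  s2 <- mk_trials(D2 = rep(c(0.2, 0.3), 8), D1 = rep(c(0.8, 0.9), 8))
  rc <- classify_stability(s1, s2, TRUE, TRUE, config = cfg)
  expect_equal(rc$tuning_class, "delta_bw")
  expect_equal(rc$new_bw, "D1")
})

test_that("within-session controls flag nothing on noiseless data", {
  sc <- noiseless_sim(n_cells = 25, seed = 55)
  exp <- simulate_experiment(sc)
  cfg <- quick_config(seed = 56)
  tab <- filter_analysis_trials(exp$tables[[1]], config = cfg)
  for (mode in c("alternate_trials", "halves")) {
    wc <- within_session_control(tab, mode, cfg)
    expect_equal(wc$fraction_changed, 0)
    expect_gt(wc$n_cells, 0)
  }
})

test_that("flagged fraction grows with alpha in the within-session control", {
  sc <- sim_config(n_cells = 60, responsive_fraction = 1, wavering_drop = 0,
                   n_sessions = 1, seed = 57)
  exp <- simulate_experiment(sc)
  tab <- filter_analysis_trials(exp$tables[[1]], config = analysis_config())
  fr <- vapply(c(0.01, 0.05, 0.2), function(a) {
    cfg <- quick_config(n_permutations = 400, n_bootstrap = 400, alpha = a,
                        seed = 58)
    within_session_control(tab, "alternate_trials", cfg)$fraction_changed
  }, numeric(1))
  expect_true(fr[1] <= fr[2] + 1e-9 && fr[2] <= fr[3] + 1e-9)
  expect_gt(fr[3], fr[1])
})

test_that("stability records track cells across session pairs with covariates", {
  sc <- sim_config(n_cells = 60, n_sessions = 3, responsive_fraction = 0.6,
                   seed = 59)
  exp <- simulate_experiment(sc)
  cfg <- quick_config(seed = 60)
  tabs <- lapply(exp$tables, filter_analysis_trials, config = cfg)
  recs <- stability_records(tabs, exp$roster, exp$map, config = cfg)
  expect_equal(sort(unique(recs$delta)), c(1, 2))
  expect_equal(sum(recs$delta == 1), 2 * 60)  # pairs (1,2), (2,3)
  expect_equal(sum(recs$delta == 2), 60)
  sr <- recs[recs$transition == "stable_responsive", ]
  expect_true(all(!is.na(sr$tuning_class)))
  expect_true(all(is.na(recs$tuning_class[recs$transition != "stable_responsive"])))
  # delta-BW flags only name whiskers sampled (and best) in session j
  named <- sr$new_bw[!is.na(sr$new_bw)]
  expect_true(all(named %in% whisker_labels()))
  expect_true(all(c("bw_response", "sharpness", "location") %in% names(recs)))
})

test_that("interval subsampling matches enumeration on a two-cell toy", {
  cfg <- quick_config(subsample_reps = 2000, seed = 61)
  # cell A: records changed = (T, F, F); cell B: (T, T, F); delta = 1
  records <- tibble::tibble(
    roi_id = rep(c("A", "B"), each = 3),
    delta = 1L,
    transition = "stable_responsive",
    tuning_class = c("delta_bw", "stable", "stable",
                     "delta_bw", "delta_com", "stable")
  )
  est <- interval_subsample(records, config = cfg)
  # enumeration over the 3 x 3 draw space: mean of (I_A + I_B)/2
  # = (1/3 + 2/3)/2 = 0.5
  expect_equal(est$mean, 0.5, tolerance = 0.03)
  expect_lte(est$ci_lo, est$mean); expect_gte(est$ci_hi, est$mean)

  # one record per cell: estimate is the plain mean with zero-width CI
  est1 <- interval_subsample(records[c(1, 4), ], config = cfg)
  expect_equal(est1$mean, 1)
  expect_equal(est1$ci_hi - est1$ci_lo, 0)
})

test_that("group comparisons reproduce exact and hand-computed results", {
  f <- group_compare(c(122, 258), c(307, 710), "fisher_exact")
  expect_equal(f$p, 0.273, tolerance = 0.001)
  expect_equal(group_compare(c(30, 100), c(30, 100), "fisher_exact")$p, 1)

  # {{2,8},{8,2}}: exact hypergeometric tail sum
  h <- group_compare(c(2, 10), c(8, 10), "fisher_exact")
  hand <- sum(vapply(0:10, function(k) {
    p <- stats::dhyper(k, 10, 10, 10)
    if (p <= stats::dhyper(2, 10, 10, 10) + 1e-12) p else 0
  }, numeric(1)))
  expect_equal(h$p, hand, tolerance = 1e-10)

  c2 <- group_compare(c(40, 100), c(25, 100), "chi2")
  expect_lt(c2$p, 0.05)
  expect_true(is.na(c2$warning))
  set.seed(3)
  expect_lt(group_compare(rnorm(50), rnorm(50, 1), "ranksum")$p, 0.001)
  expect_lt(group_compare(rnorm(80), rnorm(80, 0, 3), "ks")$p, 0.01)
})

test_that("the change model finds no signal under a null and errors on separation", {
  set.seed(71)
  n <- 400
  records <- tibble::tibble(
    roi_id = sprintf("r%03d", seq_len(n)),
    transition = "stable_responsive",
    tuning_class = sample(c("stable", "delta_bw"), n, replace = TRUE),
    location = runif(n, 0, 2), sharpness = runif(n, 0.2, 1),
    bw_response = rlnorm(n, -1, 0.4),
    cluster_index = ifelse(runif(n) < 0.3, NA, runif(n, -0.2, 0.8))
  )
  fit <- predict_change(records, "tuning_change", config = quick_config(),
                        seed = 72)
  expect_s3_class(fit, "wm_change_fit")
  expect_lt(abs(glance(fit)$cv_auc - 0.5), 0.08)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  expect_true("cluster_index_missing" %in% td$term)

  # perfect separation is an explicit error
  sep <- records
  sep$tuning_class <- ifelse(sep$location > 1, "delta_bw", "stable")
  expect_error(predict_change(sep, "tuning_change", config = quick_config()),
               "separation")

  one <- records; one$tuning_class <- "stable"
  expect_error(predict_change(one, "tuning_change", config = quick_config()),
               "single class")
})
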