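mk_means <- function(...) {
  m <- stats::setNames(rep(0, 9), whisker_labels())
  v <- c(...)
  m[names(v)] <- v
  m
}

test_that("tuning sharpness follows the zeroing rule and its bounds", {
  expect_equal(tuning_sharpness(mk_means(D2 = 0.8)), 1)
  expect_equal(tuning_sharpness(mk_means() + 0.3), 0)
  m <- mk_means(D2 = 0.8, D1 = 0.4, D3 = 0.2, C2 = -0.1)
  expect_equal(tuning_sharpness(m, "D2"), 0.725 / 0.875)
  expect_true(is.na(tuning_sharpness(mk_means(D2 = -0.1), "D2")))

  # in [0,1] and monotone decreasing as a non-BW response grows
  prev <- Inf
  for (v in seq(0, 0.8, by = 0.2)) {
    s <- tuning_sharpness(mk_means(D2 = 0.8, C1 = v), "D2")
    expect_gte(s, 0); expect_lte(s, 1)
    expect_lt(s, prev + 1e-12)
    prev <- s
  }
})

test_that("CWDI identities hold exactly, including negative-surround cases", {
  expect_equal(cw_dominance_index(mk_means(D2 = 0.5), "D2"), 1)
  expect_equal(cw_dominance_index(mk_means(D2 = 0.4, C1 = 0.4), "D2"), 0)
  # negative strongest SW inflates CWDI above 1
  m <- mk_means(D2 = 0.5) - 0.1
  m["D2"] <- 0.5
  expect_equal(cw_dominance_index(m, "D2"), 0.6 / 0.4)
  m0 <- mk_means() - 0.3
  m0["D2"] <- 0.3  # strongest SW is -0.3, denominator exactly 0
  expect_true(is.na(cw_dominance_index(m0, "D2")))
})

test_that("CW preference centres the sharpness formula on the CW", {
  expect_equal(cw_preference(mk_means(D2 = 0.5), "D2"), 1)
  expect_lt(cw_preference(mk_means(C1 = 0.5), "D2"), 0)
  # R_W = mean of zeroed others = 0.2 by construction
  m <- mk_means(D2 = 0.6) ; m[setdiff(names(m), "D2")] <- 0.2
  expect_equal(cw_preference(m, "D2"), 0.4 / 0.8)
})

test_that("tuning CoM is the zero-negative response-weighted grid centroid", {
  expect_equal(tuning_com(mk_means(D2 = 0.7)), c(x = 1, y = 1))
  expect_equal(tuning_com(mk_means() + 0.2), c(x = 1, y = 1))
  expect_equal(tuning_com(mk_means(D2 = 0.6, D3 = 0.2)),
               c(x = 1.25, y = 1))
  expect_true(all(is.na(tuning_com(mk_means(D2 = -0.5)))))

  # CoM lies in the convex hull of positive-response grid points
  set.seed(3)
  g <- whisker_grid()
  for (i in 1:20) {
    m <- mk_means()
    on <- sample(9, 3)
    m[on] <- runif(3, 0.1, 1)
    com <- tuning_com(m)
    expect_gte(com[["x"]], min(g$gx[on])); expect_lte(com[["x"]], max(g$gx[on]))
    expect_gte(com[["y"]], min(g$gy[on])); expect_lte(com[["y"]], max(g$gy[on]))
  }
})

test_that("BW and eBW selection agrees with the enumeration oracle", {
  cfg <- quick_config(n_permutations = 2000, seed = 8)
  trials <- list(D2 = c(1.0, 1.2, 0.8, 1.0), D1 = c(0.2, 0.1, 0.3, 0.2))
  blanks <- c(0.0, 0.05, -0.05, 0.0, 0.02, -0.02)
  tab <- cell_table(trials, blanks)
  prof <- response_profiles(tab, cfg)
  res <- find_bw_and_ebw(whisker_trial_list(tab, "roi_1"),
                         prof, cfg)
  expect_equal(res$bw, "D2")
  # oracle: exhaustive two-sided p for D2 vs D1 is far below alpha
  expect_lt(enum_perm_p(trials$D2, trials$D1)$p_two, 0.05)
  expect_false("D1" %in% res$ebw)
  expect_false(res$broadly_tuned)

  # identical trial sets are statistically equivalent -> both eBW
  trials2 <- list(D2 = c(0.9, 1.0, 1.1, 1.0), C1 = c(0.9, 1.0, 1.1, 1.0))
  tab2 <- cell_table(trials2, blanks)
  prof2 <- response_profiles(tab2, cfg)
  res2 <- find_bw_and_ebw(whisker_trial_list(tab2, "roi_1"), prof2, cfg)
  expect_setequal(res2$ebw, c("C1", "D2"))
  expect_true(res2$broadly_tuned)

  # single significant whisker: BW = eBW = it
  tab3 <- cell_table(list(E3 = c(0.8, 0.9, 1.0, 0.85)), blanks)
  prof3 <- response_profiles(tab3, cfg)
  res3 <- find_bw_and_ebw(whisker_trial_list(tab3, "roi_1"), prof3, cfg)
  expect_equal(res3$bw, "E3")
  expect_equal(res3$ebw, "E3")

  # contract error on non-responsive profiles
  tabn <- cell_table(list(D2 = blanks[1:4]), blanks)
  profn <- response_profiles(tabn, cfg)
  expect_error(find_bw_and_ebw(whisker_trial_list(tabn, "roi_1"), profn, cfg),
               "responsive")
})

test_that("columnar tuning class is conservative", {
  cfg <- quick_config(n_permutations = 1000, seed = 4)
  blanks <- rnorm(20, 0, 0.05)
  # BW = CW
  tr <- list(D2 = rep(c(0.8, 0.9), 6), D1 = rep(c(0.2, 0.25), 6))
  expect_equal(classify_column_tuning(
    whisker_trial_list(cell_table(tr, blanks), "roi_1"), "D2", "D2", cfg),
    "CW_tuned")
  # BW != CW with a large margin -> nonCW_tuned
  expect_equal(classify_column_tuning(
    whisker_trial_list(cell_table(tr, blanks), "roi_1"), "D2", "D1", cfg),
    "nonCW_tuned")
  # BW != CW but statistically equivalent -> CW_tuned (conservative)
  tr2 <- list(D2 = c(0.50, 0.52, 0.49, 0.51), D1 = c(0.49, 0.51, 0.50, 0.52))
  expect_equal(classify_column_tuning(
    whisker_trial_list(cell_table(tr2, blanks), "roi_1"), "D2", "D1", cfg),
    "CW_tuned")
  # septal cells
  expect_equal(classify_column_tuning(NULL, "D2", NA_character_, cfg),
               "septal")
})

test_that("rank-ordered curves apply the inclusion rule and average correctly", {
  profiles <- dplyr::bind_rows(
    tibble::tibble(roi_id = "a", whisker = whisker_labels(),
                   mean_evoked = c(0.1, 0.2, 0.1, 0.3, 0.9, 0.5,
                                   0.0, -0.1, 0.2),
                   blank_sd = 1),
    tibble::tibble(roi_id = "b", whisker = whisker_labels(),
                   mean_evoked = c(0.0, 0.1, 0.0, 0.2, 0.7, 0.3,
                                   0.1, 0.0, 0.1),
                   blank_sd = 1),
    tibble::tibble(roi_id = "corner", whisker = whisker_labels(),
                   mean_evoked = c(0.9, 0.1, 0.0, 0.1, 0.2, 0.0,
                                   0.0, 0.0, 0.0),
                   blank_sd = 1)
  )
  summaries <- tibble::tibble(roi_id = c("a", "b", "corner"),
                              bw = c("D2", "D2", "C1"))
  rc <- rank_ordered_curves(summaries, profiles, normalize = "to_blank")
  expect_equal(unique(rc$n_cells), 2)  # corner-BW cell excluded
  sa <- sort(profiles$mean_evoked[profiles$roi_id == "a"], decreasing = TRUE)
  sb <- sort(profiles$mean_evoked[profiles$roi_id == "b"], decreasing = TRUE)
  expect_equal(rc$mean, (sa + sb) / 2)
  # negatives are retained (last rank can be negative)
  expect_lt(min(rc$mean), 0.01)

  rc1 <- rank_ordered_curves(summaries[1, ], profiles, normalize = "to_max")
  expect_equal(rc1$mean, sa / sa[1])
})

test_that("noiseless synthetic data give perfect BW recovery", {
  sc <- noiseless_sim(n_cells = 40, seed = 21)
  exp <- simulate_experiment(sc)
  cfg <- quick_config(seed = 6)
  tab <- filter_analysis_trials(exp$tables[[1]], config = cfg)
  prof <- response_profiles(tab, cfg)
  ts <- tuning_summaries(tab, prof, config = cfg)
  truth <- exp$truth[[1]]
  got <- truth$peak[match(ts$roi_id, truth$roi_id)]
  expect_equal(ts$bw, got)
  expect_equal(nrow(ts), sum(truth$responsive))
})
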