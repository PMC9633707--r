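test_that("synthetic barrel maps sit on the lattice with equal areas", {
  sc <- sim_config(apothem = 120, spacing = 300)
  map <- make_barrel_map(sc)
  expect_equal(nrow(map), 9)
  d2 <- map[map$whisker == "D2", ]
  expect_equal(c(d2$centroid_x, d2$centroid_y), c(0, 0))
  # centroid-to-edge distance along an apothem equals the apothem
  expect_equal(whiskermap:::ray_boundary_distance(
    c(0, 0), c(1, 0), d2$boundary[[1]]), 120, tolerance = 1e-9)
  areas <- vapply(map$boundary, whiskermap:::polygon_area, numeric(1))
  expect_equal(max(areas) - min(areas), 0, tolerance = 1e-8)
  # row/arc adjacency: C2 sits directly above D2 in the y-up frame
  c2 <- map[map$whisker == "C2", ]
  expect_equal(c(c2$centroid_x, c2$centroid_y), c(0, 300))
})

test_that("generation is deterministic given config + seed", {
  sc <- sim_config(n_cells = 60, n_sessions = 2, seed = 123)
  a <- simulate_experiment(sc)
  b <- simulate_experiment(sc)
  expect_identical(a$roster, b$roster)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$tables, as.data.frame),
                   lapply(b$tables, as.data.frame))
  expect_identical(a$change_log, b$change_log)
})

test_that("generated trial tables satisfy the data-model invariants", {
  sc <- sim_config(n_cells = 50, n_sessions = 2, seed = 5)
  exp <- simulate_experiment(sc)
  for (tab in exp$tables) {
    expect_s3_class(trial_table(tab), "trial_table")
    expect_equal(sum(tab$stimulus_kind == "blank"), sc$n_blank)
    expect_equal(sum(tab$stimulus_kind == "single_whisker"),
                 9 * sc$trials_per_whisker)
  }
  expect_s3_class(exp$map, "barrel_map")
})

test_that("structure-free configs give position-independent peak whiskers", {
  sc <- sim_config(n_cells = 700, gradient_strength = 0, cluster_strength = 0,
                   seed = 31)
  cells <- sample_cells(sc, make_barrel_map(sc))
  tr <- cells$truth[cells$truth$responsive, ]
  ro <- cells$roster[match(tr$roi_id, cells$roster$roi_id), ]
  # co-columnar pairs only: the columnar bias itself is positional
  # structure by design; with gradient and clusters off, near pairs in a
  # column must not be more co-tuned than far co-columnar pairs
  same_bw_rate <- function(d_max, d_min = 0) {
    n <- nrow(tr); hits <- 0; tot <- 0
    for (i in seq_len(n - 1)) {
      rest <- seq(i + 1, n)
      d <- sqrt((ro$x[rest] - ro$x[i])^2 + (ro$y[rest] - ro$y[i])^2)
      sel <- d < d_max & d >= d_min & tr$ref_whisker[rest] == tr$ref_whisker[i]
      hits <- hits + sum(tr$peak[rest][sel] == tr$peak[i])
      tot <- tot + sum(sel)
    }
    c(hits, tot)
  }
  near <- same_bw_rate(25)
  far <- same_bw_rate(1e9, 60)
  expect_gt(near[2], 20)
  ci <- suppressWarnings(
    prop.test(near[1], near[2], p = far[1] / far[2]))
  expect_gt(ci$p.value, 0.01)
})

test_that("cw_tuned_fraction and drift fractions are recovered within binomial CIs", {
  sc <- sim_config(n_cells = 2000, gradient_strength = 0,
                   cluster_strength = 0, responsive_fraction = 1, seed = 17)
  cells <- sample_cells(sc, make_barrel_map(sc))
  tr <- cells$truth
  columnar <- !is.na(tr$ref_whisker) & tr$radius <= 1
  frac <- mean(tr$peak[columnar] == tr$ref_whisker[columnar])
  n <- sum(columnar)
  ci <- 1.96 * sqrt(0.52 * 0.48 / n)
  expect_lt(abs(frac - 0.52), ci + 0.02)

  # cw_tuned_fraction = 1: every columnar responsive cell peaks at its CW
  sc1 <- sim_config(n_cells = 200, cw_tuned_fraction = 1,
                    gradient_strength = 0, cluster_strength = 0,
                    responsive_fraction = 1, seed = 18)
  c1 <- sample_cells(sc1, make_barrel_map(sc1))
  expect_true(all(c1$truth$peak == c1$truth$ref_whisker))

  # drift fractions: 0.3 non-CW, 0.05 CW at n = 1000
  scd <- sim_config(n_cells = 1000, responsive_fraction = 1,
                    gradient_strength = 0, cluster_strength = 0,
                    drift_noncw = 0.3, drift_cw = 0.05,
                    com_jitter_prob = 0, seed = 19)
  cd <- sample_cells(scd, make_barrel_map(scd))
  dr <- apply_drift(cd$truth, scd, interval = 1L, seed = 20)
  log <- dr$change_log
  is_cw <- cd$truth$base_peak == cd$truth$ref_whisker
  for (cls in c(TRUE, FALSE)) {
    p_true <- if (cls) 0.05 else 0.3
    n_cls <- sum(is_cw == cls)
    obs <- mean(log$change[is_cw == cls] == "BW_shift")
    expect_lt(abs(obs - p_true),
              1.96 * sqrt(p_true * (1 - p_true) / n_cls) + 0.01)
  }
})

test_that("drift is grid-adjacent, logged consistently, and off when disabled", {
  sc0 <- sim_config(n_cells = 100, responsive_fraction = 1,
                    drift_noncw = 0, drift_cw = 0, com_jitter_prob = 0,
                    seed = 23)
  c0 <- sample_cells(sc0, make_barrel_map(sc0))
  d0 <- apply_drift(c0$truth, sc0, seed = 24)
  expect_identical(d0$truth$peak, c0$truth$peak)
  expect_true(all(d0$change_log$change == "none"))

  # non-CW fraction 1, CW fraction 0
  sc1 <- sim_config(n_cells = 150, responsive_fraction = 1,
                    drift_noncw = 1, drift_cw = 0, com_jitter_prob = 0,
                    seed = 25)
  c1 <- sample_cells(sc1, make_barrel_map(sc1))
  d1 <- apply_drift(c1$truth, sc1, seed = 26)
  is_cw <- c1$truth$base_peak == c1$truth$ref_whisker
  expect_true(all(d1$change_log$change[!is_cw] == "BW_shift"))
  expect_true(all(d1$change_log$change[is_cw] == "none"))

  # every shifted BW is grid-adjacent to its predecessor, across sessions
  scm <- sim_config(n_cells = 80, responsive_fraction = 1, n_sessions = 4,
                    drift_noncw = 0.5, drift_cw = 0.2, seed = 27)
  em <- simulate_experiment(scm)
  shifts <- em$change_log[em$change_log$change == "BW_shift", ]
  expect_gt(nrow(shifts), 10)
  adj <- vapply(seq_len(nrow(shifts)), function(i) {
    shifts$new_peak[i] %in% adjacent_whiskers(shifts$old_peak[i])
  }, logical(1))
  expect_true(all(adj))
  # change log consistent with successive truths
  for (i in seq_len(nrow(em$change_log))) {
    cl <- em$change_log[i, ]
    t_prev <- em$truth[[cl$interval]]
    t_next <- em$truth[[cl$interval + 1]]
    if (cl$change == "BW_shift") {
      expect_false(identical(
        t_prev$peak[t_prev$roi_id == cl$roi_id],
        t_next$peak[t_next$roi_id == cl$roi_id]))
    }
  }
})

test_that("session simulation obeys the noise model", {
  # zero noise: per-whisker trial means equal the true surface exactly
  sc <- noiseless_sim(n_cells = 15, seed = 33)
  exp <- simulate_experiment(sc)
  tab <- exp$tables[[1]]
  truth <- exp$truth[[1]]
  roi <- truth$roi_id[truth$responsive][1]
  surf <- truth$surface[[match(roi, truth$roi_id)]]
  for (w in c("D2", "C1", "E3")) {
    v <- tab[[roi]][tab$stimulus_kind == "single_whisker" & tab$whisker == w]
    expect_equal(unique(v), unname(surf[w]))
  }

  # non-responsive cells: whisker and blank trials share a distribution
  scn <- sim_config(n_cells = 30, responsive_fraction = 0, seed = 34)
  en <- simulate_experiment(scn)
  tn <- en$tables[[1]]
  ks <- stats::ks.test(
    tn$roi_0001[tn$stimulus_kind == "single_whisker"],
    tn$roi_0001[tn$stimulus_kind == "blank"])
  expect_gt(ks$p.value, 0.01)

  # blank-trial mean within 3 sd / sqrt(n) of zero at the stated SD
  scb <- sim_config(n_cells = 10, noise_sd = 0.08, seed = 35)
  eb <- simulate_experiment(scb)
  bl <- eb$tables[[1]]$roi_0001[eb$tables[[1]]$stimulus_kind == "blank"]
  expect_lt(abs(mean(bl)), 3 * 0.08 / sqrt(length(bl)))
})

test_that("wavering gates whole-session responsiveness without roster changes", {
  sc <- sim_config(n_cells = 120, responsive_fraction = 1,
                   wavering_drop = 0.4, n_sessions = 1, seed = 41)
  exp <- simulate_experiment(sc)
  gated <- exp$gated[[1]]
  expect_gt(length(gated), 10)
  tab <- exp$tables[[1]]
  # gated cells look like blanks on whisker trials
  g1 <- gated[1]
  ks <- stats::ks.test(tab[[g1]][tab$stimulus_kind == "single_whisker"],
                       tab[[g1]][tab$stimulus_kind == "blank"])
  expect_gt(ks$p.value, 0.01)
  expect_equal(ncol(tab) - 5, 120)  # roster unchanged
})
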