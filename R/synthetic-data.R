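#' Simulation configuration
#'
#' Parameters of the synthetic barrel map, cell roster, and trial
#' generator. Defaults emulate the study conditions for an awake L2/3
#' imaging field: ~30% of cells whisker-responsive, 52% of columnar
#' responsive cells tuned to their columnar whisker, sharp single-peak
#' 3x3 tuning surfaces with a subcolumnar gradient and local (20 um)
#' co-tuned clusters, ~40 trials per single whisker and ~100 blanks per
#' session, four sessions with bounded best-whisker drift concentrated in
#' non-CW-tuned cells (one-step row/arc shifts), and per-session
#' responsiveness wavering implemented as amplitude gating.
#'
#' @param apothem Hexagonal column apothem, um.
#' @param spacing Column centroid lattice spacing, um (septa arise from
#'   spacing exceeding the hexagon extent).
#' @param n_cells Cells in the roster.
#' @param responsive_fraction Probability a cell is whisker-responsive.
#' @param cw_tuned_fraction Probability a columnar responsive cell's true
#'   peak is its columnar whisker.
#' @param amp_mean,amp_sdlog Peak-response amplitude: lognormal with
#'   median `amp_mean` (dF/F) and log-SD `amp_sdlog`.
#' @param decay Per-grid-step multiplicative falloff of the tuning surface
#'   (Chebyshev distance on the 3x3 grid).
#' @param gradient_strength Radial pull of the CW-tuned probability toward
#'   the column center (0 disables the subcolumnar gradient).
#' @param cluster_scale,cluster_strength Local co-tuning: each responsive
#'   cell adopts a neighbour's (within `cluster_scale` um) peak whisker
#'   with probability `cluster_strength` (0 disables clusters).
#' @param suppressed_fraction Probability a responsive cell carries one
#'   suppressed (negative-mean) far whisker, exercising the
#'   negative-response rules.
#' @param suppressed_amp Mean dF/F of a suppressed whisker (negative).
#' @param noise_sd Additive blank-trial noise SD (dF/F), the blank noise
#'   floor.
#' @param gain_sdlog Log-SD of the per-trial multiplicative lognormal gain.
#' @param trials_per_whisker,n_blank Trials per single-whisker stimulus and
#'   blank trials per session.
#' @param n_sessions Number of longitudinal sessions.
#' @param drift_noncw,drift_cw Per-interval probability that a non-CW /
#'   CW ground-truth cell shifts its best whisker by one grid step
#'   (re-shifts resample around the base surface, so drift is bounded).
#' @param com_jitter_prob Probability a non-shifting responsive cell gets a
#'   bounded surface perturbation that preserves its BW.
#' @param com_jitter Bound on the multiplicative perturbation of non-peak
#'   responses for CoM jitter.
#' @param wavering_drop Per-session probability a responsive cell's surface
#'   is gated to zero (appears non-responsive that session).
#' @param wavering_gain Per-session probability a non-responsive cell
#'   transiently expresses a small random surface.
#' @param seed Integer seed.
#' @return A list of class `"wm_sim_config"`.
#' @export
sim_config <- function(apothem = 125, spacing = 300,
                       n_cells = 600,
                       responsive_fraction = 0.30,
                       cw_tuned_fraction = 0.52,
                       amp_mean = 0.4, amp_sdlog = 0.4,
                       decay = 0.35,
                       gradient_strength = 0.3,
                       cluster_scale = 20, cluster_strength = 0.4,
                       suppressed_fraction = 0.25,
                       suppressed_amp = -0.05,
                       noise_sd = 0.08, gain_sdlog = 0.5,
                       trials_per_whisker = 40, n_blank = 100,
                       n_sessions = 4,
                       drift_noncw = 0.3, drift_cw = 0.05,
                       com_jitter_prob = 0.15, com_jitter = 0.5,
                       wavering_drop = 0.15, wavering_gain = 0,
                       seed = NULL) {
  cfg <- as.list(environment())
  probs <- c("responsive_fraction", "cw_tuned_fraction",
             "suppressed_fraction", "drift_noncw", "drift_cw",
             "com_jitter_prob", "wavering_drop", "wavering_gain",
             "cluster_strength")
  for (p in probs) {
    stopifnot(cfg[[p]] >= 0, cfg[[p]] <= 1)
  }
  stopifnot(apothem > 0, spacing > 0, n_cells > 0, decay >= 0, decay < 1,
            noise_sd >= 0, gain_sdlog >= 0, trials_per_whisker > 0,
            n_blank > 0, n_sessions >= 1, suppressed_amp <= 0)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  structure(cfg, class = "wm_sim_config")
}

#' Synthetic barrel map of regular hexagons
#'
#' Nine hexagonal columns (C1-E3) on a 3x3 lattice matching the whisker
#' grid's row/arc adjacency, with the D2 centroid at the frame origin.
#' Rows run along y (C above D above E in the y-up frame), arcs along x.
#'
#' @param config A [sim_config()].
#' @return A [barrel_map()].
#' @examples
#' map <- make_barrel_map(sim_config())
#' nrow(map)  # 9
#' @export
make_barrel_map <- function(config = sim_config()) {
  R <- config$apothem / cos(pi / 6)
  hex <- function(cx, cy) {
    th <- (seq(30, 330, by = 60)) * pi / 180  # pointy-top
    cbind(cx + R * cos(th), cy + R * sin(th))
  }
  g <- whisker_grid()
  barrel_map(tibble::tibble(
    whisker = g$whisker,
    centroid_x = (g$gx - 1) * config$spacing,
    centroid_y = (1 - g$gy) * config$spacing,
    boundary = purrr::map2(
      (g$gx - 1) * config$spacing, (1 - g$gy) * config$spacing, hex)
  ))
}

# Chebyshev distance between whiskers on the 3x3 grid.
grid_cheb <- function(a, b) {
  pa <- whisker_to_grid(a); pb <- whisker_to_grid(b)
  pmax(abs(pa[, "gx"] - pb[, "gx"]), abs(pa[, "gy"] - pb[, "gy"]))
}

# Single-peak 3x3 surface: amp at the peak, geometric falloff, optional
# suppressed whisker.
make_surface <- function(peak, amp, decay, suppressed = NULL,
                         suppressed_amp = 0) {
  d <- grid_cheb(whisker_labels(), peak)
  s <- stats::setNames(amp * decay^d, whisker_labels())
  if (!is.null(suppressed) && !is.na(suppressed)) s[suppressed] <- suppressed_amp
  s
}

#' Sample a cell roster with ground-truth tuning
#'
#' Positions are uniform within the analysis inclusion zone (1.25 column
#' radii of some column). Each responsive cell's true peak whisker mixes
#' three ingredients: a columnar bias (probability `cw_tuned_fraction` of
#' matching the nearest column's whisker, non-CW peaks drawn from the
#' grid-adjacent whiskers), a radial gradient (CW probability declines
#' with normalized distance from the column center at rate
#' `gradient_strength`), and a spatially correlated cluster field (cells
#' adopt a near neighbour's peak with probability `cluster_strength`).
#'
#' @param config A [sim_config()].
#' @param map A [barrel_map()] from [make_barrel_map()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return A list: `roster` (tibble `roi_id`, `field_id`, `x`, `y`) and
#'   `truth` (tibble `roi_id`, `ref_whisker`, `responsive`, `base_peak`,
#'   `peak`, `amp`, `suppressed`, `surface` list-column of named
#'   9-vectors).
#' @export
sample_cells <- function(config = sim_config(), map = make_barrel_map(config),
                         seed = config$seed) {
  acfg <- analysis_config()
  with_seed_maybe(seed, {
    xs <- range(unlist(purrr::map(map$boundary, ~ .x[, 1])))
    ys <- range(unlist(purrr::map(map$boundary, ~ .x[, 2])))
    pad <- config$apothem * (acfg$inclusion_radius - 1) * 1.6 + 1
    pts <- matrix(numeric(0), 0, 2)
    ref <- character(0); rad <- numeric(0)
    while (nrow(pts) < config$n_cells) {
      m <- 2 * (config$n_cells - nrow(pts)) + 20
      cand <- tibble::tibble(
        roi_id = "tmp",
        x = stats::runif(m, xs[1] - pad, xs[2] + pad),
        y = stats::runif(m, ys[1] - pad, ys[2] + pad)
      )
      a <- assign_column(cand, map, acfg)
      ok <- a$column != "excluded"
      pts <- rbind(pts, cbind(a$x[ok], a$y[ok]))
      ref <- c(ref, a$nearest_column[ok])
      rad <- c(rad, a$nearest_radius[ok])
    }
    keep <- seq_len(config$n_cells)
    roster <- tibble::tibble(
      roi_id = sprintf("roi_%04d", keep), field_id = "f1",
      x = pts[keep, 1], y = pts[keep, 2]
    )
    ref <- ref[keep]; rad <- rad[keep]
    n <- config$n_cells
    responsive <- stats::runif(n) < config$responsive_fraction

    p_cw <- config$cw_tuned_fraction +
      config$gradient_strength * (0.6 - rad)
    p_cw <- pmin(pmax(p_cw, 0.01), 0.99)
    if (config$gradient_strength == 0) p_cw <- rep(config$cw_tuned_fraction, n)
    is_cw <- stats::runif(n) < p_cw
    peak <- ifelse(is_cw, ref, NA_character_)
    for (i in which(!is_cw)) {
      adj <- adjacent_whiskers(ref[i])
      peak[i] <- adj[sample.int(length(adj), 1)]
    }
    # spatially correlated cluster field: adopt a near neighbour's peak
    if (config$cluster_strength > 0) {
      ord <- sample.int(n)
      seen <- integer(0)
      for (i in ord) {
        if (responsive[i] && length(seen) > 0 &&
            stats::runif(1) < config$cluster_strength) {
          d2 <- (roster$x[seen] - roster$x[i])^2 +
            (roster$y[seen] - roster$y[i])^2
          nb <- seen[d2 < config$cluster_scale^2 & d2 > 0]
          nb <- nb[responsive[nb]]
          if (length(nb) > 0) {
            peak[i] <- peak[nb[sample.int(length(nb), 1)]]
          }
        }
        seen <- c(seen, i)
      }
    }
    amp <- stats::rlnorm(n, log(config$amp_mean), config$amp_sdlog)
    suppressed <- rep(NA_character_, n)
    surface <- vector("list", n)
    for (i in seq_len(n)) {
      if (!responsive[i]) {
        surface[[i]] <- stats::setNames(rep(0, 9), whisker_labels())
        next
      }
      if (stats::runif(1) < config$suppressed_fraction) {
        far <- whisker_labels()[grid_cheb(whisker_labels(), peak[i]) >= 2]
        if (length(far) > 0) suppressed[i] <- far[sample.int(length(far), 1)]
      }
      surface[[i]] <- make_surface(peak[i], amp[i], config$decay,
                                   suppressed[i], config$suppressed_amp)
    }
    truth <- tibble::tibble(
      roi_id = roster$roi_id, ref_whisker = ref, radius = rad,
      responsive = responsive, base_peak = peak, peak = peak,
      amp = amp, suppressed = suppressed, surface = surface
    )
    truth$base_peak[!responsive] <- NA_character_
    truth$peak[!responsive] <- NA_character_
    list(roster = roster, truth = truth)
  })
}

#' Apply one interval of bounded tuning drift
#'
#' Selected responsive cells shift their peak whisker by one grid step
#' (probability `drift_noncw` for cells whose base peak differs from their
#' columnar whisker, `drift_cw` otherwise). Shifts are bounded: a cell at
#' its base peak moves to a random grid-adjacent whisker; an already
#' shifted cell returns to its base peak, so every move is grid-adjacent
#' to its predecessor and the surface never walks away from base. Cells
#' that do not shift may instead receive a bounded, BW-preserving
#' perturbation of their non-peak responses (CoM jitter, probability
#' `com_jitter_prob`); all other cells are reset to their base surface.
#'
#' @param truth Truth tibble from [sample_cells()] (current session state).
#' @param config A [sim_config()].
#' @param interval Integer label for the change log.
#' @param seed Optional integer seed.
#' @return A list: `truth` (next session's state) and `change_log`
#'   (tibble `roi_id`, `interval`, `change` in
#'   `none`/`BW_shift`/`CoM_jitter`, `old_peak`, `new_peak`).
#' @export
apply_drift <- function(truth, config = sim_config(), interval = 1L,
                        seed = config$seed) {
  with_seed_maybe(seed, {
    n <- nrow(truth)
    change <- rep("none", n)
    old_peak <- truth$peak
    for (i in seq_len(n)) {
      if (!truth$responsive[i]) next
      is_cw <- truth$base_peak[i] == truth$ref_whisker[i]
      p_shift <- if (is_cw) config$drift_cw else config$drift_noncw
      if (stats::runif(1) < p_shift) {
        if (truth$peak[i] == truth$base_peak[i]) {
          adj <- adjacent_whiskers(truth$peak[i])
          truth$peak[i] <- adj[sample.int(length(adj), 1)]
        } else {
          truth$peak[i] <- truth$base_peak[i]  # bounded: return to base
        }
        truth$surface[[i]] <- make_surface(
          truth$peak[i], truth$amp[i], config$decay,
          truth$suppressed[i], config$suppressed_amp)
        change[i] <- "BW_shift"
      } else if (stats::runif(1) < config$com_jitter_prob) {
        s <- make_surface(truth$peak[i], truth$amp[i], config$decay,
                          truth$suppressed[i], config$suppressed_amp)
        nonpeak <- setdiff(whisker_labels(), truth$peak[i])
        fac <- stats::runif(length(nonpeak), 1 - config$com_jitter,
                            1 + config$com_jitter)
        s[nonpeak] <- pmin(s[nonpeak] * fac, 0.95 * s[[truth$peak[i]]])
        truth$surface[[i]] <- s
        change[i] <- "CoM_jitter"
      } else {
        truth$surface[[i]] <- make_surface(
          truth$peak[i], truth$amp[i], config$decay,
          truth$suppressed[i], config$suppressed_amp)
      }
    }
    list(truth = truth,
         change_log = tibble::tibble(
           roi_id = truth$roi_id, interval = interval, change = change,
           old_peak = old_peak, new_peak = truth$peak))
  })
}

#' Simulate one session's trial table
#'
#' Each single-whisker trial's evoked dF/F is the cell's true mean for the
#' presented whisker times a lognormal per-trial gain, plus additive
#' Gaussian blank noise; blank trials draw the additive noise only.
#' Trial order is randomized. Per-session responsiveness wavering gates a
#' responsive cell's whole surface to zero with probability
#' `wavering_drop`.
#'
#' @param roster,truth Output of [sample_cells()] (truth for this session).
#' @param config A [sim_config()].
#' @param session_index Session number (recorded in `session_id`).
#' @param seed Optional integer seed.
#' @return A list: `table` (a `trial_table`) and `gated` (roi_ids gated
#'   off this session).
#' @export
simulate_session <- function(roster, truth, config = sim_config(),
                             session_index = 1L, seed = config$seed) {
  with_seed_maybe(seed, {
    n_cells <- nrow(roster)
    stim <- c(rep(whisker_labels(), each = config$trials_per_whisker),
              rep(NA_character_, config$n_blank))
    stim <- stim[sample.int(length(stim))]
    n_trials <- length(stim)

    gate <- rep(1, n_cells)
    drop <- truth$responsive & stats::runif(n_cells) < config$wavering_drop
    gate[drop] <- 0
    gained <- !truth$responsive & stats::runif(n_cells) < config$wavering_gain
    surfaces <- truth$surface
    for (i in which(gained)) {
      w <- whisker_labels()[sample.int(9, 1)]
      surfaces[[i]] <- make_surface(w, config$amp_mean, config$decay)
    }
    gate[gained] <- 1

    ev <- matrix(0, n_trials, n_cells)
    smat <- do.call(rbind, surfaces)  # cells x 9
    for (t in seq_len(n_trials)) {
      if (is.na(stim[t])) {
        mu <- rep(0, n_cells)
      } else {
        mu <- smat[, stim[t]] * gate
      }
      gain <- if (config$gain_sdlog > 0) {
        stats::rlnorm(n_cells, 0, config$gain_sdlog)
      } else rep(1, n_cells)
      noise <- if (config$noise_sd > 0) {
        stats::rnorm(n_cells, 0, config$noise_sd)
      } else rep(0, n_cells)
      ev[t, ] <- mu * gain + noise
    }
    colnames(ev) <- roster$roi_id
    tab <- tibble::as_tibble(ev)
    tab <- dplyr::bind_cols(tibble::tibble(
      session_id = sprintf("s%02d", session_index),
      trial_index = seq_len(n_trials) - 1L,
      stimulus_kind = ifelse(is.na(stim), "blank", "single_whisker"),
      whisker = stim,
      lick = FALSE
    ), tab)
    list(table = trial_table(tab), gated = roster$roi_id[drop])
  })
}

#' Simulate a full longitudinal experiment
#'
#' Convenience wrapper: builds the map, samples the roster and ground
#' truth, then alternates drift intervals and session simulation.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return A list: `map`, `roster`, `truth` (per-session list of truth
#'   tibbles), `tables` (per-session `trial_table`s), `change_log`, and
#'   `gated` (per-session gated roi_ids).
#' @export
simulate_experiment <- function(config = sim_config(), seed = config$seed) {
  with_seed_maybe(seed, {
    map <- make_barrel_map(config)
    cells <- sample_cells(config, map, seed = NULL)
    truth <- cells$truth
    truths <- list(); tables <- list(); gated <- list()
    logs <- list()
    for (s in seq_len(config$n_sessions)) {
      if (s > 1) {
        dr <- apply_drift(truth, config, interval = s - 1L, seed = NULL)
        truth <- dr$truth
        logs[[s - 1]] <- dr$change_log
      }
      truths[[s]] <- truth
      ses <- simulate_session(cells$roster, truth, config,
                              session_index = s, seed = NULL)
      tables[[s]] <- ses$table
      gated[[s]] <- ses$gated
    }
    list(map = map, roster = cells$roster, truth = truths, tables = tables,
         change_log = dplyr::bind_rows(logs), gated = gated)
  })
}
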