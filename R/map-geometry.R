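#' Assign ROIs to barrel columns, septa, or exclusion
#'
#' A cell inside a column boundary belongs to that column. A cell outside
#' every boundary but within `inclusion_radius` (default 1.25) normalized
#' column radii of some column centroid is septal; anything farther is
#' excluded from analysis. The per-direction "column radius" is the
#' centroid-to-boundary distance along the centroid-to-cell ray, matching
#' [normalize_position()].
#'
#' @param rois Tibble with `roi_id`, `x`, `y` (um, barrel-map frame).
#' @param map A [barrel_map()].
#' @param config An [analysis_config()].
#' @return `rois` with added columns `column` (whisker label, `"septal"`,
#'   or `"excluded"`) and `nearest_column` / `nearest_radius` (normalized).
#' @export
assign_column <- function(rois, map, config = analysis_config()) {
  rois <- tibble::as_tibble(rois)
  n <- nrow(rois)
  column <- character(n)
  nearest_col <- character(n)
  nearest_rad <- numeric(n)
  for (i in seq_len(n)) {
    px <- rois$x[i]; py <- rois$y[i]
    inside <- NA_character_
    radii <- numeric(nrow(map))
    for (k in seq_len(nrow(map))) {
      poly <- map$boundary[[k]]
      cx <- map$centroid_x[k]; cy <- map$centroid_y[k]
      d <- sqrt((px - cx)^2 + (py - cy)^2)
      if (d == 0) {
        radii[k] <- 0
      } else {
        rb <- ray_boundary_distance(c(cx, cy), c(px, py), poly)
        radii[k] <- if (is.na(rb) || rb == 0) Inf else d / rb
      }
      if (is.na(inside) && point_in_polygon(px, py, poly)) {
        inside <- map$whisker[k]
      }
    }
    kmin <- which.min(radii)
    nearest_col[i] <- map$whisker[kmin]
    nearest_rad[i] <- radii[kmin]
    column[i] <- if (!is.na(inside)) {
      inside
    } else if (radii[kmin] <= config$inclusion_radius) {
      "septal"
    } else {
      "excluded"
    }
  }
  out <- dplyr::mutate(rois, column = column, nearest_column = nearest_col,
                       nearest_radius = nearest_rad)
  carry_config(out, config)
}

# Canonical sector angle (degrees CCW) for a lattice offset between columns.
lattice_angle <- function(d_arc, d_row) {
  # y-up frame: row C is "up" relative to D, so +d_row (C -> E) points down
  (atan2(-d_row, d_arc) * 180 / pi) %% 360
}

#' Normalized polar position of ROIs about a reference column
#'
#' Projects cells into a common columnar coordinate frame. Radius is the
#' centroid-to-cell distance divided by the centroid-to-boundary distance
#' along the same ray, giving units of column radii (0 at the centroid, 1
#' on the boundary). Angle is mapped piecewise-linearly so that the
#' vectors from the reference centroid to each neighbouring column's
#' centroid land on the canonical 45-degree sectors (0, 45, ..., 315
#' degrees, counterclockwise); physical angles between two neighbour
#' directions interpolate linearly between their canonical angles. The
#' result is invariant to global translation and rotation of the map.
#'
#' @param rois Tibble with `roi_id`, `x`, `y`.
#' @param reference_column Whisker label of the reference column.
#' @param map A [barrel_map()].
#' @return Tibble `roi_id`, `radius` (column radii), `angle` (degrees in
#'   `[0, 360)`). Cells coincident with the centroid get radius 0, angle 0.
#' @export
normalize_position <- function(rois, reference_column, map) {
  k <- match(reference_column, map$whisker)
  if (is.na(k)) stop("reference column not in map", call. = FALSE)
  cx <- map$centroid_x[k]; cy <- map$centroid_y[k]
  poly <- map$boundary[[k]]

  # anchor directions: physical angle of each neighbour centroid, canonical
  # sector angle from the lattice offset
  ref <- whisker_to_grid(reference_column)
  g <- whisker_grid()
  nb <- g[abs(g$gx - ref[, "gx"]) <= 1 & abs(g$gy - ref[, "gy"]) <= 1 &
            g$whisker != reference_column, ]
  nb <- nb[nb$whisker %in% map$whisker, ]
  if (nrow(nb) < 2) stop("reference column needs >= 2 mapped neighbours",
                         call. = FALSE)
  mi <- match(nb$whisker, map$whisker)
  phys <- (atan2(map$centroid_y[mi] - cy, map$centroid_x[mi] - cx) *
             180 / pi) %% 360
  canon <- lattice_angle(nb$gx - ref[, "gx"], nb$gy - ref[, "gy"])
  ord <- order(phys)
  phys <- phys[ord]; canon <- canon[ord]

  map_angle <- function(theta) {
    n <- length(phys)
    i <- findInterval(theta, phys)
    lo <- if (i == 0 || i == n) n else i
    hi <- if (lo == n) 1L else lo + 1L
    span_phys <- (phys[hi] - phys[lo]) %% 360
    if (span_phys == 0) return(canon[lo])
    frac <- ((theta - phys[lo]) %% 360) / span_phys
    span_canon <- (canon[hi] - canon[lo]) %% 360
    (canon[lo] + frac * span_canon) %% 360
  }

  radius <- numeric(nrow(rois))
  angle <- numeric(nrow(rois))
  for (i in seq_len(nrow(rois))) {
    dx <- rois$x[i] - cx; dy <- rois$y[i] - cy
    d <- sqrt(dx^2 + dy^2)
    if (d == 0) { radius[i] <- 0; angle[i] <- 0; next }
    rb <- ray_boundary_distance(c(cx, cy), c(rois$x[i], rois$y[i]), poly)
    radius[i] <- d / rb
    angle[i] <- map_angle((atan2(dy, dx) * 180 / pi) %% 360)
  }
  tibble::tibble(roi_id = rois$roi_id, radius = radius, angle = angle)
}

#' Tuning-ensemble topography
#'
#' For each whisker, gathers the ensemble of responsive cells whose
#' nominal BW is that whisker and summarises its spatial layout: fraction
#' of members inside the BW's anatomical column, normalized-radius
#' distribution about the BW column centroid, and the circular mean
#' direction (vector average of unit direction vectors) with resultant
#' length.
#'
#' @param summaries A [tuning_summaries()] tibble.
#' @param rois Roster tibble (`roi_id`, `x`, `y`).
#' @param map A [barrel_map()].
#' @return One row per whisker with members: `whisker`, `n_members`,
#'   `in_column_fraction`, `mean_radius`, `radii` (list-column),
#'   `circ_mean_deg`, `resultant_length`.
#' @export
ensemble_topography <- function(summaries, rois, map) {
  out <- purrr::map(map$whisker, function(w) {
    members <- summaries$roi_id[summaries$bw == w]
    if (length(members) == 0) return(NULL)
    mr <- rois[match(members, rois$roi_id), ]
    k <- match(w, map$whisker)
    poly <- map$boundary[[k]]
    np <- normalize_position(mr, w, map)
    inside <- point_in_polygon(mr$x, mr$y, poly)
    rad <- np$angle * pi / 180
    ux <- mean(cos(rad)); uy <- mean(sin(rad))
    tibble::tibble(
      whisker = w, n_members = length(members),
      in_column_fraction = mean(inside),
      mean_radius = mean(np$radius),
      radii = list(np$radius),
      circ_mean_deg = (atan2(uy, ux) * 180 / pi) %% 360,
      resultant_length = sqrt(ux^2 + uy^2)
    )
  })
  dplyr::bind_rows(out)
}

#' Linear tuning-gradient regression
#'
#' Ordinary least squares of a per-cell tuning or response measure on
#' distance from the column center, with a two-sided t test for nonzero
#' slope. Used for the subcolumnar tuning and response-magnitude
#' gradients.
#'
#' @param x Per-cell distance (column radii or um).
#' @param y Per-cell preference or magnitude.
#' @return One-row tibble: `slope`, `intercept`, `t`, `p`, `n`.
#' @export
gradient_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 finite points", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate x: zero variance", call. = FALSE)
  if (stats::sd(y) == 0) {
    return(tibble::tibble(slope = 0, intercept = y[1], t = 0, p = 1,
                          n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on essentially perfect fits; handled explicitly below
  co <- suppressWarnings(summary(fit)$coefficients)
  if (nrow(co) < 2 || is.na(co["x", "Std. Error"]) ||
      co["x", "Std. Error"] == 0) {
    slope <- stats::coef(fit)[["x"]]
    # zero residual variance: constant y (slope 0, no evidence) or an
    # exact line (p below machine floor)
    return(tibble::tibble(
      slope = slope, intercept = stats::coef(fit)[["(Intercept)"]],
      t = if (abs(slope) < 1e-12) 0 else Inf,
      p = if (abs(slope) < 1e-12) 1 else .Machine$double.xmin,
      n = length(x)
    ))
  }
  tibble::tibble(
    slope = co["x", "Estimate"], intercept = co["(Intercept)", "Estimate"],
    t = co["x", "t value"], p = co["x", "Pr(>|t|)"], n = length(x)
  )
}
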