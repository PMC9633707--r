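# Planar polygon utilities for barrel-column boundaries.
# Polygons are n x 2 matrices of vertices in um, implicitly closed.

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

point_in_polygon <- function(px, py, poly) {
  # even-odd crossing number; boundary points count as inside
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  edges <- lapply(seq_len(n), function(i) {
    list(a = poly[i, ], b = poly[if (i == n) 1L else i + 1L, ])
  })
  for (i in seq_len(n - 1L)) {
    for (k in seq(i + 1L, n)) {
      # skip adjacent edges (shared vertex)
      if (k == i + 1L || (i == 1L && k == n)) next
      if (segments_intersect(edges[[i]]$a, edges[[i]]$b,
                             edges[[k]]$a, edges[[k]]$b)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Distance from `origin` to the polygon boundary along the ray through
# `through`. Used as the per-direction "column radius". When a concave
# boundary is crossed more than once the nearest intersection is used.
ray_boundary_distance <- function(origin, through, poly) {
  dx <- through[1] - origin[1]; dy <- through[2] - origin[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(NA_real_)
  ux <- dx / len; uy <- dy / len
  n <- nrow(poly)
  best <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    den <- ux * ey - uy * ex
    if (abs(den) < 1e-12) next
    t <- ((a[1] - origin[1]) * ey - (a[2] - origin[2]) * ex) / den
    s <- ((a[1] - origin[1]) * uy - (a[2] - origin[2]) * ux) / den
    if (t > 1e-9 && s >= -1e-9 && s <= 1 + 1e-9 && t < best) best <- t
  }
  if (is.infinite(best)) NA_real_ else best
}
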