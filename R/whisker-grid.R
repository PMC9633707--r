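#' The 3x3 whisker stimulus grid
#'
#' Receptive fields are mapped with nine whiskers spanning rows C-E and
#' arcs 1-3. Each whisker label ("C1" ... "E3") maps bijectively onto a
#' Cartesian grid used for tuning center-of-mass calculations: arc gives
#' the x coordinate (arc 1 -> 0, arc 3 -> 2) and row gives y (C -> 0,
#' D -> 1, E -> 2), unit spacing.
#'
#' @return A tibble with one row per whisker: `whisker`, `row`, `arc`,
#'   and grid coordinates `gx`, `gy`.
#' @examples
#' whisker_grid()
#' @export
whisker_grid <- function() WHISKER_GRID

# built once at package build time; whisker_grid() is called in inner loops
WHISKER_GRID <- local({
  rows <- c("C", "D", "E")
  tibble::tibble(
    whisker = paste0(rep(rows, each = 3), rep(1:3, 3)),
    row = rep(rows, each = 3),
    arc = rep(1:3, 3),
    gx = rep(0:2, 3),
    gy = rep(0:2, each = 3)
  )
})

#' @rdname whisker_grid
#' @export
whisker_labels <- function() whisker_grid()$whisker

#' Convert between whisker labels and grid coordinates
#'
#' @param whisker Character vector of whisker labels, e.g. `"D2"`.
#' @param gx,gy Integer grid coordinates in `{0, 1, 2}` (arc and row axes).
#' @return `whisker_to_grid()` returns a two-column matrix of grid
#'   coordinates; `grid_to_whisker()` returns a character vector of labels.
#' @examples
#' whisker_to_grid("D2")
#' grid_to_whisker(1, 1)
#' @export
whisker_to_grid <- function(whisker) {
  g <- whisker_grid()
  idx <- match(whisker, g$whisker)
  if (anyNA(idx)) {
    stop("unknown whisker label(s): ",
         paste(unique(whisker[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  cbind(gx = g$gx[idx], gy = g$gy[idx])
}

#' @rdname whisker_to_grid
#' @export
grid_to_whisker <- function(gx, gy) {
  stopifnot(all(gx %in% 0:2), all(gy %in% 0:2))
  g <- whisker_grid()
  g$whisker[match(gx + 3L * gy, g$gx + 3L * g$gy)]
}

#' Grid-adjacent whiskers
#'
#' Two whiskers are adjacent when they share a row and differ by one arc,
#' or share an arc and differ by one row. Best-whisker drift in the
#' synthetic generator is restricted to these one-step moves.
#'
#' @param whisker A single whisker label.
#' @return Character vector of adjacent whisker labels.
#' @examples
#' adjacent_whiskers("D2")  # C2, D1, D3, E2
#' adjacent_whiskers("C1")  # C2, D1
#' @export
adjacent_whiskers <- function(whisker) {
  g <- whisker_grid()
  p <- whisker_to_grid(whisker)
  same_row <- g$gy == p[, "gy"] & abs(g$gx - p[, "gx"]) == 1L
  same_arc <- g$gx == p[, "gx"] & abs(g$gy - p[, "gy"]) == 1L
  g$whisker[same_row | same_arc]
}
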