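STIMULUS_KINDS <- c("single_whisker", "all_whisker", "tone", "blank")
TRIAL_META_COLS <- c("session_id", "trial_index", "stimulus_kind",
                     "whisker", "lick", "lick_times")

#' Construct and validate a trial table
#'
#' A trial table holds one session's trials in wide form: one row per trial,
#' metadata columns (`session_id`, `trial_index`, `stimulus_kind`, `whisker`,
#' `lick`, optional `lick_times`), and one numeric column of evoked dF/F per
#' ROI. `whisker` must be present exactly when `stimulus_kind` is
#' `"single_whisker"`. Lick trials are retained but flagged; downstream
#' analyses drop them via [filter_analysis_trials()].
#'
#' @param x A data frame in the schema above.
#' @return A validated `trial_table` tibble.
#' @seealso [read_trial_table()], [filter_analysis_trials()]
#' @export
trial_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("session_id", "trial_index", "stimulus_kind", "whisker", "lick")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_kind <- setdiff(unique(x$stimulus_kind), STIMULUS_KINDS)
  if (length(bad_kind) > 0) {
    stop("unknown stimulus kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  sw <- x$stimulus_kind == "single_whisker"
  if (any(sw & (is.na(x$whisker) | x$whisker == ""))) {
    stop("single_whisker trials must name a whisker", call. = FALSE)
  }
  if (any(!sw & !is.na(x$whisker) & x$whisker != "")) {
    stop("whisker must be absent unless stimulus_kind is single_whisker",
         call. = FALSE)
  }
  if (any(sw)) whisker_to_grid(x$whisker[sw])  # validates labels
  x$whisker[!sw] <- NA_character_
  x$trial_index <- as.integer(x$trial_index)
  if (anyNA(x$trial_index) || any(x$trial_index < 0)) {
    stop("trial_index must be a non-negative integer", call. = FALSE)
  }
  x$lick <- as.logical(x$lick)
  rois <- roi_columns(x)
  if (length(rois) > 0) {
    ev <- as.matrix(x[rois])
    if (!is.numeric(ev)) stop("ROI evoked columns must be numeric", call. = FALSE)
    bad <- which(rowSums(!is.finite(ev)) > 0)
    if (length(bad) > 0) {
      stop("non-finite evoked dF/F in trial row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  class(x) <- unique(c("trial_table", class(x)))
  x
}

#' @rdname trial_table
#' @export
roi_columns <- function(x) setdiff(names(x), TRIAL_META_COLS)

#' Read or write a trial table CSV
#'
#' @param path File path of a delimiter-separated trial table with header.
#' @param x A `trial_table`.
#' @return `read_trial_table()` returns a validated `trial_table`;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("whisker" %in% names(x)) x$whisker <- as.character(x$whisker)
  if ("lick_times" %in% names(x)) x$lick_times <- as.character(x$lick_times)
  trial_table(x)
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Restrict a trial table to analyzable trials
#'
#' Evoked responses are only analyzed on trials free of lick contamination.
#' For the one-vs-all task this keeps non-lick single-whisker and blank
#' trials. For the delayed D-vs-C/E task it keeps single-whisker and blank
#' trials with no lick during the stimulus + delay period, using per-trial
#' lick times (seconds from stimulus onset, semicolon-separated in the
#' `lick_times` column).
#'
#' @param table A `trial_table`.
#' @param task `"one_vs_all"` or `"d_vs_ce"`.
#' @param config An [analysis_config()] (supplies stimulus/delay durations).
#' @return The filtered `trial_table`. Errors if no blank trials survive,
#'   since the blank null is then undefined.
#' @export
filter_analysis_trials <- function(table, task = c("one_vs_all", "d_vs_ce"),
                                   config = analysis_config()) {
  task <- match.arg(task)
  table <- trial_table(table)
  keep_kind <- table$stimulus_kind %in% c("single_whisker", "blank")
  if (task == "one_vs_all") {
    keep <- keep_kind & !table$lick
  } else {
    cutoff <- config$stim_duration + config$delay_duration
    licks_in_window <- vapply(seq_len(nrow(table)), function(i) {
      if (!isTRUE(table$lick[i])) return(FALSE)
      lt <- table$lick_times[i]
      if (is.null(lt) || is.na(lt) || lt == "") return(TRUE)  # untimed lick
      times <- as.numeric(strsplit(lt, ";", fixed = TRUE)[[1]])
      any(times >= 0 & times < cutoff)
    }, logical(1))
    keep <- keep_kind & !licks_in_window
  }
  out <- table[keep, , drop = FALSE]
  if (!any(out$stimulus_kind == "blank")) {
    stop("no blank trials survive filtering; blank null is undefined",
         call. = FALSE)
  }
  carry_config(out, config)
}

#' Construct and validate a barrel map
#'
#' A barrel map records, for each whisker column, its whisker label, L4
#' centroid, and boundary polygon in a shared um frame. Boundaries must be
#' simple (non-self-intersecting) polygons containing their centroid;
#' the septal region is the complement of all column polygons.
#'
#' @param x A data frame with columns `whisker`, `centroid_x`, `centroid_y`
#'   and a list-column `boundary` of n x 2 vertex matrices.
#' @return A validated `barrel_map` tibble.
#' @export
barrel_map <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("whisker", "centroid_x", "centroid_y", "boundary")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("barrel map is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$whisker)) {
    stop("duplicate whisker label in barrel map", call. = FALSE)
  }
  whisker_to_grid(x$whisker)
  for (i in seq_len(nrow(x))) {
    poly <- as.matrix(x$boundary[[i]])
    if (ncol(poly) != 2 || nrow(poly) < 3) {
      stop("boundary of ", x$whisker[i], " must be an n x 2 vertex matrix",
           call. = FALSE)
    }
    if (!polygon_is_simple(poly)) {
      stop("boundary of column ", x$whisker[i], " is self-intersecting",
           call. = FALSE)
    }
    if (!point_in_polygon(x$centroid_x[i], x$centroid_y[i], poly)) {
      stop("centroid of column ", x$whisker[i], " lies outside its boundary",
           call. = FALSE)
    }
    x$boundary[[i]] <- unname(poly)
  }
  class(x) <- unique(c("barrel_map", class(x)))
  x
}

#' Read or write a barrel map JSON file
#'
#' The on-disk schema is a JSON array of objects, one per column, each with
#' fields `whisker` (label), `centroid` (`[x, y]` in um), and `boundary`
#' (array of `[x, y]` vertices in um).
#'
#' @param path JSON file path.
#' @param map A `barrel_map`.
#' @return `read_barrel_map()` returns a validated `barrel_map`;
#'   `write_barrel_map()` returns `path` invisibly.
#' @export
read_barrel_map <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  barrel_map(tibble::tibble(
    whisker = vapply(raw, function(z) z$whisker, character(1)),
    centroid_x = vapply(raw, function(z) as.numeric(z$centroid[[1]]), numeric(1)),
    centroid_y = vapply(raw, function(z) as.numeric(z$centroid[[2]]), numeric(1)),
    boundary = lapply(raw, function(z) {
      do.call(rbind, lapply(z$boundary, function(v) as.numeric(unlist(v))))
    })
  ))
}

#' @rdname read_barrel_map
#' @export
write_barrel_map <- function(map, path) {
  out <- lapply(seq_len(nrow(map)), function(i) {
    list(
      whisker = map$whisker[i],
      centroid = c(map$centroid_x[i], map$centroid_y[i]),
      boundary = unname(apply(map$boundary[[i]], 1, function(v) v,
                              simplify = FALSE))
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Split a filtered trial table into the pieces analyses consume.
trial_pieces <- function(table) {
  rois <- roi_columns(table)
  sw <- table$stimulus_kind == "single_whisker"
  list(
    rois = rois,
    whisker = table$whisker,
    evoked = as.matrix(table[rois]),
    is_blank = table$stimulus_kind == "blank",
    is_single = sw
  )
}
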