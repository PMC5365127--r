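#' Per-frame expansiveness of a motion sequence
#'
#' Simple per-frame estimators of how much space a gesturing figure takes up
#' along one axis. Vertical expansiveness sums the heights of the right hand,
#' the left hand and the throat above the desk line:
#' \deqn{E_v(t) = |y_{rh,t} - d| + |y_{lh,t} - d| + |y_{throat,t} - d|}
#' Horizontal expansiveness sums the x-offsets of both hands from the throat
#' plus the throat's offset from the coordinate origin (body sway):
#' \deqn{E_h(t) = |x_{rh,t} - x_{th,t}| + |x_{lh,t} - x_{th,t}| + |x_{th,t}|}
#'
#' @param seq A `motion_tbl` (with `desk_y` set for the vertical axis).
#' @param axis `"vertical"` or `"horizontal"`.
#' @return A tibble with columns `frame`, `value`, `axis`, `label`; one row
#'   per frame, values nonnegative, in frame order.
#' @export
#' @examples
#' seq <- synth_motion(duration_s = 6, seed = 3)
#' head(expansiveness(seq, "vertical"))
expansiveness <- function(seq, axis = c("vertical", "horizontal")) {
  stopifnot(inherits(seq, "motion_tbl"))
  axis <- match.arg(axis)
  marks <- c("right_hand", "left_hand", "throat")
  wide <- seq |>
    filter(.data$landmark %in% marks) |>
    pivot_wider(id_cols = "frame", names_from = "landmark",
                values_from = c("x", "y")) |>
    arrange(.data$frame)
  value <- if (axis == "vertical") {
    d <- motion_desk(seq)
    abs(wide$y_right_hand - d) + abs(wide$y_left_hand - d) + abs(wide$y_throat - d)
  } else {
    abs(wide$x_right_hand - wide$x_throat) +
      abs(wide$x_left_hand - wide$x_throat) +
      abs(wide$x_throat)
  }
  tibble(frame = wide$frame, value = value, axis = axis, label = motion_label(seq))
}

#' @rdname expansiveness
#' @export
vertical_expansiveness <- function(seq) expansiveness(seq, "vertical")

#' @rdname expansiveness
#' @export
horizontal_expansiveness <- function(seq) expansiveness(seq, "horizontal")

#' Maximal-score window of an expansiveness series
#'
#' Finds the contiguous window of `length_frames` frames whose summed
#' per-frame expansiveness is maximal (ties broken toward the earliest
#' start). At the source frame rate of 25 fps the default 125 frames is the
#' five-second excerpt length used for prototype selection.
#'
#' @param series An expansiveness tibble from [expansiveness()], or a bare
#'   numeric vector of per-frame scores.
#' @param length_frames Window length in frames (default 125).
#' @return One-row tibble: `start` (1-based index of the first frame in the
#'   window), `length`, `score` (window sum), `axis`, `label`.
#' @export
max_window <- function(series, length_frames = 125) {
  if (is.data.frame(series)) {
    values <- series$value
    axis <- series$axis[1] %||% NA_character_
    label <- series$label[1] %||% ""
  } else {
    values <- as.numeric(series)
    axis <- NA_character_
    label <- ""
  }
  n <- length(values)
  if (length_frames < 1L) abort("length_frames must be at least 1")
  if (n < length_frames) {
    abort(sprintf("series of length %d is shorter than the window (%d frames)", n, length_frames))
  }
  cs <- c(0, cumsum(values))
  sums <- cs[(length_frames + 1L):(n + 1L)] - cs[1:(n - length_frames + 1L)]
  start <- which.max(sums) # which.max returns the first maximum: earliest tie
  tibble(
    start = as.integer(start),
    length = as.integer(length_frames),
    score = sums[start],
    axis = axis,
    label = label
  )
}

#' Extract a window of frames as a motion sequence
#'
#' @param seq A `motion_tbl`.
#' @param start 1-based index of the first frame (in frame order).
#' @param length_frames Number of frames to keep.
#' @return A `motion_tbl` with frames renumbered 1..`length_frames`.
#' @export
extract_window <- function(seq, start, length_frames) {
  ids <- sort(unique(seq$frame))
  if (start < 1L || start + length_frames - 1L > length(ids)) {
    abort("window does not fit inside the sequence")
  }
  keep <- ids[start:(start + length_frames - 1L)]
  out <- seq |>
    filter(.data$frame %in% keep) |>
    mutate(frame = match(.data$frame, keep))
  restore_motion(out, seq)
}

#' Per-landmark amplitudes within a window
#'
#' Reports, for each landmark, the max-minus-min excursion along each axis
#' inside a chosen window. Used to summarize the range of motion of selected
#' prototype material (e.g. right-hand vertical amplitude), not for
#' selection itself.
#'
#' @inheritParams extract_window
#' @return Tibble with columns `landmark`, `axis`, `amplitude`.
#' @export
window_amplitudes <- function(seq, start, length_frames) {
  win <- extract_window(seq, start, length_frames)
  win |>
    as_tibble() |>
    pivot_longer(c("x", "y"), names_to = "axis", values_to = "coord") |>
    mutate(axis = ifelse(.data$axis == "x", "horizontal", "vertical")) |>
    group_by(.data$landmark, .data$axis) |>
    summarise(amplitude = max(.data$coord) - min(.data$coord), .groups = "drop")
}

#' Rank sequences by maximal-window expansiveness and keep the top k
#'
#' For each sequence in a catalog, finds its maximal five-second (by default)
#' window along the chosen axis, ranks all sequences by that window score and
#' returns the top `k` — the subset used as raw material for prototype
#' creation. Deterministic: ties keep catalog order.
#'
#' @param catalog A list of `motion_tbl` objects.
#' @param axis `"vertical"` or `"horizontal"`.
#' @param k Number of sequences to keep (default 10).
#' @param length_frames Window length in frames (default 125).
#' @return A tibble with one row per selected sequence: `rank`, `source`
#'   (catalog index), `label`, `start`, `length`, `score`, and a `window`
#'   list-column holding the extracted `motion_tbl` windows.
#' @export
rank_and_select <- function(catalog, axis = c("vertical", "horizontal"),
                            k = 10, length_frames = 125) {
  axis <- match.arg(axis)
  if (length(catalog) == 0) abort("catalog is empty")
  if (k > length(catalog)) {
    abort(sprintf("cannot select k = %d from a catalog of %d sequences", k, length(catalog)))
  }
  windows <- purrr::imap(catalog, function(seq, i) {
    w <- max_window(expansiveness(seq, axis), length_frames)
    mutate(w, source = as.integer(i))
  }) |> list_rbind()
  top <- windows |>
    arrange(desc(.data$score)) |> # stable sort: equal scores keep input order
    slice_head(n = k) |>
    mutate(rank = row_number())
  top$window <- purrr::map2(
    catalog[top$source], top$start,
    function(seq, s) extract_window(seq, s, length_frames)
  )
  select(top, "rank", "source", "label", "start", "length", "score", "window")
}
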