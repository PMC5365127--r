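#' Construct a motion sequence
#'
#' A motion sequence is a tidy tibble with one row per (frame, landmark) and
#' columns `frame`, `landmark`, `x`, `y`, carrying the frame rate, the desk
#' reference line and a free-text label as attributes. Coordinates are in
#' pixels with y increasing upward, so heights above the desk grow as hands
#' rise; `desk_y` is the horizontal desk line below the hands.
#'
#' @param frames A data frame with columns `frame`, `landmark`, `x`, `y`
#'   covering all 12 landmarks of [km_landmarks()] in every frame.
#' @param fps Frames per second (positive integer, default 25).
#' @param desk_y Vertical position of the desk line in pixels.
#' @param label Free-text identifier for the sequence.
#' @return A `motion_tbl` tibble.
#' @export
#' @examples
#' seq <- synth_motion(duration_s = 5, seed = 1)
#' motion_fps(seq)
motion_sequence <- function(frames, fps = 25, desk_y = 330, label = "") {
  frames <- as_tibble(frames)
  need <- c("frame", "landmark", "x", "y")
  if (!all(need %in% names(frames))) {
    abort(paste0(
      "motion data needs columns frame, landmark, x, y; missing: ",
      paste(setdiff(need, names(frames)), collapse = ", ")
    ))
  }
  if (!is.numeric(frames$x) || !is.numeric(frames$y)) {
    abort("coordinates x and y must be numeric")
  }
  if (!all(is.finite(frames$x)) || !all(is.finite(frames$y))) {
    abort("all coordinates must be finite")
  }
  fps <- as.integer(fps)
  if (is.na(fps) || fps < 1L) abort("fps must be a positive integer")

  frames <- arrange(frames[, need], .data$frame, match(.data$landmark, km_landmarks()))
  ids <- unique(frames$frame)
  if (length(ids) < 2L) abort("a motion sequence needs at least 2 frames")
  check_skeleton(unique(frames$landmark))

  # every frame must carry every landmark exactly once
  counts <- dplyr::count(frames, .data$frame, .data$landmark)
  if (any(counts$n != 1L)) {
    bad <- counts[counts$n != 1L, ][1, ]
    abort(sprintf(
      "landmark '%s' appears %d times in frame %s", bad$landmark, bad$n, bad$frame
    ))
  }
  per_frame <- dplyr::count(frames, .data$frame)
  if (any(per_frame$n != 12L)) {
    bad_frame <- per_frame$frame[per_frame$n != 12L][1]
    present <- frames$landmark[frames$frame == bad_frame]
    miss <- setdiff(km_landmarks(), present)
    abort(sprintf(
      "frame %s is missing landmark(s): %s", bad_frame, paste(miss, collapse = ", ")
    ))
  }

  new_motion(frames, fps = fps, desk_y = desk_y, label = label)
}

# low-level constructor, no validation
new_motion <- function(frames, fps, desk_y, label) {
  structure(
    as_tibble(frames),
    fps = as.integer(fps),
    desk_y = as.numeric(desk_y),
    label = as.character(label),
    class = c("motion_tbl", class(as_tibble(frames)))
  )
}

# carry a template's metadata onto transformed frames
restore_motion <- function(frames, template,
                           fps = motion_fps(template),
                           desk_y = motion_desk(template),
                           label = motion_label(template)) {
  new_motion(frames[, c("frame", "landmark", "x", "y")], fps, desk_y, label)
}

#' @rdname motion_sequence
#' @param seq A `motion_tbl`.
#' @export
motion_fps <- function(seq) attr(seq, "fps", exact = TRUE) %||% 25L

#' @rdname motion_sequence
#' @export
motion_desk <- function(seq) attr(seq, "desk_y", exact = TRUE) %||% 0

#' @rdname motion_sequence
#' @export
motion_label <- function(seq) attr(seq, "label", exact = TRUE) %||% ""

#' @rdname motion_sequence
#' @export
n_frames <- function(seq) length(unique(seq$frame))

#' @export
print.motion_tbl <- function(x, ...) {
  cat(sprintf(
    "# motion_tbl: %d frames x 12 landmarks, %d fps, desk_y = %g%s\n",
    n_frames(x), motion_fps(x), motion_desk(x),
    if (nzchar(motion_label(x))) paste0(", label = '", motion_label(x), "'") else ""
  ))
  NextMethod()
}

#' Read a motion sequence from disk
#'
#' Two plain-text dialects are supported: a tidy CSV with columns
#' `frame,landmark,x,y` and `#`-prefixed header lines for metadata
#' (`#fps=25`, `#desk_y=330`, `#label=...`), and a JSON document with fields
#' `fps`, `desk_y`, `label`, `skeleton` (landmark order) and `frames` (one
#' array of `[x, y]` pairs per frame, in skeleton order).
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; the default guesses from the extension.
#' @return A `motion_tbl`.
#' @export
read_motion <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))

  if (format == "csv") {
    head_lines <- readLines(path, n = 10L)
    meta <- grep("^#", head_lines, value = TRUE)
    get_meta <- function(key, default) {
      hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
      if (length(hit) == 0) return(default)
      sub(paste0("^#\\s*", key, "\\s*="), "", hit[1])
    }
    fps <- as.integer(get_meta("fps", "25"))
    desk_y <- as.numeric(get_meta("desk_y", "330"))
    label <- get_meta("label", "")
    df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(
                            frame = readr::col_integer(),
                            landmark = readr::col_character(),
                            x = readr::col_character(),
                            y = readr::col_character()
                          ))
    for (col in c("x", "y")) {
      val <- suppressWarnings(as.numeric(df[[col]]))
      bad <- is.na(val) & !is.na(df[[col]])
      if (any(bad)) {
        abort(sprintf(
          "non-numeric %s coordinate '%s' at frame %s, landmark '%s'",
          col, df[[col]][bad][1], df$frame[bad][1], df$landmark[bad][1]
        ))
      }
      df[[col]] <- val
    }
    motion_sequence(df, fps = fps, desk_y = desk_y, label = label)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    skeleton <- as.character(obj$skeleton)
    frames <- obj$frames # list of n_frames matrices (12 x 2) or 3d array
    if (is.list(frames)) {
      coords <- do.call(rbind, frames)
    } else {
      coords <- matrix(aperm(frames, c(2, 1, 3)), ncol = 2) # n x 12 x 2 array
    }
    nf <- nrow(coords) / length(skeleton)
    df <- tibble(
      frame = rep(seq_len(nf), each = length(skeleton)),
      landmark = rep(skeleton, times = nf),
      x = coords[, 1],
      y = coords[, 2]
    )
    motion_sequence(
      df,
      fps = obj$fps %||% 25,
      desk_y = obj$desk_y %||% 330,
      label = obj$label %||% ""
    )
  }
}

#' Write a motion sequence to disk
#'
#' JSON output round-trips coordinates bit-exactly; CSV is written with six
#' decimal places and round-trips to that precision.
#'
#' @param seq A `motion_tbl`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; the default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_motion <- function(seq, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(seq, "motion_tbl"))
  if (n_frames(seq) < 2L) abort("refusing to write a degenerate sequence")
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
      abort(paste0("cannot open '", path, "' for writing: ", conditionMessage(e)))
    })
    on.exit(close(con), add = TRUE)
    writeLines(c(
      paste0("#fps=", motion_fps(seq)),
      paste0("#desk_y=", format(motion_desk(seq), digits = 15)),
      paste0("#label=", motion_label(seq)),
      "frame,landmark,x,y"
    ), con)
    body <- sprintf("%d,%s,%.6f,%.6f", seq$frame, seq$landmark, seq$x, seq$y)
    writeLines(body, con)
  } else {
    skeleton <- km_landmarks()
    ord <- arrange(seq, .data$frame, match(.data$landmark, skeleton))
    nf <- n_frames(seq)
    frames <- lapply(split(ord, factor(ord$frame, levels = unique(ord$frame))), function(fr) {
      unname(cbind(fr$x, fr$y))
    })
    obj <- list(
      fps = motion_fps(seq),
      desk_y = motion_desk(seq),
      label = motion_label(seq),
      skeleton = skeleton,
      frames = unname(frames)
    )
    ok <- tryCatch({
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) abort(paste0("cannot write '", path, "': ", conditionMessage(ok)))
  }
  invisible(path)
}

#' Reduce a motion sequence to a single moving dot
#'
#' Projects one landmark's track out of a full-figure sequence, the reduction
#' used to test whether motion cues carry social information without any body
#' form (by default the anatomically right hand).
#'
#' @param seq A `motion_tbl`.
#' @param landmark Landmark to extract (default `"right_hand"`).
#' @return A `dot_tbl`: tibble with columns `frame`, `x`, `y` and attributes
#'   `fps` and `source_landmark`.
#' @export
to_dot <- function(seq, landmark = "right_hand") {
  stopifnot(inherits(seq, "motion_tbl"))
  if (!landmark %in% unique(seq$landmark)) {
    abort(sprintf("landmark '%s' not present in skeleton", landmark))
  }
  dot <- seq |>
    filter(.data$landmark == !!landmark) |>
    arrange(.data$frame) |>
    select("frame", "x", "y")
  structure(
    as_tibble(dot),
    fps = motion_fps(seq),
    source_landmark = landmark,
    class = c("dot_tbl", class(as_tibble(dot)))
  )
}
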