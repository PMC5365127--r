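#' Figure height of a motion sequence
#'
#' Body height of a tracked figure, measured as the maximal vertical distance
#' between the forehead landmark and the centre-of-gravity landmark over all
#' frames. This "maximum stretch" is the quantity equalized across figures
#' during standardization.
#'
#' @param seq A `motion_tbl`.
#' @return Height in pixels (strictly positive).
#' @export
figure_height <- function(seq) {
  stopifnot(inherits(seq, "motion_tbl"))
  h <- frame_heights(seq)
  hmax <- max(h)
  if (hmax <= 0) abort("degenerate figure: forehead and centre of gravity coincide in every frame")
  hmax
}

# per-frame |y_forehead - y_cog|, in frame order
frame_heights <- function(seq) {
  wide <- seq |>
    filter(.data$landmark %in% c("forehead", "centre_of_gravity")) |>
    select("frame", "landmark", "y") |>
    pivot_wider(names_from = "landmark", values_from = "y") |>
    arrange(.data$frame)
  abs(wide$forehead - wide$centre_of_gravity)
}

# frame id attaining the maximal stretch; earliest frame on ties
stretch_frame <- function(seq) {
  h <- frame_heights(seq)
  ids <- sort(unique(seq$frame))
  ids[which.max(h)]
}

#' Scale a figure to the standard height
#'
#' Rescales all coordinates uniformly (same factor on x and y, about the
#' coordinate origin) so that the maximum stretch equals `target_height`.
#' The desk line is scaled with the figure. Screen position is fixed
#' afterwards by [reposition()].
#'
#' @param seq A `motion_tbl`.
#' @param target_height Standard body height in pixels (default 275).
#' @return A rescaled `motion_tbl`.
#' @export
normalize_height <- function(seq, target_height = 275) {
  stopifnot(target_height > 0)
  f <- target_height / figure_height(seq)
  out <- mutate(as_tibble(seq), x = .data$x * f, y = .data$y * f)
  restore_motion(out, seq, desk_y = motion_desk(seq) * f)
}

#' Anchor a figure at the standard screen position
#'
#' Applies the rigid translation that puts the centre of gravity, in the
#' maximum-stretch frame, at `(anchor_x, anchor_y)`. Inter-landmark distances
#' are unchanged; the desk line is translated with the figure.
#'
#' @param seq A `motion_tbl`.
#' @param anchor_x,anchor_y Target centre-of-gravity position in pixels at
#'   maximum stretch (defaults 345, 341).
#' @return A translated `motion_tbl`.
#' @export
reposition <- function(seq, anchor_x = 345, anchor_y = 341) {
  stopifnot(anchor_x > 0, anchor_y > 0)
  fr <- stretch_frame(seq)
  cog <- filter(seq, .data$frame == fr, .data$landmark == "centre_of_gravity")
  dx <- anchor_x - cog$x
  dy <- anchor_y - cog$y
  out <- mutate(as_tibble(seq), x = .data$x + dx, y = .data$y + dy)
  restore_motion(out, seq, desk_y = motion_desk(seq) + dy)
}

#' Standardize a motion sequence
#'
#' Height normalization followed by repositioning: every figure ends up with
#' a maximum stretch of `target_height` pixels and its centre of gravity at
#' `(anchor_x, anchor_y)` in the maximum-stretch frame. Idempotent.
#'
#' @inheritParams normalize_height
#' @inheritParams reposition
#' @return A standardized `motion_tbl`.
#' @export
#' @examples
#' seq <- synth_motion(duration_s = 6, seed = 2)
#' std <- standardize_motion(seq)
#' figure_height(std) # 275
standardize_motion <- function(seq, target_height = 275, anchor_x = 345, anchor_y = 341) {
  seq |>
    normalize_height(target_height = target_height) |>
    reposition(anchor_x = anchor_x, anchor_y = anchor_y)
}
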