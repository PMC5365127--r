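#' The standard stick figure
#'
#' A neutral reference posture toward which motion is damped during
#' interpolation: the figure stands in the middle of the desk with both hands
#' held close together at navel height. Coordinates are a package convention
#' chosen to be consistent with standardized material (body height 275 px,
#' centre of gravity at (345, 341), y increasing upward).
#'
#' The same coordinate table ships as a plain-text fixture at
#' `system.file("extdata", "standard_figure.csv", package = "kinemorph")`.
#'
#' @param desk_y Desk line for the posture (default 330).
#' @return A tibble with columns `landmark`, `x`, `y` (12 rows) and attribute
#'   `desk_y`; class `standard_figure`.
#' @export
#' @examples
#' standard_figure()
standard_figure <- function(desk_y = 330) {
  fig <- tribble(
    ~landmark,           ~x,  ~y,
    "forehead",          345, 616,
    "throat",            345, 560,
    "left_shoulder",     314, 545,
    "right_shoulder",    376, 545,
    "left_elbow",        300, 482,
    "right_elbow",       390, 482,
    "left_hand",         339, 430,
    "right_hand",        351, 430,
    "left_hip",          325, 332,
    "right_hip",         365, 332,
    "centre_of_gravity", 345, 341,
    "sternum",           345, 520
  )
  check_skeleton(fig$landmark)
  structure(fig, desk_y = desk_y, class = c("standard_figure", class(fig)))
}

#' Isolate one motion axis of a sequence
#'
#' Builds an axis-pure prototype: for `axis = "vertical"` the x-coordinates of
#' every frame are replaced by the standard figure's x-coordinates, so only
#' vertical motion remains; symmetrically for `axis = "horizontal"`. The
#' result still has one coordinate pair per landmark per frame.
#'
#' @param seq A standardized `motion_tbl`.
#' @param standard A [standard_figure()] posture.
#' @param axis Which motion to keep: `"vertical"` or `"horizontal"`.
#' @return A `motion_tbl` with attribute `axis` recording the retained axis.
#' @export
isolate_axis <- function(seq, standard = standard_figure(), axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  std <- setNames(standard[[if (axis == "vertical") "x" else "y"]], standard$landmark)
  out <- as_tibble(seq)
  if (axis == "vertical") {
    out$x <- unname(std[out$landmark])
  } else {
    out$y <- unname(std[out$landmark])
  }
  res <- restore_motion(out, seq)
  attr(res, "axis") <- axis
  res
}

#' Convert a slider position to an interpolation weight
#'
#' Slider bars run over the eleven integer positions 0..10; the interpolation
#' weight is the position divided by ten (steps of 0.1).
#'
#' @param s Integer slider value(s) in 0..10.
#' @return Weight(s) in \\[0, 1\\].
#' @export
slider_to_weight <- function(s) {
  check_slider(s)
  s / 10
}

check_slider <- function(s, what = "slider value") {
  if (any(is.na(s)) || any(s != round(s)) || any(s < 0) || any(s > 10)) {
    abort(paste0(what, " must be an integer between 0 and 10"))
  }
  invisible(s)
}

#' Interpolate a prototype toward the standard posture
#'
#' The weighted mean at the heart of the morphing engine: on the prototype's
#' axis, each coordinate becomes
#' \deqn{c'_{i,t} = w\,c_{i,t} + (1 - w)\,\bar c_i}
#' where \eqn{\bar c_i} is the standard figure's coordinate for landmark i.
#' `w = 0` damps all motion on that axis to the standard posture; `w = 1`
#' reproduces the prototype exactly. The other axis is untouched.
#'
#' @param proto A prototype from [isolate_axis()] (or any `motion_tbl` with an
#'   `axis` given explicitly).
#' @param standard A [standard_figure()] posture.
#' @param w Interpolation weight in \\[0, 1\\].
#' @param axis Axis to interpolate; defaults to the prototype's `axis`
#'   attribute.
#' @return A `motion_tbl`.
#' @export
interpolate_axis <- function(proto, standard = standard_figure(), w,
                             axis = attr(proto, "axis", exact = TRUE)) {
  if (is.null(axis)) abort("no axis: pass a prototype from isolate_axis() or set `axis`")
  axis <- match.arg(axis, c("vertical", "horizontal"))
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    abort("w must be a single weight in [0, 1]")
  }
  col <- if (axis == "vertical") "y" else "x"
  std <- setNames(standard[[col]], standard$landmark)
  out <- as_tibble(proto)
  out[[col]] <- w * out[[col]] + (1 - w) * unname(std[out$landmark])
  res <- restore_motion(out, proto)
  attr(res, "axis") <- axis
  res
}

#' Map the velocity slider to a playback frame rate
#'
#' Velocity is manipulated by changing the animation frame rate: the far-left
#' slider position plays at the source rate of 25 fps and the far-right
#' position at 58 fps. Intermediate positions interpolate linearly and round
#' half away from zero, so both printed endpoints are exact.
#'
#' @param s_vel Integer slider value(s) in 0..10.
#' @return Frame rate(s) in frames per second (integer).
#' @export
#' @examples
#' velocity_to_fps(0) # 25
#' velocity_to_fps(10) # 58
velocity_to_fps <- function(s_vel) {
  check_slider(s_vel, "velocity slider value")
  as.integer(floor(25 + s_vel * (58 - 25) / 10 + 0.5))
}

#' Compose a stimulus from a vertical and a horizontal prototype
#'
#' The composed animation takes its y-track from the vertical prototype
#' interpolated at weight `s_v/10`, its x-track from the horizontal prototype
#' interpolated at weight `s_h/10`, and its frame rate from
#' [velocity_to_fps()]. Pure: the same inputs always give an identical
#' stimulus. Prototypes of unequal length are truncated to the shorter with a
#' warning.
#'
#' @param vproto Vertical prototype ([isolate_axis()] with `axis = "vertical"`).
#' @param hproto Horizontal prototype (`axis = "horizontal"`).
#' @param standard A [standard_figure()] posture.
#' @param s_v,s_h,s_vel Integer slider values in 0..10 for vertical amplitude,
#'   horizontal amplitude and velocity.
#' @return A `motion_tbl` with attributes `sliders` (named integer vector) and
#'   `provenance` (the two prototype labels).
#' @export
#' @examples
#' seq <- standardize_motion(synth_motion(duration_s = 6, seed = 4))
#' vp <- isolate_axis(seq, axis = "vertical")
#' hp <- isolate_axis(seq, axis = "horizontal")
#' stim <- compose_stimulus(vp, hp, s_v = 5, s_h = 5, s_vel = 5)
#' motion_fps(stim) # 42
compose_stimulus <- function(vproto, hproto, standard = standard_figure(),
                             s_v, s_h, s_vel) {
  check_slider(c(s_v, s_h, s_vel))
  nv <- n_frames(vproto)
  nh <- n_frames(hproto)
  if (nv != nh) {
    warn(sprintf(
      "prototypes differ in length (%d vs %d frames); truncating to %d",
      nv, nh, min(nv, nh)
    ))
    n <- min(nv, nh)
    vproto <- extract_window(vproto, 1L, n)
    hproto <- extract_window(hproto, 1L, n)
  }
  yy <- interpolate_axis(vproto, standard, slider_to_weight(s_v), axis = "vertical")
  xx <- interpolate_axis(hproto, standard, slider_to_weight(s_h), axis = "horizontal")
  ord <- function(d) arrange(as_tibble(d), .data$frame, match(.data$landmark, km_landmarks()))
  yy <- ord(yy)
  xx <- ord(xx)
  out <- tibble(
    frame = yy$frame, landmark = yy$landmark,
    x = xx$x, y = yy$y
  )
  res <- restore_motion(
    out, vproto,
    fps = velocity_to_fps(s_vel),
    label = paste0("stimulus(", motion_label(vproto), "x", motion_label(hproto), ")")
  )
  attr(res, "sliders") <- c(s_v = as.integer(s_v), s_h = as.integer(s_h), s_vel = as.integer(s_vel))
  attr(res, "provenance") <- c(vproto = motion_label(vproto), hproto = motion_label(hproto))
  res
}
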