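#' The canonical 12-landmark set
#'
#' Body landmarks tracked on a gesturing figure, in canonical order. The set
#' covers the five anatomically named points that the expansiveness and
#' standardization measures rely on (forehead, throat, both hands, centre of
#' gravity) plus the joints needed to draw a connected stick figure.
#'
#' @return Character vector of 12 unique landmark names.
#' @export
#' @examples
#' km_landmarks()
km_landmarks <- function() {
  c(
    "forehead", "throat",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_hand", "right_hand",
    "left_hip", "right_hip",
    "centre_of_gravity", "sternum"
  )
}

# landmarks that must be present for the measures to be computable
km_required_landmarks <- function() {
  c("forehead", "throat", "right_hand", "left_hand", "centre_of_gravity")
}

#' Stick-figure rendering edges
#'
#' Pairs of landmarks connected by line segments when a figure is drawn.
#'
#' @return A tibble with columns `from` and `to`.
#' @export
km_edges <- function() {
  tribble(
    ~from,            ~to,
    "forehead",        "throat",
    "throat",          "sternum",
    "sternum",         "centre_of_gravity",
    "centre_of_gravity", "left_hip",
    "centre_of_gravity", "right_hip",
    "throat",          "left_shoulder",
    "throat",          "right_shoulder",
    "left_shoulder",   "left_elbow",
    "right_shoulder",  "right_elbow",
    "left_elbow",      "left_hand",
    "right_elbow",     "right_hand"
  )
}

# validate a landmark name vector against the canonical skeleton
check_skeleton <- function(landmarks, call = rlang::caller_env()) {
  if (anyDuplicated(landmarks)) {
    abort("skeleton landmark names must be unique", call = call)
  }
  if (length(landmarks) != 12L) {
    abort(
      sprintf("skeleton must have exactly 12 landmarks, got %d", length(landmarks)),
      call = call
    )
  }
  missing <- setdiff(km_required_landmarks(), landmarks)
  if (length(missing) > 0) {
    abort(
      paste0("skeleton is missing required landmarks: ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  invisible(landmarks)
}
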