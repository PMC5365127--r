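#' Render an animation to a frame-stack directory
#'
#' Headless export of a composed stimulus (or dot track) as a stack of PNG
#' frame images plus a `manifest.json` describing playback: frame count,
#' frames per second, canvas size and mode. The canvas is 768 x 432 pixels,
#' the animation-window size of the rating interface; stick mode connects the
#' landmarks with the segments of [km_edges()], dot mode draws one disc per
#' frame.
#'
#' @param stim A `motion_tbl` (stick mode) or `dot_tbl` (dot mode).
#' @param path Output directory; created if needed.
#' @param mode `"stick"` or `"dot"`; the default picks by input class.
#' @param width,height Canvas size in pixels (defaults 768 x 432).
#' @return The manifest file path, invisibly.
#' @export
render_animation <- function(stim, path, mode = c("auto", "stick", "dot"),
                             width = 768, height = 432) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (inherits(stim, "dot_tbl")) "dot" else "stick"
  if (mode == "stick" && !inherits(stim, "motion_tbl")) {
    abort("stick mode needs a motion_tbl")
  }
  ok <- tryCatch({ dir.create(path, showWarnings = FALSE, recursive = TRUE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok) || !dir.exists(path)) abort(paste0("cannot create output directory: ", path))

  ids <- sort(unique(stim$frame))
  fps <- attr(stim, "fps", exact = TRUE) %||% 25L
  edges <- km_edges()

  # fit the whole animation's bounding box into the canvas (uniform scale,
  # centred, 5% margin); user coordinates already run y-up like the data
  bx <- range(stim$x)
  by <- range(stim$y)
  span <- max(diff(bx), diff(by), 1)
  sc <- 0.9 * min(width, height) / span
  fit_x <- function(x) width / 2 + (x - mean(bx)) * sc
  fit_y <- function(y) height / 2 + (y - mean(by)) * sc

  for (i in seq_along(ids)) {
    fr <- stim[stim$frame == ids[i], ]
    fr$x <- fit_x(fr$x)
    fr$y <- fit_y(fr$y)
    file <- file.path(path, sprintf("frame_%04d.png", i))
    grDevices::png(file, width = width, height = height)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, width), ylim = c(0, height),
                          xaxs = "i", yaxs = "i")
    if (mode == "stick") {
      pos <- setNames(seq_len(nrow(fr)), fr$landmark)
      graphics::segments(
        fr$x[pos[edges$from]], fr$y[pos[edges$from]],
        fr$x[pos[edges$to]], fr$y[pos[edges$to]],
        lwd = 3
      )
      graphics::points(fr$x, fr$y, pch = 16, cex = 0.8)
    } else {
      if (inherits(stim, "dot_tbl")) {
        graphics::points(fr$x, fr$y, pch = 16, cex = 3)
      } else {
        rh <- fr[fr$landmark == "right_hand", ]
        graphics::points(rh$x, rh$y, pch = 16, cex = 3)
      }
    }
    grDevices::dev.off()
  }

  manifest <- list(
    n_frames = length(ids),
    fps = as.integer(fps),
    width = as.integer(width),
    height = as.integer(height),
    mode = mode,
    frame_pattern = "frame_%04d.png"
  )
  manifest_path <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(manifest_path)
}
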