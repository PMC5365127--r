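# Small in-code fixtures shared across the test files.

# a minimal hand-built motion tibble: all 12 landmarks in every frame,
# coordinates offset per frame so nothing is degenerate
toy_motion <- function(n_frames = 2, fps = 25, desk_y = 50, label = "toy") {
  base <- standard_figure(desk_y = desk_y)
  frames <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    data.frame(
      frame = t, landmark = base$landmark,
      x = base$x + t, y = base$y + 2 * t
    )
  }))
  motion_sequence(frames, fps = fps, desk_y = desk_y, label = label)
}

# a motion tibble with fully random (but finite) coordinates
random_motion <- function(n_frames = 4, seed = 1) {
  withr::with_seed(seed, {
    frames <- expand.grid(frame = seq_len(n_frames), landmark = km_landmarks(),
                          stringsAsFactors = FALSE)
    frames$x <- runif(nrow(frames), 0, 700)
    frames$y <- runif(nrow(frames), 0, 400)
    motion_sequence(frames, fps = 25, desk_y = 10, label = paste0("rand", seed))
  })
}

# place chosen landmarks at exact coordinates in every frame (others from
# the standard posture), for arithmetic checks
placed_motion <- function(coords, n_frames = 2, desk_y = 0, fps = 25) {
  base <- standard_figure()
  frames <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    d <- data.frame(frame = t, landmark = base$landmark, x = base$x, y = base$y)
    for (lm in names(coords)) {
      d$x[d$landmark == lm] <- coords[[lm]][1]
      d$y[d$landmark == lm] <- coords[[lm]][2]
    }
    d
  }))
  motion_sequence(frames, fps = fps, desk_y = desk_y)
}

# brute-force window search: enumerate every start, used as the oracle
# against the cumulative-sum implementation
brute_force_window <- function(values, len) {
  starts <- seq_len(length(values) - len + 1)
  sums <- vapply(starts, function(s) sum(values[s:(s + len - 1)]), numeric(1))
  list(start = starts[which.max(sums)], score = max(sums))
}
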