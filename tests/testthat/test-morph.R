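test_that("axis isolation freezes the other axis at the standard posture", {
  std <- standard_figure()
  seq <- standardize_motion(random_motion(n_frames = 8, seed = 21))
  vp <- isolate_axis(seq, std, "vertical")

  # x-variance is zero for every landmark; y untouched
  xvar <- vp |> dplyr::group_by(landmark) |> dplyr::summarise(v = var(x))
  expect_true(all(xvar$v == 0))
  expect_identical(vp$y, seq$y)
  xs <- setNames(std$x, std$landmark)
  expect_equal(vp$x, unname(xs[vp$landmark]))

  # isolating twice changes nothing
  expect_identical(isolate_axis(vp, std, "vertical")$x, vp$x)

  # horizontal isolation of a pure-vertical prototype is a frozen posture
  frozen <- isolate_axis(vp, std, "horizontal")
  expect_true(all(frozen |> dplyr::group_by(landmark) |>
                    dplyr::summarise(v = var(x) + var(y)) |> dplyr::pull(v) == 0))
})

test_that("slider values map linearly to weights with hard bounds", {
  expect_identical(slider_to_weight(0L), 0)
  expect_identical(slider_to_weight(10L), 1)
  expect_identical(slider_to_weight(5L), 0.5)
  expect_error(slider_to_weight(11), "between 0 and 10")
  expect_error(slider_to_weight(-1), "between 0 and 10")
  expect_error(slider_to_weight(2.5), "between 0 and 10")
})

test_that("interpolation endpoints and midpoint follow the weighted-mean rule", {
  std <- standard_figure()
  seq <- standardize_motion(random_motion(n_frames = 6, seed = 22))
  vp <- isolate_axis(seq, std, "vertical")
  ys <- setNames(std$y, std$landmark)

  at0 <- interpolate_axis(vp, std, 0)
  expect_equal(at0$y, unname(ys[at0$landmark])) # total damping
  at1 <- interpolate_axis(vp, std, 1)
  expect_identical(at1$y, vp$y) # prototype reproduced
  mid <- interpolate_axis(vp, std, 0.5)
  expect_equal(mid$y, (vp$y + unname(ys[mid$landmark])) / 2)
  # x never changes under vertical interpolation
  expect_identical(at0$x, vp$x)
  expect_identical(mid$x, vp$x)

  expect_error(interpolate_axis(vp, std, 1.2), "weight")
})

test_that("interpolation is linear in the weight", {
  std <- standard_figure()
  seq <- standardize_motion(random_motion(n_frames = 5, seed = 23))
  hp <- isolate_axis(seq, std, "horizontal")
  w <- sort(runif(3))
  a <- interpolate_axis(hp, std, w[1])$x
  b <- interpolate_axis(hp, std, w[2])$x
  c_ <- interpolate_axis(hp, std, w[3])$x
  lam <- (w[2] - w[1]) / (w[3] - w[1])
  expect_equal(b, (1 - lam) * a + lam * c_, tolerance = 1e-9)
})

test_that("velocity slider maps 0..10 onto 25..58 fps with exact endpoints", {
  expect_identical(velocity_to_fps(0L), 25L)
  expect_identical(velocity_to_fps(10L), 58L)
  expect_identical(velocity_to_fps(5L), 42L) # round(25 + 16.5), half away from zero
  # independent oracle: linear map with half-away-from-zero rounding
  oracle <- vapply(0:10, function(s) {
    x <- 25 + s * 33 / 10
    as.integer(trunc(x + 0.5))
  }, integer(1))
  expect_identical(velocity_to_fps(0:10), oracle)
  expect_true(all(diff(velocity_to_fps(0:10)) > 0))
  expect_error(velocity_to_fps(11), "between 0 and 10")
})

test_that("stimulus composition merges axis tracks and sets the frame rate", {
  std <- standard_figure()
  s1 <- standardize_motion(random_motion(n_frames = 6, seed = 24))
  s2 <- standardize_motion(random_motion(n_frames = 6, seed = 25))
  vp <- isolate_axis(s1, std, "vertical")
  hp <- isolate_axis(s2, std, "horizontal")

  # centred sliders: unweighted mean of prototype and standard on each axis
  stim <- compose_stimulus(vp, hp, std, s_v = 5, s_h = 5, s_vel = 5)
  xs <- setNames(std$x, std$landmark)
  ys <- setNames(std$y, std$landmark)
  ord <- dplyr::arrange(tibble::as_tibble(hp), frame,
                        match(landmark, km_landmarks()))
  expect_equal(stim$x, (ord$x + unname(xs[stim$landmark])) / 2)
  ordv <- dplyr::arrange(tibble::as_tibble(vp), frame,
                         match(landmark, km_landmarks()))
  expect_equal(stim$y, (ordv$y + unname(ys[stim$landmark])) / 2)

  # all-zero sliders: motionless standard posture at 25 fps
  still <- compose_stimulus(vp, hp, std, s_v = 0, s_h = 0, s_vel = 0)
  expect_equal(motion_fps(still), 25L)
  spread <- still |> dplyr::group_by(landmark) |>
    dplyr::summarise(v = var(x) + var(y))
  expect_true(all(spread$v == 0))

  # all-ten sliders: prototype tracks at 58 fps
  full <- compose_stimulus(vp, hp, std, s_v = 10, s_h = 10, s_vel = 10)
  expect_equal(motion_fps(full), 58L)
  expect_equal(full$y, ordv$y)
  expect_equal(full$x, ord$x)

  # purity: identical inputs give identical outputs
  expect_identical(
    compose_stimulus(vp, hp, std, s_v = 7, s_h = 3, s_vel = 9),
    compose_stimulus(vp, hp, std, s_v = 7, s_h = 3, s_vel = 9)
  )
})

test_that("sliders act only on their own channel", {
  std <- standard_figure()
  s1 <- standardize_motion(random_motion(n_frames = 6, seed = 26))
  vp <- isolate_axis(s1, std, "vertical")
  hp <- isolate_axis(standardize_motion(random_motion(n_frames = 6, seed = 27)),
                     std, "horizontal")
  base <- compose_stimulus(vp, hp, std, s_v = 5, s_h = 5, s_vel = 5)
  for (sv in c(0L, 3L, 8L)) {
    alt <- compose_stimulus(vp, hp, std, s_v = sv, s_h = 5, s_vel = 5)
    expect_identical(alt$x, base$x) # vertical slider never touches x
  }
  for (sh in c(0L, 3L, 8L)) {
    alt <- compose_stimulus(vp, hp, std, s_v = 5, s_h = sh, s_vel = 5)
    expect_identical(alt$y, base$y) # horizontal slider never touches y
  }
  for (sp in c(0L, 9L)) {
    alt <- compose_stimulus(vp, hp, std, s_v = 5, s_h = 5, s_vel = sp)
    expect_identical(alt$x, base$x)
    expect_identical(alt$y, base$y) # velocity changes fps only
    expect_equal(motion_fps(alt), velocity_to_fps(sp))
  }
})

test_that("composed vertical expansiveness is monotone in the vertical slider", {
  std <- standard_figure()
  seq <- standardize_motion(synth_motion(duration_s = 5, seed = 28))
  vp <- isolate_axis(seq, std, "vertical")
  hp <- isolate_axis(seq, std, "horizontal")
  scores <- vapply(0:10, function(sv) {
    sum(vertical_expansiveness(
      compose_stimulus(vp, hp, std, s_v = sv, s_h = 5, s_vel = 5)
    )$value)
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("length-mismatched prototypes are truncated with a warning", {
  std <- standard_figure()
  vp <- isolate_axis(standardize_motion(random_motion(n_frames = 8, seed = 29)),
                     std, "vertical")
  hp <- isolate_axis(standardize_motion(random_motion(n_frames = 6, seed = 30)),
                     std, "horizontal")
  expect_warning(
    stim <- compose_stimulus(vp, hp, std, s_v = 5, s_h = 5, s_vel = 5),
    "truncating"
  )
  expect_equal(n_frames(stim), 6)
})

test_that("the packaged standard-figure fixture matches the in-code posture", {
  path <- system.file("extdata", "standard_figure.csv", package = "kinemorph")
  expect_true(nzchar(path))
  fixture <- readr::read_csv(path, show_col_types = FALSE)
  std <- standard_figure()
  expect_equal(fixture$landmark, std$landmark)
  expect_equal(fixture$x, std$x)
  expect_equal(fixture$y, std$y)
  # hands held close together at navel height, figure centred
  rh <- std[std$landmark == "right_hand", ]
  lh <- std[std$landmark == "left_hand", ]
  expect_lt(abs(rh$x - lh$x), 20)
  expect_equal(rh$y, lh$y)
  expect_equal(std$x[std$landmark == "centre_of_gravity"], 345)
})
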