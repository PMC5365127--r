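#' Generate a synthetic gesture motion sequence
#'
#' Emulates speaker-like gesturing behind a desk: both hands oscillate
#' smoothly (sum of sinusoids plus low-amplitude smooth jitter) around a
#' standing posture, the upper body sways and bobs with a fraction of the
#' hand amplitudes. The realized right-hand max-minus-min excursion is
#' rescaled to equal the requested amplitude exactly on each axis, so
#' requested amplitudes are the realized ranges of motion. Deterministic per
#' seed.
#'
#' @param duration_s Duration in seconds (default 15, at least 5 so that a
#'   five-second window can be extracted).
#' @param fps Frames per second (default 25).
#' @param v_amp,h_amp Requested vertical / horizontal hand amplitudes in
#'   pixels (max - min of each hand's track; defaults 170 and 170).
#' @param freq Base oscillation frequency in Hz (default 0.5, a relaxed
#'   gesture tempo; each limb perturbs it slightly).
#' @param jitter Smooth jitter scale as a fraction of the amplitude
#'   (default 0.05).
#' @param desk_y Desk line in pixels (default 330).
#' @param seed Integer seed.
#' @param label Sequence label.
#' @return A `motion_tbl`.
#' @export
#' @examples
#' seq <- synth_motion(duration_s = 6, v_amp = 170, seed = 1)
#' rh <- dplyr::filter(seq, landmark == "right_hand")
#' max(rh$y) - min(rh$y) # 170
synth_motion <- function(duration_s = 15, fps = 25, v_amp = 170, h_amp = 170,
                         freq = 0.5, jitter = 0.05, desk_y = 330,
                         seed = 1L, label = "synthetic") {
  stopifnot(duration_s >= 5, v_amp >= 0, h_amp >= 0, freq > 0, jitter >= 0)
  withr::with_seed(seed, {
    n <- as.integer(round(duration_s * fps))
    t <- seq(0, duration_s, length.out = n)
    base <- standard_figure(desk_y = desk_y)

    # smooth unit-ish waveform: two incommensurate sinusoids + smooth jitter
    wave <- function(f, amp) {
      if (amp <= 0) return(rep(0, n))
      ph <- runif(3, 0, 2 * pi)
      f2 <- f * runif(1, 1.6, 2.2)
      w <- sin(2 * pi * f * t + ph[1]) + 0.4 * sin(2 * pi * f2 * t + ph[2])
      jit <- jitter * sin(2 * pi * f * runif(1, 3, 4.5) * t + ph[3])
      w <- w + jit
      # rescale so the realized max - min equals the requested amplitude
      w <- w - min(w)
      w / max(w) * amp
    }

    # hands rest near the standard posture and gesture one-sidedly: upward on
    # the vertical axis and outward on the horizontal axis, the way expansive
    # speaker gestures depart from a hands-at-the-navel rest pose. wave()
    # already returns excursions in [0, amp], so no re-centring is applied to
    # the hands; torso sway and head bob stay centred on the base posture.
    ctr <- function(w) w - mean(w)
    tracks <- list(
      right_hand = cbind(wave(freq * runif(1, 0.9, 1.1), h_amp),
                         wave(freq * runif(1, 0.9, 1.1), v_amp)),
      left_hand = cbind(-wave(freq * runif(1, 0.9, 1.1), h_amp),
                        wave(freq * runif(1, 0.9, 1.1), v_amp)),
      throat = cbind(ctr(wave(freq * 0.6, 0.35 * h_amp)),
                     ctr(wave(freq * 0.8, 0.12 * v_amp))),
      forehead = cbind(ctr(wave(freq * 0.6, 0.35 * h_amp)),
                       ctr(wave(freq * 0.8, 0.12 * v_amp))),
      centre_of_gravity = cbind(ctr(wave(freq * 0.5, 0.15 * h_amp)), rep(0, n))
    )
    # elbows follow the hands at half excursion
    tracks$right_elbow <- 0.5 * tracks$right_hand
    tracks$left_elbow <- 0.5 * tracks$left_hand
    # shoulders, hips, sternum follow the torso sway
    for (lm in c("right_shoulder", "left_shoulder", "sternum")) {
      tracks[[lm]] <- 0.8 * tracks$throat
    }
    for (lm in c("right_hip", "left_hip")) {
      tracks[[lm]] <- 0.9 * tracks$centre_of_gravity
    }

    frames <- purrr::map(km_landmarks(), function(lm) {
      dev <- tracks[[lm]] %||% matrix(0, n, 2)
      b <- base[base$landmark == lm, ]
      tibble(
        frame = seq_len(n), landmark = lm,
        x = b$x + dev[, 1],
        y = b$y + dev[, 2]
      )
    }) |> list_rbind()
    motion_sequence(frames, fps = fps, desk_y = desk_y, label = label)
  })
}

#' Generate a catalog of synthetic gesture sequences
#'
#' Stands in for a corpus of encoded speeches: amplitudes are drawn uniformly
#' from plausibility ranges matching observed right-hand ranges of motion in
#' expansive speaker material (vertical 137-204 px, horizontal 92-243 px by
#' default).
#'
#' @param n Number of sequences (default 100).
#' @param v_amp_range,h_amp_range Amplitude plausibility ranges in pixels.
#' @param seed Master seed; per-sequence seeds are derived from it.
#' @inheritParams synth_motion
#' @return A list of `motion_tbl` objects labelled `"speech_001"`, ...
#' @export
synth_corpus <- function(n = 100, duration_s = 15, fps = 25,
                         v_amp_range = c(137, 204), h_amp_range = c(92, 243),
                         seed = 1L) {
  params <- withr::with_seed(seed, tibble(
    idx = seq_len(n),
    v_amp = runif(n, v_amp_range[1], v_amp_range[2]),
    h_amp = runif(n, h_amp_range[1], h_amp_range[2]),
    seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  purrr::pmap(params, function(idx, v_amp, h_amp, seed) {
    synth_motion(
      duration_s = duration_s, fps = fps, v_amp = v_amp, h_amp = h_amp,
      seed = seed, label = sprintf("speech_%03d", idx)
    )
  })
}

#' Response profiles for simulated participants
#'
#' Generative description of how a simulated participant sets the three
#' sliders for each (category, polarity) item: a target median per slider on
#' the 0..10 scale plus a common dispersion. The built-in profiles use the
#' observed median slider settings of the stick-figure and dot reverse-rating
#' experiments as targets. The dispersion default sigma = 3 matches the
#' printed interquartile ranges (typical IQR of about 4 slider steps implies
#' a Gaussian sigma of 4/1.349, roughly 3). A small lapse rate (default 5%)
#' makes the occasional response uniform over the whole 0..10 scale,
#' emulating the inattentive or contrarian settings real participants
#' produce; without it, well-separated target medians yield linearly
#' separable high/low groups that no real sample shows.
#'
#' @param experiment `"stick"` or `"dot"`.
#' @param sigma Response dispersion (standard deviation before rounding and
#'   clipping; default 3).
#' @param lapse Probability that a single slider response is drawn uniformly
#'   from 0..10 instead of around the target median (default 0.05).
#' @return A tibble with columns `category`, `polarity`, `m_h`, `m_v`,
#'   `m_vel`, `sigma`, `lapse`.
#' @export
#' @examples
#' response_profile("stick")
response_profile <- function(experiment = c("stick", "dot"), sigma = 3, lapse = 0.05) {
  experiment <- match.arg(experiment)
  stopifnot(sigma > 0, lapse >= 0, lapse < 1)
  prof <- if (experiment == "stick") {
    tribble(
      ~category,     ~polarity, ~m_h, ~m_v, ~m_vel,
      "dominant",    "high",    7,    7,    6,
      "dominant",    "low",     1,    1,    2.5,
      "aggressive",  "high",    9,    10,   10,
      "aggressive",  "low",     2.5,  2,    2,
      "trustworthy", "high",    4,    4,    3,
      "trustworthy", "low",     7,    6,    7,
      "competent",   "high",    4.5,  5,    4,
      "competent",   "low",     6,    4,    7,
      "friendly",    "high",    4,    4,    3,
      "friendly",    "low",     6,    8,    7.5
    )
  } else {
    tribble(
      ~category,     ~polarity, ~m_h, ~m_v, ~m_vel,
      "dominant",    "high",    5,    8,    6,
      "dominant",    "low",     2,    1.5,  2,
      "aggressive",  "high",    8.5,  9,    10,
      "aggressive",  "low",     3,    1,    1,
      "trustworthy", "high",    5,    2.5,  2,
      "trustworthy", "low",     7.5,  6,    7,
      "competent",   "high",    5,    5,    3,
      "competent",   "low",     6,    5,    7,
      "friendly",    "high",    5,    5,    3,
      "friendly",    "low",     6.5,  5,    7.5
    )
  }
  mutate(prof, sigma = sigma, lapse = lapse)
}

#' Sample a slider triplet from a response profile
#'
#' Each slider is drawn independently as a Gaussian around the profile's
#' target median, rounded to the nearest integer and clipped to 0..10; with
#' the profile's lapse probability a draw is instead uniform over 0..10.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param profile A profile tibble from [response_profile()].
#' @param category,polarity Item to respond to.
#' @param n Number of triplets to draw (default 1).
#' @return A tibble with columns `s_h`, `s_v`, `s_vel` (integers in 0..10).
#' @export
sample_sliders <- function(profile, category, polarity, n = 1) {
  row <- profile[profile$category == category & profile$polarity == polarity, ]
  if (nrow(row) == 0) {
    abort(sprintf("no profile entry for category '%s', polarity '%s'", category, polarity))
  }
  draw <- function(m) {
    v <- pmin(pmax(round(rnorm(n, mean = m, sd = row$sigma[1])), 0), 10)
    lapse <- row$lapse[1] %||% 0
    if (lapse > 0) {
      is_lapse <- runif(n) < lapse
      v[is_lapse] <- sample(0:10, sum(is_lapse), replace = TRUE)
    }
    v
  }
  tibble(
    s_h = as.integer(draw(row$m_h[1])),
    s_v = as.integer(draw(row$m_v[1])),
    s_vel = as.integer(draw(row$m_vel[1]))
  )
}

#' Simulate a full reverse-rating dataset
#'
#' Runs `n_participants` simulated sessions through the session engine: each
#' participant gets a derived seed, a seeded session of ten rounds (every
#' item-version once, fresh prototype pairing per round), touches all three
#' sliders with values drawn from the response profile, and finalizes each
#' round into a response record.
#'
#' @param n_participants Number of participants (at least 2; the original
#'   design sizes are 42 for stick figures and 40 for dots).
#' @param profile A profile tibble from [response_profile()].
#' @param experiment `"stick"` or `"dot"`.
#' @param vpool,hpool Prototype pools (defaults `1:10` each, the 100-pairing
#'   support).
#' @param seed Master seed.
#' @return A response tibble with `n_participants * 10` rows and columns
#'   `participant_id`, `category`, `polarity`, `s_h`, `s_v`, `s_vel`,
#'   `experiment`.
#' @export
#' @examples
#' head(generate_dataset(4, response_profile("stick"), "stick", seed = 1))
generate_dataset <- function(n_participants, profile,
                             experiment = c("stick", "dot"),
                             vpool = 1:10, hpool = 1:10, seed = 1L) {
  experiment <- match.arg(experiment)
  if (n_participants < 2) abort("need at least 2 participants")
  pseeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_participants))
  purrr::map(seq_len(n_participants), function(i) {
    session <- build_session(vpool, hpool, seed = pseeds[i])
    withr::with_seed(pseeds[i] %% 1000003L + 1L, {
      responses <- purrr::map(session$round, function(r) {
        s <- sample_sliders(profile, session$category[r], session$polarity[r])
        # touching all three sliders with the sampled values satisfies the
        # all-sliders-moved unlock rule by construction
        session <<- session |>
          touch_slider(r, "h", s$s_h) |>
          touch_slider(r, "v", s$s_v) |>
          touch_slider(r, "vel", s$s_vel)
        finalize_round(session, r, participant_id = i, experiment = experiment)
      })
      list_rbind(responses)
    })
  }) |> list_rbind()
}
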