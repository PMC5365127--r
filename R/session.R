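#' Default item set for a reverse-rating session
#'
#' Five interpersonal categories, each presented in a "low" and a "high"
#' version, giving the ten item-versions of one session.
#'
#' @return Character vector of category names.
#' @export
default_items <- function() {
  c("dominant", "trustworthy", "friendly", "aggressive", "competent")
}

#' Build a reverse-rating session
#'
#' One session consists of ten rounds: each of the five categories in its
#' high and its low version exactly once, in seeded random order. Every round
#' starts from a fresh stimulus composition — a vertical and a horizontal
#' prototype drawn independently and uniformly from their pools (with pools
#' of ten each, a support of 100 pairings) — and from the centred slider
#' state (5, 5, 5). A round can be completed only after all three sliders
#' have been touched.
#'
#' @param vpool,hpool Identifiers of the vertical / horizontal prototype
#'   pools (any nonempty vectors).
#' @param categories Item categories (default [default_items()]).
#' @param seed Optional integer seed; when given, the session is a pure
#'   function of the arguments.
#' @return A tibble with one row per round: `round`, `category`, `polarity`,
#'   `vproto`, `hproto`, slider columns `s_v`, `s_h`, `s_vel` (all 5),
#'   touched flags and `finalized`.
#' @export
#' @examples
#' build_session(1:10, 1:10, seed = 7)
build_session <- function(vpool, hpool, categories = default_items(), seed = NULL) {
  if (length(vpool) == 0 || length(hpool) == 0) abort("prototype pools must be nonempty")
  if (anyDuplicated(categories)) abort("item categories must be unique")
  draw <- function() {
    items <- tidyr::expand_grid(category = categories, polarity = c("high", "low"))
    items <- items[sample.int(nrow(items)), ]
    tibble(
      round = seq_len(nrow(items)),
      category = items$category,
      polarity = items$polarity,
      vproto = sample(vpool, nrow(items), replace = TRUE),
      hproto = sample(hpool, nrow(items), replace = TRUE),
      s_v = 5L, s_h = 5L, s_vel = 5L,
      touched_v = FALSE, touched_h = FALSE, touched_vel = FALSE,
      finalized = FALSE
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Adjust one slider of a round
#'
#' Sets a slider to a value and marks it as touched. Touching counts even if
#' the value equals the centred start of 5: the protocol's unlock rule is
#' about interaction with each slider, not about changing its value.
#'
#' @param session A session tibble from [build_session()].
#' @param round Round number to adjust.
#' @param which Which slider: `"v"`, `"h"` or `"vel"`.
#' @param value Integer slider value in 0..10.
#' @return The session tibble with the round updated.
#' @export
touch_slider <- function(session, round, which = c("v", "h", "vel"), value) {
  which <- match.arg(which)
  check_slider(value)
  i <- match(round, session$round)
  if (is.na(i)) abort(sprintf("no round %s in this session", round))
  if (session$finalized[i]) abort(sprintf("round %d is finalized; sliders are locked", round))
  session[[paste0("s_", which)]][i] <- as.integer(value)
  session[[paste0("touched_", which)]][i] <- TRUE
  session
}

#' Finalize a round into a response record
#'
#' Emits the immutable response for a round: the final slider triplet with
#' the item coding (high = 1, low = 0). Fails, naming the slider, if any of
#' the three sliders has not been touched.
#'
#' @inheritParams touch_slider
#' @param participant_id Identifier written into the record.
#' @param experiment `"stick"` or `"dot"`.
#' @return One-row response tibble: `participant_id`, `category`, `polarity`
#'   (1 = high, 0 = low), `s_h`, `s_v`, `s_vel`, `experiment`.
#' @export
finalize_round <- function(session, round, participant_id = 1L,
                           experiment = c("stick", "dot")) {
  experiment <- match.arg(experiment)
  i <- match(round, session$round)
  if (is.na(i)) abort(sprintf("no round %s in this session", round))
  untouched <- c(
    if (!session$touched_v[i]) "vertical",
    if (!session$touched_h[i]) "horizontal",
    if (!session$touched_vel[i]) "velocity"
  )
  if (length(untouched) > 0) {
    abort(sprintf(
      "round %d cannot be completed: %s slider%s not been touched",
      round, paste(untouched, collapse = " and "),
      if (length(untouched) > 1) "s have" else " has"
    ))
  }
  tibble(
    participant_id = participant_id,
    category = session$category[i],
    polarity = as.integer(session$polarity[i] == "high"),
    s_h = session$s_h[i],
    s_v = session$s_v[i],
    s_vel = session$s_vel[i],
    experiment = experiment
  )
}
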