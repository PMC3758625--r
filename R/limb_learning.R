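# Online estimation of the performer's limb lengths: a cumulative
# running average with time-varying coefficients (alpha = (k-1)/k,
# beta = 1/k), three phases (initialization, learning, fixation) and
# reset-based re-learning when a fixated length drifts.

#' Learner configuration
#'
#' @param N Number of accepted samples after which a limb length is
#'   considered stable and learning freezes (fixation). Default 200
#'   frames, about 6.7 s of standing at 30 fps.
#' @param max_dist Disparity threshold (mm) between the fixated estimate
#'   and an instant measurement that triggers re-learning.
#' @param min_confidence Confidence required on *both* ending joints for
#'   an instant length to be accepted (default 1: estimated centroids are
#'   discarded since they would bias the lengths).
#' @param reset_on_disparity If `TRUE` (default) a disparity beyond
#'   `max_dist` during fixation resets the sample counter and restarts
#'   learning from the new measurement; if `FALSE` only the guard of the
#'   averaging step is applied (the estimate keeps averaging with the
#'   current, small beta).
#' @param bias_sigma Optional noise SD (mm) of each coordinate of the
#'   centroid-difference vector (i.e. `sqrt(2)` times the per-centroid
#'   coordinate SD when both ends are equally noisy). When set, the
#'   chi-distribution bias of noisy Euclidean distances is compensated by
#'   subtracting `3 * sigma^2 / (2 * l)` from the estimate at read-out.
#' @return List of class `kin_learner_config`.
#' @export
learner_config <- function(N = 200, max_dist = 50, min_confidence = 1,
                           reset_on_disparity = TRUE, bias_sigma = NULL) {
  stopifnot(N >= 1, max_dist > 0)
  structure(list(N = N, max_dist = max_dist,
                 min_confidence = min_confidence,
                 reset_on_disparity = reset_on_disparity,
                 bias_sigma = bias_sigma),
            class = "kin_learner_config")
}

# Limbs whose lengths are learned, with their ending joints.
LEARNED_LIMBS <- list(
  l_upper_arm = c("l_shoulder", "l_elbow"),
  r_upper_arm = c("r_shoulder", "r_elbow"),
  l_forearm   = c("l_elbow", "l_hand"),
  r_forearm   = c("r_elbow", "r_hand")
)

#' Per-limb learning state
#'
#' Holds the running-average estimate, the accepted-sample counter `k`
#' and the phase (`initialization` until the first accepted sample,
#' `learning` while `k < N`, `fixation` afterwards).
#'
#' @param estimate Initial length estimate (mm); typically the
#'   anthropometric prior from the model. May be `NA` before any sample.
#' @return List of class `limb_length_state`.
#' @export
new_limb_state <- function(estimate = NA_real_) {
  structure(list(estimate = estimate, k = 0L,
                 phase = "initialization", resets = 0L),
            class = "limb_length_state")
}

#' Initialize learner states from a model
#' @param model A `kin_model`; its (anthropometric) lengths seed the
#'   estimates used until the first accepted sample.
#' @return Named list of `limb_length_state` over the four arm limbs.
#' @export
init_learner <- function(model) {
  out <- lapply(names(LEARNED_LIMBS), function(nm)
    new_limb_state(estimate = model$lengths[[nm]]))
  names(out) <- names(LEARNED_LIMBS)
  out
}

#' Instant limb length from raw centroids
#'
#' Euclidean distance between the two ending-joint centroids of the limb,
#' or `NA` when either confidence fails the reliability threshold (such
#' frames are discarded by the learner).
#'
#' @param frame A `tracker_frame` (raw, pre-gating).
#' @param limb One of `names(LEARNED_LIMBS)`.
#' @param min_confidence Acceptance threshold on both joints.
#' @return Length in mm, or `NA_real_`.
#' @export
instant_limb_length <- function(frame, limb, min_confidence = 1) {
  ends <- LEARNED_LIMBS[[limb]]
  if (is.null(ends))
    stop("instant_limb_length: unknown limb '", limb, "'", call. = FALSE)
  if (any(frame$confidence[ends] < min_confidence)) return(NA_real_)
  sqrt(sum((frame$positions[ends[1], ] - frame$positions[ends[2], ])^2))
}

#' Update one limb-length estimate
#'
#' Cumulative running average with time-varying coefficients: with
#' sample counter k, `l_bar <- l_bar + (l - l_bar) / k`, applied while
#' `k <= N` (learning). After fixation the estimate only changes when the
#' disparity `|l_bar - l|` exceeds `max_dist`; the length is then
#' re-evaluated by resetting the counter and learning again from the new
#' measurement (or, with `reset_on_disparity = FALSE`, by a single
#' guarded averaging step).
#'
#' @param state A `limb_length_state`.
#' @param l Instant limb length (mm); `NA` inputs leave the state
#'   untouched; non-positive values are rejected.
#' @param config A [learner_config()].
#' @return The updated `limb_length_state`.
#' @export
update_limb_length <- function(state, l, config = learner_config()) {
  if (is.na(l)) return(state)
  if (l <= 0) {
    warning("update_limb_length: rejected non-positive sample", call. = FALSE)
    return(state)
  }
  if (state$k < config$N) {
    k <- state$k + 1L
    state$estimate <- if (k == 1L) l else
      state$estimate + (l - state$estimate) / k
    state$k <- k
    state$phase <- if (k >= config$N) "fixation" else "learning"
    return(state)
  }
  # fixation
  if (abs(state$estimate - l) > config$max_dist) {
    if (config$reset_on_disparity) {
      state$k <- 1L
      state$estimate <- l
      state$phase <- "learning"
      state$resets <- state$resets + 1L
    } else {
      k <- state$k + 1L
      state$estimate <- state$estimate + (l - state$estimate) / k
      state$k <- k
    }
  }
  state
}

# Read out an estimate, optionally compensating the noise-induced
# positive distance bias E[|x+n|] - |x| ~ 3 sigma^2 / (2 l).
limb_estimate <- function(state, config) {
  est <- state$estimate
  if (!is.null(config$bias_sigma) && is.finite(est) && est > 0)
    est <- est - 3 * config$bias_sigma^2 / (2 * est)
  est
}

#' One learner step over a frame
#'
#' Updates every learned limb that has a reliable instant measurement in
#' the (raw) frame, then refreshes the model's limb lengths from the
#' current estimates so the filter immediately uses them.
#'
#' @param states Named list of `limb_length_state` (see [init_learner()]).
#' @param frame Raw `tracker_frame`.
#' @param config A [learner_config()].
#' @param model A `kin_model` to refresh, or `NULL`.
#' @return List with `states`, `model` and `resets` (number of fixation
#'   resets triggered by this frame).
#' @export
learner_step <- function(states, frame, config = learner_config(),
                         model = NULL) {
  resets <- 0L
  for (nm in names(states)) {
    l <- instant_limb_length(frame, nm, config$min_confidence)
    before <- states[[nm]]$resets
    states[[nm]] <- update_limb_length(states[[nm]], l, config)
    resets <- resets + (states[[nm]]$resets - before)
  }
  if (!is.null(model)) {
    est <- vapply(states, limb_estimate, numeric(1), config = config)
    est <- est[is.finite(est) & est > 0]
    if (length(est)) model <- set_limb_lengths(model, est)
  }
  list(states = states, model = model, resets = resets)
}

#' Serialize / restore learner states
#'
#' Plain-list form suitable for YAML/JSON so a learned model can be
#' reused across sessions.
#'
#' @param states Named list of `limb_length_state`.
#' @return `learner_to_config()`: a plain list; `learner_from_config()`:
#'   the restored state list.
#' @export
learner_to_config <- function(states) {
  lapply(states, function(s)
    list(estimate = s$estimate, k = s$k, phase = s$phase, resets = s$resets))
}

#' @rdname learner_to_config
#' @param config Plain list as produced by `learner_to_config()`.
#' @export
learner_from_config <- function(config) {
  out <- lapply(config, function(e) {
    s <- new_limb_state(e$estimate)
    s$k <- as.integer(e$k); s$phase <- e$phase
    s$resets <- as.integer(e$resets %||% 0L)
    s
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
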