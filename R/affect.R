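#' Appraise the emotion induced by one interaction
#'
#' Emotion follows appraisal theory: the agent compares the reward it
#' perceives (the counterpart's cooperation level, scaled by its own reward
#' sensitivity) against its expectation, which under the cooperation rule
#' equals its own cooperation level. The difference is squashed through
#' `tanh` so emotion stays in (-1, 1].
#'
#' A reward sensitivity of 1 is the rational case: the pre-squash argument is
#' simply `c_other - c_self`, the surprise relative to expectation. Values
#' below 1 model anhedonia (depression), values above 1 model manic reward
#' overestimation, and bipolar agents pass in a time-varying sensitivity from
#' [bipolar_reward_sensitivity()].
#'
#' @param reward_sensitivity Non-negative multiplier on the received
#'   cooperation (beta). 1 for rational agents.
#' @param c_other Cooperation level extended by the counterpart, in \[0, 1\].
#' @param c_self Own cooperation level (equal to the expectation of the
#'   counterpart), in \[0, 1\].
#' @return Emotion value `tanh(reward_sensitivity * c_other - c_self)`.
#'   Vectorised over all arguments.
#' @examples
#' appraise_emotion(1, 0.5, 0.5)   # no surprise -> 0
#' appraise_emotion(10, 0.5, 0.5)  # manic overestimation -> near 1
#' @export
appraise_emotion <- function(reward_sensitivity, c_other, c_self) {
  check_range(c_other, 0, 1, "c_other")
  check_range(c_self, 0, 1, "c_self")
  if (any(reward_sensitivity < 0)) {
    stop("`reward_sensitivity` must be non-negative", call. = FALSE)
  }
  tanh(reward_sensitivity * c_other - c_self)
}

#' Update mood from a new emotion
#'
#' Mood is a leaky integrator of emotion: it moves a fraction `kappa` of the
#' way from its previous value toward the new emotion, then is squashed with
#' `tanh` to keep it in (-1, 1). `kappa = 1` makes mood fleeting (it tracks
#' emotion exactly, up to the squash); `kappa = 0` leaves a neutral mood
#' untouched, which is how rational agents stay at mood 0.
#'
#' Bipolar agents do not use this update; their mood is generated by the
#' rhythm in [bipolar_mood()].
#'
#' @param mood_prev Previous mood in \[-1, 1\].
#' @param kappa Rate of mood change in \[0, 1\].
#' @param emotion Newly appraised emotion in \[-1, 1\].
#' @return Updated mood. Vectorised.
#' @export
update_mood <- function(mood_prev, kappa, emotion) {
  check_range(mood_prev, -1, 1, "mood_prev")
  check_range(kappa, 0, 1, "kappa")
  check_range(emotion, -1, 1, "emotion")
  tanh(mood_prev + kappa * (emotion - mood_prev))
}

#' Initial mood implied by trait reward sensitivity
#'
#' Depressed agents (beta0 < 1) start with a proportionally negative mood
#' `beta0 - 1`; manic agents (beta0 > 1) start with a positive mood obtained
#' by min-max rescaling of beta0 onto (0, 1\]; rational agents start neutral.
#'
#' @param beta0 Trait reward sensitivity in \[0, beta_max\].
#' @param beta_max Maximum reward sensitivity (> 1), 10 by default in
#'   [default_config()].
#' @return Initial mood in \[-1, 1\]. Vectorised over `beta0`.
#' @export
initial_mood <- function(beta0, beta_max = 10) {
  stopifnot(length(beta_max) == 1, beta_max > 1)
  if (any(beta0 < 0 | beta0 > beta_max)) {
    stop("`beta0` must lie in [0, beta_max]", call. = FALSE)
  }
  ifelse(beta0 < 1, beta0 - 1,
    ifelse(beta0 > 1, (beta0 - 1) / (beta_max - 1), 0)
  )
}

#' Bipolar mood rhythm
#'
#' The mood of a bipolar agent oscillates intrinsically as
#' `sin(omega * t) + offset`, clamped to \[-1, 1\]. The offset `lambda`
#' determines whether the agent is mostly manic (positive) or mostly
#' depressed (negative); `omega` sets the cycling rate and is resampled
#' periodically via [resample_omega()]. The clamp keeps mood inside the
#' domain of the reward-sensitivity map and the retrieval kernel.
#'
#' @param t Round index (non-negative).
#' @param omega Angular rate in radians per round (> 0).
#' @param offset Constant mood offset lambda in \[-1, 1\].
#' @return Mood in \[-1, 1\]. Vectorised.
#' @export
bipolar_mood <- function(t, omega, offset) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  check_range(offset, -1, 1, "offset")
  pmin(1, pmax(-1, sin(omega * t) + offset))
}

#' Resample the bipolar cycling rate
#'
#' Draws a fresh angular rate from an exponential distribution whose mean is
#' the agent's constant trait rate `omega_mean`. The engine installs the draw
#' every `omega_resample_every` rounds (50 by default), producing phases of
#' faster and slower cycling.
#'
#' @param omega_mean Agent-constant mean angular rate (> 0).
#' @param n Number of draws.
#' @return Positive draws from Exponential(mean = omega_mean).
#' @export
resample_omega <- function(omega_mean, n = 1) {
  if (any(omega_mean <= 0)) {
    stop("`omega_mean` must be positive", call. = FALSE)
  }
  stats::rexp(n * length(omega_mean), rate = 1 / omega_mean)
}

#' Mood-dependent reward sensitivity of bipolar agents
#'
#' Maps mood onto reward sensitivity piecewise: negative moods scale
#' sensitivity down linearly toward 0 (depressive hyposensitivity,
#' `mood + 1`), positive moods scale it up linearly toward `beta_max`
#' (manic overestimation, `1 + mood * (beta_max - 1)`), and neutral mood
#' gives exactly 1. Continuous at 0 and onto \[0, beta_max\].
#'
#' @param mood Current mood in \[-1, 1\].
#' @inheritParams initial_mood
#' @return Reward sensitivity in \[0, beta_max\]. Vectorised over `mood`.
#' @export
bipolar_reward_sensitivity <- function(mood, beta_max = 10) {
  stopifnot(length(beta_max) == 1, beta_max > 1)
  check_range(mood, -1, 1, "mood")
  ifelse(mood < 0, mood + 1,
    ifelse(mood > 0, 1 + mood * (beta_max - 1), 1)
  )
}

# shared range validator
check_range <- function(x, lo, hi, name) {
  if (any(is.na(x)) || any(x < lo | x > hi)) {
    stop(sprintf("`%s` must lie in [%s, %s]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}
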