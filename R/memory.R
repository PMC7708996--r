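#' Memory parameters
#'
#' Bundles the parameters of the trace store: the exponential forgetting rate,
#' the deletion threshold, the positive/negative encoding gradients with their
#' common intercept, and the mood-dependence level of retrieval.
#'
#' The emotional bias of an agent is the gradient ratio `xi = grad_pos /
#' grad_neg`: above 1 positive events are encoded more strongly (positively
#' biased agent), below 1 negative events are (negatively biased).
#'
#' @param forget_rate Exponential decay constant theta (> 0) of trace
#'   strength, per round.
#' @param min_strength Deletion threshold phi_min (> 0); traces whose strength
#'   falls below it are permanently deleted.
#' @param grad_neg,grad_pos Encoding gradients k_N, k_P (> 0) applied to
#'   negative and positive emotions.
#' @param intercept Encoding intercept c (> 0), the strength of an emotionally
#'   neutral trace. Must exceed `min_strength` so a fresh neutral trace
#'   survives at least briefly.
#' @param mood_dependence Retrieval selectivity gamma (>= 0); 0 retrieves
#'   everything, large values retrieve only traces whose stored emotion
#'   matches the current mood.
#' @return A list of class `memory_params`.
#' @examples
#' memory_params()                      # unbiased defaults
#' memory_params(grad_pos = 80, grad_neg = 40)  # positively biased, xi = 2
#' @export
memory_params <- function(forget_rate = 0.01, min_strength = 1,
                          grad_neg = 80, grad_pos = 80, intercept = 10,
                          mood_dependence = 1) {
  stopifnot(
    forget_rate > 0, min_strength > 0, grad_neg > 0, grad_pos > 0,
    intercept > 0, mood_dependence >= 0, min_strength < intercept
  )
  structure(
    list(
      forget_rate = forget_rate, min_strength = min_strength,
      grad_neg = grad_neg, grad_pos = grad_pos, intercept = intercept,
      mood_dependence = mood_dependence
    ),
    class = "memory_params"
  )
}

#' @export
print.memory_params <- function(x, ...) {
  cat("<memory_params>\n")
  cat(sprintf(
    "  forget_rate %g, min_strength %g, gradients (neg %g, pos %g), intercept %g\n",
    x$forget_rate, x$min_strength, x$grad_neg, x$grad_pos, x$intercept
  ))
  cat(sprintf(
    "  emotional bias xi = %.3g, mood_dependence %g\n",
    x$grad_pos / x$grad_neg, x$mood_dependence
  ))
  invisible(x)
}

#' Create an empty trace store
#'
#' A trace store is a tibble with one row per remembered interaction:
#' the counterpart's id, the cooperation level the counterpart extended, the
#' emotion felt at encoding, the initial strength assigned by
#' [encode_strength()], the round of the last encoding or refresh, and
#' whether the trace is firsthand (direct interaction) or a broadcast gist.
#'
#' @return A zero-row tibble with the trace columns.
#' @export
empty_traces <- function() {
  tibble::tibble(
    counterpart_id = integer(),
    cooperation = double(),
    emotion = double(),
    initial_strength = double(),
    encoded_at = integer(),
    firsthand = logical()
  )
}

#' Initial strength of a new trace
#'
#' Encoding strength is a piecewise-linear function of emotion: emotionally
#' neutral events get the intercept, and emotional intensity adds strength
#' along the negative or positive gradient. Emotionally charged events are
#' therefore encoded more strongly and, under exponential forgetting, last
#' longer in memory.
#'
#' @param emotion Emotion at encoding, in \[-1, 1\].
#' @param params A [memory_params()] object.
#' @return Initial strength phi_0 in \[intercept, max(grad) + intercept\].
#'   Vectorised over `emotion`.
#' @export
encode_strength <- function(emotion, params = memory_params()) {
  check_range(emotion, -1, 1, "emotion")
  ifelse(emotion <= 0,
    -params$grad_neg * emotion + params$intercept,
    params$grad_pos * emotion + params$intercept
  )
}

#' Trace strength after decay
#'
#' Strength decays exponentially from the initial strength, with elapsed time
#' measured from the round of the most recent encoding or refresh (successful
#' retrieval resets strength to phi_0, so the clock re-anchors).
#'
#' @param traces A trace tibble (see [empty_traces()]).
#' @param t Current round; must be >= every `encoded_at`.
#' @param params A [memory_params()] object.
#' @return Numeric vector of strengths, one per trace.
#' @export
strength_at <- function(traces, t, params = memory_params()) {
  if (nrow(traces) > 0 && any(t < traces$encoded_at)) {
    stop("`t` precedes the encoding time of a trace", call. = FALSE)
  }
  traces$initial_strength * exp(-params$forget_rate * (t - traces$encoded_at))
}

#' Unrefreshed lifetime of a trace
#'
#' The number of rounds an unrefreshed trace of initial strength `phi0`
#' survives before dropping below the deletion threshold:
#' `ln(phi0 / min_strength) / forget_rate`. Used to label forgetting-rate
#' regimes: memory is effectively perfect when the bound at the weakest
#' initial strength exceeds the run length, and absent when the bound at the
#' strongest initial strength is below one round.
#'
#' @param phi0 Initial strength (>= min_strength).
#' @inheritParams strength_at
#' @return Lifetime in rounds. Vectorised over `phi0`.
#' @export
availability_duration <- function(phi0, params = memory_params()) {
  if (any(phi0 < params$min_strength)) {
    stop("`phi0` must be at least `min_strength`", call. = FALSE)
  }
  log(phi0 / params$min_strength) / params$forget_rate
}

#' Delete decayed traces
#'
#' Keeps only traces whose current strength is at or above the deletion
#' threshold. Deletion is permanent; because strength depends only on elapsed
#' time, purging is idempotent and can run lazily at query time.
#'
#' @inheritParams strength_at
#' @return The surviving subset of `traces`.
#' @export
purge_traces <- function(traces, t, params = memory_params()) {
  traces[strength_at(traces, t, params) >= params$min_strength, , drop = FALSE]
}

#' Mood-congruent retrieval probability
#'
#' A triangular kernel centred on the current mood:
#' `max(0, 1 - gamma * |emotion - mood|)`. With `gamma = 0` retrieval is not
#' selective (probability 1 for every trace); as `gamma` grows only traces
#' whose stored emotion lies close to the current mood remain retrievable.
#'
#' @param trace_emotion Stored emotion of the trace, in \[-1, 1\].
#' @param mood Current mood, in \[-1, 1\].
#' @param gamma Mood-dependence level (>= 0).
#' @return Retrieval probability in \[0, 1\]. Vectorised.
#' @export
retrieval_probability <- function(trace_emotion, mood, gamma) {
  check_range(trace_emotion, -1, 1, "trace_emotion")
  check_range(mood, -1, 1, "mood")
  if (any(gamma < 0)) stop("`gamma` must be non-negative", call. = FALSE)
  pmax(0, 1 - gamma * abs(trace_emotion - mood))
}

#' Retrieve traces about a counterpart
#'
#' Filters the store to traces about `counterpart_id`, retrieves each one
#' independently with its mood-congruent probability, and refreshes every
#' retrieved trace by resetting its encoding clock to `t` (its strength
#' returns to phi_0). The store should already be purged at `t`.
#'
#' @inheritParams strength_at
#' @param counterpart_id Id of the counterpart being recalled.
#' @param mood Current mood of the remembering agent.
#' @return A list with `retrieved` (the refreshed retrieved traces, possibly
#'   zero rows) and `memory` (the full store with refreshed clocks applied).
#' @export
retrieve_traces <- function(traces, counterpart_id, mood, t,
                            params = memory_params()) {
  idx <- which(traces$counterpart_id == counterpart_id)
  if (length(idx) == 0) {
    return(list(retrieved = traces[0, , drop = FALSE], memory = traces))
  }
  p <- retrieval_probability(traces$emotion[idx], mood, params$mood_dependence)
  hit <- stats::runif(length(idx)) < p
  traces$encoded_at[idx[hit]] <- as.integer(t)
  list(retrieved = traces[idx[hit], , drop = FALSE], memory = traces)
}
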