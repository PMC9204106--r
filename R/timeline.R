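# Ground-truth gait timeline: left-heel-strike referenced cycles with
# within-cycle event fractions for right toe off, right heel strike and left
# toe off. Defaults follow standard gait phase decomposition: RTO at 12%,
# RHS at 50%, LTO at 62% of the cycle.

#' Generate a ground-truth gait timeline
#'
#' Cycle durations are drawn from a gamma distribution with mean `1/cadence`
#' and coefficient of variation `duration_cv` (degenerating to constant
#' durations at `duration_cv = 0`).
#'
#' @param cadence mean gait-cycle rate in cycles/s (> 0).
#' @param n_cycles number of cycles (>= 1).
#' @param duration_cv coefficient of variation of cycle durations; values at
#'   or above 0.5 are rejected as nonphysiological.
#' @param seed integer seed; all randomness is local to the call.
#' @param event_fractions named numeric vector with entries `RTO`, `RHS`,
#'   `LTO` in (0,1), strictly increasing.
#' @param t0 time of the first left heel strike (s).
#' @return a `GaitTimeline`: list with `cycle_starts` (LHS times, s),
#'   `event_fractions`, `cadence`, `duration_cv`.
#' @export
make_timeline <- function(cadence, n_cycles, duration_cv = 0.03, seed = 1,
                          event_fractions = c(RTO = 0.12, RHS = 0.50, LTO = 0.62),
                          t0 = 1) {
  if (!is.finite(cadence) || cadence <= 0) stop("cadence must be > 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (duration_cv < 0) stop("duration_cv must be >= 0")
  if (duration_cv >= 0.5) stop("duration_cv >= 0.5 rejected as nonphysiological")
  ef <- event_fractions[c("RTO", "RHS", "LTO")]
  if (anyNA(ef) || any(ef <= 0) || any(ef >= 1) || any(diff(ef) <= 0))
    stop("event_fractions must satisfy 0 < RTO < RHS < LTO < 1")
  mu <- 1 / cadence
  if (duration_cv == 0) {
    dur <- rep(mu, n_cycles)
  } else {
    old <- .Random.seed_exists()
    set.seed(seed)
    shape <- 1 / duration_cv^2
    dur <- stats::rgamma(n_cycles, shape = shape, scale = mu / shape)
    .restore_seed(old)
  }
  starts <- t0 + c(0, cumsum(dur[-n_cycles]))
  structure(list(cycle_starts = starts, durations = dur,
                 event_fractions = ef, cadence = cadence,
                 duration_cv = duration_cv),
            class = "GaitTimeline")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Total duration covered by a timeline (s)
#' @param tl a `GaitTimeline`.
#' @param pad seconds appended after the final heel strike.
#' @export
timeline_duration <- function(tl, pad = 1) {
  tail(tl$cycle_starts, 1) + tail(tl$durations, 1) + pad
}

#' Ground-truth event table of a timeline
#' @param tl a `GaitTimeline`.
#' @return a [gait_event_table()] with the exact planted event times.
#' @export
timeline_events <- function(tl) {
  s <- tl$cycle_starts; d <- tl$durations; ef <- tl$event_fractions
  gait_event_table(data.frame(
    t_LHS = s,
    t_RTO = s + ef["RTO"] * d,
    t_RHS = s + ef["RHS"] * d,
    t_LTO = s + ef["LTO"] * d,
    t_LHS_next = s + d
  ), validate_durations = FALSE)
}

#' Within-cycle phase of arbitrary time points
#'
#' Maps times to gait-cycle fraction in [0, 1); times outside any cycle get
#' phase `NA`.
#'
#' @param tl a `GaitTimeline`.
#' @param t numeric vector of times (s).
#' @return numeric vector of phases.
#' @keywords internal
timeline_phase <- function(tl, t) {
  s <- tl$cycle_starts; d <- tl$durations
  idx <- findInterval(t, s)
  ph <- rep(NA_real_, length(t))
  ok <- idx >= 1 & idx <= length(s)
  okk <- ok & t < s[pmax(idx, 1)] + d[pmax(idx, 1)]
  ph[okk] <- (t[okk] - s[idx[okk]]) / d[idx[okk]]
  # times before the first or after the last heel strike keep the cadence
  # phase so that templates extend smoothly beyond the recorded cycles
  pre <- t < s[1]
  ph[pre] <- ((t[pre] - s[1]) / d[1]) %% 1
  post <- is.na(ph) & t >= s[length(s)]
  ph[post] <- ((t[post] - s[length(s)]) / d[length(d)]) %% 1
  ph
}
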