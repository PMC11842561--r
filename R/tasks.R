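#' Trial specification
#'
#' A `trial_spec` defines one planar reach: start and end points (cm), the
#' target-onset and go times (s), the trial duration (s), and optional
#' perturbation annotations (velocity bump, visuomotor rotation, uniform
#' stimulation pulse, error clamp). Time within a trial is discretised into
#' `T = duration / dt` steps; the time attached to step `i` is `(i - 1) * dt`.
#'
#' @param p_start,p_end 2-vectors, cm.
#' @param go_time go-cue time, s.
#' @param target_on target-onset time, s.
#' @param duration trial length, s.
#' @param rotation_deg visuomotor rotation applied to the velocity output
#'   before integration (degrees, counterclockwise positive).
#' @param bump optional list(axis = "x"|"y", amplitude, onset, duration)
#'   velocity pulse in cm/s added after readout, before the rotation.
#' @param stimulation optional list(onset, duration, amplitude): a uniform
#'   extra input to all units.
#' @param error_clamp if `TRUE` the delayed error input (and the plasticity
#'   rule's error term) is forced to zero throughout the trial.
#' @param target_index centre-out target index (0-7) or `NA`.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(p_start, p_end, go_time, target_on = 0.2,
                       duration = 3, rotation_deg = 0, bump = NULL,
                       stimulation = NULL, error_clamp = FALSE,
                       target_index = NA_integer_) {
  stopifnot(length(p_start) == 2, length(p_end) == 2)
  if (!(target_on <= go_time && go_time < duration))
    stop("trial timing must satisfy target_on <= go_time < duration")
  structure(list(p_start = as.numeric(p_start), p_end = as.numeric(p_end),
                 target_on = target_on, go_time = go_time,
                 duration = duration, rotation_deg = rotation_deg,
                 bump = bump, stimulation = stimulation,
                 error_clamp = error_clamp,
                 target_index = target_index),
            class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf("<trial_spec> (%.2f, %.2f) -> (%.2f, %.2f) cm, go %.2f s, rot %g deg%s%s%s\n",
              x$p_start[1], x$p_start[2], x$p_end[1], x$p_end[2], x$go_time,
              x$rotation_deg,
              if (!is.null(x$bump)) ", bump" else "",
              if (!is.null(x$stimulation)) ", stim" else "",
              if (x$error_clamp) ", clamp" else ""))
  invisible(x)
}

#' Desired cursor trajectory for a trial
#'
#' The target path holds at the start point until the go cue, then follows a
#' logistic interpolation between start and end points,
#' `f(u) = 1 / (1 + exp(-kappa * u))` with `kappa = 10` per second, centred
#' 0.5 s after the go cue, which yields a bell-shaped speed profile peaking
#' at `go_time + 0.5` s.
#'
#' @param trial a `trial_spec`.
#' @param dt step, ms.
#' @param kappa logistic steepness, 1/s.
#' @param t_center sigmoid centring relative to the go cue, s.
#' @return 2 x T matrix of desired positions (cm).
#' @export
desired_trajectory <- function(trial, dt, kappa = 10, t_center = 0.5) {
  dts <- dt / 1000
  T <- round(trial$duration / dts)
  if (trial$go_time + 2 * t_center > trial$duration)
    warning("movement truncated: go_time + movement duration exceeds trial length")
  tt <- (seq_len(T) - 1) * dts
  f <- ifelse(tt < trial$go_time, 0,
              1 / (1 + exp(-(tt - trial$go_time - t_center) * kappa)))
  rbind(trial$p_start[1] + f * (trial$p_end[1] - trial$p_start[1]),
        trial$p_start[2] + f * (trial$p_end[2] - trial$p_start[2]))
}

#' Stimulus schedule for a trial
#'
#' Channels 1-2 carry the target displacement `p_end - p_start` from
#' `target_on` until the trial end (zero before); channel 3 is the hold
#' signal, 1 before the go cue and 0 from the go cue on.
#'
#' @inheritParams desired_trajectory
#' @param hold_amp amplitude of the hold channel.
#' @return 3 x T matrix.
#' @export
stimulus_schedule <- function(trial, dt, hold_amp = 1) {
  dts <- dt / 1000
  T <- round(trial$duration / dts)
  tt <- (seq_len(T) - 1) * dts
  d <- trial$p_end - trial$p_start
  S <- matrix(0, 3, T)
  on <- tt >= trial$target_on
  S[1, on] <- d[1]
  S[2, on] <- d[2]
  S[3, tt < trial$go_time] <- hold_amp
  S
}

#' Generate a random training reach
#'
#' Start and end points drawn uniformly per component from (-6, 6) cm; go cue
#' at 0.2 s plus a uniformly drawn instructed delay of 0 to 1.5 s.
#'
#' @param seed integer seed.
#' @return a `trial_spec`.
#' @export
make_random_reach_trial <- function(seed) {
  set.seed(seed)
  p_start <- stats::runif(2, -6, 6)
  p_end <- stats::runif(2, -6, 6)
  go <- 0.2 + stats::runif(1, 0, 1.5)
  trial_spec(p_start, p_end, go_time = go)
}

#' Generate a centre-out trial
#'
#' Eight targets equally spaced on a 5-cm circle; target `k` sits at
#' `45 * k` degrees. Reaches start at the origin with an instructed delay
#' drawn uniformly from 1.2 to 1.7 s (or fixed via `go_time`).
#'
#' @param target_index integer 0-7.
#' @param seed integer seed for the delay draw.
#' @param go_time optional fixed go time, s (used for matched probe trials).
#' @param rotation_deg visuomotor rotation for the trial.
#' @return a `trial_spec`.
#' @export
make_centerout_trial <- function(target_index, seed, go_time = NULL,
                                 rotation_deg = 0) {
  if (!(target_index %in% 0:7)) stop("target_index must be in 0..7")
  ang <- 45 * target_index * pi / 180
  p_end <- 5 * c(cos(ang), sin(ang))
  if (is.null(go_time)) {
    set.seed(seed)
    go_time <- stats::runif(1, 1.2, 1.7)
  }
  trial_spec(c(0, 0), p_end, go_time = go_time, rotation_deg = rotation_deg,
             target_index = as.integer(target_index))
}

#' Attach a random velocity bump to a trial
#'
#' With probability 0.75, adds a 0.1-s, 10-cm/s velocity pulse on the x or y
#' axis (equiprobable, random sign), with onset drawn uniformly from 0.2 to
#' 1.9 s. The pulse is added to the readout velocity before the rotation and
#' position integration.
#'
#' @param trial a `trial_spec`.
#' @param seed integer seed.
#' @param prob bump probability.
#' @param amplitude pulse amplitude, cm/s.
#' @param duration pulse duration, s.
#' @return a `trial_spec` (possibly with a `bump` annotation).
#' @export
apply_bump <- function(trial, seed, prob = 0.75, amplitude = 10,
                       duration = 0.1) {
  set.seed(seed)
  if (stats::runif(1) < prob) {
    axis <- if (stats::runif(1) < 0.5) "x" else "y"
    sgn <- if (stats::runif(1) < 0.5) 1 else -1
    onset <- stats::runif(1, 0.2, 1.9)
    trial$bump <- list(axis = axis, amplitude = sgn * amplitude,
                       onset = onset, duration = duration)
  }
  trial
}

# Build the dense per-step input arrays the C++ simulator consumes.
trial_inputs <- function(trial, params) {
  dt <- params$dt
  dts <- dt / 1000
  T <- round(trial$duration / dts)
  if (abs(trial$duration / dts - T) > 1e-9)
    stop("trial duration must be divisible by dt")
  tt <- (seq_len(T) - 1) * dts
  S <- stimulus_schedule(trial, dt)
  Pstar <- desired_trajectory(trial, dt)
  bump <- matrix(0, 2, T)
  if (!is.null(trial$bump)) {
    win <- tt >= trial$bump$onset & tt < trial$bump$onset + trial$bump$duration
    bump[if (trial$bump$axis == "x") 1 else 2, win] <- trial$bump$amplitude
  }
  rot <- rep(trial$rotation_deg, T)
  stim <- rep(0, T)
  if (!is.null(trial$stimulation)) {
    st <- trial$stimulation
    win <- tt >= st$onset & tt < st$onset + st$duration
    stim[win] <- st$amplitude
  }
  list(S = S, Pstar = Pstar, bump = bump, rot = rot, stim = stim,
       clamp = isTRUE(trial$error_clamp),
       go_step = as.integer(round(trial$go_time / dts)) + 1L, T = T)
}
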