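#' Initialise the network state for a trial
#'
#' Pre-activations are drawn i.i.d. uniformly from (-0.2, 0.2); the
#' eligibility trace starts at zero and the cursor at the trial start point.
#'
#' @param params a `network_params`.
#' @param seed non-negative integer seed.
#' @param start_position initial cursor position, cm.
#' @return An object of class `network_state` with fields `x`, `y`, `r`,
#'   `p`, `step_index`.
#' @export
init_state <- function(params, seed, start_position = c(0, 0)) {
  stopifnot(seed >= 0)
  set.seed(seed)
  x <- stats::runif(params$N, -0.2, 0.2)
  structure(list(x = x, y = pmax(x, 0), r = rep(0, params$N),
                 p = as.numeric(start_position), step_index = 0L),
            class = "network_state")
}

#' Advance the network by one Euler step
#'
#' One forward-Euler step of the leaky rectified-linear rate dynamics:
#' leak `-x`, recurrent drive `W y`, input drive `W_in s`, delayed-error
#' feedback drive `F eps(t - delta)`, bias, and an optional uniform extra
#' input (stimulation experiments). The eligibility trace accumulates the
#' new activity. The cursor position is not advanced here (see
#' [integrate_position()]).
#'
#' @param state a `network_state`.
#' @param params a `network_params`.
#' @param stimulus 3-vector input.
#' @param delayed_error 2-vector, the cursor error `delta` ms ago (zero
#'   before the delay horizon).
#' @param extra_input scalar added uniformly to all units.
#' @return the updated `network_state`.
#' @export
step_state <- function(state, params, stimulus, delayed_error,
                       extra_input = 0) {
  if (length(stimulus) != ncol(params$W_in))
    stop("stimulus dimension mismatch")
  if (length(delayed_error) != 2) stop("delayed_error must have length 2")
  lam <- params$dt / params$tau
  x <- state$x + lam * (-state$x + drop(params$W %*% state$y) +
                          drop(params$W_in %*% stimulus) +
                          drop(params$F %*% delayed_error) +
                          params$b + extra_input)
  y <- pmax(x, 0)
  state$x <- x
  state$y <- y
  state$r <- state$r + y
  state$step_index <- state$step_index + 1L
  state
}

#' Linear velocity readout
#'
#' @param y activity vector.
#' @param params a `network_params`.
#' @return 2-vector velocity, cm/s.
#' @export
readout <- function(y, params) {
  drop(params$W_out %*% y) + params$b_out
}

#' Integrate the cursor position by one step
#'
#' The velocity is rotated by the active visuomotor rotation about the
#' origin, then integrated: `p = p_prev + dt * R(theta) v` with `dt` in
#' seconds. The resulting position is the cursor position used for the
#' error signal and all behavioural metrics.
#'
#' @param p_prev 2-vector, cm.
#' @param v 2-vector, cm/s.
#' @param dt step, ms.
#' @param rotation_deg active rotation, degrees (0 when unperturbed).
#' @return 2-vector, cm.
#' @export
integrate_position <- function(p_prev, v, dt, rotation_deg = 0) {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p_prev + (dt / 1000) * drop(R %*% v)
}

#' Simulate one trial of closed-loop control
#'
#' Runs the full discrete-time loop for a trial: stimulus and desired
#' trajectory from the trial spec, Euler dynamics with delayed error
#' feedback, readout, optional velocity bump, visuomotor rotation, position
#' integration, and error bookkeeping. Deterministic given
#' `(params, trial, seed)`.
#'
#' @param params a `network_params`.
#' @param trial a `trial_spec`.
#' @param seed integer seed for the initial state.
#' @param record_full if `TRUE`, also store per-step pre-activations `x`
#'   and eligibility traces `r`.
#' @return An object of class `trial_result` with per-step arrays
#'   (`y` N x T, `v`, `v_eff`, `p`, `p_star`, `epsilon` 2 x T), the trial
#'   spec and seed, the go step, and scalar summaries `takeoff_angle`,
#'   `takeoff_error` (degrees) and `endpoint_error` (cm).
#' @export
run_trial <- function(params, trial, seed, record_full = FALSE) {
  check_params(params)
  inp <- trial_inputs(trial, params)
  set.seed(seed)
  x0 <- stats::runif(params$N, -0.2, 0.2)
  res <- cpp_run_trial(unclass(params), inp$S, inp$Pstar, inp$bump, inp$rot,
                       inp$stim, inp$clamp, x0, trial$p_start,
                       FALSE, 0, 1L, record_full)
  out <- structure(list(trial = trial, seed = seed, dt = params$dt,
                        go_step = inp$go_step,
                        y = res$y, v = res$v, v_eff = res$v_eff,
                        p = res$p, p_star = inp$Pstar,
                        epsilon = res$epsilon,
                        x = res$x, r = res$r),
                   class = "trial_result")
  out$takeoff_angle <- takeoff_angle(out)
  out$takeoff_error <- takeoff_error(out)
  out$endpoint_error <- sqrt(sum((res$p[, ncol(res$p)] - trial$p_end)^2))
  out
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %d steps, take-off error %.1f deg, endpoint error %.2f cm\n",
              ncol(x$p), x$takeoff_error, x$endpoint_error))
  invisible(x)
}
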