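#' Configuration of the feedback-driven plasticity rule
#'
#' The per-step weight increment is `dt * eta_eff * (F eps) r` with the
#' effective rate `eta_eff = eta * gain / S`, where `S = N * mean(y^2)` is
#' the network's activity scale measured on one unperturbed reference
#' trial. `eta` is the nominal learning rate. `gain / S` is a calibration
#' absorbing the unit conventions of the rule (time step in seconds, error
#' in cm, eligibility trace the raw within-trial activity sum): the
#' update's first-order effect on the recurrent drive scales with
#' `eta_eff * N * mean(y^2)`, so expressing the rate relative to `S` makes
#' the rule's trial-by-trial speed independent of network size and
#' activity magnitude. `gain` is fixed once so that a standard trained
#' network adapts to a 30-degree rotation with the published time course
#' (decay to a plateau of a few degrees within ~300 trials) while staying
#' well below the rate at which the trial-by-trial update runs away.
#'
#' @param eta nominal learning rate (default 2e-5).
#' @param gain dimensionless calibration factor applied relative to the
#'   network's activity scale (default 1500).
#' @param update_stride steps between accumulated increments (every fifth
#'   step by default).
#' @param enabled master switch.
#' @return an object of class `plasticity_config`.
#' @export
plasticity_config <- function(eta = 2e-5, gain = 1500, update_stride = 5,
                              enabled = TRUE) {
  stopifnot(eta >= 0, gain >= 0, update_stride >= 1)
  structure(list(eta = eta, gain = gain,
                 update_stride = as.integer(update_stride),
                 enabled = enabled), class = "plasticity_config")
}

#' One increment of the feedback-driven plasticity rule
#'
#' The change of the synapse from unit i to unit j is proportional to the
#' delayed error feedback received by the postsynaptic unit j, times the
#' presynaptic eligibility trace:
#' `dW_ji = dt * eta * (sum_k F_jk eps_k(t - delta)) * r_i(t)`,
#' an outer product of the projected error and the eligibility vector.
#'
#' @param F feedback weight matrix (N x 2).
#' @param delayed_error 2-vector, the cursor error delta ms ago (cm); zero
#'   before the delay horizon and on error-clamp trials.
#' @param r eligibility trace (N), the within-trial accumulated activity.
#' @param eta learning rate.
#' @param dt step, ms.
#' @return N x N weight increment.
#' @export
plasticity_increment <- function(F, delayed_error, r, eta, dt) {
  (dt / 1000) * eta * (F %*% delayed_error) %*% t(r)
}

#' Accumulate and apply the within-trial weight change
#'
#' Evaluates the plasticity increment at every `update_stride`-th step
#' (steps stride, 2 stride, ..., T), sums the increments over the trial,
#' and applies the accumulated change to the recurrent weights once at
#' trial end. Masked connections are untouched. Error-clamped trials
#' produce no change.
#'
#' @param trial_run a `trial_result` recorded with `record_full = TRUE`
#'   (eligibility traces are needed).
#' @param config a `plasticity_config`.
#' @param params a `network_params`.
#' @param activity_scale the network activity scale `S = N mean(y^2)` used
#'   to normalise the rate; defaults to the scale of the given trial
#'   (sessions use a fixed baseline reference trial instead, see
#'   [run_adaptation()]).
#' @return the updated `network_params`.
#' @export
accumulate_and_apply <- function(trial_run, config, params,
                                 activity_scale = NULL) {
  if (!config$enabled || config$eta == 0) return(params)
  if (is.null(trial_run$r)) stop("trial must be run with record_full = TRUE")
  if (is.null(activity_scale))
    activity_scale <- params$N * mean(trial_run$y^2)
  eta_eff <- config$eta * config$gain / activity_scale
  T <- ncol(trial_run$epsilon)
  ds <- params$delta_steps
  dW <- matrix(0, params$N, params$N)
  for (t in seq(config$update_stride, T, by = config$update_stride)) {
    if (isTRUE(trial_run$trial$error_clamp) || t - ds < 1) next
    ed <- trial_run$epsilon[, t - ds]
    dW <- dW + plasticity_increment(params$F, ed, trial_run$r[, t],
                                    eta_eff, params$dt)
  }
  params$W <- params$W + dW * params$mask_W
  params
}

#' Session protocol
#'
#' An ordered list of phases executed against one network, each with a
#' trial count, rotation schedule, plasticity flag and optional error-clamp
#' or stimulation settings.
#'
#' @param phases list of phases; each is a list with fields `name`,
#'   `n_trials`, `rotation` (scalar degrees, or a numeric vector of
#'   per-trial rotations), `plasticity` (logical), and optionally
#'   `clamp` (logical), `stimulation` (list: `ref` "start"/"go", `offset` s,
#'   `duration` s, `amplitude`, `trials` phase-local indices), and
#'   `target_index` to restrict all trials to a single target.
#' @param seed master session seed; per-trial substreams are derived from
#'   it by counter so any trial can be reproduced in isolation.
#' @param go_time fixed go time (s) for all trials, or `NULL` for the
#'   standard variable 1.2-1.7 s delay.
#' @return an object of class `session_protocol`.
#' @export
session_protocol <- function(phases, seed = 1, go_time = NULL) {
  for (ph in phases) stopifnot(ph$n_trials > 0)
  structure(list(phases = phases, seed = seed, go_time = go_time),
            class = "session_protocol")
}

# balanced pseudo-random target sequence: shuffled blocks of the 8 targets
balanced_targets <- function(n, seed) {
  set.seed(seed)
  out <- integer(0)
  while (length(out) < n) out <- c(out, sample(0:7))
  out[seq_len(n)]
}

#' Run a trial-by-trial adaptation session
#'
#' Executes the protocol's phases in order against a single network,
#' applying the feedback-driven plasticity rule on flagged phases: within
#' each trial the weight change is accumulated every fifth step and applied
#' to the recurrent weights at trial end. Produces a tidy per-trial log,
#' sparse weight snapshots, and optional activity recordings.
#'
#' @param params a trained `network_params`.
#' @param protocol a `session_protocol`.
#' @param config a `plasticity_config`.
#' @param snapshot_every store the recurrent weights every k trials of
#'   plastic phases (phase boundaries are always stored).
#' @param record_windows if `TRUE`, store per-unit activity in the
#'   feedback (0.7-0.9 s after go) and learning (0.4-0.6 s) windows for
#'   every perturbation-phase trial.
#' @param record_y_units optional unit indices; if given, full activity
#'   traces of those units (plus the velocity output) are stored for every
#'   perturbation-phase trial.
#' @return an object of class `adaptation_log`: `trials` (data frame),
#'   `specs` (trial specs for replay), `snapshots` (+ `snapshot_trials`),
#'   `params_final`, `params_baseline`, and optional recordings.
#' @export
run_adaptation <- function(params, protocol, config = plasticity_config(),
                           snapshot_every = 10, record_windows = FALSE,
                           record_y_units = NULL) {
  check_params(params)
  dts <- params$dt / 1000
  fb_off <- seq(round(0.7 / dts), round(0.9 / dts))
  ff_off <- seq(round(0.4 / dts), round(0.6 / dts))

  params_baseline <- params
  # activity scale from one unperturbed reference trial on the baseline
  # network; fixes the effective plasticity rate for the whole session
  ref <- run_trial(params,
                   make_centerout_trial(0, seed = substream(protocol$seed,
                                                            "scale"),
                                        go_time = 1.45),
                   seed = substream(protocol$seed, "scale_x0"))
  eta_eff <- config$eta * config$gain / (params$N * mean(ref$y^2))
  rows <- list(); specs <- list()
  snapshots <- list(); snapshot_trials <- integer(0)
  win_fb <- list(); win_ff <- list(); y_rec <- list(); v_rec <- list()
  gi <- 0L
  snapshots[["0"]] <- params$W; snapshot_trials <- 0L

  for (ph in protocol$phases) {
    targets <- if (!is.null(ph$target_index))
      rep(ph$target_index, ph$n_trials)
    else balanced_targets(ph$n_trials, substream(protocol$seed, ph$name))
    rot <- ph$rotation
    if (length(rot) == 1) rot <- rep(rot, ph$n_trials)
    plastic <- isTRUE(ph$plasticity) && config$enabled && config$eta > 0
    pert_count <- 0L

    for (i in seq_len(ph$n_trials)) {
      gi <- gi + 1L
      spec_seed <- substream(protocol$seed, "spec", gi)
      x0_seed <- substream(protocol$seed, "x0", gi)
      tr <- make_centerout_trial(targets[i], seed = spec_seed,
                                 go_time = protocol$go_time,
                                 rotation_deg = rot[i])
      tr$error_clamp <- isTRUE(ph$clamp)
      if (!is.null(ph$stimulation) && i %in% ph$stimulation$trials) {
        st <- ph$stimulation
        onset <- if (identical(st$ref, "go")) tr$go_time + st$offset
                 else st$offset
        tr$stimulation <- list(onset = onset, duration = st$duration,
                               amplitude = st$amplitude)
      }
      specs[[gi]] <- tr

      inp <- trial_inputs(tr, params)
      set.seed(x0_seed)
      x0 <- stats::runif(params$N, -0.2, 0.2)
      res <- cpp_run_trial(unclass(params), inp$S, inp$Pstar, inp$bump,
                           inp$rot, inp$stim, inp$clamp, x0, tr$p_start,
                           plastic, eta_eff, config$update_stride, FALSE)
      if (plastic) {
        params$W <- params$W + res$dW
        if (!all(is.finite(res$p)) || max(abs(res$p)) > 1e3)
          stop(sprintf(paste("adaptation diverged at trial %d: the accumulated",
                             "weight updates destabilised the network;",
                             "reduce the plasticity gain"), gi))
      }

      light <- list(p = res$p, go_step = inp$go_step, trial = tr, dt = params$dt)
      class(light) <- "trial_result"
      toe <- takeoff_error(light)
      # reaction-time proxy: first post-go step with cursor speed above 10%
      # of the trial's peak speed
      sp <- sqrt(colSums((res$p[, (inp$go_step + 1):inp$T, drop = FALSE] -
                            res$p[, inp$go_step:(inp$T - 1), drop = FALSE])^2))
      rt <- which(sp > 0.1 * max(sp))[1] * dts

      rows[[gi]] <- data.frame(
        phase = ph$name, trial = i, index = gi,
        target_deg = 45 * targets[i], rotation_deg = rot[i],
        takeoff_error_deg = toe,
        endpoint_error_cm = sqrt(sum((res$p[, inp$T] - tr$p_end)^2)),
        reaction_time_s = rt, go_time = tr$go_time,
        stimulated = !is.null(tr$stimulation), seed = x0_seed)

      if (ph$name == "perturbation") {
        pert_count <- pert_count + 1L
        if (record_windows) {
          win_fb[[pert_count]] <- res$y[, inp$go_step + fb_off]
          win_ff[[pert_count]] <- res$y[, inp$go_step + ff_off]
        }
        if (!is.null(record_y_units)) {
          y_rec[[pert_count]] <- res$y[record_y_units, , drop = FALSE]
          v_rec[[pert_count]] <- res$v
        }
      }
      if (plastic && (i %% snapshot_every == 0)) {
        snapshots[[as.character(gi)]] <- params$W
        snapshot_trials <- c(snapshot_trials, gi)
      }
    }
    snapshots[[as.character(gi)]] <- params$W
    snapshot_trials <- unique(c(snapshot_trials, gi))
  }

  log <- list(trials = do.call(rbind, rows), specs = specs,
              snapshots = snapshots, snapshot_trials = snapshot_trials,
              params_final = params, params_baseline = params_baseline,
              protocol = protocol, config = config)
  if (record_windows && length(win_fb) > 0) {
    log$window_record <- list(
      fb = array(unlist(win_fb), c(params$N, length(fb_off), length(win_fb))),
      ff = array(unlist(win_ff), c(params$N, length(ff_off), length(win_ff))),
      fb_offsets = fb_off, ff_offsets = ff_off)
  }
  if (!is.null(record_y_units) && length(y_rec) > 0) {
    T <- ncol(v_rec[[1]])
    log$y_record <- list(
      y = array(unlist(y_rec), c(length(record_y_units), T, length(y_rec))),
      v = array(unlist(v_rec), c(2, T, length(v_rec))),
      units = record_y_units)
  }
  class(log) <- "adaptation_log"
  log
}

#' @export
print.adaptation_log <- function(x, ...) {
  ph <- table(x$trials$phase)[unique(x$trials$phase)]
  cat("<adaptation_log>", paste(sprintf("%s: %d", names(ph), ph),
                                collapse = ", "), "trials\n")
  invisible(x)
}

#' Weight snapshot closest to a given plastic-trial index
#'
#' @param log an `adaptation_log`.
#' @param index global trial index (0 = pre-session weights).
#' @return `network_params` with the recurrent weights of that snapshot.
#' @export
snapshot_params <- function(log, index) {
  stored <- log$snapshot_trials
  pick <- stored[which.min(abs(stored - index))]
  p <- log$params_baseline
  p$W <- log$snapshots[[as.character(pick)]]
  p
}
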