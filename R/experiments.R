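#' Standard visuomotor-rotation adaptation session
#'
#' Baseline (plasticity off), perturbation (rotation on, plasticity on),
#' washout (rotation off, plasticity on).
#'
#' @param params trained `network_params`.
#' @param rotation_deg rotation during the perturbation phase.
#' @param counts named or positional 3-vector: baseline, perturbation,
#'   washout trial counts.
#' @param seed session seed.
#' @param config a `plasticity_config`.
#' @param ... passed to [run_adaptation()] (recording options).
#' @return an `adaptation_log`.
#' @export
vr_adaptation_session <- function(params, rotation_deg = 30,
                                  counts = c(200, 500, 200), seed = 1,
                                  config = plasticity_config(), ...) {
  proto <- session_protocol(list(
    list(name = "baseline", n_trials = counts[[1]], rotation = 0,
         plasticity = FALSE),
    list(name = "perturbation", n_trials = counts[[2]],
         rotation = rotation_deg, plasticity = TRUE),
    list(name = "washout", n_trials = counts[[3]], rotation = 0,
         plasticity = TRUE)), seed = seed)
  run_adaptation(params, proto, config, ...)
}

#' Build a matched centre-out probe set
#'
#' Balanced targets at a fixed go time so that probe epochs are aligned
#' step-for-step; the same `(trial, seed)` pairs are reused across epochs.
#'
#' @param n number of probe trials.
#' @param seed probe-set seed.
#' @param rotation_deg rotation applied in this epoch's probes.
#' @param go_time fixed go time, s.
#' @param seed_stream substream name for the initial-state seeds (use a
#'   different stream to build an independent baseline repeat for nulls).
#' @return list of fields `trials` and `seeds`.
#' @export
make_probe_set <- function(n, seed, rotation_deg = 0, go_time = 1.45,
                           seed_stream = "probe") {
  targets <- balanced_targets(n, substream(seed, "probe_targets"))
  trials <- lapply(seq_len(n), function(i)
    make_centerout_trial(targets[i], seed = 0, go_time = go_time,
                         rotation_deg = rotation_deg))
  seeds <- vapply(seq_len(n), function(i) substream(seed, seed_stream, i),
                  integer(1))
  list(trials = trials, seeds = seeds)
}

#' Probe a frozen network on a fixed seeded trial set
#'
#' Runs the identical trial set (same specs and initial-state seeds)
#' against a weight snapshot with plasticity disabled, for epoch-matched
#' activity comparisons.
#'
#' @param params `network_params` snapshot.
#' @param probe_set from [make_probe_set()].
#' @return list of `trial_result`.
#' @export
probe_frozen <- function(params, probe_set) {
  lapply(seq_along(probe_set$trials), function(i)
    run_trial(params, probe_set$trials[[i]], probe_set$seeds[i]))
}

#' Epoch probes for activity-change analysis
#'
#' Simulates the three matched epochs: baseline (A: pre-adaptation weights,
#' no rotation), perturbation onset (B: pre-adaptation weights, rotation
#' on), and late adaptation (C: weights after `adapted_at` plastic trials,
#' rotation on), all on the same seeded trial set, plus an independent
#' baseline repeat (fresh initial states) used for classification nulls.
#'
#' @param log an `adaptation_log` from a rotation session.
#' @param n_trials probe trials per epoch.
#' @param seed probe seed.
#' @param adapted_at number of perturbation trials after which the
#'   "adapted" snapshot is taken (epoch C); the default of 500 is where
#'   the standard network has reached its near-zero plateau, with the
#'   feedback component back near baseline.
#' @param rotation_deg the session's rotation.
#' @return list with probes `A`, `B`, `C`, `A_null` and the window/go
#'   bookkeeping.
#' @export
epoch_probes <- function(log, n_trials = 200, seed = 1, adapted_at = 500,
                         rotation_deg = 30) {
  base <- log$params_baseline
  n_baseline <- sum(log$trials$phase == "baseline")
  adapted <- snapshot_params(log, n_baseline + adapted_at)
  set_a <- make_probe_set(n_trials, seed, rotation_deg = 0)
  set_b <- make_probe_set(n_trials, seed, rotation_deg = rotation_deg)
  set_null <- make_probe_set(n_trials, seed, rotation_deg = 0,
                             seed_stream = "probe_null")
  list(A = probe_frozen(base, set_a),
       B = probe_frozen(base, set_b),
       C = probe_frozen(adapted, set_b),
       A_null = probe_frozen(base, set_null))
}

#' Policy-remap experiment
#'
#' Adapt fully to a rotation matching the inter-target spacing (45 deg),
#' then cue each baseline target with the rotation removed and plasticity
#' off. If learning updated the input-output policy, the evoked reach
#' shifts by about the rotation toward the neighbouring target.
#'
#' @param params trained `network_params`.
#' @param seed experiment seed.
#' @param rotation_deg rotation (degrees; 45 matches the target spacing).
#' @param n_adapt perturbation trials before probing.
#' @param n_probe_reps probe repetitions per target.
#' @param config a `plasticity_config`.
#' @return list with per-target shifts (degrees, adapted minus baseline
#'   reach direction) and the session log.
#' @export
policy_remap_experiment <- function(params, seed = 1, rotation_deg = 45,
                                    n_adapt = 400, n_probe_reps = 5,
                                    config = plasticity_config()) {
  proto <- session_protocol(list(
    list(name = "baseline", n_trials = 24, rotation = 0, plasticity = FALSE),
    list(name = "perturbation", n_trials = n_adapt,
         rotation = rotation_deg, plasticity = TRUE)), seed = seed)
  log <- run_adaptation(params, proto, config)
  adapted <- log$params_final
  shifts <- matrix(NA_real_, n_probe_reps, 8)
  for (k in 0:7) {
    for (r in seq_len(n_probe_reps)) {
      tr <- make_centerout_trial(k, seed = 0, go_time = 1.45,
                                 rotation_deg = 0)
      s <- substream(seed, "remap", k * n_probe_reps + r)
      dir_base <- early_reach_direction(run_trial(log$params_baseline, tr, s))
      dir_adapt <- early_reach_direction(run_trial(adapted, tr, s))
      shifts[r, k + 1] <- wrap_deg(dir_adapt - dir_base)
    }
  }
  mean_shift <- wrap_deg(apply(shifts, 2, function(s) {
    # circular mean of the per-rep shifts
    atan2(mean(sin(s * pi / 180)), mean(cos(s * pi / 180))) * 180 / pi
  }))
  list(shift_by_target = data.frame(target_deg = 45 * (0:7),
                                    shift_deg = mean_shift),
       mean_abs_shift = mean(abs(mean_shift)), log = log)
}

#' Single-target generalization experiment
#'
#' Adapt with the rotation applied to one target only, then probe all
#' eight targets under the rotation with plasticity off; report the
#' residual take-off error (and its reduction from the unadapted state)
#' against angular distance from the adapted target.
#'
#' @param params trained `network_params`.
#' @param adapted_target_index target trained on (0-7).
#' @param seed experiment seed.
#' @param rotation_deg rotation, degrees.
#' @param n_adapt adaptation trials.
#' @param n_probe_reps probe repetitions per target.
#' @param config a `plasticity_config`.
#' @return list with a per-target data frame (`generalization`) and the
#'   session log.
#' @export
generalization_experiment <- function(params, adapted_target_index = 0,
                                      seed = 1, rotation_deg = 30,
                                      n_adapt = 400, n_probe_reps = 5,
                                      config = plasticity_config()) {
  proto <- session_protocol(list(
    list(name = "perturbation", n_trials = n_adapt,
         rotation = rotation_deg, plasticity = TRUE,
         target_index = adapted_target_index)), seed = seed)
  log <- run_adaptation(params, proto, config)
  err <- function(p, k, r) {
    tr <- make_centerout_trial(k, seed = 0, go_time = 1.45,
                               rotation_deg = rotation_deg)
    abs(takeoff_error(run_trial(p, tr, substream(seed, "gen", k * 100 + r))))
  }
  res <- lapply(0:7, function(k) {
    e_un <- mean(vapply(seq_len(n_probe_reps), function(r)
      err(log$params_baseline, k, r), numeric(1)))
    e_ad <- mean(vapply(seq_len(n_probe_reps), function(r)
      err(log$params_final, k, r), numeric(1)))
    data.frame(target_deg = 45 * k,
               angular_distance = abs(wrap_deg(45 * (k - adapted_target_index))),
               err_unadapted = e_un, err_adapted = e_ad,
               reduction = e_un - e_ad)
  })
  list(generalization = do.call(rbind, res), log = log)
}

#' Perturbation-variability sweep
#'
#' Runs one adaptation session per noise level with the per-trial rotation
#' drawn from Normal(mean_deg, sigma^2), and reports the asymptotic mean
#' absolute take-off error over the final trials.
#'
#' @param params trained `network_params`.
#' @param sigma_list_deg rotation s.d. values to sweep.
#' @param seed experiment seed.
#' @param mean_deg mean rotation.
#' @param n_trials perturbation trials per session.
#' @param n_asymptotic trials at the end of each session used for the
#'   asymptote.
#' @param config a `plasticity_config`.
#' @return data frame sigma_deg vs asymptotic_error_deg.
#' @export
variability_experiment <- function(params, sigma_list_deg = c(0, 4, 8, 12, 16),
                                   seed = 1, mean_deg = 30, n_trials = 500,
                                   n_asymptotic = 100,
                                   config = plasticity_config()) {
  out <- lapply(seq_along(sigma_list_deg), function(k) {
    sig <- sigma_list_deg[k]
    set.seed(substream(seed, "sigma", k))
    rots <- stats::rnorm(n_trials, mean_deg, sig)
    proto <- session_protocol(list(
      list(name = "perturbation", n_trials = n_trials, rotation = rots,
           plasticity = TRUE)), seed = substream(seed, "varsess", k))
    log <- run_adaptation(params, proto, config)
    e <- abs(log$trials$takeoff_error_deg)
    data.frame(sigma_deg = sig,
               asymptotic_error_deg = mean(utils::tail(e, n_asymptotic)))
  })
  do.call(rbind, out)
}

#' Early (pre-feedback) reach direction
#'
#' The direction of the cursor displacement from the go cue to the moment
#' the cursor has covered a given fraction of the reach length. Taken
#' early enough, this captures the cue-evoked aim before delayed feedback
#' has had time to bend the path, which is the relevant quantity when
#' probing what input-output mapping the network has learnt.
#'
#' @param result a `trial_result`.
#' @param frac fraction of the reach length defining the measurement point.
#' @return direction in degrees.
#' @export
early_reach_direction <- function(result, frac = 0.2) {
  go <- result$go_step
  p <- result$p
  d <- sqrt(colSums((p - p[, go])^2))
  L <- sqrt(sum((result$trial$p_end - result$trial$p_start)^2))
  t1 <- which(d > frac * L & seq_along(d) > go)[1]
  if (is.na(t1)) stop("cursor never covered the requested fraction of the reach")
  dd <- p[, t1] - p[, go]
  atan2(dd[2], dd[1]) * 180 / pi
}

stim_windows <- list(
  target   = list(ref = "start", offset = 0,    duration = 0.2),
  go_cue   = list(ref = "go",    offset = -0.2, duration = 0.2),
  movement = list(ref = "go",    offset = 0.4,  duration = 0.2),
  feedback = list(ref = "go",    offset = 0.65, duration = 0.2))

#' Delay/feedback-period stimulation experiment
#'
#' During adaptation, every other trial between adaptation trials 10 and
#' 50 receives a uniform extra input to all units (amplitude 0.1, 200 ms)
#' in the named within-trial window. Reports the current-trial take-off
#' error, the reaction-time proxy, and the next-trial learning
#' (drop in absolute error to the following trial) for stimulated versus
#' unstimulated trials in that range.
#'
#' @param params trained `network_params`.
#' @param window_label one of `"target"`, `"go_cue"`, `"movement"`,
#'   `"feedback"`.
#' @param seed experiment seed.
#' @param rotation_deg rotation, degrees.
#' @param n_baseline,n_adapt trial counts.
#' @param amplitude stimulation amplitude (0 for a sham control).
#' @param config a `plasticity_config`.
#' @return list with the per-trial comparison frame and stimulated vs
#'   unstimulated summary means.
#' @export
stimulation_experiment <- function(params, window_label = "go_cue", seed = 1,
                                   rotation_deg = 30, n_baseline = 20,
                                   n_adapt = 60, amplitude = 0.1,
                                   config = plasticity_config()) {
  win <- stim_windows[[window_label]]
  if (is.null(win)) stop("unknown stimulation window: ", window_label)
  range_trials <- 10:49
  stim_trials <- range_trials[seq_along(range_trials) %% 2 == 1]
  proto <- session_protocol(list(
    list(name = "baseline", n_trials = n_baseline, rotation = 0,
         plasticity = FALSE),
    list(name = "perturbation", n_trials = n_adapt, rotation = rotation_deg,
         plasticity = TRUE,
         stimulation = list(ref = win$ref, offset = win$offset,
                            duration = win$duration, amplitude = amplitude,
                            trials = stim_trials))), seed = seed)
  log <- run_adaptation(params, proto, config)
  pert <- log$trials[log$trials$phase == "perturbation", ]
  e <- abs(pert$takeoff_error_deg)
  idx <- range_trials[range_trials < nrow(pert)]
  cmp <- data.frame(trial = idx, stimulated = pert$stimulated[idx],
                    takeoff_abs_error = e[idx],
                    reaction_time_s = pert$reaction_time_s[idx],
                    next_trial_learning = e[idx] - e[idx + 1])
  agg <- stats::aggregate(cmp[, c("takeoff_abs_error", "reaction_time_s",
                                  "next_trial_learning")],
                          by = list(stimulated = cmp$stimulated), mean)
  list(comparison = cmp, summary = agg, window = window_label, log = log)
}

#' Error-clamp experiment
#'
#' Adaptation, a brief counter-rotation, then a block of error-clamp
#' trials in which the feedback error (both the input to the network and
#' the plasticity rule's error term) is forced to zero. With a purely
#' error-gated rule, the weights are untouched during the clamp and the
#' behaviour shows no spontaneous recovery.
#'
#' @param params trained `network_params`.
#' @param seed experiment seed.
#' @param rotation_deg adaptation rotation.
#' @param counts trial counts: adaptation, counter-perturbation, clamp.
#' @param config a `plasticity_config`.
#' @return list with the log and the per-phase take-off error summaries.
#' @export
error_clamp_experiment <- function(params, seed = 1, rotation_deg = 30,
                                   counts = c(300, 20, 100),
                                   config = plasticity_config()) {
  proto <- session_protocol(list(
    list(name = "perturbation", n_trials = counts[[1]],
         rotation = rotation_deg, plasticity = TRUE),
    list(name = "counter", n_trials = counts[[2]],
         rotation = -rotation_deg, plasticity = TRUE),
    list(name = "clamp", n_trials = counts[[3]], rotation = 0,
         plasticity = TRUE, clamp = TRUE)), seed = seed)
  log <- run_adaptation(params, proto, config, snapshot_every = 5)
  tr <- log$trials
  cl <- tr[tr$phase == "clamp", ]
  # de-bias by target before looking for a trend: per-target take-off
  # biases would otherwise masquerade as drift
  bias <- tapply(cl$takeoff_error_deg, cl$target_deg, mean)
  e_corr <- cl$takeoff_error_deg - bias[as.character(cl$target_deg)]
  slope <- stats::coef(stats::lm(e_corr ~ seq_along(e_corr)))[2]
  n12 <- counts[[1]] + counts[[2]]
  w_before <- log$snapshots[[as.character(n12)]]
  w_after <- log$params_final$W
  list(log = log,
       clamp_errors = cl$takeoff_error_deg,
       clamp_drift = abs(unname(slope)) * (nrow(cl) - 1),
       weights_frozen = identical(w_before, w_after))
}
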