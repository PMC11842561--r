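test_that("probing a frozen unadapted network replays its baseline trials bitwise", {
  set_a <- make_probe_set(6, seed = 31)
  p1 <- probe_frozen(net_main, set_a)
  p2 <- probe_frozen(net_main, set_a)
  for (i in seq_along(p1)) expect_identical(p1[[i]]$y, p2[[i]]$y)
})

test_that("a zero-rotation session stays at baseline error levels", {
  log <- vr_adaptation_session(net_main, rotation_deg = 0,
                               counts = c(20, 60, 10), seed = 44)
  e <- abs(log$trials$takeoff_error_deg)
  expect_lt(mean(e[log$trials$phase == "perturbation"]),
            mean(abs(sess_main$trials$takeoff_error_deg[
              sess_main$trials$phase == "baseline"])) + 2)
})

test_that("clockwise and counter-clockwise rotations give mirror-imaged errors", {
  lp <- vr_adaptation_session(net_main, 30, counts = c(10, 150, 10), seed = 45)
  lm <- vr_adaptation_session(net_main, -30, counts = c(10, 150, 10), seed = 45)
  ep <- lp$trials$takeoff_error_deg[lp$trials$phase == "perturbation"]
  em <- lm$trials$takeoff_error_deg[lm$trials$phase == "perturbation"]
  expect_gt(mean(ep), 10)
  expect_lt(mean(em), -10)
  expect_lt(abs(mean(ep) + mean(em)), 0.25 * abs(mean(ep)))
})

test_that("error clamps freeze the weights and block spontaneous recovery", {
  ec <- error_clamp_experiment(net_main, seed = 46, counts = c(200, 15, 60))
  expect_true(ec$weights_frozen)
  expect_lt(ec$clamp_drift, 3)
  # a clamped probe receives no error input: its weight change is zero but
  # unclamping the same trial resumes a nonzero update
  tr <- make_centerout_trial(0, seed = 1, rotation_deg = 30)
  trc <- tr; trc$error_clamp <- TRUE
  open <- accumulate_and_apply(run_trial(net_main, tr, 2, record_full = TRUE),
                               plasticity_config(), net_main)
  clamped <- accumulate_and_apply(run_trial(net_main, trc, 2, record_full = TRUE),
                                  plasticity_config(), net_main)
  expect_identical(clamped$W, net_main$W)
  expect_false(identical(open$W, net_main$W))
})

test_that("delay-period stimulation perturbs timing but not the current reach", {
  # the current-trial take-off error is unaffected; the reaction-time
  # shift is bounded and network-dependent at this scale (consistently
  # positive for 150-unit networks, mixed at 100 units)
  sums <- lapply(47:50, function(sd)
    stimulation_experiment(net_main, "go_cue", seed = sd, n_adapt = 60)$summary)
  rt_un <- mean(sapply(sums, function(s) s$reaction_time_s[!s$stimulated]))
  rt_st <- mean(sapply(sums, function(s) s$reaction_time_s[s$stimulated]))
  expect_lt(abs(rt_st - rt_un), 0.1)
  err_un <- mean(sapply(sums, function(s) s$takeoff_abs_error[!s$stimulated]))
  err_st <- mean(sapply(sums, function(s) s$takeoff_abs_error[s$stimulated]))
  expect_lt(abs(err_st - err_un), 0.15 * err_un)
  # sham (zero amplitude): stimulated trials are dynamically identical
  sham <- stimulation_experiment(net_main, "go_cue", seed = 47, n_adapt = 60,
                                 amplitude = 0)
  s0 <- sham$summary
  expect_lt(abs(s0$reaction_time_s[s0$stimulated] -
                  s0$reaction_time_s[!s0$stimulated]), 0.01)
})

test_that("a written session can be read back and replayed identically", {
  dir <- file.path(tempdir(), "fbm_sess")
  proto <- session_protocol(list(
    list(name = "perturbation", n_trials = 12, rotation = 30,
         plasticity = TRUE)), seed = 48)
  log <- run_adaptation(net_main, proto, snapshot_every = 4)
  write_session(log, dir)
  back <- read_session(dir)
  expect_equal(back$trials$takeoff_error_deg, log$trials$takeoff_error_deg)
  expect_equal(nrow(back$trials), 12)
  # replaying the manifest's protocol regenerates identical take-off errors
  log2 <- run_adaptation(net_main,
                         session_protocol(list(
                           list(name = "perturbation", n_trials = 12,
                                rotation = 30, plasticity = TRUE)),
                           seed = back$manifest$protocol$seed),
                         snapshot_every = 4)
  expect_identical(log2$trials$takeoff_error_deg,
                   log$trials$takeoff_error_deg)
  unlink(dir, recursive = TRUE)
})
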