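# Shared fixtures: scaled-down trained networks and adaptation sessions,
# built once per test run. Sizes are chosen so the whole suite trains and
# adapts in a few minutes while preserving the qualitative regime of the
# full-size model (see the methods vignette for the scaling rationale).

message("setup: training shared networks (a few minutes) ...")

tc100 <- training_config(N = 100, epochs = c(40, 120, 140), seed = 5)
net_main <- train_initial(tc100)

tc100b <- training_config(N = 100, epochs = c(40, 120, 140), seed = 6)
net_second <- train_initial(tc100b)

tc80 <- training_config(N = 80, epochs = c(30, 80, 100), seed = 5)
net_nofb <- train_no_feedback(tc80)
net_norec <- train_no_recurrence(tc80)

# standard 30-degree rotation session on the main network, with activity
# recordings for the unit-level analyses
set.seed(401)
rec_units <- sample(net_main$N, 60)
sess_main <- vr_adaptation_session(net_main, rotation_deg = 30,
                                   counts = c(60, 500, 60), seed = 7,
                                   record_windows = TRUE,
                                   record_y_units = rec_units)
sess_second <- vr_adaptation_session(net_second, rotation_deg = 30,
                                     counts = c(20, 500, 20), seed = 8,
                                     record_windows = TRUE)

probes_main <- epoch_probes(sess_main, n_trials = 120, seed = 99,
                            adapted_at = 500, rotation_deg = 30)
probes_second <- epoch_probes(sess_second, n_trials = 120, seed = 98,
                              adapted_at = 500, rotation_deg = 30)

# gradient-descent adaptation control (no online feedback)
gd_ctrl <- adapt_by_gradient_descent(net_main, rotation_deg = 30,
                                     n_updates = 15, config = tc100,
                                     seed = 13)

message("setup: done")
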