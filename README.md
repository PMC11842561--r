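# fbmotor

Closed-loop recurrent network simulation of feedback-based motor control
and trial-by-trial motor adaptation.

## What this package is for

When reaching movements are perturbed — classically by a visuomotor
rotation (VR) that rotates the visual feedback of the hand about the
workspace centre — subjects first correct online within each movement and
then, over tens of trials, re-aim so the reach starts out in the right
direction. `fbmotor` implements a circuit-level model in which both
behaviours come from one signal: a recurrent neural network (RNN) that
receives its own cursor error as a delayed input uses that input to steer
the ongoing movement, and the very same input gates a local synaptic
plasticity rule that updates the recurrent weights trial by trial. The
package is aimed at computational/systems neuroscientists who want to
simulate these experiments, probe the resulting population activity, and
fit behavioural learning models to the output.

The dynamics (N rectified-linear units, time step dt = 10 ms, time
constant tau = 50 ms, feedback delay Delta = 120 ms) are

    x(t+1) = x(t) + dt/tau * ( -x(t) + W y(t) + W_in s(t)
                               + F eps(t - Delta) + b )
    y = max(0, x),   v = W_out y + b_out,
    p(t) = p(t-1) + dt * R(theta) v(t),   eps = p* - p

with `v` the cursor velocity (cm/s), `p*` a logistic desired trajectory,
and `R(theta)` the active rotation. The plasticity rule accumulates, every
fifth step,

    dW_ji = dt * eta * ( sum_k F_jk eps_k(t - Delta) ) * r_i(t)

(the delayed error projected through the postsynaptic unit's feedback
weights, times the presynaptic eligibility trace `r`, the running
within-trial activity sum) and applies the sum at trial end.

The package covers: gradient training of the closed loop (BPTT through the
delayed feedback path, implemented in C++), no-feedback / no-recurrence /
gradient-descent-adaptation control models, scripted experiments (VR
adaptation and washout, error clamps, perturbation-variability sweeps,
single-target generalization, 45-degree policy remapping, delay-period
stimulation), and the analysis suite (take-off angles, epoch-matched
activity-change traces and peak latencies, null-calibrated unit
classification, velocity decoders and back-tests, single- and dual-rate
state-space fits with a nested F-test).

## Worked example

```r
library(fbmotor)

# train a scaled-down network (a few minutes; N = 400 is the full model)
tc  <- training_config(N = 150, epochs = c(40, 130, 150), seed = 42)
net <- train_initial(tc)

# unperturbed centre-out reach
r <- run_trial(net, make_centerout_trial(0, seed = 1, go_time = 1.45), seed = 2)
r
#> <trial_result> 300 steps, take-off error -0.7 deg, endpoint error 0.13 cm

# a 30-degree visuomotor rotation session with the plasticity rule
log <- vr_adaptation_session(net, rotation_deg = 30,
                             counts = c(100, 500, 100), seed = 7)
pe <- subset(log$trials, phase == "perturbation")$takeoff_error_deg
wo <- subset(log$trials, phase == "washout")$takeoff_error_deg
round(c(first_40 = mean(pe[1:40]), last_80 = mean(tail(pe, 80)),
        washout_first_20 = mean(wo[1:20])), 1)
#>         first_40          last_80 washout_first_20
#>             21.7              7.5            -15.6
```

The first perturbation trials mis-reach by roughly the rotation (slightly
less, because online feedback already bends the path before peak speed);
errors then decay several-fold over a few hundred trials (how far depends
on the network: plateaus of 2-8 degrees across training seeds), and
removing the rotation leaves opposite-signed after-effects that wash
out. Probing frozen weight
snapshots on matched trials (`epoch_probes()`, `activity_change()`,
`find_peak_times()`) shows the learning-related activity change peaking
about 0.5 s after the go cue and the feedback-related change peaking about
0.8 s after it.

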