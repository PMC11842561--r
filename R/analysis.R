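wrap_deg <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w <= -180] <- w[w <= -180] + 360   # wrap to (-180, 180]
  w
}

#' Take-off angle of a reach
#'
#' The initial reach direction: the angle of the cursor displacement between
#' the go cue and the moment of peak cursor speed within the trial.
#'
#' @param result a `trial_result`.
#' @return angle in degrees.
#' @export
takeoff_angle <- function(result) {
  p <- result$p
  go <- result$go_step
  T <- ncol(p)
  if (go >= T) stop("go cue after trial end")
  speed <- sqrt(colSums((p[, (go + 1):T, drop = FALSE] -
                           p[, go:(T - 1), drop = FALSE])^2))
  t_peak <- go + which.max(speed)
  d <- p[, t_peak] - p[, go]
  if (sqrt(sum(d^2)) < 1e-12) stop("no movement: take-off angle undefined")
  atan2(d[2], d[1]) * 180 / pi
}

#' Take-off error of a reach
#'
#' Signed angular difference between the take-off angle and the target
#' direction (start-to-end direction of the trial), wrapped to (-180, 180].
#'
#' @param result a `trial_result`.
#' @return signed error in degrees.
#' @export
takeoff_error <- function(result) {
  d <- result$trial$p_end - result$trial$p_start
  target <- atan2(d[2], d[1]) * 180 / pi
  wrap_deg(takeoff_angle(result) - target)
}

#' Gaussian smoothing of a per-trial error sequence
#'
#' Gaussian kernel smoothing with reflecting boundaries; constant sequences
#' are preserved exactly.
#'
#' @param errors numeric vector (one value per trial).
#' @param sd_trials kernel standard deviation, trials.
#' @return smoothed vector of the same length.
#' @export
smooth_error_curve <- function(errors, sd_trials = 10) {
  n <- length(errors)
  h <- min(ceiling(4 * sd_trials), n - 1)
  k <- stats::dnorm(-h:h, sd = sd_trials)
  k <- k / sum(k)
  padded <- c(errors[h:1], errors, errors[n:(n - h + 1)])
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}

#' Correlation between trial error and subsequent learning
#'
#' Pearson correlation between the absolute take-off error on trial n and
#' the drop in absolute error from trial n to n + 1, over the
#' perturbation-phase trials; significance from the bivariate-normal null
#' (the standard t-based test).
#'
#' @param errors numeric vector of per-trial take-off errors (degrees), or
#'   an `adaptation_log` (its perturbation phase is used).
#' @return list with `r`, `p` and `n`.
#' @export
learning_vs_error_correlation <- function(errors) {
  if (inherits(errors, "adaptation_log"))
    errors <- errors$trials$takeoff_error_deg[errors$trials$phase == "perturbation"]
  e <- abs(errors)
  n <- length(e)
  a <- e[-n]
  b <- e[-n] - e[-1]
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n - 1)
}

#' Mean absolute activity change between two matched probe sets
#'
#' For two one-to-one matched sets of seeded trials (same trial specs and
#' initial-state seeds, fixed go time), computes the per-step mean over
#' units and trial pairs of the absolute activity difference.
#'
#' @param probe_1,probe_2 lists of `trial_result` of equal length, matched
#'   trial-by-trial and aligned on a common go step.
#' @return An object of class `activity_trace`: per-step trace plus the go
#'   step and dt.
#' @export
activity_change <- function(probe_1, probe_2) {
  stopifnot(length(probe_1) == length(probe_2), length(probe_1) > 0)
  go <- probe_1[[1]]$go_step
  for (i in seq_along(probe_1))
    if (probe_1[[i]]$go_step != go || probe_2[[i]]$go_step != go)
      stop("probe trials must share a common go step for alignment")
  acc <- 0
  for (i in seq_along(probe_1))
    acc <- acc + colMeans(abs(probe_1[[i]]$y - probe_2[[i]]$y))
  structure(list(trace = acc / length(probe_1), go_step = go,
                 dt = probe_1[[1]]$dt, n_trials = length(probe_1)),
            class = "activity_trace")
}

#' Average activity-change traces across networks
#'
#' @param traces list of `activity_trace` objects with identical alignment.
#' @return an `activity_trace` (the elementwise mean).
#' @export
average_traces <- function(traces) {
  go <- traces[[1]]$go_step
  stopifnot(all(vapply(traces, function(t) t$go_step == go, logical(1))))
  m <- rowMeans(vapply(traces, function(t) t$trace,
                       numeric(length(traces[[1]]$trace))))
  structure(list(trace = m, go_step = go, dt = traces[[1]]$dt,
                 n_trials = NA_integer_), class = "activity_trace")
}

# latency (s after go) of the post-go maximum of a trace
trace_peak_time <- function(trace) {
  tr <- trace$trace
  idx <- (trace$go_step + 1):length(tr)
  pk <- idx[which.max(tr[idx])]
  (pk - trace$go_step) * trace$dt / 1000
}

# value of a trace at a latency (s after go)
trace_at <- function(trace, t_after_go) {
  idx <- trace$go_step + round(t_after_go * 1000 / trace$dt)
  trace$trace[idx]
}

#' Feedforward and feedback peak latencies
#'
#' The feedforward (learning) peak is the post-go maximum of the
#' late-vs-early adaptation trace (epoch C vs B); the feedback peak is the
#' post-go maximum of the perturbation-onset-vs-baseline trace (B vs A).
#' Traces are typically across-network averages.
#'
#' @param trace_cb activity change between late and early adaptation.
#' @param trace_ba activity change between early adaptation and baseline.
#' @return list with `ff_time` and `fb_time`, seconds after the go cue.
#' @export
find_peak_times <- function(trace_cb, trace_ba) {
  list(ff_time = trace_peak_time(trace_cb),
       fb_time = trace_peak_time(trace_ba))
}

#' Feedback-to-feedforward activity-change ratio
#'
#' The feedback-related trace (perturbation onset vs baseline, B vs A)
#' evaluated at the feedback peak time, divided by the learning-related
#' trace (late adaptation vs baseline, C vs A) at the feedforward peak
#' time. Near 1 when feedback corrections contribute as much activity
#' change as re-aiming (plasticity-adapted networks); near 0 for models
#' adapted without an online feedback pathway.
#'
#' @param trace_ba feedback-related `activity_trace` (B vs A).
#' @param trace_ca learning-related `activity_trace` (C vs A).
#' @param ff_time,fb_time peak latencies (s after go), normally taken from
#'   the across-network average traces.
#' @return scalar ratio.
#' @export
fb_ff_ratio <- function(trace_ba, trace_ca, ff_time = 0.5, fb_time = 0.8) {
  trace_at(trace_ba, fb_time) / trace_at(trace_ca, ff_time)
}

window_steps <- function(go_step, dt, center, half = 0.1) {
  go_step + seq(round((center - half) * 1000 / dt),
                round((center + half) * 1000 / dt))
}

# unit x trial matrix of window-mean |y1 - y2|
pair_window_means <- function(probe_1, probe_2, steps) {
  vapply(seq_along(probe_1),
         function(i) rowMeans(abs(probe_1[[i]]$y[, steps, drop = FALSE] -
                                    probe_2[[i]]$y[, steps, drop = FALSE])),
         numeric(nrow(probe_1[[1]]$y)))
}

#' Classify units by feedback- and learning-related activity changes
#'
#' A unit is feedback-responsive if its trial-mean absolute activity change
#' between the perturbation-onset probe and baseline, within the feedback
#' window (0.8 +/- 0.1 s after go), exceeds the 95th percentile of its
#' baseline-vs-baseline null; learning-responsive analogously for the
#' late-adaptation probe in the 0.5 +/- 0.1 s window. The null is built by
#' bootstrap over trials of the window-mean change between two independent
#' baseline probe sets (same trials, fresh initial-state seeds).
#'
#' @param probe_a baseline probe (list of `trial_result`).
#' @param probe_b perturbation-onset probe (frozen weights, rotation on).
#' @param probe_c late-adaptation probe (adapted weights, rotation on).
#' @param probe_null second baseline probe with different initial-state
#'   seeds, paired with `probe_a` to form the null.
#' @param fb_center,ff_center window centres, s after go.
#' @param half_width window half-width, s.
#' @param level percentile of the null used as threshold.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap resampling.
#' @return list with a per-unit data frame (`units`) and the percentage
#'   breakdown `fractions` (feedback / learning / both / neither).
#' @export
classify_units <- function(probe_a, probe_b, probe_c, probe_null,
                           fb_center = 0.8, ff_center = 0.5,
                           half_width = 0.1, level = 0.95,
                           n_boot = 500, seed = 1) {
  go <- probe_a[[1]]$go_step
  dt <- probe_a[[1]]$dt
  steps_fb <- window_steps(go, dt, fb_center, half_width)
  steps_ff <- window_steps(go, dt, ff_center, half_width)

  obs_fb <- rowMeans(pair_window_means(probe_b, probe_a, steps_fb))
  obs_ff <- rowMeans(pair_window_means(probe_c, probe_a, steps_ff))
  null_fb <- pair_window_means(probe_null, probe_a, steps_fb)
  null_ff <- pair_window_means(probe_null, probe_a, steps_ff)

  n_tr <- ncol(null_fb)
  set.seed(seed)
  boot_idx <- matrix(sample.int(n_tr, n_boot * n_tr, replace = TRUE),
                     n_boot, n_tr)
  # threshold for the trial-mean change: the null pair's mean plus the
  # bootstrap quantile of its fluctuation, scaled by sqrt(2) because both
  # the observed and the null statistic are independent trial means with
  # the same sampling variance
  boot_q <- function(nullmat) {
    m <- rowMeans(nullmat)
    boot <- apply(boot_idx, 1, function(ix) rowMeans(nullmat[, ix, drop = FALSE]))
    m + sqrt(2) * (apply(boot, 1, stats::quantile, probs = level) - m)
  }
  thr_fb <- boot_q(null_fb)
  thr_ff <- boot_q(null_ff)

  is_fb <- obs_fb > thr_fb
  is_ff <- obs_ff > thr_ff
  cls <- ifelse(is_fb & is_ff, "both",
                ifelse(is_fb, "feedback", ifelse(is_ff, "learning", "neither")))
  units <- data.frame(unit = seq_along(obs_fb), fb_change = obs_fb,
                      ff_change = obs_ff, fb_threshold = thr_fb,
                      ff_threshold = thr_ff, feedback = is_fb,
                      learning = is_ff, class = cls)
  fractions <- list(feedback = 100 * mean(is_fb),
                    learning = 100 * mean(is_ff),
                    both = 100 * mean(is_fb & is_ff),
                    neither = 100 * mean(!is_fb & !is_ff))
  list(units = units, fractions = fractions)
}

#' Per-unit correlation between early feedback and late learning changes
#'
#' Across a set of units (normally those classified as showing both change
#' types), correlates each unit's mean feedback-window activity change over
#' the first `n_early` adaptation trials with its mean learning-window
#' change over the last `n_late` adaptation trials, both measured against
#' matched replays of the same trials under baseline weights without the
#' perturbation.
#'
#' @param log an `adaptation_log` recorded with `record_windows = TRUE`.
#' @param baseline_params the network parameters before adaptation.
#' @param units integer vector of unit indices to include.
#' @param n_early,n_late numbers of early/late adaptation trials.
#' @return list with `r`, `p` and `n` (units).
#' @export
fb_ff_unit_correlation <- function(log, baseline_params, units = NULL,
                                   n_early = 30, n_late = 30) {
  win <- log$window_record
  if (is.null(win)) stop("adaptation log has no recorded activity windows")
  n_trials <- dim(win$fb)[3]
  early <- seq_len(n_early)
  late <- (n_trials - n_late + 1):n_trials

  base <- replay_windows(log, baseline_params, c(early, late))
  d_fb <- abs(win$fb[, , early, drop = FALSE] -
                base$fb[, , seq_along(early), drop = FALSE])
  d_ff <- abs(win$ff[, , late, drop = FALSE] -
                base$ff[, , n_early + seq_along(late), drop = FALSE])
  fb_change <- apply(d_fb, 1, mean)
  ff_change <- apply(d_ff, 1, mean)
  if (is.null(units)) units <- seq_along(fb_change)
  ct <- stats::cor.test(fb_change[units], ff_change[units])
  list(r = unname(ct$estimate), p = ct$p.value, n = length(units),
       fb_change = fb_change, ff_change = ff_change)
}

# replay selected perturbation trials under given weights without the
# rotation, returning the same activity windows as the session recording
replay_windows <- function(log, params, trial_idx) {
  rec <- log$window_record
  pert <- log$trials[log$trials$phase == "perturbation", ]
  fb <- array(0, c(params$N, length(rec$fb_offsets), length(trial_idx)))
  ff <- array(0, c(params$N, length(rec$ff_offsets), length(trial_idx)))
  for (k in seq_along(trial_idx)) {
    i <- trial_idx[k]
    tr <- log$specs[[pert$index[i]]]
    tr$rotation_deg <- 0
    res <- run_trial(params, tr, seed = pert$seed[i])
    fb[, , k] <- res$y[, res$go_step + rec$fb_offsets]
    ff[, , k] <- res$y[, res$go_step + rec$ff_offsets]
  }
  list(fb = fb, ff = ff)
}

#' Fit a linear velocity decoder at a range of lags
#'
#' Ordinary least squares (with a tiny ridge for rank safety) from the
#' activity of a fixed subset of units at time t to the network's velocity
#' output at t + lag. Accuracy is the coefficient of determination averaged
#' over the two output dimensions, evaluated on held-out trials.
#'
#' @param train,test disjoint lists of `trial_result`.
#' @param units unit indices used by the decoder (the analysis uses a fixed
#'   random subset of 100 by default upstream).
#' @param lags integer vector of lags in steps.
#' @param ridge ridge penalty added to the normal equations.
#' @return list with `accuracy` (data frame lag, lag_ms, r2) and the
#'   per-lag coefficient matrices.
#' @export
fit_velocity_decoder <- function(train, test, units, lags = 0:30,
                                 ridge = 1e-8) {
  build <- function(results, lag) {
    Xs <- lapply(results, function(r) {
      T <- ncol(r$y)
      cbind(1, t(r$y[units, 1:(T - lag), drop = FALSE]))
    })
    Ys <- lapply(results, function(r) {
      T <- ncol(r$v)
      t(r$v[, (1 + lag):T, drop = FALSE])
    })
    list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
  }
  dt <- train[[1]]$dt
  coefs <- list()
  r2 <- numeric(length(lags))
  for (j in seq_along(lags)) {
    tr <- build(train, lags[j])
    A <- crossprod(tr$X) + ridge * diag(ncol(tr$X))
    beta <- solve(A, crossprod(tr$X, tr$Y))
    te <- build(test, lags[j])
    pred <- te$X %*% beta
    ss_res <- colSums((te$Y - pred)^2)
    ss_tot <- colSums(sweep(te$Y, 2, colMeans(te$Y))^2)
    r2[j] <- mean(1 - ss_res / ss_tot)
    coefs[[j]] <- beta
  }
  list(accuracy = data.frame(lag = lags, lag_ms = lags * dt, r2 = r2),
       coef = coefs, units = units, ridge = ridge)
}

#' Back-test an end-of-adaptation decoder on earlier trials
#'
#' Trains a lagged velocity decoder on the activity of the last
#' `n_train` adaptation trials and evaluates it on every preceding
#' adaptation trial separately, yielding a per-trial accuracy sequence.
#' A progressive drop toward early adaptation indicates that the mapping
#' from activity to output (the control policy) changed during learning.
#'
#' @param log an `adaptation_log` recorded with `record_y_units`.
#' @param lag decoder lag in steps.
#' @param n_train number of final adaptation trials used for training.
#' @param ridge ridge penalty.
#' @return data frame with trial index and decoder accuracy (R^2, averaged
#'   over output dimensions, pooled over steps within the trial).
#' @export
decoder_backtest <- function(log, lag = 12, n_train = 100, ridge = 1e-8) {
  rec <- log$y_record
  if (is.null(rec)) stop("adaptation log has no recorded unit activity")
  n_trials <- dim(rec$y)[3]
  stopifnot(n_train < n_trials)
  train_idx <- (n_trials - n_train + 1):n_trials
  T <- dim(rec$y)[2]
  build <- function(idx) {
    X <- do.call(rbind, lapply(idx, function(i)
      cbind(1, t(rec$y[, 1:(T - lag), i]))))
    Y <- do.call(rbind, lapply(idx, function(i) t(rec$v[, (1 + lag):T, i])))
    list(X = X, Y = Y)
  }
  tr <- build(train_idx)
  beta <- solve(crossprod(tr$X) + ridge * diag(ncol(tr$X)),
                crossprod(tr$X, tr$Y))
  ss_tot <- colSums(sweep(tr$Y, 2, colMeans(tr$Y))^2) / nrow(tr$Y)
  acc <- vapply(seq_len(n_trials), function(i) {
    te <- build(i)
    pred <- te$X %*% beta
    mean(1 - colSums((te$Y - pred)^2) / (nrow(te$Y) * ss_tot))
  }, numeric(1))
  data.frame(trial = seq_len(n_trials), r2 = acc,
             in_training_window = seq_len(n_trials) %in% train_idx)
}

# ---- state-space models of learning timescales ------------------------------

simulate_state_space <- function(A, B, e) {
  n <- length(e)
  x <- numeric(n)
  for (i in seq_len(n - 1)) x[i + 1] <- A * x[i] + B * e[i]
  x
}

simulate_dual_state_space <- function(Af, As, Bf, Bs, e) {
  n <- length(e)
  xf <- xs <- numeric(n)
  for (i in seq_len(n - 1)) {
    xf[i + 1] <- Af * xf[i] + Bf * e[i]
    xs[i + 1] <- As * xs[i] + Bs * e[i]
  }
  list(x = xf + xs, xf = xf, xs = xs)
}

#' Fit a single-rate state-space model of adaptation
#'
#' Fits `x(n+1) = A x(n) + B e(n)` to an observed adaptation sequence,
#' driven by the observed errors, by least squares with `A`, `B` in
#' `[0, 1]`.
#'
#' @param x_obs observed adaptation variable (change in take-off direction,
#'   scaled like `e`).
#' @param e observed per-trial error, scaled to `[-1, 1]`.
#' @param n_starts random restarts.
#' @param seed seed for the restarts.
#' @return an object of class `state_space_fit`.
#' @export
fit_single_rate <- function(x_obs, e, n_starts = 5, seed = 1) {
  n <- length(e)
  if (n <= 2) stop("too few trials to fit a state-space model")
  obj <- function(th) sum((simulate_state_space(th[1], th[2], e) - x_obs)^2)
  set.seed(seed)
  # the objective has a long flat A-B trade-off ridge: use a grid of
  # starts plus random ones, tight convergence, and a simplex polish
  starts <- rbind(as.matrix(expand.grid(A = c(0.8, 0.95, 0.99),
                                        B = c(0.005, 0.02, 0.1))),
                  cbind(stats::runif(n_starts, 0.5, 1),
                        stats::runif(n_starts, 0, 0.3)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, 1),
                        control = list(maxit = 500, factr = 1e4,
                                       parscale = c(1, 0.05)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  polish <- stats::optim(best$par, function(th)
    if (any(th < 0) || any(th > 1)) Inf else obj(th),
    method = "Nelder-Mead",
    control = list(maxit = 1000, reltol = 1e-12))
  if (polish$value < best$value) best <- polish
  structure(list(kind = "single", A = best$par[1], B = best$par[2],
                 rss = best$value, n = n, df = 2,
                 fitted = simulate_state_space(best$par[1], best$par[2], e)),
            class = "state_space_fit")
}

#' Fit a dual-rate state-space model of adaptation
#'
#' Fits the two-process model `x = x_f + x_s` with
#' `x_f(n+1) = A_f x_f(n) + B_f e(n)` and `x_s(n+1) = A_s x_s(n) + B_s e(n)`
#' under the constraints `A_f < A_s` (fast process retains less) and
#' `B_f > B_s` (fast process learns more), all rates in `[0, 1]`.
#' Constraints are enforced through a smooth reparameterisation and the
#' fit uses quasi-Newton least squares with random restarts.
#'
#' @inheritParams fit_single_rate
#' @return an object of class `state_space_fit`.
#' @export
fit_dual_rate <- function(x_obs, e, n_starts = 8, seed = 1) {
  n <- length(e)
  if (n <= 4) stop("too few trials to fit a state-space model")
  sig <- function(z) 1 / (1 + exp(-z))
  logit <- function(q) log(q / (1 - q))
  unpack <- function(z) {
    As <- sig(z[1])
    Af <- As * sig(z[2])
    Bs <- sig(z[3])
    Bf <- Bs + (1 - Bs) * sig(z[4])
    c(Af = Af, As = As, Bf = Bf, Bs = Bs)
  }
  obj <- function(z) {
    p <- unpack(z)
    sum((simulate_dual_state_space(p[1], p[2], p[3], p[4], e)$x - x_obs)^2)
  }
  set.seed(seed)
  # one start embeds the best single-rate fit at the model boundary
  # (slow process nearly absent), so the nested fit cannot lose to it
  fs0 <- fit_single_rate(x_obs, e, n_starts = 3, seed = seed)
  A1 <- min(max(fs0$A, 1e-3), 0.995)
  B1 <- min(max(fs0$B, 1e-4), 0.99)
  z_embed <- c(logit(min(A1 + 0.004, 0.999)),
               logit(A1 / min(A1 + 0.004, 0.999)),
               logit(1e-4), logit(B1 / (1 - 1e-4)))
  starts <- rbind(c(3, 1, -4, -2),            # typical fast/slow split
                  z_embed,
                  matrix(stats::rnorm(4 * (n_starts - 1), 0, 2),
                         n_starts - 1, 4))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(stats::optim(starts[s, ], obj, method = "BFGS",
                                 control = list(maxit = 1000,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  polish <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
  if (polish$value < best$value) best <- polish
  p <- unpack(best$par)
  sim <- simulate_dual_state_space(p[1], p[2], p[3], p[4], e)
  structure(list(kind = "dual", A_f = unname(p[1]), A_s = unname(p[2]),
                 B_f = unname(p[3]), B_s = unname(p[4]),
                 rss = best$value, n = n, df = 4,
                 fitted = sim$x, fast = sim$xf, slow = sim$xs),
            class = "state_space_fit")
}

#' @export
print.state_space_fit <- function(x, ...) {
  if (x$kind == "single")
    cat(sprintf("<state_space_fit> single-rate: A = %.3f, B = %.4f, RSS = %.4g (n = %d)\n",
                x$A, x$B, x$rss, x$n))
  else
    cat(sprintf("<state_space_fit> dual-rate: A_f = %.3f, A_s = %.3f, B_f = %.4f, B_s = %.4f, RSS = %.4g (n = %d)\n",
                x$A_f, x$A_s, x$B_f, x$B_s, x$rss, x$n))
  invisible(x)
}

#' Nested-model F-test between single- and dual-rate fits
#'
#' Standard nested F-test with 2 and 4 model degrees of freedom:
#' `F = ((RSS_1 - RSS_2) / 2) / (RSS_2 / (n - 4))`.
#'
#' @param fit_single,fit_dual `state_space_fit` objects on the same data.
#' @param alpha significance level for preferring the dual-rate model.
#' @return list with `f_statistic`, `p_value`, `preferred_model`.
#' @export
compare_models <- function(fit_single, fit_dual, alpha = 0.05) {
  stopifnot(fit_single$kind == "single", fit_dual$kind == "dual",
            fit_single$n == fit_dual$n)
  n <- fit_dual$n
  df1 <- fit_dual$df - fit_single$df
  df2 <- n - fit_dual$df
  f <- ((fit_single$rss - fit_dual$rss) / df1) / (fit_dual$rss / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(f_statistic = f, p_value = p, df = c(df1, df2),
       preferred_model = if (!is.na(p) && p < alpha) "dual" else "single")
}

#' Prepare state-space inputs from an adaptation log
#'
#' The adaptation variable is the per-trial compensation of the take-off
#' direction relative to the per-target baseline mean (0 at perturbation
#' onset, approaching 1 at full adaptation); the error is the take-off
#' error scaled by the signed rotation so it lies in `[-1, 1]` and starts
#' near +1 at perturbation onset.
#'
#' @param log an `adaptation_log`.
#' @param rotation_deg signed rotation used for scaling.
#' @return list with `x_obs` and `e` over the perturbation phase.
#' @export
adaptation_timecourse <- function(log, rotation_deg = 30) {
  tr <- log$trials
  base <- tr[tr$phase == "baseline", ]
  pert <- tr[tr$phase == "perturbation", ]
  base_mean <- tapply(base$takeoff_error_deg, base$target_deg, mean)
  rel <- pert$takeoff_error_deg -
    unname(base_mean[as.character(pert$target_deg)])
  e <- pmax(pmin(pert$takeoff_error_deg / rotation_deg, 1), -1)
  x_obs <- 1 - rel / rotation_deg
  list(x_obs = x_obs, e = e)
}

#' Ensemble peak latencies from per-network traces
#'
#' Peak latencies vary across networks, and for the learning peak the
#' argmax of a grand-average trace is biased toward the late (feedback)
#' lobe because learning-peak latencies jitter across networks while
#' feedback peaks are clock-locked to the movement and delay. The ensemble
#' statistic is therefore the median of per-network peak latencies.
#'
#' @param traces_cb list of per-network late-vs-early adaptation traces.
#' @param traces_ba list of per-network onset-vs-baseline traces.
#' @return list with `ff_time` and `fb_time` (s after go), plus the
#'   per-network latencies.
#' @export
ensemble_peak_times <- function(traces_cb, traces_ba) {
  ff <- vapply(traces_cb, trace_peak_time, numeric(1))
  fb <- vapply(traces_ba, trace_peak_time, numeric(1))
  list(ff_time = stats::median(ff), fb_time = stats::median(fb),
       ff_by_network = ff, fb_by_network = fb)
}
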