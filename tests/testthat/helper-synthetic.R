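# Small constructors for synthetic objects used by analysis tests.

# a trial_result with fabricated cursor path / activity
fake_result <- function(p = NULL, y = NULL, go_step = 146, dt = 10,
                        p_start = c(0, 0), p_end = c(5, 0)) {
  trial <- trial_spec(p_start, p_end, go_time = (go_step - 1) * dt / 1000)
  out <- list(trial = trial, go_step = go_step, dt = dt, p = p, y = y)
  class(out) <- "trial_result"
  out
}

# straight constant-speed reach from p_start towards `angle_deg`, starting
# at the go step
fake_reach <- function(angle_deg, go_step = 146, T = 300, speed = 0.05,
                       p_start = c(0, 0), p_end = c(5, 0)) {
  th <- angle_deg * pi / 180
  p <- matrix(p_start, 2, T)
  for (t in (go_step + 1):T)
    p[, t] <- p[, t - 1] + speed * c(cos(th), sin(th))
  fake_result(p = p, go_step = go_step, p_start = p_start, p_end = p_end)
}

# list of fake probe trials with N x T gaussian activity (optionally with a
# per-unit offset added inside a window)
fake_probe <- function(n_trials, N, T = 150, go_step = 50, sd = 1,
                       offset = 0, offset_steps = NULL, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    y <- matrix(stats::rnorm(N * T, sd = sd), N, T)
    if (!is.null(offset_steps)) y[, offset_steps] <- y[, offset_steps] + offset
    fake_result(y = y, go_step = go_step)
  })
}

# dual-rate generator: closed loop with unit perturbation, driven noise
gen_dual_rate <- function(Af, As, Bf, Bs, n, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  xf <- xs <- 0
  x_obs <- e_obs <- numeric(n)
  for (i in seq_len(n)) {
    x <- xf + xs
    e <- 1 - x + stats::rnorm(1, 0, noise_sd)
    x_obs[i] <- x + stats::rnorm(1, 0, noise_sd)
    e_obs[i] <- e
    xf <- Af * xf + Bf * e
    xs <- As * xs + Bs * e
  }
  list(x_obs = x_obs, e = e_obs)
}

gen_single_rate <- function(A, B, n, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  x <- 0
  x_obs <- e_obs <- numeric(n)
  for (i in seq_len(n)) {
    e <- 1 - x + stats::rnorm(1, 0, noise_sd)
    x_obs[i] <- x + stats::rnorm(1, 0, noise_sd)
    e_obs[i] <- e
    x <- A * x + B * e
  }
  list(x_obs = x_obs, e = e_obs)
}
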