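test_that("take-off angles wrap correctly and flag absent movement", {
  expect_equal(takeoff_angle(fake_reach(0)), 0, tolerance = 1e-9)
  expect_equal(takeoff_error(fake_reach(0)), 0, tolerance = 1e-9)
  # target at 170, reach at -170: error is 20, not 340
  tr170 <- fake_reach(-170, p_end = 5 * c(cos(170 * pi / 180),
                                          sin(170 * pi / 180)))
  expect_equal(takeoff_error(tr170), 20, tolerance = 1e-9)
  still <- fake_result(p = matrix(0, 2, 300))
  expect_error(takeoff_angle(still), "undefined")
})

test_that("Gaussian trial smoothing preserves constants and mass", {
  expect_equal(smooth_error_curve(rep(3.5, 120)), rep(3.5, 120),
               tolerance = 1e-12)
  imp <- c(rep(0, 100), 1, rep(0, 100))
  sm <- smooth_error_curve(imp, sd_trials = 10)
  expect_equal(which.max(sm), 101)
  expect_equal(sm[101], dnorm(0, sd = 10) / sum(dnorm(-40:40, sd = 10)),
               tolerance = 1e-9)
  expect_equal(sum(sm), 1, tolerance = 1e-9)  # reflection conserves mass
})

test_that("error-size vs next-trial learning correlation behaves at the extremes", {
  # perfectly proportional learning: e(n+1) = (1 - k) e(n)
  e <- 30 * 0.97^(0:299)
  expect_equal(learning_vs_error_correlation(e)$r, 1, tolerance = 1e-9)
  # independent errors: the shared-term (regression-to-the-mean) artifact
  # fixes the correlation at 1/sqrt(2) for i.i.d. sequences
  set.seed(3)
  shuf <- learning_vs_error_correlation(rnorm(4000, 0, 5))
  expect_equal(shuf$r, 1 / sqrt(2), tolerance = 0.06)
})

test_that("activity-change traces are exact averages with planted peaks recovered", {
  pa <- fake_probe(6, N = 20, seed = 1)
  expect_true(all(activity_change(pa, pa)$trace == 0))
  # doubling one unit's activity in one probe raises the trace by its share
  pb <- lapply(pa, function(r) { r$y[3, ] <- 2 * r$y[3, ]; r })
  tr <- activity_change(pa, pb)
  expect_equal(tr$trace,
               colMeans(do.call(rbind, lapply(seq_along(pa), function(i)
                 abs(pa[[i]]$y[3, ]) / 20))), tolerance = 1e-12)
  # planted gaussian bumps at known latencies are recovered exactly
  go <- 50; T <- 150
  bump <- function(center_step, amp) {
    y <- matrix(0, 4, T)
    y[, ] <- rep(amp * dnorm(seq_len(T), mean = center_step, sd = 5),
                 each = 4)
    list(fake_result(y = matrix(0, 4, T), go_step = go),
         fake_result(y = y, go_step = go))
  }
  b1 <- bump(go + 50, 1)   # 0.5 s after go
  b2 <- bump(go + 80, 1)   # 0.8 s after go
  pk <- find_peak_times(activity_change(list(b1[[1]]), list(b1[[2]])),
                        activity_change(list(b2[[1]]), list(b2[[2]])))
  expect_equal(pk$ff_time, 0.5)
  expect_equal(pk$fb_time, 0.8)
})

test_that("null-calibrated unit classification has ~5% false positives per type", {
  N <- 400
  A  <- fake_probe(60, N, seed = 10)
  A2 <- fake_probe(60, N, seed = 11)
  B  <- fake_probe(60, N, seed = 12)   # same distribution: everything null
  C  <- fake_probe(60, N, seed = 13)
  cl <- classify_units(A, B, C, A2, n_boot = 300, seed = 5)
  expect_lt(abs(cl$fractions$feedback / 100 - 0.05),
            3 * sqrt(0.05 * 0.95 / N) + 0.025)
  expect_lt(abs(cl$fractions$learning / 100 - 0.05),
            3 * sqrt(0.05 * 0.95 / N) + 0.025)
  # an injected late-window change is classified feedback-only
  Bp <- fake_probe(60, N, seed = 12)
  go <- Bp[[1]]$go_step
  late <- go + 70:90
  Bp <- lapply(Bp, function(r) { r$y[1, late] <- r$y[1, late] + 5; r })
  cl2 <- classify_units(A, Bp, C, A2, n_boot = 300, seed = 5)
  expect_equal(unname(cl2$units$class[1]), "feedback")
})

test_that("dual-rate parameters are recovered and the F-test selects the true model", {
  truth <- c(Af = 0.92, As = 0.996, Bf = 0.03, Bs = 0.004)
  d <- gen_dual_rate(truth[1], truth[2], truth[3], truth[4], n = 600,
                     noise_sd = 0.01, seed = 2)
  fs <- fit_single_rate(d$x_obs, d$e)
  fd <- fit_dual_rate(d$x_obs, d$e)
  expect_lte(fd$rss, fs$rss + 1e-9)           # nesting
  est <- c(fd$A_f, fd$A_s, fd$B_f, fd$B_s)
  expect_true(all(abs(est - truth) / truth < 0.10))
  expect_lt(fd$A_f, fd$A_s)
  expect_gt(fd$B_f, fd$B_s)
  cmp <- compare_models(fs, fd)
  expect_equal(cmp$preferred_model, "dual")
  # single-rate ground truth: the F-test keeps the single model in the
  # clear majority of replicates (it is a 5%-level test, so occasional
  # dual preferences are expected)
  picks <- vapply(1:5, function(k) {
    s <- gen_single_rate(0.98, 0.02, n = 600, noise_sd = 0.01, seed = 2 + k)
    compare_models(fit_single_rate(s$x_obs, s$e),
                   fit_dual_rate(s$x_obs, s$e))$preferred_model
  }, character(1))
  expect_gte(sum(picks == "single"), 4)
})

test_that("the velocity decoder is near-perfect on linear data and dies on shuffles", {
  # synthetic linear map v = A y + noise
  set.seed(4)
  A <- matrix(rnorm(2 * 30), 2, 30)
  mk <- function(n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      y <- matrix(rnorm(30 * 100), 30, 100)
      r <- fake_result(y = y, go_step = 30)
      r$v <- A %*% y + matrix(rnorm(200, 0, 0.01), 2, 100)
      r$dt <- 10
      r
    })
  }
  train <- mk(10, 1); test <- mk(10, 2)
  d <- fit_velocity_decoder(train, test, units = 1:30, lags = 0)
  expect_gt(d$accuracy$r2[1], 0.99)
  shuffled <- lapply(test, function(r) { r$v <- r$v[, sample(100)]; r })
  d2 <- fit_velocity_decoder(train, shuffled, units = 1:30, lags = 0)
  expect_lt(d2$accuracy$r2[1], 0.1)
})
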