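test_that("Euler step matches an independently hand-iterated recurrence", {
  # 3-unit network with hand-chosen weights, iterated in plain R arithmetic
  p <- network_params(N = 3, seed = 1)
  p$W <- matrix(c(0.3, -0.2, 0.1, 0.0, 0.4, -0.1, 0.2, 0.1, -0.3), 3, 3)
  p$W_in <- matrix(0.05, 3, 3)
  p$F <- matrix(c(0.1, -0.2, 0.3, 0.2, 0.0, -0.1), 3, 2)
  p$b <- c(0.01, -0.02, 0.03)
  s <- c(1, -2, 1); ed <- c(0.5, -0.3)
  lam <- 10 / 50
  x <- c(0.1, -0.1, 0.05)
  xr <- x
  for (t in 1:10) {
    y <- pmax(xr, 0)
    xr <- xr + lam * (-xr + c(p$W %*% y) + c(p$W_in %*% s) +
                        c(p$F %*% ed) + p$b)
  }
  st <- init_state(p, 0, c(0, 0))
  st$x <- x; st$y <- pmax(x, 0); st$r <- rep(0, 3)
  for (t in 1:10) st <- step_state(st, p, s, ed)
  expect_lt(max(abs(st$x - xr)) / max(abs(xr)), 1e-12)
})

test_that("leak-only dynamics decay geometrically with factor 1 - dt/tau", {
  p <- network_params(N = 4, seed = 2)
  p$W[] <- 0; p$W_in[] <- 0; p$F[] <- 0; p$b[] <- 0
  st <- init_state(p, 3, c(0, 0))
  x0 <- st$x
  for (i in 1:7) st <- step_state(st, p, c(0, 0, 0), c(0, 0))
  expect_equal(st$x, x0 * (1 - p$dt / p$tau)^7, tolerance = 1e-14)
})

test_that("initial state is uniform in (-0.2, 0.2) with the right moments", {
  p <- network_params(N = 1e4, seed = 4)
  st1 <- init_state(p, 0, c(0, 0))
  st2 <- init_state(p, 0, c(0, 0))
  expect_identical(st1$x, st2$x)
  expect_true(all(st1$x >= -0.2 & st1$x <= 0.2))
  v <- 0.4^2 / 12
  expect_lt(abs(mean(st1$x)), 3 * sqrt(v / 1e4))
  expect_lt(abs(var(st1$x) - v) / v, 0.1)
  expect_equal(st1$y, pmax(st1$x, 0))
  expect_true(all(st1$r == 0))
})

test_that("step rejects mismatched input dimensions", {
  p <- network_params(N = 3, seed = 1)
  st <- init_state(p, 0, c(0, 0))
  expect_error(step_state(st, p, c(1, 2), c(0, 0)), "dimension")
  expect_error(step_state(st, p, c(1, 2, 3), c(0, 0, 0)), "length 2")
})

test_that("readout is the affine map W_out y + b_out", {
  p <- network_params(N = 6, seed = 5)
  expect_equal(readout(rep(0, 6), p), p$b_out)
  p0 <- p; p0$W_out[] <- 0; p0$b_out <- c(1, -2)
  expect_equal(readout(runif(6), p0), c(1, -2))
  set.seed(1)
  y <- runif(6)
  manual <- c(sum(p$W_out[1, ] * y), sum(p$W_out[2, ] * y)) + p$b_out
  expect_equal(readout(y, p), manual)
})

test_that("position integration applies the visuomotor rotation", {
  expect_equal(integrate_position(c(0, 0), c(1, 0), 10), c(0.01, 0))
  d30 <- integrate_position(c(0, 0), c(1, 0), 10, rotation_deg = 30)
  expect_equal(atan2(d30[2], d30[1]) * 180 / pi, 30)
  # rotation composition: 90 degrees applied twice equals a single 180
  v <- c(1, 0)
  v90 <- integrate_position(c(0, 0), v, 1000, 90)       # dt of 1 s: p = R v
  v90_90 <- integrate_position(c(0, 0), v90, 1000, 90)
  v180 <- integrate_position(c(0, 0), v, 1000, 180)
  expect_equal(v90_90, v180, tolerance = 1e-12)
})

test_that("trial execution is deterministic and keeps exact error bookkeeping", {
  p <- network_params(N = 12, seed = 9)
  tr <- make_centerout_trial(3, seed = 21)
  r1 <- run_trial(p, tr, seed = 77, record_full = TRUE)
  r2 <- run_trial(p, tr, seed = 77, record_full = TRUE)
  expect_identical(r1$y, r2$y)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$takeoff_error, r2$takeoff_error)
  # epsilon(t) = p*(t) - p(t) exactly, y >= 0, r non-decreasing
  expect_identical(r1$epsilon, r1$p_star - r1$p)
  expect_true(all(r1$y >= 0))
  expect_true(all(diff(t(r1$r)) >= 0))
  expect_equal(r1$r[, 25], rowSums(r1$y[, 1:25]))
  # duration must divide into whole steps
  bad <- tr; bad$duration <- 2.995
  expect_error(run_trial(p, bad, 1), "divisible")
})

test_that("perturbations cannot influence the network before the feedback delay", {
  p <- network_params(N = 10, seed = 3)
  tr <- make_centerout_trial(1, seed = 4, go_time = 1.3)
  bumped <- tr
  bumped$bump <- list(axis = "x", amplitude = 10, onset = 0.8, duration = 0.1)
  r0 <- run_trial(p, tr, seed = 6, record_full = TRUE)
  r1 <- run_trial(p, bumped, seed = 6, record_full = TRUE)
  t0 <- which(colSums(abs(r1$epsilon - r0$epsilon)) > 0)[1]
  expect_equal(t0, 81)                       # bump onset at 0.8 s, step 81
  ds <- p$delta_steps
  pre <- seq_len(t0 + ds - 1)
  expect_identical(r1$x[, pre], r0$x[, pre])
  expect_identical(r1$y[, pre], r0$y[, pre])
  expect_identical(r1$v[, pre], r0$v[, pre])
  expect_false(isTRUE(all.equal(r1$x[, t0 + ds], r0$x[, t0 + ds])))
})
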