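test_that("desired trajectory holds, passes the midpoint, and has a bell-shaped speed", {
  tr <- trial_spec(c(-2, 1), c(4, -3), go_time = 1.0)
  ps <- desired_trajectory(tr, 10)
  tt <- (seq_len(ncol(ps)) - 1) * 0.01
  # constant at the start point before go
  expect_true(all(ps[, tt < 1.0] == c(-2, 1)))
  # midpoint of the reach half a second after go (sigmoid midpoint f(0) = 0.5)
  mid_idx <- which(tt == 1.5)
  expect_equal(ps[, mid_idx], (c(-2, 1) + c(4, -3)) / 2, tolerance = 1e-9)
  # within ~0.7% of the end point at trial end (unnormalised logistic)
  expect_lt(sqrt(sum((ps[, ncol(ps)] - c(4, -3))^2)) /
              sqrt(sum((c(4, -3) - c(-2, 1))^2)), 0.007)
  # bell-shaped speed: single maximum at go + 0.5 s, monotone on both sides
  sp <- sqrt(rowSums(diff(t(ps))^2))
  tsp <- tt[-1]
  move <- tsp > 1.02                 # skip the small onset step of the raw sigmoid
  expect_equal(tsp[move][which.max(sp[move])], 1.5, tolerance = 0.011)
  rise <- sp[tsp > 1.05 & tsp < 1.49]
  fall <- sp[tsp > 1.51 & tsp < 2.2]
  expect_true(all(diff(rise) > 0))
  expect_true(all(diff(fall) < 0))
  # movement truncated by the trial end raises a warning
  late <- trial_spec(c(0, 0), c(5, 0), go_time = 2.5)
  expect_warning(desired_trajectory(late, 10), "truncated")
})

test_that("random reach generator respects the workspace and delay ranges", {
  gos <- numeric(2000); lens <- numeric(2000)
  for (i in 1:2000) {
    tr <- make_random_reach_trial(i)
    gos[i] <- tr$go_time
    lens[i] <- sqrt(sum((tr$p_end - tr$p_start)^2))
    if (i <= 50) expect_true(all(abs(c(tr$p_start, tr$p_end)) <= 6))
  }
  expect_true(all(gos >= 0.2 & gos <= 1.7))
  expect_true(all(lens <= 12 * sqrt(2)))
  expect_gt(max(lens), 8.5)     # workspace supports reaches beyond 8.5 cm
  expect_identical(make_random_reach_trial(7), make_random_reach_trial(7))
})

test_that("centre-out targets sit on the 5-cm circle with 45-degree spacing", {
  ends <- sapply(0:7, function(k) make_centerout_trial(k, seed = 1)$p_end)
  expect_equal(sqrt(colSums(ends^2)), rep(5, 8))
  angs <- atan2(ends[2, ], ends[1, ]) * 180 / pi
  expect_equal(sort(((diff(c(angs, angs[1] + 360)) + 360) %% 360)), rep(45, 8))
  expect_equal(make_centerout_trial(0, seed = 1)$p_end, c(5, 0))
  gos <- sapply(1:200, function(s) make_centerout_trial(0, seed = s)$go_time)
  expect_true(all(gos >= 1.2 & gos <= 1.7))
  expect_error(make_centerout_trial(8, seed = 1), "0..7")
})

test_that("stimulus schedule switches target and hold channels at the right steps", {
  tr <- trial_spec(c(1, 2), c(4, 6), go_time = 1.7)
  S <- stimulus_schedule(tr, 10)
  tt <- (seq_len(ncol(S)) - 1) * 0.01
  expect_true(all(S[, tt < 0.2] == c(0, 0, 1)))
  expect_true(all(S[1:2, tt >= 0.2] == c(3, 4)))
  expect_true(all(S[3, tt >= 1.7] == 0))
  expect_equal(sum(S[3, ] == 1), 170)
  # piecewise constant with at most 2 change-points per channel
  for (ch in 1:3) expect_lte(sum(diff(S[ch, ]) != 0), 2)
})

test_that("velocity bumps occur at the stated rate, duration, and open-loop size", {
  hits <- 0
  for (i in 1:1000) {
    tr <- apply_bump(make_centerout_trial(i %% 8, seed = i), seed = 5000 + i)
    if (!is.null(tr$bump)) {
      hits <- hits + 1
      expect_true(tr$bump$onset >= 0.2 && tr$bump$onset <= 1.9)
      expect_equal(abs(tr$bump$amplitude), 10)
    }
  }
  expect_lt(abs(hits / 1000 - 0.75), 3 * sqrt(0.75 * 0.25 / 1000))

  # bump occupies exactly 10 steps and shifts the effective velocity by
  # exactly its amplitude until the loop can react (the first delay window)
  p <- network_params(N = 8, seed = 2)
  tr <- make_centerout_trial(0, seed = 3, go_time = 1.4)
  bumped <- tr
  bumped$bump <- list(axis = "y", amplitude = 10, onset = 1.0, duration = 0.1)
  r0 <- run_trial(p, tr, seed = 4)
  r1 <- run_trial(p, bumped, seed = 4)
  dv <- r1$v_eff - r0$v_eff
  on <- which(colSums(abs(dv)) > 0)
  expect_equal(length(intersect(on, 101:110)), 10)
  expect_equal(dv[2, 101:110], rep(10, 10), tolerance = 1e-12)
  expect_equal(dv[1, 101:110], rep(0, 10), tolerance = 1e-12)
})
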