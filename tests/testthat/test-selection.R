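test_that("perfect geometric odds recover omega exactly", {
  # p/q ratios 1, 3, 9, 27 at t = 0..3
  ratios <- c(1, 3, 9, 27)
  series <- data.frame(week = 0:3, p = ratios / (1 + ratios))
  fit <- estimate_selection(series)
  expect_equal(fit$slope, log(3), tolerance = 1e-12)
  expect_equal(fit$omega, 3, tolerance = 1e-12)

  flat <- data.frame(week = 0:4, p = rep(0.5, 5))
  expect_equal(estimate_selection(flat)$omega, 1, tolerance = 1e-12)
})

test_that("noise-free simulated trajectories recover omega to 1e-9 relative", {
  # the full range of reported strengths, plus weak and strong extremes
  for (omega in c(0.1, 1.80, 2.31, 2.62, 2.81, 2.87, 3.36, 3.63, 10)) {
    for (p0 in c(0.01, 0.5, 0.9)) {
      traj <- simulate_trajectory(omega = omega, p0 = p0, weeks = 6)
      fit <- estimate_selection(traj)
      expect_lt(abs(fit$omega - omega) / omega, 1e-9)
    }
  }
})

test_that("points at p = 0 or 1 are excluded, not log-transformed", {
  traj <- simulate_trajectory(omega = 3, p0 = 0.5, weeks = 4)
  traj$p[1] <- 0
  traj$q <- 1 - traj$p
  fit <- estimate_selection(traj)
  expect_equal(fit$n, 4L)
  expect_equal(fit$t_start, 1)
  expect_equal(fit$omega, 3, tolerance = 1e-9)

  # fewer than two usable points is an error
  degen <- data.frame(week = 0:2, p = c(0, 1, 0.5))
  expect_error(estimate_selection(degen), ">= 2")
})

test_that("window selection restricts the fitted time range", {
  traj <- simulate_trajectory(omega = 2, p0 = 0.5, weeks = 10)
  fit <- estimate_selection(traj, window = c(2, 6))
  expect_equal(fit$t_start, 2)
  expect_equal(fit$t_end, 6)
  expect_equal(fit$omega, 2, tolerance = 1e-9)
})

test_that("A-vs-B and B-vs-A omegas are reciprocal", {
  for (seed in 1:5) {
    traj <- simulate_trajectory(omega = 2.5, p0 = 0.3, weeks = 6,
                                sampling_depth = 500, seed = seed)
    swapped <- traj
    swapped$p <- traj$q
    swapped$q <- traj$p
    usable <- traj$p > 0 & traj$p < 1
    if (sum(usable) < 2) next
    o1 <- estimate_selection(traj)$omega
    o2 <- estimate_selection(swapped)$omega
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
  }
})

test_that("time-shift changes the intercept, never slope or omega", {
  traj <- simulate_trajectory(omega = 3.2, p0 = 0.4, weeks = 5)
  shifted <- traj
  shifted$week <- traj$week + 7
  f1 <- estimate_selection(traj)
  f2 <- estimate_selection(shifted)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$omega, f2$omega, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))
})

test_that("frequencies_from_depths forms symbiont-only shares", {
  tab <- data.frame(week = 0:2, depth_A = c(9, 5, 0), depth_B = c(1, 5, 3))
  fs <- frequencies_from_depths(tab)
  expect_equal(fs$p, c(0.9, 0.5, 0))
  # p = 0 rows are retained in the series but excluded from any fit window
  expect_equal(nrow(fs), 3L)

  expect_warning(
    frequencies_from_depths(
      data.frame(week = 0:1, depth_A = c(1, 0), depth_B = c(1, 0))
    ),
    "zero depth on both strains"
  )

  # optional genome-length normalisation
  fs2 <- frequencies_from_depths(
    data.frame(week = 0, depth_A = 10, depth_B = 10),
    lengths = c(1000, 2000)
  )
  expect_equal(fs2$p, 10 / 1000 / (10 / 1000 + 10 / 2000))
})

test_that("fold change regression returns printed-style weekly percentages", {
  s_up <- data.frame(week = 0:2, titer = c(1, 1.17, 1.3689))
  expect_equal(weekly_fold_change(s_up)$percent, 17, tolerance = 1e-9)

  s_down <- data.frame(week = 0:2, titer = c(1, 0.86, 0.7396))
  expect_equal(weekly_fold_change(s_down)$percent, -14, tolerance = 1e-9)

  s_flat <- data.frame(week = 0:3, titer = rep(2.5, 4))
  expect_equal(weekly_fold_change(s_flat)$percent, 0, tolerance = 1e-12)

  expect_warning(
    fit <- weekly_fold_change(data.frame(week = 0:2, titer = c(0, 1, 1.17))),
    "nonpositive"
  )
  expect_equal(fit$n, 2L)
  expect_error(
    suppressWarnings(
      weekly_fold_change(data.frame(week = 0:1, titer = c(0, 1)))
    ),
    ">= 2"
  )
})

test_that("selection and fold-change share the exp(slope) transformation", {
  # the same geometric series fed to both fits gives the same exp(slope)
  omega <- 1.7
  odds <- omega^(0:5)
  p <- odds / (1 + odds)
  sel <- estimate_selection(data.frame(week = 0:5, p = p))
  fold <- weekly_fold_change(data.frame(week = 0:5, titer = odds))
  expect_equal(sel$omega, fold$fold, tolerance = 1e-12)
})
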