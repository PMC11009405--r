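# Kinematics: position filtering, velocity, radius-angle transform,
# spiral fit, self-intersection.

test_that("position low-pass passes DC and 1 Hz, rejects 20 Hz", {
  tr_dc <- make_trial(function(t) rep(3, length(t)),
                      function(t) rep(-2, length(t)))
  out <- preprocess_position(tr_dc)
  expect_equal(out$x, tr_dc$x, tolerance = 1e-8)
  expect_equal(out$y, tr_dc$y, tolerance = 1e-8)

  tr20 <- make_trial(function(t) sin(2 * pi * 20 * t), function(t) 0 * t)
  out20 <- preprocess_position(tr20)
  expect_lt(rms(out20$x), 0.05 * rms(tr20$x))

  tr1 <- make_trial(function(t) sin(2 * pi * 1 * t), function(t) 0 * t)
  out1 <- preprocess_position(tr1)
  expect_equal(rms(out1$x), rms(tr1$x), tolerance = 0.02)
})

test_that("jittery timestamps are resampled to a uniform grid", {
  set.seed(1)
  t <- cumsum(runif(500, 0.005, 0.015))
  tr <- kinematic_trial(t, sin(t), cos(t))
  out <- preprocess_position(tr)
  expect_lt(max(abs(diff(out$t) - median(diff(out$t)))), 1e-9)
})

test_that("preprocess_position refuses too-short trials", {
  tr <- make_trial(function(t) t, function(t) t, duration = 0.2)
  expect_error(preprocess_position(tr), "too short")
})

test_that("tangential velocity: circle, stationary pen, straight line", {
  R <- 3; omega <- 2
  tr <- make_trial(function(t) R * cos(omega * t),
                   function(t) R * sin(omega * t))
  prof <- tangential_velocity(tr, smooth_sigma = 0)
  core <- seq(10, length(prof$v) - 10)
  expect_equal(prof$v[core], rep(R * omega, length(core)), tolerance = 0.01)

  still <- make_trial(function(t) rep(1, length(t)),
                      function(t) rep(1, length(t)))
  p0 <- tangential_velocity(still)
  expect_true(all(p0$v == 0))
  expect_true(all(p0$a == 0))

  line <- make_trial(function(t) 2 * t, function(t) 0 * t)
  pl <- tangential_velocity(line)
  expect_equal(pl$v[core], rep(2, length(core)), tolerance = 1e-6)
  expect_equal(max(abs(pl$a[core])), 0, tolerance = 1e-6)
})

test_that("trial_summary means and scaling property", {
  prof <- structure(list(t = 1:3, v = c(3, 3, 3), a = rep(0, 3),
                         draw_span = c(1, 3)), class = "velocity_profile")
  s <- trial_summary(prof)
  expect_equal(s$mean_velocity, 3)
  expect_equal(s$log_velocity, log10(3))
  prof$v <- c(1, 2, 3)
  expect_equal(trial_summary(prof)$mean_velocity, 2)

  # v scales linearly with the trace (property over random trials)
  set.seed(2)
  for (k in c(0.5, 2, 7)) {
    tr <- make_spiral_trial(noise_sd = 0.003)
    tr2 <- tr; tr2$x <- k * tr$x; tr2$y <- k * tr$y
    v1 <- trial_summary(tangential_velocity(tr))$mean_velocity
    v2 <- trial_summary(tangential_velocity(tr2))$mean_velocity
    expect_equal(v2, k * v1, tolerance = 1e-9)
  }
})

test_that("radius-angle transform inverts the spiral construction", {
  b <- 1.5 / (2 * pi)
  tr <- make_spiral_trial(b = b)
  ra <- radius_angle_transform(tr, center = c(0, 0))
  # theta starts at -pi/2 by convention; radius = b * (theta - theta0)
  expect_equal(ra$radius, b * (ra$theta + pi / 2), tolerance = 1e-6)

  # circle: constant radius, 2*pi per revolution
  circ <- make_trial(function(t) 2 * cos(t), function(t) 2 * sin(t),
                     duration = 4 * pi, fs = 50)
  rc <- radius_angle_transform(circ, center = c(0, 0))
  expect_equal(rc$radius, rep(2, length(rc$radius)), tolerance = 1e-9)
  expect_equal(max(rc$theta) - min(rc$theta), 4 * pi, tolerance = 1e-3)
})

test_that("cw and mirrored ccw spirals give identical (theta, radius)", {
  tr_cw <- make_spiral_trial(cw = TRUE)
  tr_ccw <- make_spiral_trial(cw = FALSE) # mirror image
  ra1 <- radius_angle_transform(tr_cw, center = c(0, 0))
  ra2 <- radius_angle_transform(tr_ccw, center = c(0, 0))
  expect_equal(ra1$theta, ra2$theta, tolerance = 1e-9)
  expect_equal(ra1$radius, ra2$radius, tolerance = 1e-9)
})

test_that("fit_spiral: exact line, noisy rmse, exclusion and errors", {
  theta <- seq(-pi / 2, 9 * pi, length.out = 2000)
  fit <- fit_spiral(list(theta = theta, radius = 0.2387 * theta,
                         t = seq_along(theta)))
  expect_equal(fit$slope, 0.2387, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  expect_true(all(fit$excluded_mask == (theta <= 1.5 * pi)))
  expect_equal(mean(fit$residuals[!fit$excluded_mask]), 0, tolerance = 1e-9)

  set.seed(3)
  r <- 0.2387 * theta + rnorm(2000, 0, 0.1)
  fitn <- fit_spiral(list(theta = theta, radius = r, t = seq_along(theta)))
  expect_equal(fitn$rmse, 0.1, tolerance = 0.01)

  short <- seq(-pi / 2, 2 * pi, length.out = 100)
  expect_error(fit_spiral(list(theta = short, radius = 0.2 * short,
                               t = seq_along(short))), "1.5 revolutions")
})

test_that("spiral slope is invariant to uniform time-resampling", {
  tr <- make_spiral_trial(noise_sd = 0.002)
  fit1 <- fit_spiral(radius_angle_transform(tr, center = c(0, 0)))
  t2 <- seq(tr$t[1], tr$t[length(tr$t)], length.out = 431)
  tr2 <- kinematic_trial(t2, approx(tr$t, tr$x, t2)$y,
                         approx(tr$t, tr$y, t2)$y)
  fit2 <- fit_spiral(radius_angle_transform(tr2, center = c(0, 0)))
  expect_equal(fit2$slope, fit1$slope, tolerance = 1e-3)
})

test_that("self-intersection: spiral false, figure-eight true, threshold case", {
  expect_false(detect_self_intersection(make_spiral_trial()))

  t <- seq(0, 2 * pi, length.out = 200)
  fig8 <- kinematic_trial(t, sin(t), sin(2 * t))
  expect_true(detect_self_intersection(fig8))

  # one loop perturbed inward: crossing iff the bump exceeds the spacing
  mk <- function(depth) {
    b <- 1.5 / (2 * pi)
    tt <- seq(0, 15, by = 0.01)
    theta <- 2 * pi * 5 * tt / 15
    r <- b * theta - depth * exp(-(theta - 7 * pi)^2 / (2 * 0.3^2))
    kinematic_trial(tt, r * cos(theta), r * sin(theta))
  }
  expect_true(detect_self_intersection(mk(1.8)))
  expect_false(detect_self_intersection(mk(0.7)))
})

test_that("segment test agrees with a brute-force R oracle", {
  seg_int <- function(p1, p2, q1, q2) {
    o <- function(a, b, c)
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2)
    d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  brute <- function(x, y) {
    n <- length(x) - 1
    for (i in 1:(n - 2)) for (j in (i + 2):n)
      if (seg_int(c(x[i], y[i]), c(x[i + 1], y[i + 1]),
                  c(x[j], y[j]), c(x[j + 1], y[j + 1]))) return(TRUE)
    FALSE
  }
  set.seed(4)
  for (i in 1:25) {
    x <- cumsum(rnorm(20)); y <- cumsum(rnorm(20))
    tr <- kinematic_trial(seq_along(x), x, y)
    expect_identical(detect_self_intersection(tr), brute(x, y))
  }
})
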