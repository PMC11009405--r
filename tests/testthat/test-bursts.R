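# Burst layer: beta-peak selection, envelope, thresholds, detection,
# metrics.

make_warped_map <- function(freqs = 13:30, rest_level = 1,
                            draw_level = rep(1, length(freqs))) {
  power <- cbind(matrix(rest_level, length(freqs), 50),
                 matrix(rep(draw_level, 100), length(freqs), 100))
  structure(list(freqs = freqs, times = 1:150, power = power,
                 segments = c(rep("rest", 50), rep("draw_early", 50),
                              rep("draw_late", 50)),
                 warped = TRUE), class = "tfr_map")
}

test_that("find_beta_peak picks the deepest desynchronization", {
  draw <- rep(1, 18); draw[13:30 == 18] <- 0.6; draw[13:30 == 25] <- 0.8
  m <- make_warped_map(draw_level = draw)
  expect_equal(find_beta_peak(m), 18)
})

test_that("find_beta_peak tie and no-desync rules fall back to rest peak", {
  # two nearly equal desynchronization depths -> rest peak (22 Hz)
  draw <- rep(1, 18); draw[13:30 == 18] <- 0.6; draw[13:30 == 25] <- 0.61
  rest <- rep(1, 18); rest[13:30 == 22] <- 2
  m <- make_warped_map(rest_level = rest, draw_level = draw * rest)
  expect_equal(find_beta_peak(m), 22)
  # no desynchronization anywhere -> rest peak with warning
  m2 <- make_warped_map(rest_level = rest, draw_level = 1.2 * rest)
  expect_warning(f <- find_beta_peak(m2), "rest peak")
  expect_equal(f, 22)
})

test_that("per-subject beta peaks are recovered from generated LFP", {
  cfg <- simulation_config(burst_rate_draw = 0.3)
  for (fb in c(16, 24)) {
    maps <- lapply(1:4, function(i) {
      s <- simulate_lfp_epoch(cfg, "free", "off", f_beta = fb,
                              duration = 12, seed = fb * 100 + i)
      timewarp_tfr(morlet_tfr(preprocess_lfp(s$epoch)))
    })
    avg <- maps[[1]]
    avg$power <- Reduce(`+`, lapply(maps, `[[`, "power")) / length(maps)
    expect_lte(abs(find_beta_peak(avg) - fb), 1)
  }
})

test_that("beta envelope: rectified-sine level, stopband, zero signal", {
  A <- 2
  # frequency incommensurate with fs so sampling covers all phases
  ep <- make_epoch(function(t) A * sin(2 * pi * 19.7 * t))
  env <- beta_envelope(ep, 19.7)
  core <- in_interval(env$t, c(-4, 9))
  expect_equal(mean(env$env[core]), 2 * A / pi, tolerance = 0.02)

  off <- beta_envelope(make_epoch(function(t) A * sin(2 * pi * 29.7 * t)),
                       19.7)
  expect_lt(mean(off$env[core]), 0.1 * mean(env$env[core]))

  z <- beta_envelope(make_epoch(function(t) numeric(length(t))), 20)
  expect_equal(max(z$env), 0)
  expect_error(beta_envelope(ep, 5), "outside")
})

test_that("rest threshold: percentile definition and homogeneity", {
  env <- make_env(c(1, 2, 3, 4), fs = 200, t0 = -5,
                  intervals = list(rest = c(-5, -4.98), draw = c(0, 1)))
  expect_equal(rest_threshold(list(env)), 3.25)
  const <- make_env(rep(2.5, 1000))
  expect_equal(rest_threshold(const), 2.5)
  set.seed(9)
  e1 <- make_env(abs(rnorm(2000)))
  e2 <- e1; e2$env <- 3 * e1$env
  expect_equal(rest_threshold(e2), 3 * rest_threshold(e1))
})

test_that("detect_bursts: run-length definitions and 100 ms rule", {
  base <- rep(0.1, 2000)
  expect_identical(nrow(detect_bursts(make_env(base), 0.5)), 0L)
  # 25 suprathreshold samples at 200 Hz = 125 ms
  e <- base; e[300:324] <- 1
  b <- detect_bursts(make_env(e), 0.5)
  expect_identical(nrow(b), 1L)
  expect_equal(b$duration, 0.125)
  expect_equal(b$peak_amplitude, 1)
  # 15 samples = 75 ms < 100 ms -> dropped
  e2 <- base; e2[300:314] <- 1
  expect_identical(nrow(detect_bursts(make_env(e2), 0.5)), 0L)
  # threshold ties count as subthreshold (strict >)
  e3 <- base; e3[300:340] <- 0.5
  expect_identical(nrow(detect_bursts(make_env(e3), 0.5)), 0L)
})

test_that("detect_bursts equals the brute-force oracle on random envelopes", {
  set.seed(10)
  for (i in 1:60) {
    env <- abs(spiralburst:::gaussian_smooth(rnorm(1500), 8))
    tr <- make_env(env)
    thr <- quantile(env, runif(1, 0.5, 0.9), type = 7)
    got <- detect_bursts(tr, thr, truncate = FALSE)
    want <- oracle_bursts(env, tr$t, tr$fs, thr)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$onset, want$onset)
      expect_equal(got$offset, want$offset)
    }
  }
})

test_that("amplitude equivariance and percentile monotonicity", {
  set.seed(11)
  env <- abs(spiralburst:::gaussian_smooth(rnorm(3000), 10))
  tr <- make_env(env)
  thr <- rest_threshold(tr)
  b1 <- detect_bursts(tr, thr)
  tr2 <- tr; tr2$env <- 4 * env
  b2 <- detect_bursts(tr2, 4 * thr)
  expect_identical(nrow(b1), nrow(b2))
  expect_equal(b2$duration, b1$duration)
  expect_equal(b2$peak_amplitude, 4 * b1$peak_amplitude)
  counts <- sapply(c(50, 75, 90), function(p)
    nrow(detect_bursts(tr, rest_threshold(tr, p))))
  expect_true(all(diff(counts) <= 0))
})

test_that("suprathreshold rest time is 25% on the defining pool", {
  set.seed(12)
  env <- abs(spiralburst:::gaussian_smooth(rnorm(20000), 10))
  tr <- make_env(env, intervals = list(rest = c(-5, 95), draw = c(95, 100)))
  thr <- rest_threshold(tr)
  expect_equal(mean(env > thr), 0.25, tolerance = 0.01)
})

test_that("burst metrics: rate, means, zero-burst flag", {
  b <- data.frame(onset = c(1, 3), offset = c(1.1, 3.3),
                  duration = c(0.1, 0.3), peak_amplitude = c(2, 4),
                  interval = "draw")
  m <- burst_metrics(b, "draw", 10)
  expect_equal(m$n_bursts, 2)
  expect_equal(m$rate, 0.2)
  expect_equal(m$mean_duration, 0.2)
  expect_equal(m$mean_amplitude, 3)
  m5 <- burst_metrics(b[rep(1, 5), ], "draw", 10)
  expect_equal(m5$rate, 0.5)
  m0 <- burst_metrics(b[0, ], "rest", 5)
  expect_true(m0$flagged)
  expect_true(is.na(m0$mean_duration))
})

test_that("draw-phase duration reduction is recovered across trials", {
  # low rates so ground-truth merging of overlaps stays rare
  cfg <- simulation_config(burst_duration_factor_draw = 0.7,
                           burst_duration_sdlog = 0.3,
                           burst_rate_rest = 0.4, burst_rate_draw = 0.4)
  rd <- c(); rr <- c()
  for (i in 1:15) {
    sim <- simulate_lfp_epoch(cfg, "free", "off", f_beta = 20,
                              duration = 20, seed = 600 + i)
    g <- sim$bursts
    rd <- c(rd, g$duration[g$interval == "draw"])
    rr <- c(rr, g$duration[g$interval == "rest"])
  }
  expect_lt(abs(mean(rd) / mean(rr) - 0.7), 0.1)
})
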