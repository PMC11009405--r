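# Time-frequency layer: Morlet maps, time-warping, baseline
# normalization, multitaper band power, cluster permutation test.

test_that("Morlet TFR localizes frequency and scales as squared amplitude", {
  ep <- make_epoch(function(t) sin(2 * pi * 20 * t))
  tfr <- morlet_tfr(ep)
  avg <- rowMeans(tfr$power, na.rm = TRUE)
  expect_equal(tfr$freqs[which.max(avg)], 20)

  ep2 <- make_epoch(function(t) 2 * sin(2 * pi * 20 * t))
  tfr2 <- morlet_tfr(ep2)
  r <- rowMeans(tfr2$power, na.rm = TRUE)[tfr$freqs == 20] /
    avg[tfr$freqs == 20]
  expect_equal(r, 4, tolerance = 0.01)
})

test_that("Morlet TFR resolves two disjoint bursts in time", {
  f <- function(t) {
    out <- numeric(length(t))
    b1 <- t >= 2 & t < 3
    b2 <- t >= 6 & t < 7
    out[b1] <- sin(2 * pi * 15 * t[b1]) * sin(pi * (t[b1] - 2))^2
    out[b2] <- sin(2 * pi * 25 * t[b2]) * sin(pi * (t[b2] - 6))^2
    out
  }
  tfr <- morlet_tfr(make_epoch(f))
  t15 <- tfr$times[which.max(tfr$power[tfr$freqs == 15, ])]
  t25 <- tfr$times[which.max(tfr$power[tfr$freqs == 25, ])]
  expect_lt(abs(t15 - 2.5), 0.05)
  expect_lt(abs(t25 - 6.5), 0.05)
})

test_that("onset exclusion and short-epoch frequency dropping", {
  tfr <- morlet_tfr(make_epoch(function(t) sin(2 * pi * 20 * t)))
  expect_true(all(is.na(tfr$power[, abs(tfr$times) <= 0.1])))
  short <- lfp_epoch(seq(0, 1.2, by = 1 / 200), rnorm(241), 200,
                     intervals = list(rest = c(0, 0.5), draw = c(0.5, 1.2)))
  expect_warning(tfr2 <- morlet_tfr(short, onset_exclude = 0),
                 "low frequencies")
  expect_gt(min(tfr2$freqs), 4)
})

test_that("time-warping: fixed lengths, constants, ramps, invariance", {
  mk <- function(t_draw, f) {
    ep <- make_epoch(function(t) rnorm(length(t)), t_draw = t_draw)
    tfr <- morlet_tfr(ep)
    tfr$power <- outer(rep(1, length(tfr$freqs)), f(tfr$times))
    tfr
  }
  for (td in c(8, 12, 25, 40)) {
    w <- timewarp_tfr(mk(td, function(t) rep(3.3, length(t))))
    expect_identical(ncol(w$power), 150L)
    expect_identical(sum(w$segments == "rest"), 50L)
    expect_identical(sum(w$segments != "rest"), 100L)
    expect_equal(as.vector(w$power), rep(3.3, 150 * nrow(w$power)))
  }
  # linear ramp warps to a ramp with matching endpoints
  wr <- timewarp_tfr(mk(10, function(t) t))
  draw <- wr$power[1, wr$segments != "rest"]
  expect_equal(diff(range(diff(draw))), 0, tolerance = 1e-9)
  expect_equal(draw[1], 0.05, tolerance = 0.011) # midpoint of first bin
  # duration invariance of a shape defined in normalized time
  shape <- function(u) 1 + sin(2 * pi * u) + 0.5 * cos(4 * pi * u)
  w1 <- timewarp_tfr(mk(12, function(t) ifelse(t < 0, 1, shape(t / 12))))
  w2 <- timewarp_tfr(mk(30, function(t) ifelse(t < 0, 1, shape(t / 30))))
  d1 <- w1$power[1, w1$segments != "rest"]
  d2 <- w2$power[1, w2$segments != "rest"]
  expect_equal(d1, d2, tolerance = 0.01)
  # min/max preserved within interpolation error
  expect_lte(max(d1), max(shape(seq(0, 1, 0.001))) + 1e-6)
  expect_gte(min(d1), min(shape(seq(0, 1, 0.001))) - 1e-6)
})

test_that("timewarp rejects too-short draw intervals", {
  ep <- make_epoch(function(t) rnorm(length(t)), t_draw = 5)
  tfr <- morlet_tfr(ep)
  expect_error(timewarp_tfr(tfr, draw_span = c(0, 0.1)), "native TFR bins")
})

test_that("baseline relchange: zero map, doubling, zero-baseline flag", {
  ep <- make_epoch(function(t) rnorm(length(t)), t_draw = 10)
  w <- timewarp_tfr(morlet_tfr(ep))
  w$power[] <- 2
  w$power[, w$segments != "rest"] <- 4
  rel <- baseline_relchange(w)
  expect_equal(rel$power[, rel$segments == "rest"],
               matrix(0, nrow(rel$power), 50))
  expect_equal(rel$power[, rel$segments != "rest"],
               matrix(1, nrow(rel$power), 100))
  w$power[3, ] <- 0
  rel2 <- baseline_relchange(w)
  expect_true(all(is.na(rel2$power[3, ])))
  expect_identical(attr(rel2, "flagged_rows"), 3L)
})

test_that("band power: Parseval, sinusoid, silence, bad band", {
  set.seed(6)
  n <- 16000
  ep <- lfp_epoch(seq(0, by = 1 / 200, length.out = n), rnorm(n, 0, 1.5),
                  200, intervals = list(rest = c(0, 5), draw = c(5, 80)))
  total <- band_power(ep, c(0, 80), band = c(0, 99.99), aggregate = "sum")
  expect_equal(total, 1.5^2, tolerance = 0.05 * 1.5^2)

  eps <- make_epoch(function(t) 0.8 * sin(2 * pi * 20 * t))
  beta <- band_power(eps, "draw", band = c(13, 30), aggregate = "sum")
  gamma <- band_power(eps, "draw", band = c(30, 45), aggregate = "sum")
  expect_equal(beta, 0.8^2 / 2, tolerance = 0.01)
  expect_lt(gamma, 0.001 * beta)

  silent <- make_epoch(function(t) numeric(length(t)))
  expect_equal(band_power(silent, "draw"), 0)
  expect_error(band_power(eps, "draw", band = c(90, 150)), "fs/2")
})

test_that("cluster permutation test matches exact enumeration oracle at n = 6", {
  set.seed(7)
  n <- 6; nf <- 4; nt <- 6
  a <- array(rnorm(n * nf * nt, -0.5, 0.8), c(n, nf, nt))
  b <- array(rnorm(n * nf * nt), c(n, nf, nt))
  res <- cluster_permutation_test(a, b, exact = TRUE)
  expect_identical(res$n_perm, 64L)
  want <- cluster_oracle(a, b)
  expect_equal(sort(want$masses), sort(res$masses))
  expect_equal(sort(want$p), sort(res$p_values))
})

test_that("cluster p-values are invariant to common positive rescaling", {
  set.seed(8)
  a <- array(rnorm(8 * 5 * 10, -0.4, 1), c(8, 5, 10))
  b <- array(rnorm(8 * 5 * 10), c(8, 5, 10))
  r1 <- cluster_permutation_test(a, b, exact = TRUE)
  r2 <- cluster_permutation_test(a * 37.5, b * 37.5, exact = TRUE)
  expect_equal(r1$p_values, r2$p_values)
  expect_equal(r1$masses, r2$masses, tolerance = 1e-9)
})
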