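# Signal-processing primitives shared by the kinematics, LFP and spectral
# layers. No IIR filter-design package is available in the target library,
# so Butterworth design (bilinear transform) and zero-phase application are
# implemented here and exercised directly by the test suite.

#' Butterworth filter coefficients
#'
#' Digital Butterworth design via the bilinear transform with frequency
#' pre-warping, matching the conventional `butter()` of scipy/Octave.
#'
#' @param n filter order (for `"pass"`/`"stop"` the returned filter has
#'   order `2n`).
#' @param w cutoff as a fraction of the Nyquist frequency; scalar for
#'   `"low"`/`"high"`, length-2 `c(lo, hi)` for `"pass"`.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return list with numerator `b` and denominator `a` (with `a[1] = 1`).
#' @keywords internal
butter_design <- function(n, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot(n >= 1, all(w > 0), all(w < 1))
  # analog lowpass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  gain <- 1
  warp <- function(x) tan(pi * x / 2)
  if (type == "low") {
    W <- warp(w)
    p <- W * p
    gain <- W^n
  } else if (type == "high") {
    W <- warp(w)
    p <- W / p
    z <- rep(0 + 0i, n)
    gain <- 1
  } else {
    stopifnot(length(w) == 2, w[1] < w[2])
    W1 <- warp(w[1]); W2 <- warp(w[2])
    bw <- W2 - W1
    W0 <- sqrt(W1 * W2)
    ps <- p * bw / 2
    p <- c(ps + sqrt(ps^2 - W0^2), ps - sqrt(ps^2 - W0^2))
    z <- rep(0 + 0i, n)
    gain <- bw^n
  }
  # bilinear transform s -> (z-1)/(z+1) (unit "2/T", pre-warped above)
  deg <- length(p) - length(z)
  gain <- gain * Re(prod(1 - z) / prod(1 - p))
  zd <- (1 + z) / (1 - z)
  pd <- (1 + p) / (1 - p)
  zd <- c(zd, rep(-1 + 0i, deg))
  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a / a[1])
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Steady-state initial filter state for a unit step input
#'
#' The standard `lfilter_zi` construction: with state `zi * x[1]` the filter
#' starts in steady state, which suppresses edge transients even for poles
#' close to the unit circle (e.g. the 4 Hz high-pass at 2048 Hz).
#' @keywords internal
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2) comp[cbind(seq(2, n - 1), seq_len(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - b[1] * a[-1]
  solve(IminusA, B)
}

#' Zero-phase (forward-backward) filtering
#'
#' Odd-reflection edge padding plus steady-state initial conditions,
#' followed by a forward and a reverse pass, so the effective magnitude
#' response is |H|^2 and the phase is zero; burst onset timing is
#' therefore not shifted by filtering.
#'
#' @param x numeric signal.
#' @param b,a filter coefficients as from [butter_design()].
#' @keywords internal
filtfilt2 <- function(x, b, a) {
  n <- length(x)
  # pad long enough for edge transients to decay (slowest pole radius)
  rmax <- max(Mod(polyroot(rev(a))))
  pad <- 3L * max(length(a), length(b))
  if (rmax < 1)
    pad <- max(pad, min(n - 2L, ceiling(log(1e-6) / log(rmax))))
  if (n <= pad + 1)
    stop("signal too short for zero-phase filtering (need > ", pad + 1,
         " samples)")
  zi <- lfilter_zi(b, a)
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xx <- c(front, x, back)
  y <- c_lfilter(b, a, xx, zi * xx[1])
  y <- rev(y)
  y <- c_lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[seq(pad + 1, pad + n)]
}

#' Smooth with a Gaussian kernel (reflection-padded)
#' @param x signal; @param sigma kernel SD in samples.
#' @keywords internal
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_convolve(x, k)
}

#' Centred moving average (reflection-padded)
#' @keywords internal
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  pad_convolve(x, k)
}

pad_convolve <- function(x, k) {
  n <- length(x)
  hl <- (length(k) - 1) %/% 2
  hr <- length(k) - 1 - hl
  if (n <= max(hl, hr) + 1) stop("signal too short for kernel")
  xx <- c(x[seq(hl + 1, 2)], x, x[seq(n - 1, n - hr)])
  y <- stats::filter(xx, k, method = "convolution", sides = 2)
  as.numeric(y)[seq(hl + 1, hl + n)]
}

#' Discrete-Fourier-transform notch
#'
#' Per-epoch line-noise filter: the coherent sinusoid at each target
#' frequency is removed by least-squares fit-and-subtract (exact for a
#' stationary tone of any phase, immune to spectral leakage from
#' non-integer cycle counts), then any residual drifting component is
#' removed by zeroing the Fourier coefficients inside a `width`-Hz bin
#' centred on the target (bins k with |k*fs/n - f0| <= width/2).
#'
#' @param x signal; @param fs sampling rate (Hz);
#' @param freqs target frequencies (Hz); @param width bin width (Hz).
#' @keywords internal
dft_notch <- function(x, fs, freqs, width = 1) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / fs
  for (f0 in freqs) {
    # centred regressors so the fit-and-subtract leaves the mean untouched
    s <- sin(2 * pi * f0 * tt); s <- s - mean(s)
    co <- cos(2 * pi * f0 * tt); co <- co - mean(co)
    x <- x - sum(x * s) / sum(s * s) * s - sum(x * co) / sum(co * co) * co
  }
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # fold to [0, fs/2]
  kill <- rep(FALSE, n)
  for (f0 in freqs) kill <- kill | (abs(f - f0) <= width / 2)
  X[kill] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Fourier-domain resampling to a new length
#'
#' Spectrum truncation/zero-padding (the `scipy.signal.resample` scheme);
#' exact for signals band-limited below the new Nyquist frequency.
#' @keywords internal
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  nmin <- min(n, n_out)
  half <- nmin %/% 2
  idx_pos <- seq_len(half + 1)          # DC .. +half
  Y[idx_pos] <- X[idx_pos]
  if (half >= 1) {
    idx_neg <- seq_len(half - if (nmin %% 2 == 0) 1 else 0)
    Y[n_out + 1 - idx_neg] <- X[n + 1 - idx_neg]
  }
  if (nmin %% 2 == 0) {
    # split the shared Nyquist coefficient symmetrically
    if (n_out > n) {
      Y[half + 1] <- X[half + 1] / 2
      Y[n_out - half + 1] <- X[half + 1] / 2
    } else {
      Y[half + 1] <- X[half + 1] + X[n - half + 1]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n * 1 # scaled below
}

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computed from the symmetric tridiagonal commuting matrix; standard
#' formulation, adequate for the 1-s, 2-Hz-smoothing windows used here.
#'
#' @param n window length (samples); @param nw time-bandwidth product;
#' @param k number of tapers (default `2 nw - 1`).
#' @return n x k matrix, columns unit-energy tapers ordered by concentration.
#' @keywords internal
dpss_tapers <- function(n, nw, k = max(1L, floor(2 * nw - 1))) {
  W <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- diag(d)
  A[cbind(seq_len(n - 1), seq(2, n))] <- e
  A[cbind(seq(2, n), seq_len(n - 1))] <- e
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j]
    v <- v / sqrt(sum(v^2))
    if (sum(v) < 0) v <- -v
    if (abs(sum(v)) < 1e-8 && v[2] < v[1]) v <- -v
    V[, j] <- v
  }
  V
}
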