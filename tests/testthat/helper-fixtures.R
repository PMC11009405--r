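# Shared fixture builders (everything is generated in code at test time).

# uniform-grid kinematic trial from coordinate functions
make_trial <- function(fx, fy, duration = 10, fs = 100, ...) {
  t <- seq(0, duration, by = 1 / fs)
  kinematic_trial(t, fx(t), fy(t), ...)
}

# perfect Archimedean spiral r = b*theta, clockwise, constant angular speed
make_spiral_trial <- function(b = 1.5 / (2 * pi), loops = 5, duration = 15,
                              fs = 100, cw = TRUE, noise_sd = 0) {
  t <- seq(0, duration, by = 1 / fs)
  theta <- 2 * pi * loops * t / duration
  sgn <- if (cw) -1 else 1
  x <- b * theta * cos(sgn * theta) + stats::rnorm(length(t), 0, noise_sd)
  y <- b * theta * sin(sgn * theta) + stats::rnorm(length(t), 0, noise_sd)
  kinematic_trial(t, x, y, rotation = if (cw) "cw" else "ccw")
}

# LFP epoch from a signal function of time (rest [-5,0), draw [0,Tdraw))
make_epoch <- function(f, t_draw = 10, fs = 200, t_pre = -5, stim = "off") {
  t <- t_pre + (seq_len(round((t_draw - t_pre) * fs)) - 1) / fs
  lfp_epoch(t, f(t), fs,
            intervals = list(rest = c(-5, 0), draw = c(0, t_draw)),
            stim = stim)
}

# envelope trace straight from a vector (for detector tests)
make_env <- function(env, fs = 200, t0 = -5,
                     intervals = list(rest = c(-5, 0), draw = c(0, 10))) {
  structure(list(t = t0 + (seq_along(env) - 1) / fs, env = env,
                 f_peak = 20, band = c(18, 22), fs = fs,
                 intervals = intervals, subject = "S01",
                 drawing = "free", stim = "off", trial_id = "T"),
            class = "envelope_trace")
}

rms <- function(x) sqrt(mean(x^2))

# brute-force cluster permutation oracle: paired t per bin, flood fill
# with 4-connectivity, full enumeration of all 2^n sign flips
cluster_oracle <- function(a, b, alpha = 0.05) {
  n <- dim(a)[1]; nf <- dim(a)[2]; nt <- dim(a)[3]
  D <- matrix(a - b, nrow = n)
  tcrit <- qt(alpha, n - 1)
  tmapf <- function(S) {
    m <- colMeans(D * S)
    s <- apply(D * S, 2, sd)
    matrix(ifelse(s > 0, m / (s / sqrt(n)), 0), nf, nt)
  }
  flood_masses <- function(tm) {
    mask <- tm < tcrit
    seen <- matrix(FALSE, nf, nt); masses <- numeric(0)
    for (i in seq_len(nf)) for (j in seq_len(nt)) {
      if (!mask[i, j] || seen[i, j]) next
      stack <- list(c(i, j)); mass <- 0
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nf || p[2] < 1 || p[2] > nt) next
        if (seen[p[1], p[2]] || !mask[p[1], p[2]]) next
        seen[p[1], p[2]] <- TRUE
        mass <- mass + tm[p[1], p[2]]
        stack <- c(stack, list(p + c(1, 0), p - c(1, 0),
                               p + c(0, 1), p - c(0, 1)))
      }
      masses <- c(masses, mass)
    }
    masses
  }
  obs <- flood_masses(tmapf(rep(1, n)))
  grid <- expand.grid(rep(list(c(1, -1)), n))
  null_max <- apply(grid, 1, function(s)
    max(c(0, abs(flood_masses(tmapf(as.numeric(s)))))))
  list(masses = obs,
       p = sapply(obs, function(ms) mean(null_max >= abs(ms))))
}

# brute-force burst scan: independent oracle for detect_bursts
oracle_bursts <- function(env, t, fs, threshold, min_duration = 0.1) {
  out <- list()
  i <- 1; n <- length(env)
  while (i <= n) {
    if (env[i] > threshold) {
      j <- i
      while (j < n && env[j + 1] > threshold) j <- j + 1
      onset <- t[i]
      offset <- if (j < n) t[j + 1] else t[j] + 1 / fs
      if (offset - onset >= min_duration)
        out[[length(out) + 1]] <- c(onset, offset)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(out))
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(onset = m[, 1], offset = m[, 2])
}
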