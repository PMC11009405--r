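# Spiral kinematics: position conditioning, tangential velocity, the
# radius-angle transform with its linear spiral fit, and accuracy flags.

#' Low-pass filter pen positions
#'
#' Fourth-order 10 Hz Butterworth applied forward-backward (zero phase) to
#' x and y. Trials with timestamp jitter above `jitter_tol` are first
#' resampled to a uniform grid at the median sampling interval.
#'
#' @param trial a [kinematic_trial()].
#' @param cutoff low-pass cutoff (Hz).
#' @param order filter order.
#' @param jitter_tol maximal relative deviation of sampling intervals from
#'   their median before resampling kicks in.
#' @return the filtered trial.
#' @export
preprocess_position <- function(trial, cutoff = 10, order = 4,
                                jitter_tol = 0.1) {
  stopifnot(inherits(trial, "kinematic_trial"))
  dt <- diff(trial$t)
  dt_med <- stats::median(dt)
  if (max(abs(dt - dt_med)) / dt_med > jitter_tol) {
    tt <- seq(trial$t[1], trial$t[length(trial$t)], by = dt_med)
    trial$x <- stats::approx(trial$t, trial$x, tt)$y
    trial$y <- stats::approx(trial$t, trial$y, tt)$y
    trial$t <- tt
  }
  fs <- 1 / dt_med
  if (cutoff >= fs / 2)
    stop("low-pass cutoff at or above Nyquist frequency")
  f <- butter_design(order, cutoff / (fs / 2), "low")
  min_len <- 3L * (3L * max(length(f$a), length(f$b)) + 1L)
  if (length(trial$t) < min_len)
    stop("trial too short to filter (need >= ", min_len, " samples)")
  trial$x <- filtfilt2(trial$x, f$b, f$a)
  trial$y <- filtfilt2(trial$y, f$b, f$a)
  trial
}

#' Tangential velocity and acceleration
#'
#' Central-difference derivatives of the pen path give the instantaneous
#' tangential velocity `sqrt(dx^2 + dy^2)/dt`, which is then smoothed with
#' a Gaussian kernel (our reading of the velocity smoothing step; sigma is
#' configurable). Acceleration is the central difference of the smoothed
#' velocity, so the mean acceleration over a window equals
#' `(v_end - v_start) / window` -- the identity the peri-burst analysis
#' relies on.
#'
#' @param trial a preprocessed [kinematic_trial()].
#' @param smooth_sigma Gaussian kernel SD in seconds (default 0.025).
#' @return object of class `velocity_profile` with `t`, `v` (cm/s) and
#'   `a` (cm/s^2).
#' @export
tangential_velocity <- function(trial, smooth_sigma = 0.025) {
  stopifnot(inherits(trial, "kinematic_trial"))
  t <- trial$t
  if (any(diff(t) <= 0)) stop("nonpositive sampling interval")
  vx <- central_diff(trial$x, t)
  vy <- central_diff(trial$y, t)
  v <- sqrt(vx^2 + vy^2)
  fs <- 1 / stats::median(diff(t))
  if (smooth_sigma > 0) v <- gaussian_smooth(v, smooth_sigma * fs)
  a <- central_diff(v, t)
  structure(list(t = t, v = v, a = a, draw_span = range_span(trial)),
            class = "velocity_profile")
}

range_span <- function(trial) c(trial$t[1], trial$t[length(trial$t)])

central_diff <- function(x, t) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Per-trial velocity summary
#'
#' @param profile a `velocity_profile`.
#' @return list with `mean_velocity` (cm/s) and `log_velocity` (log10);
#'   `log_velocity` is `NA` with a flag when the mean is zero.
#' @export
trial_summary <- function(profile) {
  stopifnot(inherits(profile, "velocity_profile"), length(profile$v) > 0)
  mv <- mean(profile$v)
  list(mean_velocity = mv,
       log_velocity = if (mv > 0) log10(mv) else NA_real_,
       flagged = mv <= 0)
}

#' Radius-angle transform of a spiral trace
#'
#' Re-parameterizes the drawing from (x, y) to (cumulative angle, radius).
#' The angle is unwrapped and oriented so that the dominant rotation maps
#' to increasing theta for both drawing directions; by convention theta at
#' the first sample is -pi/2, so the first revolution occupies
#' (-pi/2, 1.5*pi].
#'
#' @param trial a [kinematic_trial()].
#' @param center `"auto"` (centroid of the first `center_window` seconds;
#'   the drawing starts at the spiral center by task design) or a numeric
#'   `c(x, y)`.
#' @param center_window seconds of samples averaged for the auto center.
#' @return list with `theta` (rad), `radius` (cm) and `t` (s).
#' @export
radius_angle_transform <- function(trial, center = "auto",
                                   center_window = 0.5) {
  stopifnot(inherits(trial, "kinematic_trial"))
  if (identical(center, "auto")) {
    sel <- trial$t <= trial$t[1] + center_window
    center <- c(mean(trial$x[sel]), mean(trial$y[sel]))
  }
  xr <- trial$x - center[1]
  yr <- trial$y - center[2]
  radius <- sqrt(xr^2 + yr^2)
  theta <- unwrap_angle(atan2(yr, xr))
  if (theta[length(theta)] < theta[1]) theta <- -theta # cw -> increasing
  theta <- theta - theta[1] - pi / 2
  list(theta = theta, radius = radius, t = trial$t)
}

unwrap_angle <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(a[1], d))
}

#' Linear fit of the radius-angle transform
#'
#' Ordinary least squares of radius on theta, excluding the first
#' revolution (theta <= 1.5*pi under the -pi/2 start convention) since the
#' radius of an Archimedean spiral grows linearly only after the first
#' turn. Residuals are reported for all samples (the fitted line is
#' extrapolated into the excluded region) for the trace-deviation analysis.
#'
#' @param ra output of [radius_angle_transform()].
#' @return object of class `spiral_fit`: `slope` (cm/rad), `intercept`,
#'   `rmse` (cm, over fitted points), `residuals` (all samples),
#'   `excluded_mask`, plus the inputs.
#' @export
fit_spiral <- function(ra) {
  theta <- ra$theta
  radius <- ra$radius
  if (mean(diff(theta) < 0) > 0.2)
    warning("theta is not close to monotone; fit may be unreliable")
  if (max(theta) - theta[1] < 3 * pi)
    stop("net rotation below 1.5 revolutions; cannot exclude first revolution")
  keep <- theta > 1.5 * pi
  if (sum(keep) < 10) stop("fewer than 10 points beyond the first revolution")
  fit <- stats::lm.fit(cbind(1, theta[keep]), radius[keep])
  coefs <- fit$coefficients
  pred <- coefs[1] + coefs[2] * theta
  res <- radius - pred
  structure(
    list(theta = theta, radius = radius, t = ra$t,
         slope = unname(coefs[2]), intercept = unname(coefs[1]),
         rmse = sqrt(mean(res[keep]^2)), residuals = res,
         excluded_mask = !keep),
    class = "spiral_fit")
}

#' Does the pen trace cross itself?
#'
#' Exact orientation test over all non-adjacent polyline segment pairs;
#' trials where it returns `TRUE` are flagged inaccurate.
#'
#' @param trial a [kinematic_trial()].
#' @return logical scalar.
#' @export
detect_self_intersection <- function(trial) {
  stopifnot(inherits(trial, "kinematic_trial"), length(trial$x) >= 4)
  c_polyline_self_intersects(trial$x, trial$y)
}
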