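# Burst-triggered kinematics: mean acceleration in the +/-250 ms windows
# around burst onsets, the linear-grid and shuffled-onset null controls,
# and trace deviation (spiral-fit residuals) around bursts.

#' Peri-burst acceleration samples
#'
#' For each onset with a full `window` margin inside the draw interval,
#' the mean acceleration in the pre (`[-window, 0)`) and post
#' (`[0, window)`) windows is computed as `(v(end) - v(start)) / window`
#' (equal to the mean of sample-wise central-difference acceleration),
#' with velocities looked up at the nearest kinematic sample on the shared
#' clock. Onsets without a sample within half a sampling period are
#' excluded and counted.
#'
#' @param profile a `velocity_profile` (from [tangential_velocity()]).
#' @param onsets burst onset times (s).
#' @param window window length (s).
#' @param draw_span half-open draw interval `c(start, end)`; defaults to
#'   the profile's span.
#' @param min_spacing optional minimal spacing between consecutive kept
#'   onsets (s); overlapping windows are kept by default.
#' @return data.frame with `onset`, `a_pre`, `a_post`, `delta_a` (cm/s^2)
#'   and `v_onset` (cm/s); excluded onset count in attribute `n_excluded`.
#' @export
peri_burst_segments <- function(profile, onsets, window = 0.25,
                                draw_span = NULL, min_spacing = NULL) {
  stopifnot(inherits(profile, "velocity_profile"))
  if (is.null(draw_span)) draw_span <- profile$draw_span
  dt <- stats::median(diff(profile$t))
  onsets <- sort(onsets)
  ok <- onsets - window >= draw_span[1] & onsets + window <= draw_span[2]
  if (!is.null(min_spacing) && any(ok)) {
    kept <- onsets[ok]
    keep2 <- c(TRUE, diff(kept) >= min_spacing)
    ok[ok] <- keep2
  }
  n_excluded <- sum(!ok)
  onsets <- onsets[ok]
  v_at <- function(times) {
    i <- round((times - profile$t[1]) / dt) + 1
    bad <- i < 1 | i > length(profile$t) |
      abs(profile$t[pmin(pmax(i, 1), length(profile$t))] - times) > dt / 2 + 1e-9
    v <- profile$v[pmin(pmax(i, 1), length(profile$t))]
    v[bad] <- NA_real_
    v
  }
  v0 <- v_at(onsets)
  vm <- v_at(onsets - window)
  vp <- v_at(onsets + window)
  res <- data.frame(onset = onsets,
                    a_pre = (v0 - vm) / window,
                    a_post = (vp - v0) / window,
                    v_onset = v0)
  bad <- !stats::complete.cases(res)
  n_excluded <- n_excluded + sum(bad)
  res <- res[!bad, , drop = FALSE]
  res$delta_a <- res$a_post - res$a_pre
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Construct control onsets
#'
#' `"linear"` places artificial onsets every `step` seconds across the
#' eligible draw span (margins of one window respected, half-open at the
#' end), testing for drift in acceleration over time. `"shuffled"` draws
#' as many onsets as there are real bursts, uniformly over the eligible
#' span, testing the same count under random timing.
#'
#' @param draw_span half-open draw interval `c(start, end)` (s).
#' @param mode `"linear"` or `"shuffled"`.
#' @param real_onsets real burst onsets (required for `"shuffled"`).
#' @param step grid step for `"linear"` (s).
#' @param window peri-burst window (margin kept at both edges, s).
#' @return numeric vector of onset times (possibly empty).
#' @export
control_onsets <- function(draw_span, mode = c("linear", "shuffled"),
                           real_onsets = NULL, step = 0.05, window = 0.25) {
  mode <- match.arg(mode)
  lo <- draw_span[1] + window
  hi <- draw_span[2] - window
  if (hi - lo < window) return(numeric(0))
  if (mode == "linear") {
    on <- seq(lo, hi, by = step)
    return(on[on < hi])
  }
  if (is.null(real_onsets)) stop("shuffled mode requires real_onsets")
  n <- length(real_onsets)
  if (n == 0) return(numeric(0))
  sort(stats::runif(n, lo, hi))
}

#' Trace deviation around burst onsets
#'
#' Mean absolute spiral-fit residual in the pre and post windows around
#' each onset, on the trial clock. Onsets falling in the excluded first
#' revolution are dropped and counted.
#'
#' @param fit a `spiral_fit` (residuals for all samples).
#' @param onsets onset times (s).
#' @param window window length (s).
#' @return data.frame with `onset`, `dev_pre`, `dev_post` (cm); excluded
#'   onset count in attribute `n_excluded`.
#' @export
residual_deviation <- function(fit, onsets, window = 0.25) {
  stopifnot(inherits(fit, "spiral_fit"))
  t <- fit$t
  res <- abs(fit$residuals)
  first_rev_end <- if (any(fit$excluded_mask))
    max(t[fit$excluded_mask]) else t[1]
  ok <- onsets - window >= t[1] & onsets + window <= t[length(t)] &
    onsets > first_rev_end
  out <- lapply(onsets[ok], function(on) {
    pre <- t >= on - window & t < on
    post <- t >= on & t < on + window
    data.frame(onset = on, dev_pre = mean(res[pre]),
               dev_post = mean(res[post]))
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(onset = numeric(0), dev_pre = numeric(0),
               dev_post = numeric(0))
  attr(out, "n_excluded") <- sum(!ok)
  out
}
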