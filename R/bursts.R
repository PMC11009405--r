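# Beta-burst layer: individual beta-peak selection, envelope extraction,
# rest-referenced percentile thresholds, burst event detection, and
# per-interval burst summaries.

#' Individual beta peak frequency
#'
#' The subject's beta frequency is the one with the deepest movement-related
#' desynchronization (most negative draw-vs-rest relative change inside the
#' beta band). When the two deepest frequencies are within `tie_rel`
#' relative of each other ("similar levels"), or when nothing
#' desynchronizes, the peak frequency of the rest spectrum is used instead.
#'
#' @param tfr a warped `tfr_map` for one subject (per-condition average),
#'   or a relchange map; rest columns must be present.
#' @param band beta band searched (Hz).
#' @param tie_rel relative-depth tie tolerance.
#' @return beta peak frequency (Hz).
#' @export
find_beta_peak <- function(tfr, band = c(13, 30), tie_rel = 0.05) {
  stopifnot(inherits(tfr, "tfr_map"), isTRUE(tfr$warped))
  rows <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(rows)) stop("no frequencies inside the beta band")
  rest_cols <- which(tfr$segments == "rest")
  draw_cols <- which(tfr$segments != "rest")
  B <- rowMeans(tfr$power[rows, rest_cols, drop = FALSE], na.rm = TRUE)
  Pd <- rowMeans(tfr$power[rows, draw_cols, drop = FALSE], na.rm = TRUE)
  rel <- (Pd - B) / B
  rest_peak <- tfr$freqs[rows[which.max(B)]]
  depth <- -rel
  ord <- order(depth, decreasing = TRUE)
  if (depth[ord[1]] <= 0) {
    warning("no desynchronization in the beta band; using rest peak")
    return(rest_peak)
  }
  if (length(ord) > 1 &&
      (depth[ord[1]] - depth[ord[2]]) / depth[ord[1]] < tie_rel)
    return(rest_peak)
  tfr$freqs[rows[ord[1]]]
}

#' Beta envelope of an LFP epoch
#'
#' Zero-phase 4th-order Butterworth band-pass around the individual beta
#' frequency (+/- `half_bw` Hz), rectification, and a centred moving
#' average (default 200 ms). Centring keeps the envelope zero-phase so
#' burst onset timing is unbiased.
#'
#' @param epoch a preprocessed [lfp_epoch()].
#' @param f_peak individual beta frequency (Hz).
#' @param half_bw half bandwidth (Hz).
#' @param smooth_s moving-average window (s).
#' @return object of class `envelope_trace`: `t`, `env` (microvolts),
#'   `f_peak`, `band`, `fs`, `intervals`, metadata.
#' @export
beta_envelope <- function(epoch, f_peak, half_bw = 2, smooth_s = 0.2) {
  stopifnot(inherits(epoch, "lfp_epoch"))
  band <- c(f_peak - half_bw, f_peak + half_bw)
  if (band[1] <= 4 || band[2] >= 100)
    stop("band ", band[1], "-", band[2], " Hz outside (4, 100) Hz")
  bp <- butter_design(4, band / (epoch$fs / 2), "pass")
  env <- abs(filtfilt2(epoch$signal, bp$b, bp$a))
  env <- moving_average(env, round(smooth_s * epoch$fs))
  structure(list(t = epoch$t, env = env, f_peak = f_peak, band = band,
                 fs = epoch$fs, intervals = epoch$intervals,
                 subject = epoch$subject, drawing = epoch$drawing,
                 stim = epoch$stim, trial_id = epoch$trial_id),
            class = "envelope_trace")
}

#' Condition-specific rest threshold
#'
#' Pools the envelope samples of all rest intervals of one condition for
#' one subject and returns their 75th percentile (linear-interpolation
#' percentile, R type 7).
#'
#' @param env_traces list of `envelope_trace` objects (one condition).
#' @param percentile percentile in (0, 100).
#' @return threshold (microvolts).
#' @export
rest_threshold <- function(env_traces, percentile = 75) {
  if (inherits(env_traces, "envelope_trace")) env_traces <- list(env_traces)
  pool <- unlist(lapply(env_traces, function(e) {
    e$env[in_interval(e$t, e$intervals$rest)]
  }))
  if (!length(pool)) stop("empty rest-envelope pool")
  unname(stats::quantile(pool, percentile / 100, type = 7))
}

#' Detect beta bursts by threshold crossing
#'
#' Bursts are maximal runs of envelope samples strictly above the
#' threshold; onset is the first suprathreshold sample, offset the first
#' subsequent sample at or below threshold (ties count as subthreshold),
#' and runs shorter than `min_duration` are discarded. Bursts are assigned
#' to the interval containing their onset; with `truncate = TRUE`
#' durations are clipped at the interval boundary.
#'
#' @param env an `envelope_trace`.
#' @param threshold burst threshold (microvolts), from [rest_threshold()].
#' @param min_duration minimal burst duration (s).
#' @param truncate clip bursts at the boundary of their onset interval.
#' @return data.frame with columns `onset`, `offset`, `duration` (s),
#'   `peak_amplitude` (microvolts), `interval`.
#' @export
detect_bursts <- function(env, threshold, min_duration = 0.1,
                          truncate = TRUE) {
  stopifnot(inherits(env, "envelope_trace"), threshold > 0)
  supra <- env$env > threshold
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  dt <- 1 / env$fs
  out <- lapply(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    onset <- env$t[i0]
    offset <- if (i1 < length(env$t)) env$t[i1 + 1] else env$t[i1] + dt
    data.frame(onset = onset, offset = offset,
               peak_amplitude = max(env$env[i0:i1]))
  })
  b <- if (length(out)) do.call(rbind, out) else
    data.frame(onset = numeric(0), offset = numeric(0),
               peak_amplitude = numeric(0))
  b$interval <- rep(NA_character_, nrow(b))
  for (nm in names(env$intervals))
    b$interval[in_interval(b$onset, env$intervals[[nm]])] <- nm
  if (truncate && nrow(b)) {
    for (nm in names(env$intervals)) {
      sel <- !is.na(b$interval) & b$interval == nm
      b$offset[sel] <- pmin(b$offset[sel], env$intervals[[nm]][2])
    }
  }
  b$duration <- b$offset - b$onset
  b <- b[b$duration >= min_duration, , drop = FALSE]
  rownames(b) <- NULL
  b[, c("onset", "offset", "duration", "peak_amplitude", "interval")]
}

#' Per-interval burst summaries
#'
#' @param bursts data.frame from [detect_bursts()].
#' @param interval interval name (`"rest"`/`"draw"`).
#' @param interval_duration interval length (s).
#' @return one-row data.frame: `n_bursts`, `rate` (1/s), `mean_duration`,
#'   `mean_amplitude` and their log10s; duration/amplitude summaries are NA
#'   (flagged) when no burst fell in the interval.
#' @export
burst_metrics <- function(bursts, interval, interval_duration) {
  stopifnot(interval_duration > 0)
  b <- bursts[!is.na(bursts$interval) & bursts$interval == interval, ,
              drop = FALSE]
  n <- nrow(b)
  md <- if (n > 0) mean(b$duration) else NA_real_
  ma <- if (n > 0) mean(b$peak_amplitude) else NA_real_
  data.frame(interval = interval, n_bursts = n,
             rate = n / interval_duration,
             mean_duration = md, log_duration = log10(md),
             mean_amplitude = ma, log_amplitude = log10(ma),
             interval_duration = interval_duration,
             flagged = n == 0)
}
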