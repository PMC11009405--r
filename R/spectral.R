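# Time-frequency layer: Morlet wavelet maps on a 1 Hz / 20 ms grid,
# temporal normalization (time-warping) of variable-length draw intervals,
# baseline normalization, multitaper band power, and the cluster-based
# permutation test used for the drawing-vs-rest contrast.

#' Morlet time-frequency map
#'
#' Complex Morlet wavelets with a fixed number of cycles per frequency
#' (width 7), frequencies 4-100 Hz at 1 Hz steps, power sampled at 20 ms
#' window centers. Edge columns without full wavelet support and a
#' `+/- onset_exclude` window around the draw onset (t = 0) are set NA.
#'
#' @param epoch a preprocessed [lfp_epoch()] (200 Hz).
#' @param freqs frequencies (Hz).
#' @param width wavelet width in cycles.
#' @param step time step between window centers (s).
#' @param onset_exclude half-width of the exclusion window around t = 0 (s).
#' @return object of class `tfr_map`: `freqs`, `times`, `power`
#'   (freq x time, microvolts^2), `intervals`, `warped = FALSE`.
#' @export
morlet_tfr <- function(epoch, freqs = 4:100, width = 7, step = 0.02,
                       onset_exclude = 0.1) {
  stopifnot(inherits(epoch, "lfp_epoch"))
  fs <- epoch$fs
  x <- epoch$signal
  n <- length(x)
  span <- diff(range(epoch$t))
  too_long <- width / freqs > span
  if (any(too_long)) {
    warning("epoch too short for ", sum(too_long), " low frequencies; dropped")
    freqs <- freqs[!too_long]
    if (!length(freqs)) stop("epoch too short for every requested frequency")
  }
  # centers aligned to multiples of `step` on the shared clock
  t0 <- ceiling(epoch$t[1] / step) * step
  times <- seq(t0, epoch$t[n], by = step)
  idx <- round((times - epoch$t[1]) * fs) + 1
  keep <- idx >= 1 & idx <= n
  times <- times[keep]; idx <- idx[keep]
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  power <- matrix(NA_real_, length(freqs), length(times))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma_t <- width / (2 * pi * f)
    half <- min(n - 1, ceiling(3.5 * sigma_t * fs))
    tt <- seq(-half, half) / fs
    env <- exp(-tt^2 / (2 * sigma_t^2))
    w <- env * exp(1i * 2 * pi * f * tt) * (2 / sum(env))
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::fft(X * W, inverse = TRUE)[seq_len(n + 2 * half)] / nfft
    anal <- conv[seq(half + 1, half + n)] # centred
    row <- Mod(anal[idx])^2 / 2
    invalid <- idx <= half | idx > n - half
    row[invalid] <- NA_real_
    power[k, ] <- row
  }
  if (onset_exclude > 0) power[, abs(times) <= onset_exclude] <- NA_real_
  structure(list(freqs = freqs, times = times, power = power,
                 intervals = epoch$intervals, warped = FALSE,
                 subject = epoch$subject, drawing = epoch$drawing,
                 stim = epoch$stim, trial_id = epoch$trial_id),
            class = "tfr_map")
}

#' Time-warp a TFR onto fixed-length segments
#'
#' Linear interpolation of each frequency row onto `n_rest` equispaced
#' points over the rest interval and `n_draw` over the draw interval, so
#' trials of different durations become comparable. Warped sample
#' positions are the midpoints of an even partition of each half-open
#' interval. NA source columns (edges, onset exclusion) are skipped.
#'
#' @param tfr an unwarped `tfr_map` covering both intervals.
#' @param rest_span,draw_span half-open `[start, end)` spans (s); default
#'   from the map's interval bookkeeping.
#' @param n_rest,n_draw warped segment lengths (samples).
#' @param min_draw_bins minimal native bins the draw span must cover.
#' @return a warped `tfr_map`: `power` is freq x (n_rest + n_draw),
#'   `segments` labels columns `rest`, `draw_early`, `draw_late`.
#' @export
timewarp_tfr <- function(tfr, rest_span = NULL, draw_span = NULL,
                         n_rest = 50, n_draw = 100, min_draw_bins = 10) {
  stopifnot(inherits(tfr, "tfr_map"), !isTRUE(tfr$warped))
  if (is.null(rest_span)) rest_span <- tfr$intervals$rest
  if (is.null(draw_span)) draw_span <- tfr$intervals$draw
  step <- stats::median(diff(tfr$times))
  if (diff(draw_span) < min_draw_bins * step)
    stop("draw interval shorter than ", min_draw_bins, " native TFR bins")
  mid <- function(span, k) span[1] + (seq_len(k) - 0.5) / k * diff(span)
  targets <- c(mid(rest_span, n_rest), mid(draw_span, n_draw))
  out <- matrix(NA_real_, nrow(tfr$power), n_rest + n_draw)
  for (i in seq_len(nrow(tfr$power))) {
    ok <- !is.na(tfr$power[i, ])
    if (sum(ok) < 2) next
    out[i, ] <- stats::approx(tfr$times[ok], tfr$power[i, ok], targets,
                              rule = 2)$y
  }
  half <- n_draw %/% 2
  segments <- c(rep("rest", n_rest), rep("draw_early", half),
                rep("draw_late", n_draw - half))
  structure(list(freqs = tfr$freqs, times = seq_len(n_rest + n_draw),
                 power = out, segments = segments, warped = TRUE,
                 n_rest = n_rest, n_draw = n_draw,
                 subject = tfr$subject, drawing = tfr$drawing,
                 stim = tfr$stim, trial_id = tfr$trial_id),
            class = "tfr_map")
}

#' Baseline-relative power change
#'
#' Per frequency: `(P(t,f) - B(f)) / B(f)` with `B(f)` the mean power over
#' the rest segment (the `relchange` convention).
#'
#' @param tfr a warped `tfr_map` (or any map plus an explicit baseline
#'   column selection).
#' @param baseline_cols columns defining the baseline; default the `rest`
#'   segment of a warped map.
#' @return a `tfr_map` whose `power` holds relative changes; rows with a
#'   zero baseline are NA and listed in attribute `flagged_rows`.
#' @export
baseline_relchange <- function(tfr, baseline_cols = NULL) {
  stopifnot(inherits(tfr, "tfr_map"))
  if (is.null(baseline_cols)) {
    if (!isTRUE(tfr$warped)) stop("need a warped map or explicit baseline")
    baseline_cols <- which(tfr$segments == "rest")
  }
  B <- rowMeans(tfr$power[, baseline_cols, drop = FALSE], na.rm = TRUE)
  flagged <- which(!is.finite(B) | B == 0)
  rel <- sweep(sweep(tfr$power, 1, B, "-"), 1, B, "/")
  rel[flagged, ] <- NA_real_
  tfr$power <- rel
  attr(tfr, "flagged_rows") <- flagged
  tfr
}

#' Multitaper band power
#'
#' DPSS (Slepian) multitaper spectra on non-overlapping windows (default
#' 1 s, 2 Hz half-bandwidth smoothing), averaged across windows, then
#' aggregated over the requested band. `aggregate = "mean"` averages the
#' per-bin power across band bins (the convention used for the trial-level
#' beta/gamma statistics); `"sum"` integrates it, so that summing over
#' [0, Nyquist] recovers the signal variance (Parseval).
#'
#' @param epoch a preprocessed [lfp_epoch()].
#' @param interval `"rest"`, `"draw"`, or a numeric `c(start, end)` (s).
#' @param band frequency band `c(lo, hi)` (Hz).
#' @param window_s taper window length (s).
#' @param smoothing_hz spectral half-bandwidth (Hz).
#' @param aggregate `"mean"` or `"sum"` over band bins.
#' @return band power (microvolts^2).
#' @export
band_power <- function(epoch, interval = "draw", band = c(13, 30),
                       window_s = 1, smoothing_hz = 2,
                       aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(epoch, "lfp_epoch"))
  if (is.character(interval)) interval <- epoch$intervals[[interval]]
  if (band[1] < 0 || band[2] >= epoch$fs / 2) stop("band outside [0, fs/2)")
  sel <- in_interval(epoch$t, interval)
  x <- epoch$signal[sel]
  nwin <- round(window_s * epoch$fs)
  k <- floor(length(x) / nwin)
  if (k < 1) stop("interval shorter than one taper window")
  nw <- smoothing_hz * window_s
  tapers <- dpss_tapers(nwin, nw)
  freqs <- (seq_len(nwin %/% 2 + 1) - 1) / window_s
  spec <- numeric(length(freqs))
  for (w in seq_len(k)) {
    seg <- x[seq((w - 1) * nwin + 1, w * nwin)]
    pw <- 0
    for (j in seq_len(ncol(tapers))) {
      X <- stats::fft(seg * tapers[, j])
      pw <- pw + Mod(X[seq_along(freqs)])^2
    }
    pw <- pw / ncol(tapers) / nwin
    # one-sided: double everything but DC (and Nyquist for even windows)
    dbl <- rep(2, length(freqs)); dbl[1] <- 1
    if (nwin %% 2 == 0) dbl[length(freqs)] <- 1
    spec <- spec + pw * dbl
  }
  spec <- spec / k
  bins <- freqs >= band[1] & freqs <= band[2]
  if (!any(bins)) stop("no spectral bins inside the requested band")
  if (aggregate == "mean") mean(spec[bins]) else sum(spec[bins])
}

#' Cluster-based permutation test (paired, within-subject)
#'
#' Paired t statistics per time-frequency bin across subjects; bins beyond
#' the one-sided `alpha_cluster` t-quantile form candidate clusters under
#' 4-connectivity, scored by their summed t (cluster mass). The null
#' distribution is the maximal absolute cluster mass over random
#' within-subject condition-label flips (or full enumeration of all 2^n
#' sign patterns when `exact = TRUE` or `n_perm >= 2^n`).
#'
#' @param cond,baseline numeric arrays, subjects x freq x time, equal
#'   shapes (e.g. per-subject averaged warped segments).
#' @param alpha_cluster cluster-forming alpha (one-sided).
#' @param n_perm number of permutations.
#' @param tail `"neg"` tests for cond < baseline (the expected
#'   movement-related desynchronization), `"pos"` the reverse.
#' @param exact force full enumeration of sign flips.
#' @return object of class `cluster_result`: cluster `masses` (sorted by
#'   absolute mass), `p_values`, label matrix `labels`, observed `tmap`,
#'   `null_max` distribution.
#' @export
cluster_permutation_test <- function(cond, baseline, alpha_cluster = 0.05,
                                     n_perm = 5000, tail = c("neg", "pos"),
                                     exact = FALSE) {
  tail <- match.arg(tail)
  stopifnot(length(dim(cond)) == 3, all(dim(cond) == dim(baseline)))
  n <- dim(cond)[1]
  if (n < 5 && !exact) warning("fewer than 5 subjects")
  nf <- dim(cond)[2]; nt <- dim(cond)[3]
  D <- matrix(cond - baseline, nrow = n) # subjects x (nf*nt), column-major
  m <- colMeans(D)
  s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
  tval <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  negative <- tail == "neg"
  tcrit <- stats::qt(if (negative) alpha_cluster else 1 - alpha_cluster,
                     df = n - 1)
  obs <- c_cluster_masses(matrix(tval, nf, nt), tcrit, negative)
  masses <- obs$masses
  enumerate <- exact || n_perm >= 2^n
  if (enumerate) {
    grid <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    signs <- matrix(as.integer(grid), nrow(grid), n)
  } else {
    signs <- matrix(sample(c(1L, -1L), n_perm * n, replace = TRUE),
                    n_perm, n)
  }
  null_max <- c_perm_max_mass(D, nf, nt, tcrit, negative, signs)
  # relative epsilon so ties at the observed mass survive float rounding
  geq <- function(ms) null_max >= abs(ms) * (1 - 1e-10)
  p <- if (enumerate) {
    vapply(masses, function(ms) mean(geq(ms)), numeric(1))
  } else {
    vapply(masses, function(ms) (1 + sum(geq(ms))) /
             (1 + length(null_max)), numeric(1))
  }
  ord <- order(abs(masses), decreasing = TRUE)
  structure(list(masses = masses[ord], p_values = p[ord],
                 labels = obs$labels, label_order = ord,
                 tmap = matrix(tval, nf, nt), tcrit = tcrit,
                 alpha_cluster = alpha_cluster,
                 n_perm = nrow(signs), tail = tail, exact = enumerate,
                 null_max = null_max),
            class = "cluster_result")
}
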