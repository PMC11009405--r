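# LFP conditioning chain: 4 Hz high-pass at the native rate, anti-aliased
# resampling to 200 Hz, demeaning/detrending, per-epoch DFT line-noise
# notches, and stimulation-artifact suppression for stim-on epochs.

#' Preprocess an LFP epoch
#'
#' Fixed-order chain: zero-phase 4th-order Butterworth high-pass at
#' `highpass` Hz at the native rate, resampling to `target_fs`, demeaning,
#' linear detrending, DFT notches at `notch_freqs`. For stim-on epochs an
#' additional DFT notch targets the stimulation frequency (at its alias if
#' above the new Nyquist) and suprathreshold artifact segments are
#' interpolated away (see [suppress_stim_artifact()]).
#'
#' @param epoch an [lfp_epoch()] at its native sampling rate.
#' @param highpass high-pass corner (Hz).
#' @param target_fs analysis sampling rate (Hz).
#' @param notch_freqs line-noise frequencies (Hz).
#' @param stim_freq stimulation frequency (Hz).
#' @param artifact_threshold artifact amplitude threshold (microvolts).
#' @return the preprocessed epoch; for stim-on epochs the fraction of
#'   interpolated samples is attached as field `fraction_removed`.
#' @export
preprocess_lfp <- function(epoch, highpass = 4, target_fs = 200,
                           notch_freqs = c(50, 100), stim_freq = 130,
                           artifact_threshold = 10) {
  stopifnot(inherits(epoch, "lfp_epoch"))
  if (diff(range(epoch$t)) < 1) stop("epoch shorter than 1 s")
  hp <- butter_design(4, highpass / (epoch$fs / 2), "high")
  epoch$signal <- filtfilt2(epoch$signal, hp$b, hp$a)
  epoch <- resample_lfp(epoch, target_fs)
  epoch$signal <- epoch$signal - mean(epoch$signal)
  epoch$signal <- detrend_linear(epoch$signal)
  epoch$signal <- dft_notch(epoch$signal, epoch$fs, notch_freqs)
  if (identical(epoch$stim, "on")) {
    res <- suppress_stim_artifact(epoch, threshold = artifact_threshold,
                                  stim_freq = stim_freq)
    epoch <- res$epoch
    epoch$fraction_removed <- res$fraction_removed
  }
  epoch
}

detrend_linear <- function(x) {
  n <- length(x)
  i <- seq_len(n) - (n + 1) / 2
  x - sum(i * x) / sum(i * i) * i - mean(x)
}

#' Resample an LFP epoch with anti-aliasing
#'
#' Zero-phase Butterworth low-pass at the target Nyquist frequency followed
#' by Fourier-domain resampling onto a uniform grid; exact for signals
#' band-limited below the new Nyquist. Interval bookkeeping is in seconds
#' and therefore unaffected.
#'
#' @param epoch an [lfp_epoch()].
#' @param target_fs new sampling rate (Hz), below the current rate.
#' @export
resample_lfp <- function(epoch, target_fs = 200) {
  stopifnot(inherits(epoch, "lfp_epoch"))
  if (target_fs >= epoch$fs) stop("target_fs must be below the current rate")
  aa <- butter_design(4, (target_fs / 2) / (epoch$fs / 2), "low")
  x <- filtfilt2(epoch$signal, aa$b, aa$a)
  n_out <- round(length(x) * target_fs / epoch$fs)
  epoch$signal <- fft_resample(x, n_out)
  epoch$t <- epoch$t[1] + (seq_len(n_out) - 1) / target_fs
  epoch$fs <- target_fs
  epoch
}

#' Suppress residual stimulation artifacts
#'
#' Applies a DFT notch at the stimulation frequency -- folded to its alias
#' `|round(f/fs)*fs - f|` when above the Nyquist of the analysis rate --
#' then marks samples whose absolute amplitude exceeds `threshold` and
#' replaces each contiguous marked run by linear interpolation between the
#' flanking clean samples. The threshold is applied after the notch by
#' default (`notch_first = FALSE` applies it to the incoming signal).
#'
#' @param epoch an [lfp_epoch()] at the analysis rate.
#' @param threshold artifact threshold (microvolts, absolute value).
#' @param stim_freq stimulation frequency (Hz).
#' @param notch_first logical; threshold after (default) or before the notch.
#' @return list with the cleaned `epoch` and `fraction_removed`; epochs
#'   losing more than half their samples are flagged `unusable` with a
#'   warning.
#' @export
suppress_stim_artifact <- function(epoch, threshold = 10, stim_freq = 130,
                                   notch_first = TRUE) {
  stopifnot(inherits(epoch, "lfp_epoch"), threshold > 0)
  f_target <- stim_freq
  if (f_target > epoch$fs / 2)
    f_target <- abs(round(stim_freq / epoch$fs) * epoch$fs - stim_freq)
  notched <- dft_notch(epoch$signal, epoch$fs, f_target)
  x <- if (notch_first) notched else epoch$signal
  bad <- abs(x) > threshold
  if (notch_first) epoch$signal <- notched
  frac <- mean(bad)
  good <- which(!bad)
  if (any(bad) && length(good) >= 2) {
    epoch$signal <- stats::approx(epoch$t[good], epoch$signal[good],
                                  epoch$t, rule = 2)$y
  }
  if (frac > 0.5) {
    warning("more than 50% of samples replaced; epoch flagged unusable")
    epoch$unusable <- TRUE
  }
  list(epoch = epoch, fraction_removed = frac)
}
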