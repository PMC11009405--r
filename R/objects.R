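# Lightweight S3 containers for the pipeline. Conventions used everywhere:
# time in seconds with draw onset at t = 0, rest = [-5, 0); positions in cm;
# LFP in microvolts; intervals half-open [start, end).

#' Construct a kinematic trial
#'
#' @param t time stamps (s), strictly increasing, draw onset at 0.
#' @param x,y pen position (cm).
#' @param subject subject identifier.
#' @param drawing `"free"` or `"template"`.
#' @param stim `"off"` or `"on"`.
#' @param rotation `"cw"` or `"ccw"` (drawing direction).
#' @param inaccurate,tremor_subject logical quality flags.
#' @param trial_id optional trial identifier.
#' @return object of class `kinematic_trial`.
#' @export
kinematic_trial <- function(t, x, y, subject = "S01",
                            drawing = c("free", "template"),
                            stim = c("off", "on"),
                            rotation = c("cw", "ccw"),
                            inaccurate = FALSE, tremor_subject = FALSE,
                            trial_id = NA_character_) {
  drawing <- match.arg(drawing)
  stim <- match.arg(stim)
  rotation <- match.arg(rotation)
  stopifnot(length(t) == length(x), length(x) == length(y), length(t) >= 2)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("pen positions must be finite")
  structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         subject = subject, drawing = drawing, stim = stim,
         rotation = rotation,
         flags = list(inaccurate = isTRUE(inaccurate),
                      tremor_subject = isTRUE(tremor_subject)),
         trial_id = trial_id),
    class = "kinematic_trial")
}

#' @export
print.kinematic_trial <- function(x, ...) {
  cat(sprintf(
    "<kinematic_trial> %s %s/%s: %d samples, %.1f s, rotation %s%s\n",
    x$subject, x$drawing, x$stim, length(x$t), diff(range(x$t)),
    x$rotation,
    if (x$flags$inaccurate) " [inaccurate]" else ""))
  invisible(x)
}

#' Construct an LFP epoch
#'
#' @param t time stamps (s), draw onset at 0.
#' @param signal single-channel LFP (microvolts).
#' @param fs sampling rate (Hz).
#' @param intervals named list of half-open `[start, end)` spans in seconds;
#'   must contain `rest` and `draw`.
#' @param subject,drawing,stim,trial_id metadata as for [kinematic_trial()].
#' @export
lfp_epoch <- function(t, signal, fs, intervals, subject = "S01",
                      drawing = c("free", "template"),
                      stim = c("off", "on"), trial_id = NA_character_) {
  drawing <- match.arg(drawing)
  stim <- match.arg(stim)
  stopifnot(length(t) == length(signal), fs > 0)
  if (!all(c("rest", "draw") %in% names(intervals)))
    stop("intervals must contain 'rest' and 'draw'")
  for (iv in intervals)
    if (iv[1] < t[1] - 1.5 / fs || iv[2] > t[length(t)] + 1.5 / fs)
      stop("interval bounds outside epoch span")
  structure(
    list(t = as.numeric(t), signal = as.numeric(signal), fs = fs,
         intervals = intervals, subject = subject, drawing = drawing,
         stim = stim, trial_id = trial_id, unusable = FALSE),
    class = "lfp_epoch")
}

#' @export
print.lfp_epoch <- function(x, ...) {
  cat(sprintf(
    "<lfp_epoch> %s %s/%s: %d samples @ %g Hz, rest [%g, %g), draw [%g, %g)\n",
    x$subject, x$drawing, x$stim, length(x$signal), x$fs,
    x$intervals$rest[1], x$intervals$rest[2],
    x$intervals$draw[1], x$intervals$draw[2]))
  invisible(x)
}

# interval membership on the shared clock (half-open)
in_interval <- function(t, span) t >= span[1] & t < span[2]

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map> %d freqs x %d times (%s)\n",
              length(x$freqs), length(x$times),
              if (isTRUE(x$warped)) "warped 50+100" else "native grid"))
  invisible(x)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations, tail %s\n",
              length(x$masses), x$n_perm, x$tail))
  if (length(x$masses))
    print(data.frame(mass = x$masses, p = x$p_values))
  invisible(x)
}
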