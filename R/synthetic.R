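# Synthetic cohort generator. Emulates the stated world of the study:
# Archimedean-spiral drawing (five loops, 1.5 cm spacing) with
# radius-dependent velocity growth, bursty beta-band LFP on a 1/f
# background with line noise and an optional 130 Hz stimulation artifact,
# condition-dependent modulation of burst rate/duration/amplitude, and a
# burst-locked deceleration present only while drawing freely. Every trial
# returns its injected ground truth so downstream stages can be tested for
# recovery.

#' Simulation configuration
#'
#' Defaults encode the task geometry (five loops, 7.5 cm maximal radius,
#' 1.5 cm spacing), the fixed 5 s rest interval, typical free/template
#' draw durations (15 s / 25 s), and burst statistics chosen to give a
#' rest suprathreshold fraction near the 75th-percentile design point.
#' All rates are per second, durations in seconds, amplitudes in
#' microvolts (envelope peak), positions in cm.
#'
#' @param n_subjects,trials_per_condition cohort size.
#' @param fs_lfp,fs_tablet sampling rates (Hz).
#' @param beta_peak_range interval the per-subject beta peak is drawn from
#'   (Hz, within 13-30).
#' @param burst_rate_rest,burst_rate_draw burst occurrence rates (1/s).
#' @param burst_duration_meanlog,burst_duration_sdlog log-normal burst
#'   duration parameters (s).
#' @param burst_amplitude_meanlog,burst_amplitude_sdlog log-normal burst
#'   envelope-peak amplitude parameters (microvolts).
#' @param burst_duration_factor_draw,burst_amplitude_factor_draw
#'   multiplicative reduction of duration/amplitude during drawing.
#' @param stim_amplitude_factor multiplicative burst-amplitude reduction
#'   under stimulation, in [0, 1]; also scales the kinematic coupling.
#' @param coupling_decel deceleration pulse amplitude after burst onsets in
#'   the free condition (cm/s^2, negative).
#' @param coupling_window deceleration pulse length (s).
#' @param coupling_recovery_tau time constant (s) on which the velocity
#'   decrement left by a pulse decays back to the baseline growth; bounds
#'   the standing slow-down so repeated bursts cannot stall the pen. The
#'   decay starts only after the pulse, so the acceleration ground truth
#'   over the pulse window is exact; a long constant keeps the recovery's
#'   own acceleration slowly varying so it does not bias peri-burst
#'   windows.
#' @param start_speed_frac tangential speed at draw onset as a fraction of
#'   the trial's mean speed; the base speed then grows linearly in time
#'   (constant base acceleration), reaching the spiral's end at the
#'   nominal duration.
#' @param spiral_loops,spiral_spacing,spiral_max_radius spiral geometry.
#' @param spiral_start_angle angle (rad) at which the trace begins; the
#'   exact centre point cannot be traced from standstill, so the pen
#'   starts ~0.4 turn in (r about 0.6 cm) at nonzero speed, which also
#'   keeps the acceleration profile near-stationary from the first
#'   sample.
#' @param draw_duration_free,draw_duration_template nominal draw durations
#'   (s); per-trial durations jitter around these.
#' @param rest_duration rest interval length (s).
#' @param lfp_pad epoch padding before rest / after draw (s).
#' @param noise_exponent 1/f^chi background slope.
#' @param background_rms broadband background RMS (microvolts).
#' @param line_noise_hz,line_noise_uv mains component.
#' @param stim_artifact_hz stimulation frequency (Hz).
#' @param stim_artifact_rate,stim_artifact_uv,stim_artifact_width
#'   transient-artifact event rate (1/s), median amplitude (microvolts) and
#'   double-exponential decay time constant (s); calibrated so roughly 6%
#'   of stim-on samples exceed the 10 microvolt cleaning threshold.
#' @param stim_velocity_effect stimulation speed-up on log10 velocity.
#' @param subject_velocity_sd,subject_amplitude_sd between-subject SDs of
#'   the log10-velocity intercept and log burst-amplitude factor.
#' @param trial_velocity_sd within-subject trial-to-trial SD (log10).
#' @param position_noise_free,position_noise_template pen position noise SD
#'   (cm); the tablet resolution is ~0.005 cm.
#' @param tremor_fraction fraction of subjects flagged tremor-dominant
#'   (7/19 in the cohort emulated).
#' @param tremor_amplitude,tremor_freq_range tremor component (cm, Hz).
#' @param prob_inaccurate_free,prob_inaccurate_template probability that a
#'   trial receives an inward perturbation making it cross its own trace.
#' @param seed integer; fully determines the generated cohort.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 19, trials_per_condition = 12,
                              fs_lfp = 2048, fs_tablet = 100,
                              beta_peak_range = c(15, 28),
                              burst_rate_rest = 0.8, burst_rate_draw = 0.6,
                              burst_duration_meanlog = log(0.3),
                              burst_duration_sdlog = 0.4,
                              burst_amplitude_meanlog = log(5),
                              burst_amplitude_sdlog = 0.3,
                              burst_duration_factor_draw = 0.7,
                              burst_amplitude_factor_draw = 0.8,
                              stim_amplitude_factor = 0.7,
                              coupling_decel = -0.8, coupling_window = 0.25,
                              coupling_recovery_tau = 6,
                              start_speed_frac = 0.4,
                              spiral_loops = 5, spiral_spacing = 1.5,
                              spiral_max_radius = 7.5,
                              spiral_start_angle = 2.5,
                              draw_duration_free = 15,
                              draw_duration_template = 25,
                              rest_duration = 5, lfp_pad = 1,
                              noise_exponent = 1.5, background_rms = 1,
                              line_noise_hz = 50, line_noise_uv = 0.3,
                              stim_artifact_hz = 130,
                              stim_artifact_rate = 1.5,
                              stim_artifact_uv = 50,
                              stim_artifact_width = 0.018,
                              stim_velocity_effect = 0.05,
                              subject_velocity_sd = 0.15,
                              subject_amplitude_sd = 0.2,
                              trial_velocity_sd = 0.1,
                              position_noise_free = 0.005,
                              position_noise_template = 0.003,
                              tremor_fraction = 7 / 19,
                              tremor_amplitude = 0.05,
                              tremor_freq_range = c(4, 6),
                              prob_inaccurate_free = 0.25,
                              prob_inaccurate_template = 0.1,
                              seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_subjects >= 1, trials_per_condition >= 1,
              fs_lfp > 0, fs_tablet > 0, fs_tablet <= 200,
              beta_peak_range[1] >= 13, beta_peak_range[2] <= 30,
              burst_rate_rest > 0, burst_rate_draw >= 0,
              stim_amplitude_factor >= 0, stim_amplitude_factor <= 1,
              coupling_window > 0, spiral_loops >= 2,
              spiral_spacing > 0, rest_duration > 0,
              draw_duration_free > 0, draw_duration_template > 0)
    if (coupling_window > min(draw_duration_free, draw_duration_template))
      stop("coupling_window longer than the draw interval")
  })
  structure(cfg, class = "simulation_config")
}

#' Sample burst events for one interval (Poisson process)
#'
#' Onset times are uniform over the span with a Poisson-distributed count;
#' durations and envelope-peak amplitudes are log-normal. Overlapping
#' events are merged into a single event spanning their union (amplitude =
#' maximum), matching the ground-truth convention.
#'
#' @param span `c(start, end)` (s).
#' @param rate events per second.
#' @param duration_meanlog,duration_sdlog,amplitude_meanlog,amplitude_sdlog
#'   log-normal parameters.
#' @param merge merge overlapping events.
#' @return data.frame `onset`, `offset`, `duration`, `peak_amplitude`.
#' @export
sample_burst_events <- function(span, rate, duration_meanlog = log(0.3),
                                duration_sdlog = 0.4,
                                amplitude_meanlog = log(2.5),
                                amplitude_sdlog = 0.3, merge = TRUE) {
  len <- diff(span)
  n <- stats::rpois(1, rate * len)
  if (n == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), peak_amplitude = numeric(0)))
  onset <- sort(stats::runif(n, span[1], span[2]))
  duration <- stats::rlnorm(n, duration_meanlog, duration_sdlog)
  offset <- pmin(onset + duration, span[2])
  amp <- stats::rlnorm(n, amplitude_meanlog, amplitude_sdlog)
  ev <- data.frame(onset = onset, offset = offset, peak_amplitude = amp)
  if (merge && n > 1) {
    out <- ev[1, ]
    for (i in 2:n) {
      last <- nrow(out)
      if (ev$onset[i] <= out$offset[last]) {
        out$offset[last] <- max(out$offset[last], ev$offset[i])
        out$peak_amplitude[last] <- max(out$peak_amplitude[last],
                                        ev$peak_amplitude[i])
      } else out <- rbind(out, ev[i, ])
    }
    ev <- out
  }
  ev$duration <- ev$offset - ev$onset
  rownames(ev) <- NULL
  ev[, c("onset", "offset", "duration", "peak_amplitude")]
}

#' Simulate one spiral-drawing trial
#'
#' The pen traces `r = b * theta` with `b = spacing / (2*pi)` at constant
#' base angular speed, so tangential velocity grows with the radius. In
#' the free condition each burst onset triggers a deceleration pulse of
#' amplitude `coupling_decel` lasting `coupling_window` (scaled by
#' `stim_amplitude_factor` under stimulation); template trials have no
#' coupling, a lower base speed (longer nominal duration) and less motor
#' noise. Gaussian position noise, optional 4-6 Hz tremor for flagged
#' subjects, and optional inward perturbations that make the trace cross
#' itself (inaccurate trials) complete the model.
#'
#' @param config a [simulation_config()].
#' @param drawing,stim condition labels.
#' @param subject_effects list with `velocity_intercept` (log10 units) and
#'   optional `tremor` flag and `subject` id.
#' @param burst_onsets burst onset times inside the draw interval (s).
#' @param duration draw duration (s); default the condition's nominal
#'   duration adjusted by the subject/stimulation velocity effects.
#' @param seed integer seed (determinism contract).
#' @param make_inaccurate force (TRUE/FALSE) or sample (NULL) the
#'   self-crossing perturbation.
#' @return a [kinematic_trial()]; injected coupling per onset is attached
#'   as attribute `injected_coupling`.
#' @export
simulate_spiral_trial <- function(config, drawing = "free", stim = "off",
                                  subject_effects = list(velocity_intercept = 0),
                                  burst_onsets = numeric(0),
                                  duration = NULL, seed = 1L,
                                  make_inaccurate = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  drawing <- match.arg(drawing, c("free", "template"))
  stim <- match.arg(stim, c("off", "on"))
  set.seed(seed)
  b <- config$spiral_spacing / (2 * pi)
  theta_max <- 2 * pi * config$spiral_loops
  nominal <- if (drawing == "free") config$draw_duration_free else
    config$draw_duration_template
  vel_log <- subject_effects$velocity_intercept +
    (stim == "on") * config$stim_velocity_effect +
    stats::rnorm(1, 0, config$trial_velocity_sd)
  if (is.null(duration)) duration <- nominal / 10^vel_log
  if (config$coupling_window > duration)
    stop("coupling_window longer than the trial")
  theta0 <- config$spiral_start_angle
  coupling <- if (drawing == "free")
    config$coupling_decel *
      (if (stim == "on") config$stim_amplitude_factor else 1) else 0
  dt <- 1 / config$fs_tablet
  t <- seq(0, duration, by = dt)
  n <- length(t)
  onsets <- burst_onsets[burst_onsets >= 0 & burst_onsets <= duration]
  # base tangential speed: linear in time (constant acceleration), sized
  # so the spiral arc from theta0 to theta_max is covered in `duration`
  arc <- function(th) b / 2 * (th * sqrt(1 + th^2) + asinh(th))
  L <- arc(theta_max) - arc(theta0)
  v0 <- config$start_speed_frac * L / duration
  k <- 2 * (L - v0 * duration) / duration^2
  # velocity perturbation: linear ramp (constant deceleration) over the
  # pulse window, then slow exponential recovery of the standing decrement
  dv <- numeric(n)
  w <- config$coupling_window
  tau <- config$coupling_recovery_tau
  for (on in onsets) {
    u <- t - on
    dv <- dv + coupling * ifelse(u <= 0, 0,
                                 ifelse(u <= w, u, w * exp(-(u - w) / tau)))
  }
  theta <- numeric(n)
  theta[1] <- theta0
  for (i in 2:n) {
    sp <- max(v0 + k * t[i - 1] + dv[i - 1], 0.05)
    theta[i] <- theta[i - 1] + sp / (b * sqrt(1 + theta[i - 1]^2)) * dt
  }
  r <- b * theta
  if (is.null(make_inaccurate)) {
    p <- if (drawing == "free") config$prob_inaccurate_free else
      config$prob_inaccurate_template
    make_inaccurate <- stats::runif(1) < p
  }
  if (make_inaccurate && max(theta) > 5 * pi) {
    th0 <- stats::runif(1, 4 * pi, max(theta) - pi)
    r <- r - 1.2 * config$spiral_spacing *
      exp(-(theta - th0)^2 / (2 * 0.35^2))
    r <- pmax(r, 0)
  }
  sgn <- -1 # clockwise (dominant hand); ccw mirrors
  x <- r * cos(sgn * theta)
  y <- r * sin(sgn * theta)
  sd_pos <- if (drawing == "free") config$position_noise_free else
    config$position_noise_template
  # hand jitter is band-limited, not white: smooth to ~8 Hz so noise does
  # not fold sample-scale zigzags into the slow near-center trace
  if (sd_pos > 0) {
    mk_noise <- function() {
      e <- gaussian_smooth(stats::rnorm(n), 0.02 * config$fs_tablet)
      e / stats::sd(e) * sd_pos
    }
    x <- x + mk_noise()
    y <- y + mk_noise()
  }
  if (isTRUE(subject_effects$tremor)) {
    f_tr <- stats::runif(1, config$tremor_freq_range[1],
                         config$tremor_freq_range[2])
    ph <- stats::runif(2, 0, 2 * pi)
    x <- x + config$tremor_amplitude * sin(2 * pi * f_tr * t + ph[1])
    y <- y + config$tremor_amplitude * sin(2 * pi * f_tr * t + ph[2])
  }
  trial <- kinematic_trial(
    t, x, y,
    subject = subject_effects$subject %||% "S01",
    drawing = drawing, stim = stim, rotation = "cw",
    inaccurate = make_inaccurate,
    tremor_subject = isTRUE(subject_effects$tremor))
  attr(trial, "injected_coupling") <- coupling
  trial
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one LFP epoch with injected beta bursts
#'
#' Signal model: 1/f^chi background + mains line + beta bursts (sinusoid
#' at the subject's beta peak under a Hann envelope with log-normal
#' duration and peak amplitude) + (stim on) a 130 Hz carrier plus
#' broadband transient artifacts. The rest interval is the fixed 5 s
#' before draw onset; during drawing, burst rate/duration/amplitude are
#' multiplied down, and stimulation multiplies amplitudes by
#' `stim_amplitude_factor` in both intervals.
#'
#' @param config a [simulation_config()].
#' @param drawing,stim condition labels.
#' @param f_beta subject beta peak (Hz), inside `beta_peak_range`.
#' @param duration draw duration (s).
#' @param amplitude_factor extra multiplicative burst-amplitude factor
#'   (e.g. a subject random effect).
#' @param events optional data.frame (`onset`, `duration`,
#'   `peak_amplitude`) of burst events to inject verbatim instead of
#'   sampling them (oracle/recovery tests); interval labels are assigned
#'   from the onsets and overlaps are merged as usual.
#' @param seed integer seed.
#' @return list with `epoch` ([lfp_epoch()]) and `bursts` (the injected
#'   ground-truth events with `interval` labels; overlaps merged).
#' @export
simulate_lfp_epoch <- function(config, drawing = "free", stim = "off",
                               f_beta = 20, duration = NULL,
                               amplitude_factor = 1, events = NULL,
                               seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  drawing <- match.arg(drawing, c("free", "template"))
  stim <- match.arg(stim, c("off", "on"))
  if (f_beta < config$beta_peak_range[1] - 1e-9 ||
      f_beta > config$beta_peak_range[2] + 1e-9)
    stop("f_beta outside beta_peak_range")
  set.seed(seed)
  if (is.null(duration))
    duration <- if (drawing == "free") config$draw_duration_free else
      config$draw_duration_template
  fs <- config$fs_lfp
  t0 <- -config$rest_duration - config$lfp_pad
  t1 <- duration + config$lfp_pad
  n <- round((t1 - t0) * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  stim_amp <- if (stim == "on") config$stim_amplitude_factor else 1
  if (!is.null(events)) {
    ev <- events
    ev$peak_amplitude <- ev$peak_amplitude * stim_amp * amplitude_factor
    ev$offset <- ev$onset + ev$duration
    ev <- ev[order(ev$onset), , drop = FALSE]
    if (nrow(ev) > 1) { # merge overlapping injected events
      keep <- ev[1, ]
      for (i in 2:nrow(ev)) {
        last <- nrow(keep)
        if (ev$onset[i] <= keep$offset[last]) {
          keep$offset[last] <- max(keep$offset[last], ev$offset[i])
          keep$peak_amplitude[last] <- max(keep$peak_amplitude[last],
                                           ev$peak_amplitude[i])
        } else keep <- rbind(keep, ev[i, ])
      }
      ev <- keep
    }
    ev$duration <- ev$offset - ev$onset
    ev$interval <- ifelse(ev$onset < 0, "rest", "draw")
    rest_ev <- ev[ev$interval == "rest", , drop = FALSE]
    draw_ev <- ev[ev$interval == "draw", , drop = FALSE]
  } else {
  rest_ev <- sample_burst_events(
    c(-config$rest_duration, 0), config$burst_rate_rest,
    config$burst_duration_meanlog, config$burst_duration_sdlog,
    config$burst_amplitude_meanlog +
      log(stim_amp * amplitude_factor),
    config$burst_amplitude_sdlog)
  draw_ev <- sample_burst_events(
    c(0, duration), config$burst_rate_draw,
    config$burst_duration_meanlog + log(config$burst_duration_factor_draw),
    config$burst_duration_sdlog,
    config$burst_amplitude_meanlog +
      log(config$burst_amplitude_factor_draw * stim_amp * amplitude_factor),
    config$burst_amplitude_sdlog)
  if (nrow(rest_ev)) rest_ev$interval <- "rest"
  if (nrow(draw_ev)) draw_ev$interval <- "draw"
  }
  cols <- c("onset", "offset", "duration", "peak_amplitude", "interval")
  bursts <- rbind(rest_ev[, intersect(cols, names(rest_ev)), drop = FALSE],
                  draw_ev[, intersect(cols, names(draw_ev)), drop = FALSE])
  sig <- one_over_f_noise(n, fs, config$noise_exponent) *
    config$background_rms
  sig <- sig + config$line_noise_uv * sin(2 * pi * config$line_noise_hz * t +
                                          stats::runif(1, 0, 2 * pi))
  for (i in seq_len(nrow(bursts))) {
    i0 <- max(1L, round((bursts$onset[i] - t0) * fs) + 1L)
    i1 <- min(n, round((bursts$offset[i] - t0) * fs))
    if (i1 <= i0) next
    tt <- t[i0:i1] - bursts$onset[i]
    hann <- 0.5 * (1 - cos(2 * pi * tt / bursts$duration[i]))
    ph <- stats::runif(1, 0, 2 * pi)
    sig[i0:i1] <- sig[i0:i1] + bursts$peak_amplitude[i] * hann *
      sin(2 * pi * f_beta * tt + ph)
  }
  if (stim == "on") {
    # narrowband carrier (removed by the DFT notch) plus broadband
    # saturation-like transients (double-exponential; these survive the
    # anti-alias filter and are what the 10 uV threshold catches)
    sig <- sig + 2 * sin(2 * pi * config$stim_artifact_hz * t)
    n_ev <- stats::rpois(1, config$stim_artifact_rate * (t1 - t0))
    if (n_ev > 0) {
      at <- stats::runif(n_ev, t0, t1)
      aa <- stats::rlnorm(n_ev, log(config$stim_artifact_uv), 0.4) *
        sample(c(-1, 1), n_ev, replace = TRUE)
      tau <- config$stim_artifact_width
      for (j in seq_len(n_ev)) {
        lo <- max(1L, round((at[j] - 8 * tau - t0) * fs))
        hi <- min(n, round((at[j] + 8 * tau - t0) * fs))
        tt <- t[lo:hi] - at[j]
        sig[lo:hi] <- sig[lo:hi] + aa[j] * exp(-abs(tt) / tau)
      }
    }
  }
  epoch <- lfp_epoch(t, sig, fs,
                     intervals = list(rest = c(-config$rest_duration, 0),
                                      draw = c(0, duration)),
                     drawing = drawing, stim = stim)
  list(epoch = epoch, bursts = bursts)
}

# FFT-shaped 1/f^chi Gaussian noise, unit RMS
one_over_f_noise <- function(n, fs, chi) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f > 0, f^(-chi / 2), 0)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a full cohort with ground truth
#'
#' Generates `n_subjects x 4 conditions x trials_per_condition` paired
#' kinematic/LFP trials. LFP and kinematics of a trial share the burst
#' onsets and the shared clock (draw onset at 0). Per-subject random
#' intercepts (velocity, burst amplitude), beta peaks, and tremor flags
#' are drawn once per subject.
#'
#' @param config a [simulation_config()].
#' @param root optional directory; when given the dataset is written via
#'   [write_dataset()] and the manifest path is included in the result.
#' @return list with `trials` (metadata table), `kinematics` and `lfp`
#'   (lists of objects keyed by trial id), `ground_truth` (injected bursts
#'   and effects), `subjects` (per-subject effects), and optionally
#'   `manifest`.
#' @export
simulate_cohort <- function(config, root = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(ns)),
    f_beta = round(stats::runif(ns, config$beta_peak_range[1],
                                config$beta_peak_range[2])),
    velocity_intercept = stats::rnorm(ns, 0, config$subject_velocity_sd),
    amplitude_factor = stats::rlnorm(ns, 0, config$subject_amplitude_sd),
    tremor = seq_len(ns) %in%
      sample(ns, round(ns * config$tremor_fraction)))
  conds <- expand.grid(drawing = c("free", "template"),
                       stim = c("off", "on"),
                       stringsAsFactors = FALSE)
  trials <- list(); kin <- list(); lfp <- list(); gt <- list()
  idx <- 0L
  base_seed <- (config$seed %% 99991L) * 20000L
  for (s in seq_len(ns)) {
    se <- list(subject = subjects$subject[s],
               velocity_intercept = subjects$velocity_intercept[s],
               tremor = subjects$tremor[s])
    for (c_i in seq_len(nrow(conds))) {
      for (k in seq_len(config$trials_per_condition)) {
        idx <- idx + 1L
        tseed <- base_seed + idx
        id <- sprintf("%s_%s_%s_T%02d", se$subject,
                      conds$drawing[c_i], conds$stim[c_i], k)
        # duration first (kinematic speed model), then LFP, then the trace
        set.seed(tseed)
        nominal <- if (conds$drawing[c_i] == "free")
          config$draw_duration_free else config$draw_duration_template
        vel_log <- se$velocity_intercept +
          (conds$stim[c_i] == "on") * config$stim_velocity_effect +
          stats::rnorm(1, 0, config$trial_velocity_sd)
        duration <- nominal / 10^vel_log
        sim_l <- simulate_lfp_epoch(
          config, conds$drawing[c_i], conds$stim[c_i],
          f_beta = subjects$f_beta[s], duration = duration,
          amplitude_factor = subjects$amplitude_factor[s],
          seed = tseed + 1L)
        draw_onsets <- sim_l$bursts$onset[sim_l$bursts$interval == "draw"]
        trial <- simulate_spiral_trial(
          config, conds$drawing[c_i], conds$stim[c_i],
          subject_effects = se, burst_onsets = draw_onsets,
          duration = duration, seed = tseed + 2L)
        trial$trial_id <- id
        sim_l$epoch$subject <- se$subject
        sim_l$epoch$trial_id <- id
        trials[[idx]] <- data.frame(
          trial_id = id, subject = se$subject,
          drawing = conds$drawing[c_i], stim = conds$stim[c_i],
          duration = duration, f_beta = subjects$f_beta[s],
          inaccurate = trial$flags$inaccurate,
          tremor_subject = subjects$tremor[s])
        kin[[id]] <- trial
        lfp[[id]] <- sim_l$epoch
        gt[[id]] <- list(bursts = sim_l$bursts,
                         coupling = attr(trial, "injected_coupling"))
      }
    }
  }
  out <- list(trials = do.call(rbind, trials), kinematics = kin, lfp = lfp,
              ground_truth = gt, subjects = subjects, config = config)
  if (!is.null(root)) out$manifest <- write_dataset(out, root)
  out
}
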