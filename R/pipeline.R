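# Pipeline driver: preprocess -> kinematics -> tfr -> bursts -> periburst
# -> stats, each stage idempotent and resumable from its on-disk outputs.
# A stage is skipped when its stamp (hash of parameters + upstream stamp)
# matches the previous run, so a config change reruns only downstream
# stages.

PIPELINE_STAGES <- c("preprocess", "kinematics", "tfr", "bursts",
                     "periburst", "stats")

#' Run the analysis pipeline on a dataset
#'
#' @param root dataset root (directory containing `manifest.json`), or
#'   pass `dataset` directly.
#' @param out_dir results directory.
#' @param dataset optional in-memory dataset from [simulate_cohort()] or
#'   [read_dataset()].
#' @param stages subset of stages to run (upstream stages are loaded from
#'   cache or recomputed as needed).
#' @param seed master seed for all pipeline randomness (shuffled onsets,
#'   permutations).
#' @param drop_inaccurate,drop_tremor exclusion toggles for the stats stage.
#' @param n_perm permutations for the cluster tests.
#' @param params list of per-stage parameter overrides.
#' @return (invisibly) list of stage outputs; everything is also on disk
#'   under `out_dir`.
#' @export
run_pipeline <- function(root = NULL, out_dir, dataset = NULL,
                         stages = PIPELINE_STAGES, seed = 1L,
                         drop_inaccurate = FALSE, drop_tremor = FALSE,
                         n_perm = 1000, params = list()) {
  if (is.null(dataset)) {
    if (is.null(root)) stop("need a dataset root or an in-memory dataset")
    dataset <- read_dataset(file.path(root, "manifest.json"))
  }
  dir.create(file.path(out_dir, "stamps"), recursive = TRUE,
             showWarnings = FALSE)
  log_file <- file.path(out_dir, "pipeline_log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = log_file,
                               append = TRUE)
  logline("pipeline start; seed=", seed,
          " drop_inaccurate=", drop_inaccurate,
          " drop_tremor=", drop_tremor)
  state <- list(dataset = dataset, out_dir = out_dir, seed = seed,
                drop_inaccurate = drop_inaccurate,
                drop_tremor = drop_tremor, n_perm = n_perm)
  upstream_stamp <- "root"
  for (stage in PIPELINE_STAGES) {
    pars <- c(params[[stage]], list(seed = seed, n_perm = n_perm,
                                    drop_inaccurate = drop_inaccurate,
                                    drop_tremor = drop_tremor))
    stamp <- stage_stamp(stage, pars, upstream_stamp)
    stamp_file <- file.path(out_dir, "stamps", paste0(stage, ".txt"))
    cached <- file.exists(stamp_file) &&
      identical(readLines(stamp_file, warn = FALSE)[1], stamp)
    if (!(stage %in% stages) && !cached) {
      # stage not requested but needed downstream: run it anyway
    }
    fun <- switch(stage,
                  preprocess = stage_preprocess,
                  kinematics = stage_kinematics,
                  tfr = stage_tfr,
                  bursts = stage_bursts,
                  periburst = stage_periburst,
                  stats = stage_stats)
    if (cached) {
      logline(stage, ": cached (stamp match)")
      state <- fun(state, load_only = TRUE)
    } else {
      logline(stage, ": computing")
      set.seed(seed + match(stage, PIPELINE_STAGES))
      state <- tryCatch(fun(state, load_only = FALSE),
                        error = function(e)
                          stop("pipeline stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
      writeLines(stamp, stamp_file)
    }
    upstream_stamp <- stamp
  }
  logline("pipeline done")
  invisible(state)
}

stage_stamp <- function(stage, pars, upstream) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(list(stage = stage, pars = pars,
                            upstream = upstream), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_preprocess <- function(state, load_only = FALSE) {
  out <- file.path(state$out_dir, "preprocess")
  dir.create(out, showWarnings = FALSE)
  qc_file <- file.path(out, "qc_log.tsv")
  if (load_only && file.exists(qc_file)) {
    ids <- state$dataset$trials$trial_id
    state$clean_lfp <- lapply(ids, function(id) {
      sc <- jsonlite::read_json(file.path(out, paste0(id, ".json")),
                                simplifyVector = TRUE)
      sig <- data.table::fread(file.path(out, paste0(id, ".tsv")))$signal_uv
      lfp_epoch(sc$t0_s + (seq_along(sig) - 1) / sc$fs_hz, sig, sc$fs_hz,
                lapply(sc$intervals, as.numeric), subject = sc$subject,
                drawing = sc$drawing, stim = sc$stim, trial_id = id)
    })
    names(state$clean_lfp) <- ids
    return(state)
  }
  qc <- list()
  state$clean_lfp <- lapply(state$dataset$lfp, function(ep) {
    clean <- preprocess_lfp(ep)
    qc[[ep$trial_id]] <<- data.frame(
      trial_id = ep$trial_id,
      fraction_removed = clean$fraction_removed %||% 0)
    data.table::fwrite(data.table::data.table(signal_uv = clean$signal),
                       file.path(out, paste0(ep$trial_id, ".tsv")),
                       sep = "\t")
    jsonlite::write_json(
      list(fs_hz = clean$fs, t0_s = clean$t[1], units = "uV",
           intervals = clean$intervals, subject = clean$subject,
           drawing = clean$drawing, stim = clean$stim),
      file.path(out, paste0(ep$trial_id, ".json")),
      auto_unbox = TRUE, digits = NA)
    clean
  })
  data.table::fwrite(data.table::rbindlist(qc), qc_file, sep = "\t")
  state
}

stage_kinematics <- function(state, load_only = FALSE) {
  out <- file.path(state$out_dir, "kinematics")
  dir.create(out, showWarnings = FALSE)
  sum_file <- file.path(out, "trial_summary.tsv")
  if (load_only && file.exists(sum_file)) {
    state$kin_summary <- as.data.frame(data.table::fread(sum_file))
    return(state)
  }
  rows <- lapply(state$dataset$kinematics, function(tr) {
    trc <- preprocess_position(tr)
    prof <- tangential_velocity(trc)
    ts <- trial_summary(prof)
    fit <- tryCatch(fit_spiral(radius_angle_transform(trc)),
                    error = function(e) NULL)
    data.frame(trial_id = tr$trial_id, subject = tr$subject,
               drawing = tr$drawing, stim = tr$stim,
               mean_velocity = ts$mean_velocity,
               log_velocity = ts$log_velocity,
               rmse = if (is.null(fit)) NA_real_ else fit$rmse,
               slope = if (is.null(fit)) NA_real_ else fit$slope,
               inaccurate = detect_self_intersection(tr),
               tremor_subject = tr$flags$tremor_subject)
  })
  state$kin_summary <- do.call(rbind, c(rows, make.row.names = FALSE))
  data.table::fwrite(state$kin_summary, sum_file, sep = "\t")
  state
}

stage_tfr <- function(state, load_only = FALSE) {
  out <- file.path(state$out_dir, "tfr")
  dir.create(out, showWarnings = FALSE)
  peaks_file <- file.path(out, "beta_peaks.tsv")
  if (load_only && file.exists(peaks_file)) {
    state$beta_peaks <- as.data.frame(data.table::fread(peaks_file))
    return(state)
  }
  trials <- state$dataset$trials
  subjects <- unique(trials$subject)
  peaks <- list(); subj_maps <- list()
  for (s in subjects) {
    ids <- trials$trial_id[trials$subject == s]
    warped <- lapply(ids, function(id)
      timewarp_tfr(morlet_tfr(state$clean_lfp[[id]])))
    avg <- warped[[1]]
    avg$power <- Reduce(`+`, lapply(warped, `[[`, "power")) / length(warped)
    subj_maps[[s]] <- avg
    peaks[[s]] <- data.frame(subject = s, f_peak = find_beta_peak(avg))
  }
  state$beta_peaks <- do.call(rbind, peaks)
  data.table::fwrite(state$beta_peaks, peaks_file, sep = "\t")
  # cluster tests: per-subject relchange, early and late draw vs rest
  rel <- lapply(subj_maps, baseline_relchange)
  beta_rows <- which(rel[[1]]$freqs >= 13 & rel[[1]]$freqs <= 30)
  seg <- rel[[1]]$segments
  pick <- function(m, cols) m$power[beta_rows, cols, drop = FALSE]
  to_arr <- function(cols) {
    a <- array(NA_real_, c(length(rel), length(beta_rows), length(cols)))
    for (i in seq_along(rel)) a[i, , ] <- pick(rel[[i]], cols)
    a
  }
  rest_a <- to_arr(which(seg == "rest"))
  results <- list()
  for (which_seg in c("draw_early", "draw_late")) {
    arr <- to_arr(which(seg == which_seg))
    res <- if (dim(arr)[1] >= 2)
      cluster_permutation_test(arr, rest_a, n_perm = state$n_perm)
    else NULL
    results[[which_seg]] <- if (is.null(res)) NULL else
      list(masses = res$masses, p_values = res$p_values,
           n_perm = res$n_perm, labels_rle = rle(as.vector(res$labels)))
  }
  jsonlite::write_json(results, file.path(out, "cluster_results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (s in subjects) {
    m <- subj_maps[[s]]
    data.table::fwrite(data.table::as.data.table(m$power),
                       file.path(out, paste0(s, "_warped.tsv")), sep = "\t")
  }
  jsonlite::write_json(
    list(freqs = subj_maps[[1]]$freqs, segments = subj_maps[[1]]$segments,
         warped = TRUE),
    file.path(out, "warped_header.json"), auto_unbox = TRUE, digits = NA)
  state
}

stage_bursts <- function(state, load_only = FALSE) {
  out <- file.path(state$out_dir, "bursts")
  dir.create(out, showWarnings = FALSE)
  ev_file <- file.path(out, "burst_events.tsv")
  met_file <- file.path(out, "burst_metrics.tsv")
  if (load_only && file.exists(ev_file)) {
    state$burst_events <- as.data.frame(data.table::fread(ev_file))
    state$burst_metrics <- as.data.frame(data.table::fread(met_file))
    return(state)
  }
  trials <- state$dataset$trials
  events <- list(); metrics <- list()
  for (s in unique(trials$subject)) {
    f_peak <- state$beta_peaks$f_peak[state$beta_peaks$subject == s]
    for (dr in c("free", "template")) for (st in c("off", "on")) {
      ids <- trials$trial_id[trials$subject == s & trials$drawing == dr &
                               trials$stim == st]
      if (!length(ids)) next
      envs <- lapply(ids, function(id)
        beta_envelope(state$clean_lfp[[id]], f_peak))
      thr <- rest_threshold(envs)
      for (j in seq_along(ids)) {
        b <- detect_bursts(envs[[j]], thr)
        iv <- envs[[j]]$intervals
        if (nrow(b)) {
          b$trial_id <- ids[j]; b$subject <- s
          b$drawing <- dr; b$stim <- st
          events[[length(events) + 1]] <- b
        }
        for (nm in c("rest", "draw")) {
          m <- burst_metrics(b, nm, diff(iv[[nm]]))
          m$trial_id <- ids[j]; m$subject <- s
          m$drawing <- dr; m$stim <- st
          metrics[[length(metrics) + 1]] <- m
        }
      }
    }
  }
  state$burst_events <- as.data.frame(data.table::rbindlist(events))
  state$burst_metrics <- as.data.frame(data.table::rbindlist(metrics))
  data.table::fwrite(state$burst_events, ev_file, sep = "\t")
  data.table::fwrite(state$burst_metrics, met_file, sep = "\t")
  state
}

stage_periburst <- function(state, load_only = FALSE) {
  out <- file.path(state$out_dir, "periburst")
  dir.create(out, showWarnings = FALSE)
  pb_file <- file.path(out, "periburst_samples.tsv")
  if (load_only && file.exists(pb_file)) {
    state$periburst <- as.data.frame(data.table::fread(pb_file))
    return(state)
  }
  trials <- state$dataset$trials
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    ev <- state$burst_events
    onsets <- ev$onset[ev$trial_id == id & ev$interval == "draw"]
    tr <- preprocess_position(state$dataset$kinematics[[id]])
    prof <- tangential_velocity(tr)
    span <- state$dataset$lfp[[id]]$intervals$draw
    set.seed(state$seed + i)
    sets <- list(
      real = peri_burst_segments(prof, onsets, draw_span = span),
      linear = peri_burst_segments(
        prof, control_onsets(span, "linear"), draw_span = span),
      shuffled = peri_burst_segments(
        prof, control_onsets(span, "shuffled", real_onsets = onsets),
        draw_span = span))
    for (mode in names(sets)) {
      d <- sets[[mode]]
      if (!nrow(d)) next
      d$mode <- mode; d$trial_id <- id
      d$subject <- trials$subject[i]
      d$drawing <- trials$drawing[i]; d$stim <- trials$stim[i]
      rows[[length(rows) + 1]] <- d
    }
  }
  state$periburst <- as.data.frame(data.table::rbindlist(rows))
  data.table::fwrite(state$periburst, pb_file, sep = "\t")
  state
}

stage_stats <- function(state, load_only = FALSE) {
  out <- file.path(state$out_dir, "stats")
  dir.create(out, showWarnings = FALSE)
  res_file <- file.path(out, "models.json")
  if (load_only && file.exists(res_file)) {
    state$stats <- jsonlite::read_json(res_file, simplifyVector = TRUE)
    return(state)
  }
  kin <- state$kin_summary
  filt <- exclusion_filters(kin, state$drop_inaccurate, state$drop_tremor)
  kin <- filt$data
  models <- list(exclusions = filt$report)
  vel <- fit_mixed_model(kin, model_spec("log_velocity",
                                         c("drawing", "stim")),
                         posthoc = c("stim"))
  models$velocity <- vel$coefficients
  bm <- state$burst_metrics
  bm <- bm[!bm$flagged, , drop = FALSE]
  for (dep in c("log_duration", "log_amplitude", "rate")) {
    fitb <- fit_mixed_model(
      bm, model_spec(dep, c("drawing", "stim", "interval")))
    models[[paste0("burst_", dep)]] <- fitb$coefficients
  }
  pb <- state$periburst[state$periburst$mode == "real", , drop = FALSE]
  if (nrow(pb) > 10) {
    long <- rbind(
      data.frame(pb[c("subject", "drawing", "stim")],
                 accel = pb$a_pre, interval = "pre"),
      data.frame(pb[c("subject", "drawing", "stim")],
                 accel = pb$a_post, interval = "post"))
    fita <- fit_mixed_model(
      long, model_spec("accel", c("drawing", "stim", "interval")))
    models$periburst_accel <- fita$coefficients
  }
  jsonlite::write_json(models, res_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows")
  txt <- file.path(out, "report.txt")
  sink(txt); on.exit(sink(), add = TRUE)
  cat("spiralburst pipeline report\n===========================\n\n")
  for (nm in names(models)) {
    cat("##", nm, "\n")
    print(models[[nm]])
    cat("\n")
  }
  state$stats <- models
  state
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), one of the stage
#' names to run the pipeline up to that stage, `all`, or `report`.
#' Flags: `--root`, `--out`, `--config`, `--seed`, `--drop-inaccurate`,
#' `--drop-tremor`.
#'
#' @param args character vector (default: the command line).
#' @return invisibly, the pipeline state or dataset.
#' @export
sb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: spiralburst <subcommand> [--flags]")
  cmd <- args[1]
  flag <- function(name, default = NULL) {
    hit <- grep(paste0("^--", name, "="), args)
    if (length(hit)) sub(paste0("^--", name, "="), "", args[hit[1]])
    else if (paste0("--", name) %in% args) TRUE else default
  }
  seed <- as.integer(flag("seed", "1"))
  root <- flag("root", "dataset")
  out <- flag("out", "results")
  if (cmd == "simulate") {
    cfg_path <- flag("config")
    cfg_args <- list(seed = seed)
    if (!is.null(cfg_path) && !isTRUE(cfg_path)) {
      fc <- read_config_file(cfg_path)
      cfg_args <- utils::modifyList(
        cfg_args, fc$synthetic_data %||% fc$global %||% list())
    }
    cfg <- do.call(simulation_config, cfg_args)
    ds <- simulate_cohort(cfg, root = root)
    message("dataset written to ", root)
    return(invisible(ds))
  }
  stages <- if (cmd %in% c("all", "report")) PIPELINE_STAGES
    else if (cmd %in% PIPELINE_STAGES)
      PIPELINE_STAGES[seq_len(match(cmd, PIPELINE_STAGES))]
    else stop("unknown subcommand: ", cmd)
  st <- run_pipeline(root = root, out_dir = out, stages = stages,
                     seed = seed,
                     drop_inaccurate = isTRUE(flag("drop-inaccurate")),
                     drop_tremor = isTRUE(flag("drop-tremor")))
  invisible(st)
}
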