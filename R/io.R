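# On-disk dataset layout and config handling.
#
#   root/
#     manifest.json        dataset manifest (subjects, trials, seed, hash)
#     config.json          generator configuration
#     ground_truth.json    injected bursts / coupling / subject effects
#     kin/<id>.tsv         t_s, x_cm, y_cm
#     lfp/<id>.tsv         signal_uv (single column)
#     lfp/<id>.json        sidecar: fs_hz, t0_s, units, intervals, labels

#' Write a simulated dataset to disk
#'
#' @param dataset result of [simulate_cohort()].
#' @param root target directory (created if needed).
#' @return path to the manifest file.
#' @export
write_dataset <- function(dataset, root) {
  dir.create(file.path(root, "kin"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "lfp"), recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_len(nrow(dataset$trials))) {
    id <- dataset$trials$trial_id[i]
    kin <- dataset$kinematics[[id]]
    kin_file <- file.path("kin", paste0(id, ".tsv"))
    data.table::fwrite(
      data.table::data.table(t_s = kin$t, x_cm = kin$x, y_cm = kin$y),
      file.path(root, kin_file), sep = "\t")
    ep <- dataset$lfp[[id]]
    lfp_file <- file.path("lfp", paste0(id, ".tsv"))
    data.table::fwrite(
      data.table::data.table(signal_uv = ep$signal),
      file.path(root, lfp_file), sep = "\t")
    sidecar <- list(fs_hz = ep$fs, t0_s = ep$t[1], n = length(ep$signal),
                    units = "uV", intervals = ep$intervals,
                    subject = ep$subject, drawing = ep$drawing,
                    stim = ep$stim, trial_id = id)
    jsonlite::write_json(sidecar, file.path(root, paste0(lfp_file, ".json")),
                         auto_unbox = TRUE, digits = NA)
    entries[[i]] <- c(as.list(dataset$trials[i, ]),
                      list(kin_file = kin_file, lfp_file = lfp_file))
  }
  gt <- lapply(dataset$ground_truth, function(g)
    list(bursts = g$bursts, coupling = g$coupling))
  jsonlite::write_json(gt, file.path(root, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  cfg <- unclass(dataset$config)
  jsonlite::write_json(cfg, file.path(root, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(format = "spiralburst-dataset-v1",
                   seed = dataset$config$seed,
                   config_hash = config_hash(dataset$config),
                   subjects = dataset$subjects,
                   trials = entries)
  path <- file.path(root, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  path
}

#' Read a dataset from its manifest
#'
#' Rebuilds typed [kinematic_trial()] / [lfp_epoch()] objects with
#' validated invariants; malformed entries abort with the file named.
#'
#' @param manifest path to `manifest.json`.
#' @return list with `trials`, `kinematics`, `lfp`, `subjects`,
#'   `ground_truth` (if present), `config` (if present).
#' @export
read_dataset <- function(manifest) {
  root <- dirname(manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (!identical(m$format, "spiralburst-dataset-v1"))
    stop("unrecognized manifest format in ", manifest)
  trials <- as.data.frame(m$trials)
  kin <- list(); lfp <- list()
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    kf <- file.path(root, trials$kin_file[i])
    if (!file.exists(kf)) stop("missing kinematic file for trial ", id)
    kd <- data.table::fread(kf)
    if (!all(c("t_s", "x_cm", "y_cm") %in% names(kd)))
      stop("bad kinematic columns in ", kf)
    kin[[id]] <- kinematic_trial(
      kd$t_s, kd$x_cm, kd$y_cm, subject = trials$subject[i],
      drawing = trials$drawing[i], stim = trials$stim[i],
      inaccurate = isTRUE(trials$inaccurate[i]),
      tremor_subject = isTRUE(trials$tremor_subject[i]), trial_id = id)
    lf <- file.path(root, trials$lfp_file[i])
    sc_file <- paste0(lf, ".json")
    if (!file.exists(sc_file)) stop("missing LFP sidecar for trial ", id)
    sc <- jsonlite::read_json(sc_file, simplifyVector = TRUE)
    if (!identical(sc$units, "uV"))
      stop("unit mismatch in sidecar for trial ", id, " (need uV)")
    sig <- data.table::fread(lf)$signal_uv
    if (length(sig) != sc$n)
      stop("sample count mismatch for trial ", id)
    t <- sc$t0_s + (seq_along(sig) - 1) / sc$fs_hz
    lfp[[id]] <- lfp_epoch(t, sig, sc$fs_hz,
                           intervals = lapply(sc$intervals, as.numeric),
                           subject = sc$subject, drawing = sc$drawing,
                           stim = sc$stim, trial_id = id)
  }
  out <- list(trials = trials, kinematics = kin, lfp = lfp,
              subjects = as.data.frame(m$subjects))
  gt_file <- file.path(root, "ground_truth.json")
  if (file.exists(gt_file))
    out$ground_truth <- lapply(
      jsonlite::read_json(gt_file, simplifyVector = TRUE),
      function(g) list(bursts = as.data.frame(g$bursts),
                       coupling = g$coupling))
  cfg_file <- file.path(root, "config.json")
  if (file.exists(cfg_file)) {
    cfg <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
    out$config <- structure(cfg, class = "simulation_config")
  }
  out
}

#' Stable hash of a configuration (cache key)
#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Parse a flat key-value config file
#'
#' Lines of `key = value` grouped under `[section]` headers; values are
#' parsed as numerics where possible, `true`/`false` as logicals, and
#' comma-separated lists as vectors. `#` starts a comment.
#' @param path file path.
#' @return nested named list (one element per section).
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!any(is.na(num))) num
      else if (all(tolower(parts) %in% c("true", "false")))
        tolower(parts) == "true"
      else parts
    out[[section]][[key]] <- parsed
  }
  out
}
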