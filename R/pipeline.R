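#' Default run configuration
#'
#' Every default equals the study's stated value where one exists: two
#' oddball blocks of 630 standards and 2 x 105 deviants at 2 s SOA,
#' 1000 Hz simulation, 0.3-30 Hz band-pass, decimation to 200 Hz, +25 ms
#' trigger shift, -50...800 ms epochs with a 50 ms baseline, 120/25
#' microvolt rejection thresholds, |r| > 0.3 ocular component screening
#' with 64 components, plus-minus SNR exclusion at SNR < 1 or signal <
#' 1 microvolt in the 100-200 ms window, a 46-channel fronto-central ROI,
#' F > F_crit(0.05, 1, n - 1) voxel thresholding and 1000 permutations.
#'
#' @param n_eeg EEG channel count of the synthetic montage (default 128).
#' @return A nested `run_config` list (YAML-serializable).
#' @export
default_config <- function(n_eeg = 128) {
  structure(list(
    montage = list(n_eeg = n_eeg, roi_size = 46, path = NULL),
    design = list(
      blocks = list(
        sicher = list(standard = "sicher",
                      deviants = c("sicherheit", "sicherkeit")),
        sauber = list(standard = "sauber",
                      deviants = c("sauberheit", "sauberkeit"))),
      n_standards = 630, n_per_deviant = 105, gap_range = c(3, 5),
      habituation_len = 15, soa = 2),
    gen = list(sampling_rate = 1000, noise_sd = 4, noise_exponent = 1,
               mmn_amplitude = c(sicherheit = -5.5, sicherkeit = -3.0,
                                 sauberheit = -2.0, sauberkeit = -4.5)),
    artifacts = list(blink_rate = 6, blink_amplitude = 100,
                     n_jump_trials = 3, n_bad_channels = 1),
    preproc = list(lo = 0.3, hi = 30, target_rate = 200,
                   trigger_shift = 0.025, divergence_offset = 0.625,
                   tmin = -0.050, tmax = 0.800, baseline = c(-0.050, 0),
                   maxmin = 120, jump = 25, r_thresh = 0.3,
                   n_components = 64, bad_channel_k = 5,
                   filter_length = NULL),
    qc = list(window = c(0.100, 0.200), roi = "frontocentral",
              snr_min = 1, signal_min = 1),
    stats = list(windows = default_windows(), roi = "frontocentral",
                 grid = c(32, 32), n_perm = 1000, alpha = 0.05,
                 time_window = NULL, run_cluster = TRUE)),
    class = "run_config")
}

## paper-stated defaults used by validate_config
paper_defaults <- function() {
  list("design.n_standards" = 630, "design.n_per_deviant" = 105,
       "design.gap_range" = c(3, 5), "design.habituation_len" = 15,
       "design.soa" = 2, "gen.sampling_rate" = 1000,
       "preproc.lo" = 0.3, "preproc.hi" = 30, "preproc.target_rate" = 200,
       "preproc.trigger_shift" = 0.025, "preproc.divergence_offset" = 0.625,
       "preproc.tmin" = -0.050, "preproc.tmax" = 0.800,
       "preproc.baseline" = c(-0.050, 0), "preproc.maxmin" = 120,
       "preproc.jump" = 25, "preproc.r_thresh" = 0.3,
       "preproc.n_components" = 64,
       "qc.window" = c(0.100, 0.200), "qc.snr_min" = 1,
       "qc.signal_min" = 1, "stats.n_perm" = 1000, "stats.alpha" = 0.05)
}

#' Check a configuration against the study's stated values
#'
#' Lists every deviation of the configuration from the study defaults, plus
#' an informational note when the ROI size differs from the 46-channel
#' fronto-central configuration. Structural problems (missing fields,
#' malformed values) raise a config error naming the offending field.
#'
#' @param config a `run_config`.
#' @return Data frame `field`, `value`, `expected`, `severity`
#'   (`"deviation"` or `"note"`); zero rows for a default configuration.
#' @export
validate_config <- function(config) {
  get_path <- function(path) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    x <- config
    for (p in parts) {
      if (!is.list(x) || is.null(x[[p]]))
        stop("config error: missing field '", path, "'", call. = FALSE)
      x <- x[[p]]
    }
    x
  }
  defs <- paper_defaults()
  rows <- list()
  for (field in names(defs)) {
    val <- get_path(field)
    if (!is.numeric(val) || length(val) != length(defs[[field]]))
      stop("config error: malformed field '", field, "'", call. = FALSE)
    if (!isTRUE(all.equal(as.numeric(val), as.numeric(defs[[field]]))))
      rows[[field]] <- data.frame(
        field = field, value = paste(val, collapse = ","),
        expected = paste(defs[[field]], collapse = ","),
        severity = "deviation", stringsAsFactors = FALSE)
  }
  roi_size <- config$montage$roi_size
  if (!identical(as.numeric(roi_size), 46))
    rows[["roi"]] <- data.frame(
      field = "montage.roi_size", value = as.character(roi_size),
      expected = "46", severity = "note", stringsAsFactors = FALSE)
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(field = character(0), value = character(0),
               expected = character(0), severity = character(0))
}

#' Pool epochs objects on a common grid
#'
#' @param eps list of `mmn_epochs` with identical channel/time grids.
#' @return A single `mmn_epochs` with trials stacked in order.
#' @export
pool_epochs <- function(eps) {
  stopifnot(length(eps) >= 1)
  e1 <- eps[[1]]
  if (length(eps) == 1) return(e1)
  for (e in eps[-1])
    if (e$rate != e1$rate || !identical(dim(e$data)[-1], dim(e1$data)[-1]) ||
        !identical(e$channel_names, e1$channel_names))
      stop("input error: epoch grids do not match", call. = FALSE)
  out <- e1
  out$data <- do.call(abind3, lapply(eps, `[[`, "data"))
  for (f in c("labels", "is_deviant", "trial_index", "kept_mask",
              "reject_reason"))
    out[[f]] <- do.call(c, lapply(eps, `[[`, f))
  out
}

## bind trial (first) dimension of 3D arrays
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(0, c(sum(vapply(arrs, function(a) dim(a)[1], 0L)), d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Preprocess one block recording into cleaned epochs
#'
#' The study's chain: EOG derivation, band-pass filtering, decimation,
#' variance-based bad-channel detection, linear decomposition with
#' EOG-correlation component screening and reconstruction,
#' spherical-spline interpolation of bad channels, divergence-locked
#' epoching with trigger-shift compensation, baseline correction, and
#' amplitude/jump rejection.
#'
#' @param rec an `mmn_recording` (with EOG channels).
#' @param montage the montage it was recorded with.
#' @param pp the `preproc` sub-list of a [default_config()].
#' @return An `mmn_epochs` object; counts are recorded in attribute `log`.
#' @export
preprocess_block <- function(rec, montage, pp) {
  rec <- derive_eog(rec)
  rec <- bandpass_filter(rec, pp$lo, pp$hi, pp$filter_length)
  rec <- resample(rec, pp$target_rate, anti_alias = FALSE)
  bad <- detect_bad_channels(rec, pp$bad_channel_k)
  dec <- decompose_signal(rec, pp$n_components)
  veog <- rec$signal[match("vEOG", rec$channel_names), ]
  heog <- rec$signal[match("hEOG", rec$channel_names), ]
  remove <- screen_components(dec$timecourses, veog, heog, pp$r_thresh)
  rec <- remove_components(rec, dec, remove)
  rec <- interpolate_channels(rec, bad, montage)
  ep <- epoch_recording(rec, pp$tmin, pp$tmax, pp$trigger_shift,
                        pp$divergence_offset)
  ep <- baseline_correct(ep, pp$baseline)
  ep <- reject_artifacts(ep, pp$maxmin, pp$jump)
  attr(ep, "log") <- list(bad_channels = bad, components_removed = remove,
                          n_trials = dim(ep$data)[1],
                          n_kept = sum(ep$kept_mask))
  ep
}

## build gen_params from config with per-subject overrides
subject_params <- function(config, quality, subject_seed) {
  gp <- do.call(gen_params, config$gen)
  if (quality == "low_signal") {
    ## constructed to violate the signal-amplitude criterion: no evoked
    ## activity at all, so the pooled deviant ERP is residual noise
    gp$mmn_amplitude[] <- 0
    gp$standard_response_amplitude <- 0
    gp$trial_jitter_sd <- 0
  } else {
    rng <- local_rng(subject_seed)
    gp$mmn_amplitude <- gp$mmn_amplitude +
      rng(rnorm(length(gp$mmn_amplitude), 0, gp$subject_amp_sd))
  }
  gp
}

#' Simulate and preprocess one participant
#'
#' Runs both counterbalanced blocks through simulation, artifact injection,
#' and [preprocess_block()], pools the epochs, and computes the plus-minus
#' QC record and per-condition ERPs.
#'
#' @param config a `run_config`.
#' @param montage,proj montage and its projection (built once per cohort).
#' @param subject_id text id.
#' @param subject_index 0-based index (controls block counterbalancing).
#' @param seed integer seed for everything this subject consumes.
#' @param quality `"good"`, `"low_signal"` (constructed to fail the
#'   signal/SNR rules), or `"flagged"` (externally flagged, e.g. muscle
#'   artifacts).
#' @return List `qc` (one-row data.frame), `erps` (named condition list or
#'   NULL if excluded), `log`.
#' @export
process_subject <- function(config, montage, proj, subject_id,
                            subject_index, seed, quality = "good") {
  quality <- match.arg(quality, c("good", "low_signal", "flagged"))
  gp <- subject_params(config, quality, seed)
  dsn <- config$design
  blocks <- lapply(seq_along(dsn$blocks), function(b) {
    bl <- dsn$blocks[[b]]
    spec <- block_spec(bl$standard, bl$deviants, dsn$n_standards,
                       dsn$n_per_deviant, dsn$gap_range,
                       dsn$habituation_len, dsn$soa)
    generate_block(spec, seed + b, block_id = names(dsn$blocks)[b])
  })
  blocks <- concat_experiment(blocks, subject_index)
  art <- config$artifacts
  eps <- vector("list", length(blocks))
  logs <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    rec <- simulate_recording(blocks[[b]], gp, montage, proj,
                              seed = seed + 100 + b)
    if (art$blink_rate > 0 || art$n_jump_trials > 0 ||
        art$n_bad_channels > 0) {
      inj <- inject_artifacts(rec, art$blink_rate, art$blink_amplitude,
                              art$n_jump_trials,
                              n_bad_channels = art$n_bad_channels,
                              seed = seed + 200 + b, montage = montage)
      rec <- inj$recording
    }
    eps[[b]] <- preprocess_block(rec, montage, config$preproc)
    logs[[b]] <- attr(eps[[b]], "log")
  }
  pooled <- pool_epochs(eps)
  dev_lab <- unlist(lapply(dsn$blocks, `[[`, "deviants"), use.names = FALSE)
  roi <- montage$rois[[config$qc$roi]]
  sel <- which(pooled$kept_mask & pooled$is_deviant)
  if (length(sel) == 0)
    stop("QC error: no kept deviant trials for subject ", subject_id,
         call. = FALSE)
  ## pooled signal across all deviant conditions
  signal_erp <- new_erp(
    apply(pooled$data[sel, , , drop = FALSE], c(2, 3), mean),
    pooled$rate, pooled$tmin, pooled$tmax, pooled$channel_names,
    "deviant-pooled", length(sel))
  noise <- polarity_flip_noise(pooled)
  snr <- snr_statistic(signal_erp, noise, config$qc$window, roi)
  flags <- if (quality == "flagged") "muscle-artifact" else character(0)
  qc <- qc_record(subject_id, snr$snr, snr$signal_rms, snr$noise_rms, flags)
  erps <- NULL
  if (!qc$excluded)
    erps <- setNames(lapply(dev_lab, average_erp, ep = pooled), dev_lab)
  list(qc = qc, erps = erps,
       log = list(blocks = logs, n_kept_deviants = length(sel)))
}

#' Run a full simulated experiment
#'
#' Simulates a cohort, preprocesses every subject, applies the QC exclusion
#' rules, and runs the sensor statistics (window-mean 2x2 repeated-measures
#' ANOVA with planned comparisons per window, and the cluster-mass
#' permutation test) on the retained subjects. Fully reproducible from
#' `(config, seed)`.
#'
#' @param config a [default_config()]-style `run_config`.
#' @param n_subjects cohort size.
#' @param seed integer master seed; every stage derives its seeds from it.
#' @param out_dir optional directory for `qc.csv` and `summary.json`.
#' @param subject_quality optional character vector (length `n_subjects`)
#'   of per-subject quality classes (see [process_subject()]).
#' @return Invisible list: `qc` (full report), `retained_subjects`,
#'   `anova` (per window), `planned` (per window), `cluster`
#'   (`mmn_cluster_result` or NULL), `tables`, `config_deviations`.
#' @export
run_experiment <- function(config, n_subjects, seed, out_dir = NULL,
                           subject_quality = NULL) {
  stopifnot(inherits(config, "run_config"), n_subjects >= 1)
  if (is.null(subject_quality))
    subject_quality <- rep("good", n_subjects)
  stopifnot(length(subject_quality) == n_subjects)
  montage <- if (!is.null(config$montage$path))
    load_montage(config$montage$path) else
    synthetic_montage(config$montage$n_eeg, config$montage$roi_size)
  proj <- project_to_plane(montage, config$stats$grid)

  subjects <- lapply(seq_len(n_subjects), function(i) {
    process_subject(config, montage, proj, sprintf("S%02d", i), i - 1L,
                    seed = seed + 1000L * i,
                    quality = subject_quality[i])
  })
  qc <- do.call(rbind, lapply(subjects, `[[`, "qc"))
  excl <- exclude_participants(qc)
  retained <- which(!excl$report$excluded)

  conditions <- unlist(lapply(config$design$blocks, `[[`, "deviants"),
                       use.names = FALSE)
  roots <- rep(names(config$design$blocks),
               vapply(config$design$blocks,
                      function(b) length(b$deviants), 0L))
  suffixes <- sub("^.*(heit|keit)$", "\\1", conditions)
  anova <- list(); planned <- list(); tables <- list(); cluster <- NULL
  ## the 2x2 factorial stage needs the full four-condition design
  if (length(retained) >= 2 && length(conditions) == 4) {
    erps <- lapply(subjects[retained],
                   function(s) s$erps[conditions])
    roi <- montage$rois[[config$stats$roi]]
    for (wn in names(config$stats$windows)) {
      vals <- t(vapply(erps, function(e)
        vapply(e, window_mean, numeric(1),
               window = config$stats$windows[[wn]], roi = roi),
        numeric(length(conditions))))
      colnames(vals) <- conditions
      tab <- condition_table(vals, root = roots, suffix = suffixes)
      tables[[wn]] <- tab
      anova[[wn]] <- rm_anova_2x2(tab)
      ## planned comparisons: the two deviants within each root/block
      planned[[wn]] <- lapply(config$design$blocks, function(b)
        planned_comparison(vals[, b$deviants[1]], vals[, b$deviants[2]]))
    }
    if (isTRUE(config$stats$run_cluster)) {
      vols <- erps_to_volumes(erps, proj,
                              time_window = config$stats$time_window,
                              root = roots, suffix = suffixes)
      cluster <- cluster_permutation(vols, "interaction",
                                     alpha = config$stats$alpha,
                                     n_perm = config$stats$n_perm,
                                     seed = seed + 7L)
    }
  }
  res <- list(qc = excl$report, retained_subjects = qc$subject[retained],
              n_retained = length(retained), anova = anova,
              planned = planned, cluster = cluster, tables = tables,
              config_deviations = validate_config(config), seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_qc_report(excl$report, file.path(out_dir, "qc.csv"))
    summary <- list(
      seed = seed, n_subjects = n_subjects, n_retained = length(retained),
      retained = qc$subject[retained],
      anova = lapply(anova, function(a) as.list(a[, c("effect", "F", "p")])),
      clusters = if (!is.null(cluster)) cluster$clusters else NULL,
      f_threshold = if (!is.null(cluster)) cluster$f_threshold else NULL)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(res)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields missing from the file keep their
#'   [default_config()] values.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  structure(merge_in(unclass(config), user), class = "run_config")
}
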