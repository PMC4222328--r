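#' Simulation parameters for synthetic oddball EEG
#'
#' Defaults emulate the study's recording conditions (1000 Hz sampling,
#' high-density cap, 2 s SOA handled by the design module) with ground-truth
#' condition effects chosen to mimic a retained participant: a
#' mismatch-negativity (MMN) kernel peaking 155 ms after the acoustic
#' divergence point at fronto-central channels, stronger (more negative) for
#' congruent derived words than for incongruent ones and stronger for the
#' high-frequency root, on top of an obligatory auditory onset response and
#' 1/f-type background noise. Amplitudes are in microvolts at the kernel
#' peak and topography center; they are synthetic choices (the study reports
#' effects only as F statistics), fixed from the closed-form ground truth so
#' the nominal subject clears the plus-minus QC rules with a wide margin.
#'
#' @param sampling_rate Hz (default 1000).
#' @param noise_sd per-channel background noise SD, microvolts (default 4).
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background
#'   (default 1).
#' @param noise_shared_frac fraction of noise variance shared across EEG
#'   channels, giving spatially correlated scalp noise (default 0.3).
#' @param mmn_amplitude named numeric map condition -> microvolts at the
#'   kernel peak (negative = MMN). The default encodes the cross-over
#'   congruency effect plus a root-frequency offset.
#' @param mmn_latency_center seconds after the divergence point (default
#'   0.155).
#' @param mmn_half_width kernel half-width in seconds; the Hann kernel spans
#'   `2 * mmn_half_width` (default 0.020, so the default kernel covers
#'   135-175 ms).
#' @param divergence_offset seconds from deviant onset to the acoustic
#'   divergence point (default 0.625).
#' @param topography_center projected-plane point of the spatial peak
#'   (default the FCz site).
#' @param topography_sd Gaussian spatial spread on the projected plane, in
#'   plane units (radians from vertex; default 1.0).
#' @param standard_response_amplitude microvolts of the obligatory auditory
#'   onset response shared by every stimulus (default -3.5); deviants evoke
#'   it again at the divergence point (suffix onset).
#' @param standard_response_latency,standard_response_half_width timing of
#'   the onset-response Hann kernel, seconds (defaults 0.100 and 0.050).
#' @param trial_jitter_sd per-trial SD of the MMN amplitude, microvolts
#'   (default 0.5).
#' @param subject_amp_sd between-subject SD of per-condition MMN amplitude,
#'   microvolts, used by cohort-level simulators (default 0.7).
#' @param stimulus_delay seconds between event marker and actual stimulus
#'   arrival, emulating the delivery-system delay the preprocessing
#'   trigger shift compensates (default 0.025).
#' @param seed default seed consumed by [simulate_recording()] when none is
#'   given there.
#' @return A `gen_params` list.
#' @export
gen_params <- function(sampling_rate = 1000,
                       noise_sd = 4,
                       noise_exponent = 1,
                       noise_shared_frac = 0.3,
                       mmn_amplitude = c(sicherheit = -5.5, sicherkeit = -3.0,
                                         sauberheit = -2.0, sauberkeit = -4.5),
                       mmn_latency_center = 0.155,
                       mmn_half_width = 0.020,
                       divergence_offset = 0.625,
                       topography_center = NULL,
                       topography_sd = 1.0,
                       standard_response_amplitude = -3.5,
                       standard_response_latency = 0.100,
                       standard_response_half_width = 0.050,
                       trial_jitter_sd = 0.5,
                       subject_amp_sd = 0.7,
                       stimulus_delay = 0.025,
                       seed = NULL) {
  stopifnot(sampling_rate > 0, mmn_half_width > 0, noise_sd >= 0,
            topography_sd > 0, standard_response_half_width > 0)
  if (is.null(topography_center)) topography_center <- FCZ_PLANE
  structure(list(sampling_rate = sampling_rate, noise_sd = noise_sd,
                 noise_exponent = noise_exponent,
                 noise_shared_frac = noise_shared_frac,
                 mmn_amplitude = mmn_amplitude,
                 mmn_latency_center = mmn_latency_center,
                 mmn_half_width = mmn_half_width,
                 divergence_offset = divergence_offset,
                 topography_center = topography_center,
                 topography_sd = topography_sd,
                 standard_response_amplitude = standard_response_amplitude,
                 standard_response_latency = standard_response_latency,
                 standard_response_half_width = standard_response_half_width,
                 trial_jitter_sd = trial_jitter_sd,
                 subject_amp_sd = subject_amp_sd,
                 stimulus_delay = stimulus_delay,
                 seed = seed),
            class = "gen_params")
}

## Hann bump of unit peak centered at `center` with half-width `hw` (s)
hann_kernel <- function(t, center, hw) {
  ifelse(abs(t - center) <= hw, 0.5 * (1 + cos(pi * (t - center) / hw)), 0)
}

#' Spectrally shaped (1/f^alpha) Gaussian noise
#'
#' White Gaussian noise is shaped in the frequency domain by
#' `1/f^(alpha/2)` amplitude scaling (DC removed) and rescaled to unit
#' standard deviation.
#'
#' @param n number of samples.
#' @param alpha spectral slope of the power spectrum (0 = white).
#' @param rate sampling rate in Hz (sets the frequency axis; the shape is
#'   rate-invariant up to normalization).
#' @return Numeric vector of length `n`, SD 1.
#' @export
colored_noise <- function(n, alpha = 1, rate = 1000) {
  if (n < 2) return(rnorm(n))
  w <- rnorm(n)
  if (alpha == 0) return(w)
  X <- fft(w)
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  f[f > rate / 2] <- rate - f[f > rate / 2]  # fold to physical frequencies
  scale <- c(0, 1 / f[-1]^(alpha / 2))
  x <- Re(fft(X * scale, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

## Gaussian spatial weights on the projected plane for all channels of a
## montage (0 for non-EEG channels).
spatial_weights <- function(montage, params, proj = NULL) {
  if (is.null(proj)) proj <- project_to_plane(montage)
  w <- numeric(nrow(montage$channels))
  names(w) <- montage$channels$name
  ctr <- params$topography_center
  d2 <- (proj$plane[, 1] - ctr[1])^2 + (proj$plane[, 2] - ctr[2])^2
  w[proj$channel] <- exp(-d2 / (2 * params$topography_sd^2))
  w
}

new_recording <- function(signal, rate, channel_names, roles, events) {
  structure(list(signal = signal, rate = rate,
                 channel_names = channel_names, roles = roles,
                 events = events),
            class = "mmn_recording")
}

#' @export
print.mmn_recording <- function(x, ...) {
  cat(sprintf("<mmn_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$rate, nrow(x$events)))
  invisible(x)
}

#' Simulate a continuous oddball EEG recording
#'
#' Builds `1/f^alpha` background noise (independent per channel plus a
#' shared component across EEG channels) and adds, per trial, the evoked
#' components: an obligatory onset response for every stimulus, and for
#' deviants a second onset response at the acoustic divergence point plus
#' the condition-specific MMN kernel (Hann temporal window, Gaussian spatial
#' weighting on the projected electrode plane, per-trial amplitude jitter).
#' All evoked activity is delayed by `params$stimulus_delay` after the event
#' marker, emulating the delivery delay that the preprocessing trigger shift
#' compensates. Event markers are written at nominal trial onsets.
#'
#' @param seq a `trial_sequence` from [generate_block()].
#' @param params a [gen_params()] object; `params$mmn_amplitude` must cover
#'   every deviant label in `seq`.
#' @param montage an `mmn_montage` with EEG and EOG channels.
#' @param proj optional precomputed `mmn_projection` of `montage`.
#' @param seed integer seed (defaults to `params$seed`).
#' @return An `mmn_recording`: `signal` (channels x samples, microvolts),
#'   `rate`, `channel_names`, `roles`, `events` (sample index, label,
#'   exclusion flags).
#' @export
simulate_recording <- function(seq, params, montage, proj = NULL,
                               seed = params$seed) {
  stopifnot(inherits(seq, "trial_sequence"), inherits(params, "gen_params"),
            inherits(montage, "mmn_montage"), nrow(seq$trials) > 0)
  missing_amp <- setdiff(seq$deviant_labels, names(params$mmn_amplitude))
  if (length(missing_amp))
    stop("config error: no amplitude for deviant label(s): ",
         paste(missing_amp, collapse = ", "), call. = FALSE)
  if (is.null(seed)) seed <- 0L
  rate <- params$sampling_rate
  n_ch <- nrow(montage$channels)
  n_samp <- as.integer(round((max(seq$trials$onset) + seq$soa) * rate))
  is_eeg <- montage$channels$role == "EEG"
  rng <- local_rng(seed)

  signal <- matrix(0, n_ch, n_samp)
  if (params$noise_sd > 0) {
    shared <- rng(colored_noise(n_samp, params$noise_exponent, rate))
    a_ind <- sqrt(1 - params$noise_shared_frac)
    a_sh <- sqrt(params$noise_shared_frac)
    for (c in seq_len(n_ch)) {
      own <- rng(colored_noise(n_samp, params$noise_exponent, rate))
      signal[c, ] <- params$noise_sd *
        (if (is_eeg[c]) a_ind * own + a_sh * shared else own)
    }
  }

  w <- spatial_weights(montage, params, proj)
  delay <- round(params$stimulus_delay * rate)
  ## sampled kernels (time measured from the evoking acoustic event)
  kt_std <- seq(0, 2 * (params$standard_response_latency +
                        params$standard_response_half_width), by = 1 / rate)
  k_std <- hann_kernel(kt_std, params$standard_response_latency,
                       params$standard_response_half_width)
  kt_mmn <- seq(0, params$mmn_latency_center + params$mmn_half_width,
                by = 1 / rate)
  k_mmn <- hann_kernel(kt_mmn, params$mmn_latency_center,
                       params$mmn_half_width)
  div <- round(params$divergence_offset * rate)

  onset_samp <- as.integer(round(seq$trials$onset * rate)) + 1L
  is_dev <- seq$trials$label %in% seq$deviant_labels
  jit <- rng(rnorm(nrow(seq$trials), 0, params$trial_jitter_sd))
  ## accumulate the evoked activity per channel-independent time course
  ## first (outer product once per unique spatial pattern), avoiding a
  ## full-matrix copy per trial
  tc_std <- numeric(n_samp)
  tc_mmn <- numeric(n_samp)
  put <- function(tc, at, kernel, amp) {
    idx <- at + seq_along(kernel) - 1L
    keep <- idx >= 1L & idx <= n_samp
    tc[idx[keep]] <- tc[idx[keep]] + amp * kernel[keep]
    tc
  }
  for (i in seq_len(nrow(seq$trials))) {
    at <- onset_samp[i] + delay
    if (params$standard_response_amplitude != 0) {
      tc_std <- put(tc_std, at, k_std, params$standard_response_amplitude)
      if (is_dev[i])
        tc_std <- put(tc_std, at + div, k_std,
                      params$standard_response_amplitude)
    }
    if (is_dev[i]) {
      amp <- params$mmn_amplitude[[seq$trials$label[i]]]
      if (params$trial_jitter_sd > 0) amp <- amp + jit[i]
      if (amp != 0) tc_mmn <- put(tc_mmn, at + div, k_mmn, amp)
    }
  }
  ## both evoked components share the Gaussian topography
  signal <- signal + w %o% (tc_std + tc_mmn)

  events <- data.frame(sample = onset_samp, label = seq$trials$label,
                       is_deviant = is_dev,
                       is_habituation = seq$trials$is_habituation,
                       is_post_deviant = seq$trials$is_post_deviant,
                       stringsAsFactors = FALSE)
  new_recording(signal, rate, montage$channels$name, montage$channels$role,
                events)
}

#' Inject ocular, jump, and bad-channel artifacts
#'
#' Adds blinks (low-frequency deflections with a periocular/frontal spatial
#' pattern, opposite polarity above vs. below the eye so they dominate the
#' derived vertical EOG), square-pulse jump artifacts into randomly chosen
#' analyzable trials, and replaces channels with high-variance noise. Every
#' injected artifact is logged exactly so downstream rejection can be
#' verified against ground truth.
#'
#' @param rec an `mmn_recording`.
#' @param blink_rate blinks per minute (default 0).
#' @param blink_amplitude blink peak at the upper periocular channel,
#'   microvolts (default 100).
#' @param n_jump_trials number of analyzable trials receiving a jump pulse
#'   (default 0).
#' @param jump_amplitude pulse height in microvolts (default 150, large
#'   enough to survive band-pass filtering and trip the default rejection
#'   thresholds).
#' @param n_bad_channels number of EEG channels replaced by noise
#'   (default 0).
#' @param seed integer seed.
#' @param montage the `mmn_montage` the recording was simulated from (used
#'   for the blink spatial pattern).
#' @return List with `recording` and `log` (data.frame `kind`, `trial`,
#'   `label`, `channel`, `sample`, `amplitude`).
#' @export
inject_artifacts <- function(rec, blink_rate = 0, blink_amplitude = 100,
                             n_jump_trials = 0, jump_amplitude = 150,
                             n_bad_channels = 0, seed = 1, montage = NULL) {
  stopifnot(inherits(rec, "mmn_recording"))
  rng <- local_rng(seed)
  log <- data.frame(kind = character(0), trial = integer(0),
                    label = character(0), channel = character(0),
                    sample = integer(0), amplitude = numeric(0),
                    stringsAsFactors = FALSE)
  n_samp <- ncol(rec$signal)
  rate <- rec$rate
  eeg_idx <- which(rec$roles == "EEG")

  n_blinks <- round(blink_rate * n_samp / rate / 60)
  if (n_blinks > 0) {
    if (is.null(montage))
      stop("montage required for blink injection", call. = FALSE)
    bl_t <- seq(0, 0.4, by = 1 / rate)
    bl_k <- hann_kernel(bl_t, 0.2, 0.2)
    ## spatial pattern: +1 above the eye, -0.5 below, frontal EEG falloff
    pat <- numeric(nrow(rec$signal))
    names(pat) <- rec$channel_names
    pat["EOGup"] <- 1; pat["EOGlow"] <- -0.5
    if ("EOGlat" %in% rec$channel_names) pat["EOGlat"] <- 0.2
    uv <- azimuthal_xy(as.matrix(
      montage$channels[montage$channels$role == "EEG", c("x", "y", "z")]))
    ## steep periocular falloff: blinks barely reach central sites
    d2 <- uv[, 1]^2 + (uv[, 2] - 1.45)^2  # centered at the frontal pole
    pat[montage$channels$name[montage$channels$role == "EEG"]] <-
      0.5 * exp(-d2 / (2 * 0.25^2))
    at <- sort(rng(rand_subset(seq(rate, n_samp - length(bl_k) - rate),
                            min(n_blinks, n_samp))))[seq_len(n_blinks)]
    for (s in at) {
      idx <- s + seq_along(bl_k) - 1L
      rec$signal[, idx] <- rec$signal[, idx] +
        (blink_amplitude * pat) %o% bl_k
      log <- rbind(log, data.frame(kind = "blink", trial = NA_integer_,
                                   label = NA_character_, channel = "EOGup",
                                   sample = s, amplitude = blink_amplitude))
    }
  }

  if (n_jump_trials > 0) {
    ev <- rec$events
    analyzable <- which(!ev$is_habituation & !ev$is_post_deviant)
    if (n_jump_trials > length(analyzable))
      stop("not enough analyzable trials for requested jumps", call. = FALSE)
    pick <- sort(rng(rand_subset(analyzable, n_jump_trials)))
    for (tr in pick) {
      ch <- rng(rand_subset(eeg_idx, 1))
      ## pulse inside the analysis epoch; deviants are divergence-locked
      lock <- ev$sample[tr] +
        round((0.025 + if (isTRUE(ev$is_deviant[tr])) 0.625 else 0) * rate)
      start <- lock + rng(rand_subset(round(c(0.10, 0.15, 0.20, 0.25) * rate), 1))
      len <- round(0.08 * rate)
      idx <- start:min(start + len, n_samp)
      rec$signal[ch, idx] <- rec$signal[ch, idx] + jump_amplitude
      log <- rbind(log, data.frame(kind = "jump", trial = tr,
                                   label = ev$label[tr],
                                   channel = rec$channel_names[ch],
                                   sample = start,
                                   amplitude = jump_amplitude))
    }
  }

  if (n_bad_channels > 0) {
    bad <- rng(rand_subset(eeg_idx, n_bad_channels))
    for (ch in bad) {
      ## broadband + drift-heavy noise, so the fault survives band-limiting
      rec$signal[ch, ] <- 50 * rng(colored_noise(n_samp, 1, rec$rate))
      log <- rbind(log, data.frame(kind = "bad_channel", trial = NA_integer_,
                                   label = NA_character_,
                                   channel = rec$channel_names[ch],
                                   sample = NA_integer_, amplitude = 50))
    }
  }
  list(recording = rec, log = log)
}

#' Closed-form expected condition effects
#'
#' Computes, without simulation, the expected baseline-corrected window mean
#' per condition over a region of interest, from the kernel shapes, spatial
#' weights, and amplitude map, together with the 2x2 interaction contrast
#' `(c11 - c12) - (c21 - c22)` of those means. Used as the
#' parameter-recovery oracle for the statistics downstream.
#'
#' @param params a [gen_params()].
#' @param windows list of `c(lo, hi)` windows in seconds relative to the
#'   divergence-locked, delay-compensated time zero (half-open).
#' @param roi character vector of ROI channel names.
#' @param montage an `mmn_montage`.
#' @param rate analysis sampling rate, Hz (default 200).
#' @param tmin epoch start relative to time zero (default -0.050).
#' @param conditions condition labels ordered (c11, c12, c21, c22); default
#'   the names of `params$mmn_amplitude`.
#' @param proj optional precomputed projection.
#' @return List with `expected_window_mean` (conditions x windows matrix,
#'   microvolts) and `interaction_contrast` (per window).
#' @export
ground_truth <- function(params, windows, roi, montage, rate = 200,
                         tmin = -0.050, conditions = NULL, proj = NULL) {
  stopifnot(inherits(params, "gen_params"))
  if (is.null(conditions)) conditions <- names(params$mmn_amplitude)
  w <- spatial_weights(montage, params, proj)
  roi_w <- mean(w[roi])
  gt <- matrix(NA_real_, length(conditions), length(windows),
               dimnames = list(conditions, names(windows)))
  for (j in seq_along(windows)) {
    win <- windows[[j]]
    ## replicate the epoch sample grid and half-open window selection
    tt <- tmin + (seq_len(round((1.0 - tmin) * rate)) - 1) / rate
    sel <- in_window(tt, win)
    for (i in seq_along(conditions)) {
      amp <- params$mmn_amplitude[[conditions[i]]]
      v <- amp * hann_kernel(tt[sel], params$mmn_latency_center,
                             params$mmn_half_width) +
        params$standard_response_amplitude *
          hann_kernel(tt[sel], params$standard_response_latency,
                      params$standard_response_half_width)
      gt[i, j] <- roi_w * mean(v)
    }
  }
  ic <- as.vector(gt[1, , drop = FALSE] - gt[2, , drop = FALSE] -
                  gt[3, , drop = FALSE] + gt[4, , drop = FALSE])
  names(ic) <- colnames(gt)
  list(expected_window_mean = gt, interaction_contrast = ic)
}

#' Fast ERP-level cohort simulation
#'
#' Draws per-subject, per-condition ERPs directly on the epoch grid:
#' condition template (onset response + MMN kernel with Gaussian topography)
#' with a per-subject, per-condition amplitude perturbation
#' (`subject_amp_sd`), plus spatially and spectrally correlated residual
#' noise scaled as the average of `n_trials` single trials. This is the fast
#' path for statistical calibration studies (type-I error, power), where
#' simulating and preprocessing full continuous recordings for hundreds of
#' cohorts would add nothing: the statistics consume subject-level ERPs.
#'
#' @param n_subjects number of subjects.
#' @param params a [gen_params()].
#' @param montage an `mmn_montage`.
#' @param proj optional precomputed projection.
#' @param rate epoch sampling rate, Hz (default 200).
#' @param tmin,tmax epoch limits in seconds (half-open grid; defaults
#'   -0.050 and 0.800).
#' @param n_trials trials per condition entering each ERP (default 90,
#'   the per-condition analyzable deviant count of the full design).
#' @param conditions condition labels (default names of the amplitude map).
#' @param seed integer seed.
#' @return List of subjects, each a named list of condition ERP objects
#'   (class `mmn_erp`).
#' @export
simulate_erp_cohort <- function(n_subjects, params, montage, proj = NULL,
                                rate = 200, tmin = -0.050, tmax = 0.800,
                                n_trials = 90, conditions = NULL, seed = 1) {
  stopifnot(inherits(params, "gen_params"))
  if (is.null(conditions)) conditions <- names(params$mmn_amplitude)
  if (is.null(proj)) proj <- project_to_plane(montage)
  rng <- local_rng(seed)
  w <- spatial_weights(montage, params, proj)
  eeg <- montage$channels$role == "EEG"
  w <- w[eeg]
  ch <- montage$channels$name[eeg]
  n_t <- as.integer(round((tmax - tmin) * rate))
  tt <- tmin + (seq_len(n_t) - 1) / rate
  k_mmn <- hann_kernel(tt, params$mmn_latency_center, params$mmn_half_width)
  k_std <- hann_kernel(tt, params$standard_response_latency,
                       params$standard_response_half_width)
  ## effective residual SD of an n-trial average in the analysis band
  erp_sd <- params$noise_sd / sqrt(max(1, n_trials))
  a_ind <- sqrt(1 - params$noise_shared_frac)
  a_sh <- sqrt(params$noise_shared_frac)
  lapply(seq_len(n_subjects), function(s) {
    erps <- lapply(conditions, function(cond) {
      amp <- params$mmn_amplitude[[cond]] +
        rng(rnorm(1, 0, params$subject_amp_sd))
      m <- w %o% (amp * k_mmn +
                  params$standard_response_amplitude * k_std)
      if (erp_sd > 0) {
        shared <- rng(colored_noise(n_t, params$noise_exponent, rate))
        noise <- t(vapply(seq_along(ch), function(i)
          a_ind * rng(colored_noise(n_t, params$noise_exponent, rate)) +
            a_sh * shared, numeric(n_t)))
        m <- m + erp_sd * noise
      }
      new_erp(m, rate = rate, tmin = tmin, tmax = tmax,
              channel_names = ch, condition = cond, n_trials = n_trials)
    })
    names(erps) <- conditions
    erps
  })
}
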