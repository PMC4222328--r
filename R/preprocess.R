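## ---- zero-phase FIR filtering -------------------------------------------

## Hamming-windowed sinc low-pass, odd length, unit DC gain
windowed_sinc_lowpass <- function(fc, rate, length) {
  L <- as.integer(length)
  if (L %% 2L == 0L) L <- L + 1L
  n <- seq_len(L) - (L + 1L) / 2L
  h <- 2 * fc / rate * sinc(2 * fc / rate * n)
  h <- h * (0.54 + 0.46 * cos(2 * pi * n / (L - 1)))
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

## zero-phase application of a symmetric odd-length kernel to the rows of a
## matrix, with reflection padding and FFT convolution
apply_fir <- function(signal, h) {
  L <- length(h)
  p <- (L - 1L) / 2L
  n <- ncol(signal)
  if (p >= n)
    stop("filter kernel (", L, " taps) too long for signal (", n,
         " samples)", call. = FALSE)
  pad_l <- signal[, (p + 1L):2L, drop = FALSE]
  pad_r <- signal[, (n - 1L):(n - p), drop = FALSE]
  xp <- cbind(pad_l, signal, pad_r)          # channels x (n + 2p)
  m <- ncol(xp)
  nfft <- stats::nextn(m + L - 1L, 2)
  H <- fft(c(h, rep(0, nfft - L)))
  ## samples x channels orientation: H recycles down columns
  X <- stats::mvfft(rbind(t(xp), matrix(0, nfft - m, nrow(xp))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  ## full convolution index of the zero-phase output aligned with x[i]
  t(y[(2L * p + 1L):(2L * p + n), , drop = FALSE])
}

#' Zero-phase band-pass filter
#'
#' Linear-phase FIR band-pass built as the difference of two unit-gain
#' Hamming-windowed-sinc low-pass kernels (so the DC gain is exactly zero),
#' applied with delay compensation and reflection padding: group delay is
#' zero and component latencies are preserved. The default band is
#' 0.3-30 Hz.
#'
#' @param rec an `mmn_recording`.
#' @param lo,hi corner frequencies in Hz (`0 < lo < hi < rate/2`).
#' @param filter_length number of taps; default `3.3 * rate / lo` (capped at
#'   an odd length shorter than the signal), giving a transition band on
#'   the order of the low corner.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, lo = 0.3, hi = 30, filter_length = NULL) {
  stopifnot(inherits(rec, "mmn_recording"))
  if (!(lo > 0 && hi > lo && hi < rec$rate / 2))
    stop("config error: need 0 < lo < hi < rate/2", call. = FALSE)
  n <- ncol(rec$signal)
  if (is.null(filter_length)) filter_length <- ceiling(3.3 * rec$rate / lo)
  L <- min(as.integer(filter_length), 2L * ((n - 1L) %/% 2L) + 1L)
  if (L %% 2L == 0L) L <- L - 1L
  h <- windowed_sinc_lowpass(hi, rec$rate, L) -
    windowed_sinc_lowpass(lo, rec$rate, L)
  rec$signal <- apply_fir(rec$signal, h)
  rec
}

#' Decimate a recording to a lower sampling rate
#'
#' Keeps every `rate/target`-th sample (the factor must be an integer) after
#' an optional anti-alias low-pass; event sample indices are rescaled and
#' rounded to the nearest sample. Within the standard pipeline the band-pass
#' filter has already bounded the spectrum well below the target Nyquist
#' frequency, so the anti-alias stage can be skipped.
#'
#' @param rec an `mmn_recording`.
#' @param target target rate in Hz (default 200); must divide `rec$rate`.
#' @param anti_alias apply a low-pass at `0.45 * target` first (default
#'   TRUE).
#' @return The decimated recording.
#' @export
resample <- function(rec, target = 200, anti_alias = TRUE) {
  stopifnot(inherits(rec, "mmn_recording"))
  if (target > rec$rate)
    stop("config error: target rate above recording rate", call. = FALSE)
  if (target == rec$rate) return(rec)
  factor <- rec$rate / target
  if (abs(factor - round(factor)) > 1e-9)
    stop("config error: target must divide the recording rate", call. = FALSE)
  factor <- as.integer(round(factor))
  if (anti_alias) {
    L <- min(33L * factor, 2L * ((ncol(rec$signal) - 1L) %/% 2L) + 1L)
    h <- windowed_sinc_lowpass(0.45 * target, rec$rate, L)
    rec$signal <- apply_fir(rec$signal, h)
  }
  rec$signal <- rec$signal[, seq(1L, ncol(rec$signal), by = factor),
                           drop = FALSE]
  rec$events$sample <- as.integer(round((rec$events$sample - 1L) / factor)) + 1L
  rec$rate <- target
  rec
}

## ---- EOG derivation and component screening -----------------------------

#' Derive vertical and horizontal EOG channels
#'
#' Appends `vEOG = upper - lower` (samplewise) and `hEOG = vEOG - lateral`
#' to the recording; the periocular source channels are retained.
#'
#' @param rec an `mmn_recording`.
#' @param upper,lower,lateral names of the periocular channels (above and
#'   below the left eye, lateral to the right eye).
#' @return The recording with channels `vEOG` and `hEOG` appended.
#' @export
derive_eog <- function(rec, upper = "EOGup", lower = "EOGlow",
                       lateral = "EOGlat") {
  stopifnot(inherits(rec, "mmn_recording"))
  need <- c(upper, lower, lateral)
  missing <- setdiff(need, rec$channel_names)
  if (length(missing))
    stop("input error: missing channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  i <- match(need, rec$channel_names)
  veog <- rec$signal[i[1], ] - rec$signal[i[2], ]
  heog <- veog - rec$signal[i[3], ]
  rec$signal <- rbind(rec$signal, veog, heog)
  rec$channel_names <- c(rec$channel_names, "vEOG", "hEOG")
  rec$roles <- c(rec$roles, "EOG", "EOG")
  rownames(rec$signal) <- NULL
  rec
}

#' Linear decomposition of the EEG channels
#'
#' Pluggable decomposer interface: any linear unmixing into
#' `n_components` component time courses with a mixing matrix satisfies it.
#' The default implementation is a varimax-rotated principal-component
#' decomposition of the mean-centered EEG channels: the rotation localizes
#' each component's spatial loading, so spatially compact sources such as
#' ocular artifacts separate from broad evoked topographies instead of
#' mixing with them along variance-ordered axes. The bespoke, tested
#' pipeline logic is the downstream correlation screening and
#' reconstruction, not the unmixing algorithm, which the study treated as
#' off-the-shelf.
#'
#' @param rec an `mmn_recording`.
#' @param n_components number of components (default 64, capped at the EEG
#'   channel count).
#' @param rotate `"varimax"` (default) or `"none"` for raw principal
#'   components.
#' @return An `mmn_decomposition`: `mixing` (channels x components),
#'   `timecourses` (components x samples), `center` (per-channel means),
#'   `channels` (EEG channel names).
#' @export
decompose_signal <- function(rec, n_components = 64,
                             rotate = c("varimax", "none")) {
  stopifnot(inherits(rec, "mmn_recording"))
  rotate <- match.arg(rotate)
  eeg <- rec$roles == "EEG"
  X <- rec$signal[eeg, , drop = FALSE]
  ctr <- rowMeans(X)
  X <- X - ctr
  k <- min(n_components, nrow(X))
  e <- eigen(tcrossprod(X), symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  if (rotate == "varimax" && k >= 2) {
    R <- stats::varimax(U, normalize = FALSE)$rotmat
    U <- U %*% R
  }
  structure(list(mixing = U, timecourses = crossprod(U, X), center = ctr,
                 channels = rec$channel_names[eeg], n_components = k),
            class = "mmn_decomposition")
}

#' Flag components correlated with the EOG
#'
#' A component is flagged if and only if the absolute Pearson correlation of
#' its time course with the vertical or horizontal EOG reference is
#' strictly greater than `r_thresh` (matching the open inequalities
#' `r < -0.3 | r > 0.3`). Zero-variance components cannot be correlated and
#' are skipped with a warning.
#'
#' @param timecourses components x samples matrix.
#' @param veog,heog reference signals (same sample count).
#' @param r_thresh correlation threshold (default 0.3).
#' @return Integer vector of component indices to remove.
#' @export
screen_components <- function(timecourses, veog, heog, r_thresh = 0.3) {
  stopifnot(ncol(timecourses) == length(veog),
            ncol(timecourses) == length(heog))
  flagged <- integer(0)
  for (i in seq_len(nrow(timecourses))) {
    tc <- timecourses[i, ]
    if (sd(tc) == 0) {
      warning("component ", i, " has zero variance; skipped")
      next
    }
    r <- suppressWarnings(c(cor(tc, veog), cor(tc, heog)))
    if (isTRUE(any(abs(r) > r_thresh))) flagged <- c(flagged, i)
  }
  flagged
}

#' Reconstruct a recording with components removed
#'
#' Zeroes the flagged components and rebuilds the EEG channels from the
#' remaining ones (plus the channel means removed by the decomposer);
#' non-EEG channels are untouched.
#'
#' @param rec an `mmn_recording`.
#' @param decomp an `mmn_decomposition` of `rec`.
#' @param remove integer component indices to remove (possibly empty).
#' @return The cleaned recording.
#' @export
remove_components <- function(rec, decomp, remove = integer(0)) {
  stopifnot(inherits(rec, "mmn_recording"),
            inherits(decomp, "mmn_decomposition"))
  k <- decomp$n_components
  remove <- as.integer(remove)
  if (length(remove) && (any(remove < 1L) || any(remove > k)))
    stop("input error: component index out of range", call. = FALSE)
  keep <- setdiff(seq_len(k), remove)
  recon <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$timecourses[keep, , drop = FALSE] + decomp$center
  rec$signal[match(decomp$channels, rec$channel_names), ] <- recon
  rec
}

#' Variance-based bad-channel detection
#'
#' Flags EEG channels whose standard deviation exceeds `k` times the median
#' EEG channel SD (or falls below `1/k` of it, catching dead channels). A
#' reproducible stand-in for by-eye bad-channel marking.
#'
#' @param rec an `mmn_recording`.
#' @param k multiplicative threshold (default 5).
#' @return Character vector of channel names.
#' @export
detect_bad_channels <- function(rec, k = 5) {
  eeg <- which(rec$roles == "EEG")
  sds <- apply(rec$signal[eeg, , drop = FALSE], 1, sd)
  med <- median(sds)
  rec$channel_names[eeg[sds > k * med | sds < med / k]]
}

## ---- spherical-spline interpolation -------------------------------------

## Perrin-style spherical spline kernel g(cos(angle)) with stiffness m,
## truncated Legendre series.
spline_g <- function(x, m = 4, n_terms = 50) {
  dims <- dim(x)
  x <- as.vector(x)
  ## Legendre recurrence, vectorized over x
  p_prev <- rep(1, length(x))  # P_0
  p <- x                       # P_1
  out <- (2 * 1 + 1) / (1 * 2)^m * p
  for (n in 2:n_terms) {
    p_new <- ((2 * n - 1) * x * p - (n - 1) * p_prev) / n
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_new
    p_prev <- p
    p <- p_new
  }
  out <- out / (4 * pi)
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels with spherical-spline estimates (stiffness
#' `m = 4`, 50 Legendre terms, ridge regularization `1e-5` on the
#' self-interaction matrix) computed from the remaining good EEG channels,
#' using the montage positions projected to the unit sphere. Good channels
#' are untouched.
#'
#' @param rec an `mmn_recording`.
#' @param bad character vector of channel names to rebuild.
#' @param montage the `mmn_montage` supplying electrode positions.
#' @param m spline stiffness (default 4).
#' @param n_terms Legendre series length (default 50).
#' @param lambda ridge regularization (default 1e-5).
#' @return The recording with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad, montage, m = 4, n_terms = 50,
                                 lambda = 1e-5) {
  stopifnot(inherits(rec, "mmn_recording"))
  if (length(bad) == 0) return(rec)
  eeg <- rec$channel_names[rec$roles == "EEG"]
  bad <- intersect(bad, eeg)
  good <- setdiff(eeg, bad)
  if (length(good) < 4)
    stop("input error: need at least 4 good EEG channels", call. = FALSE)
  pos <- as.matrix(montage$channels[match(c(good, bad), montage$channels$name),
                                    c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  ng <- length(good)
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  G <- spline_g(cosang, m, n_terms)
  Ggg <- G[seq_len(ng), seq_len(ng)] + diag(lambda, ng)
  Gbg <- G[ng + seq_along(bad), seq_len(ng), drop = FALSE]
  A <- rbind(cbind(Ggg, 1), c(rep(1, ng), 0))
  V <- rec$signal[match(good, rec$channel_names), , drop = FALSE]
  sol <- solve(A, rbind(V, 0))
  interp <- Gbg %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1L, ], length(bad), ncol(V), byrow = TRUE)
  rec$signal[match(bad, rec$channel_names), ] <- interp
  rec
}

## ---- epoching ------------------------------------------------------------

new_epochs <- function(data, rate, tmin, tmax, channel_names, roles, labels,
                       is_deviant, trial_index) {
  n_t <- dim(data)[3]
  structure(list(data = data, rate = rate, tmin = tmin, tmax = tmax,
                 times = tmin + (seq_len(n_t) - 1) / rate,
                 channel_names = channel_names, roles = roles,
                 labels = labels, is_deviant = is_deviant,
                 trial_index = trial_index,
                 kept_mask = rep(TRUE, dim(data)[1]),
                 reject_reason = rep(NA_character_, dim(data)[1])),
            class = "mmn_epochs")
}

#' @export
print.mmn_epochs <- function(x, ...) {
  cat(sprintf("<mmn_epochs> %d trials (%d kept) x %d ch x %d samples [%g, %g) s @ %g Hz\n",
              dim(x$data)[1], sum(x$kept_mask), dim(x$data)[2],
              dim(x$data)[3], x$tmin, x$tmax, x$rate))
  invisible(x)
}

#' Segment a recording into analysis epochs
#'
#' Cuts per-trial segments on the half-open sample grid `[tmin, tmax)`
#' (`round((tmax - tmin) * rate)` samples, the `t = 0` sample included).
#' Time zero is the event marker shifted forward by `trigger_shift`
#' (compensating the stimulus delivery delay) and, for deviant trials,
#' additionally by `divergence_offset` so deviants are locked to the point
#' of acoustic divergence. Habituation and post-deviant-standard trials are
#' excluded; trials whose window leaves the recording are dropped with a
#' logged reason.
#'
#' @param rec an `mmn_recording` with flagged events.
#' @param tmin,tmax epoch limits in seconds (defaults -0.050 and 0.800).
#' @param trigger_shift seconds added to every trigger (default +0.025).
#' @param divergence_offset seconds from deviant onset to the acoustic
#'   divergence point (default 0.625).
#' @param include_excluded keep habituation/post-deviant trials (default
#'   FALSE).
#' @return An `mmn_epochs` object (with a `dropped` attribute listing
#'   out-of-bounds trials, if any).
#' @export
epoch_recording <- function(rec, tmin = -0.050, tmax = 0.800,
                            trigger_shift = 0.025, divergence_offset = 0.625,
                            include_excluded = FALSE) {
  stopifnot(inherits(rec, "mmn_recording"), tmax > tmin)
  ev <- rec$events
  use <- if (include_excluded) rep(TRUE, nrow(ev)) else
    !(ev$is_habituation | ev$is_post_deviant)
  ev <- ev[use, , drop = FALSE]
  n_t <- as.integer(round((tmax - tmin) * rec$rate))
  n_ch <- nrow(rec$signal)
  t0 <- ev$sample + as.integer(round(trigger_shift * rec$rate)) +
    ifelse(ev$is_deviant, as.integer(round(divergence_offset * rec$rate)), 0L)
  start <- t0 + as.integer(round(tmin * rec$rate))
  ok <- start >= 1L & (start + n_t - 1L) <= ncol(rec$signal)
  dropped <- data.frame(trial = which(use)[!ok],
                        reason = rep("window outside recording", sum(!ok)))
  ev <- ev[ok, , drop = FALSE]; start <- start[ok]
  data <- array(0, c(nrow(ev), n_ch, n_t))
  for (i in seq_len(nrow(ev)))
    data[i, , ] <- rec$signal[, start[i] + seq_len(n_t) - 1L]
  ep <- new_epochs(data, rec$rate, tmin, tmax, rec$channel_names, rec$roles,
                   ev$label, ev$is_deviant, which(use)[ok])
  attr(ep, "dropped") <- dropped
  ep
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (half-open, default the 50 ms before time zero); afterwards the
#' baseline-window mean is exactly zero.
#'
#' @param ep an `mmn_epochs`.
#' @param window `c(lo, hi)` in seconds, with `lo >= tmin` and `hi <= 0`.
#' @return The corrected epochs.
#' @export
baseline_correct <- function(ep, window = c(-0.050, 0)) {
  stopifnot(inherits(ep, "mmn_epochs"))
  if (window[1] < ep$tmin - 1e-9 || window[2] > 1e-9)
    stop("config error: baseline window must lie within [tmin, 0]",
         call. = FALSE)
  sel <- in_window(ep$times, window)
  if (!any(sel)) stop("config error: empty baseline window", call. = FALSE)
  bl <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(bl)  # recycles over the 3rd dimension
  ep
}

#' Reject epochs by amplitude range and sample-to-sample jumps
#'
#' A trial is rejected if and only if any in-scope channel has a
#' maximum-minus-minimum range strictly above `maxmin` or any
#' consecutive-sample difference strictly above `jump` (both boundaries
#' exclusive). Scope is EEG channels only: ocular channels carry blinks by
#' design and are handled by component screening, not epoch rejection.
#'
#' @param ep an `mmn_epochs`.
#' @param maxmin range threshold in microvolts (default 120).
#' @param jump consecutive-sample difference threshold in microvolts
#'   (default 25).
#' @return The epochs with `kept_mask` and `reject_reason` updated.
#' @export
reject_artifacts <- function(ep, maxmin = 120, jump = 25) {
  stopifnot(inherits(ep, "mmn_epochs"), maxmin > 0, jump > 0)
  scope <- which(ep$roles == "EEG")
  for (i in which(ep$kept_mask)) {
    x <- matrix(ep$data[i, scope, ], nrow = length(scope))
    rng <- apply(x, 1, function(v) max(v) - min(v))
    if (any(rng > maxmin)) {
      ep$kept_mask[i] <- FALSE
      ep$reject_reason[i] <- "range"
      next
    }
    dmax <- max(abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]))
    if (dmax > jump) {
      ep$kept_mask[i] <- FALSE
      ep$reject_reason[i] <- "jump"
    }
  }
  ep
}

## ---- averaging -----------------------------------------------------------

new_erp <- function(data, rate, tmin, tmax, channel_names, condition,
                    n_trials) {
  structure(list(data = data, rate = rate, tmin = tmin, tmax = tmax,
                 times = tmin + (seq_len(ncol(data)) - 1) / rate,
                 channel_names = channel_names, condition = condition,
                 n_trials = n_trials),
            class = "mmn_erp")
}

#' @export
print.mmn_erp <- function(x, ...) {
  cat(sprintf("<mmn_erp> '%s': %d ch x %d samples, %d trials\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Average kept epochs of one condition into an ERP
#'
#' @param ep an `mmn_epochs`.
#' @param condition trial label to average.
#' @return An `mmn_erp` (channels x samples mean, trial count recorded).
#' @export
average_erp <- function(ep, condition) {
  stopifnot(inherits(ep, "mmn_epochs"))
  sel <- which(ep$kept_mask & ep$labels == condition)
  if (length(sel) == 0)
    stop("QC error: no kept trials for condition '", condition, "'",
         call. = FALSE)
  m <- apply(ep$data[sel, , , drop = FALSE], c(2, 3), mean)
  new_erp(m, ep$rate, ep$tmin, ep$tmax, ep$channel_names, condition,
          length(sel))
}

#' Deviant-minus-standard difference waveform
#'
#' Computes the mismatch-negativity difference wave for display and quality
#' control; the inferential statistics run on the unsubtracted deviant ERPs.
#'
#' @param deviant,standard `mmn_erp` objects on the same grid.
#' @return An `mmn_erp` holding the samplewise difference.
#' @export
compute_mmn <- function(deviant, standard) {
  stopifnot(inherits(deviant, "mmn_erp"), inherits(standard, "mmn_erp"))
  if (deviant$rate != standard$rate ||
      !identical(dim(deviant$data), dim(standard$data)) ||
      !identical(deviant$channel_names, standard$channel_names))
    stop("input error: ERP grids do not match", call. = FALSE)
  out <- deviant
  out$data <- deviant$data - standard$data
  out$condition <- paste0(deviant$condition, "-", standard$condition)
  out
}
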