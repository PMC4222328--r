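#' Plus-minus (polarity-flip) noise estimate
#'
#' Pools the kept deviant epochs in chronological order, sign-flips every
#' second one (even chronological indices, a deterministic, seed-free
#' choice), and averages flipped and unflipped epochs together. Since the
#' stimulus-locked signal is assumed constant across trials, it cancels and
#' the average estimates the residual noise of the ERP. An odd epoch is
#' dropped from the end so the two halves are balanced (logged via the
#' `n_dropped` attribute).
#'
#' @param ep an `mmn_epochs`; all kept deviant trials are pooled.
#' @return Channels x samples noise waveform (matrix) with attributes
#'   `n_epochs` and `n_dropped`.
#' @export
polarity_flip_noise <- function(ep) {
  stopifnot(inherits(ep, "mmn_epochs"))
  sel <- which(ep$kept_mask & ep$is_deviant)
  if (length(sel) < 2)
    stop("QC error: need at least 2 kept deviant epochs", call. = FALSE)
  dropped <- length(sel) %% 2L
  if (dropped) sel <- sel[-length(sel)]
  signs <- rep_len(c(-1, 1), length(sel))  # flip even chronological indices
  acc <- matrix(0, dim(ep$data)[2], dim(ep$data)[3])
  for (i in seq_along(sel)) acc <- acc + signs[i] * ep$data[sel[i], , ]
  out <- acc / length(sel)
  attr(out, "n_epochs") <- length(sel)
  attr(out, "n_dropped") <- dropped
  out
}

#' RMS signal-to-noise statistic
#'
#' Averages the signal ERP and the noise waveform over the ROI channels
#' first, then takes the root-mean-square over the (half-open) window for
#' each; the SNR is their ratio. The alternative ordering (per-channel RMS,
#' then ROI average) is available via `per_channel_rms = TRUE`.
#'
#' @param signal_erp an `mmn_erp` (typically the pooled-deviant average).
#' @param noise channels x samples noise waveform on the same grid.
#' @param window `c(lo, hi)` seconds, default `c(0.100, 0.200)` (100-200 ms
#'   after acoustic deviance).
#' @param roi character vector of ROI channel names.
#' @param per_channel_rms take RMS per channel before averaging (default
#'   FALSE).
#' @return List `snr`, `signal_rms`, `noise_rms` (microvolts). A zero noise
#'   RMS yields `snr = Inf` with a warning.
#' @export
snr_statistic <- function(signal_erp, noise, window = c(0.100, 0.200), roi,
                          per_channel_rms = FALSE) {
  stopifnot(inherits(signal_erp, "mmn_erp"), length(roi) >= 1)
  if (!all(roi %in% signal_erp$channel_names))
    stop("config error: ROI channel(s) missing from ERP", call. = FALSE)
  sel <- in_window(signal_erp$times, window)
  if (!any(sel)) stop("config error: window outside epoch span", call. = FALSE)
  i <- match(roi, signal_erp$channel_names)
  rms <- function(x) sqrt(mean(x^2))
  wrms <- function(mat) {
    if (per_channel_rms) mean(apply(mat[i, sel, drop = FALSE], 1, rms))
    else rms(colMeans(mat[i, sel, drop = FALSE]))
  }
  s <- wrms(signal_erp$data)
  n <- wrms(noise)
  if (n == 0) {
    warning("noise RMS is zero; SNR reported as +Inf")
    return(list(snr = Inf, signal_rms = s, noise_rms = n))
  }
  list(snr = s / n, signal_rms = s, noise_rms = n)
}

#' Build a participant QC record
#'
#' @param subject_id subject identifier.
#' @param snr,signal_rms,noise_rms values from [snr_statistic()].
#' @param external_flags character vector of externally supplied exclusion
#'   flags (e.g. `"muscle-artifact"`), mirroring by-eye judgments.
#' @return A one-row data.frame with the exclusion decision applied:
#'   excluded iff `snr < 1` (strict) or `signal_rms < 1` microvolt (strict)
#'   or any external flag.
#' @export
qc_record <- function(subject_id, snr, signal_rms, noise_rms,
                      external_flags = character(0)) {
  reason <- c(if (snr < 1) "snr<1",
              if (signal_rms < 1) "signal<1uV",
              external_flags)
  data.frame(subject = subject_id, snr = snr, signal_rms = signal_rms,
             noise_rms = noise_rms,
             flags = paste(external_flags, collapse = ";"),
             excluded = length(reason) > 0,
             reason = paste(reason, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Apply the participant exclusion rules
#'
#' A subject is excluded if and only if `snr < 1` (strict), `signal_rms <
#' 1` microvolt (strict), or any external flag is set; boundary values
#' (SNR exactly 1, signal exactly 1 microvolt) are retained.
#'
#' @param records data.frame of rows from [qc_record()] (or equivalent
#'   columns `subject`, `snr`, `signal_rms`, `flags`).
#' @return List `retained` (subset of records), `excluded` (subset), and
#'   `report` (all records with decisions).
#' @export
exclude_participants <- function(records) {
  if (NROW(records) == 0)
    return(list(retained = records, excluded = records, report = records))
  flags <- if (is.null(records$flags)) rep("", nrow(records)) else
    ifelse(is.na(records$flags), "", records$flags)
  out <- records$snr < 1 | records$signal_rms < 1 | nzchar(flags)
  reason <- mapply(function(s, g, f) paste(
    c(if (s < 1) "snr<1", if (g < 1) "signal<1uV",
      if (nzchar(f)) strsplit(f, ";")[[1]]), collapse = ";"),
    records$snr, records$signal_rms, flags)
  records$excluded <- out
  records$reason <- reason
  list(retained = records[!out, , drop = FALSE],
       excluded = records[out, , drop = FALSE],
       report = records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a QC report to CSV
#'
#' @param report the `report` element from [exclude_participants()].
#' @param path output CSV path.
#' @export
write_qc_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
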