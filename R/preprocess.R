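#' Raw multichannel sensor recording
#'
#' @param samples channels x time numeric matrix.
#' @param sampling_rate_hz sampling rate (> 0).
#' @param channel_names unique channel labels, one per row.
#' @param event_markers data.frame with columns `time_s` (marker times,
#'   within the recording) and `spike_type` (character); typically the peaks
#'   of visually marked interictal discharges.
#' @return Object of class `sensor_recording`.
#' @export
sensor_recording <- function(samples, sampling_rate_hz, channel_names,
                             event_markers = NULL) {
  samples <- as.matrix(samples)
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0")
  if (length(channel_names) != nrow(samples)) {
    stop("channel_names must match rows of samples")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (is.null(event_markers)) {
    event_markers <- data.frame(time_s = numeric(0), spike_type = character(0))
  }
  dur <- ncol(samples) / sampling_rate_hz
  if (nrow(event_markers) &&
      (any(event_markers$time_s < 0) || any(event_markers$time_s > dur))) {
    stop("event marker times fall outside the recording")
  }
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 channel_names = channel_names, event_markers = event_markers),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("sensor_recording:", nrow(x$samples), "channels x", ncol(x$samples),
      sprintf("samples @ %g Hz, %d markers\n", x$sampling_rate_hz,
              nrow(x$event_markers)))
  invisible(x)
}

#' Condition a sensor recording
#'
#' DC-offset removal, zero-phase line-frequency notch and bandpass
#' filtering, and resampling to a target rate. Filters are Butterworth
#' sections applied forward-backward (`signal::filtfilt`), so the output is
#' zero-phase and marker times remain valid.
#'
#' @param rec a [sensor_recording()].
#' @param notch_hz line frequency to suppress (default 60; `NA` disables).
#' @param band_hz length-2 bandpass edges in Hz (default `c(0.3, 70)`;
#'   `NULL` disables). The high edge must be below the Nyquist frequency of
#'   the target rate.
#' @param target_rate_hz output sampling rate (default 600).
#' @return A conditioned [sensor_recording()] at `target_rate_hz`.
#' @export
condition_recording <- function(rec, notch_hz = 60, band_hz = c(0.3, 70),
                                target_rate_hz = 600) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (!is.null(band_hz) && band_hz[2L] >= target_rate_hz / 2) {
    stop("bandpass high edge must be below the target Nyquist frequency")
  }
  x <- rec$samples - rowMeans(rec$samples)     # DC removal
  fs <- rec$sampling_rate_hz
  nyq <- fs / 2
  if (!is.null(notch_hz) && !is.na(notch_hz)) {
    bw <- 2                                    # +/- 2 Hz stop band
    ns <- signal::butter(2, c(notch_hz - bw, notch_hz + bw) / nyq,
                         type = "stop")
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(ns, ch)))
  }
  if (!is.null(band_hz)) {
    bp <- signal::butter(2, band_hz / nyq, type = "pass")
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(bp, ch)))
  }
  if (!isTRUE(all.equal(fs, target_rate_hz))) {
    frac <- .rate_fraction(target_rate_hz, fs)
    x <- t(apply(x, 1L, function(ch) {
      as.numeric(signal::resample(ch, frac[1L], frac[2L]))
    }))
  }
  sensor_recording(x, target_rate_hz, rec$channel_names, rec$event_markers)
}

.rate_fraction <- function(p, q) {
  # small integer ratio p/q
  for (k in 1:1000) {
    pk <- p * k / q
    if (abs(pk - round(pk)) < 1e-9) return(c(as.integer(round(pk)), k))
  }
  stop("cannot express rate ratio ", p, "/", q, " as a small fraction")
}

#' Epoch a recording around spike markers and average
#'
#' Cuts 2 s epochs around each marker of the requested spike type using the
#' half-open window \[-1 s, +1 s) — exactly `2 * rate` samples with the
#' marker peak at index `rate + 1` (1-based) — and averages them. Epochs
#' that are not fully inside the recording, or that overlap a declared
#' artifact interval, are excluded. Fewer than `min_epochs` usable epochs
#' rejects the study.
#'
#' @param rec a conditioned [sensor_recording()].
#' @param spike_type which marker type to average.
#' @param artifact_intervals optional data.frame with `start_s`, `end_s`
#'   rows; epochs intersecting any interval are dropped.
#' @param min_epochs minimum usable epochs (default 5, the standard clinical
#'   exclusion bound).
#' @param patient_id,study_id identifiers carried into the result.
#' @return Object of class `averaged_study`: `average` (channels x
#'   `2*rate`), `peak_index`, `n_epochs`, `spike_type`, `sampling_rate_hz`,
#'   `baseline_window` (seconds relative to the peak), ids.
#' @export
epoch_and_average <- function(rec, spike_type, artifact_intervals = NULL,
                              min_epochs = 5L, patient_id = NA_character_,
                              study_id = NA_character_) {
  stopifnot(inherits(rec, "sensor_recording"))
  fs <- rec$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("sampling rate must be an integer for epoching")
  fs <- as.integer(round(fs))
  mk <- rec$event_markers
  times <- mk$time_s[mk$spike_type == spike_type]
  if (length(times) < min_epochs) {
    stop("study rejected [too_few_spikes]: ", length(times), " markers of type '",
         spike_type, "' (minimum ", min_epochs, ")")
  }
  n_t <- ncol(rec$samples)
  half <- fs                      # samples per second
  kept <- list()
  for (tt in times) {
    peak <- round(tt * fs) + 1L   # 1-based sample of the marker
    i0 <- peak - half             # window [-1, +1): i0 .. i0 + 2*fs - 1
    i1 <- i0 + 2L * half - 1L
    if (i0 < 1L || i1 > n_t) next
    if (!is.null(artifact_intervals) && nrow(artifact_intervals)) {
      w0 <- (i0 - 1L) / fs; w1 <- i1 / fs
      hit <- any(artifact_intervals$start_s < w1 & artifact_intervals$end_s > w0)
      if (hit) next
    }
    kept[[length(kept) + 1L]] <- rec$samples[, i0:i1, drop = FALSE]
  }
  if (length(kept) < min_epochs) {
    stop("study rejected [too_few_usable_epochs]: ", length(kept),
         " usable epochs (minimum ", min_epochs, ")")
  }
  avg <- Reduce(`+`, kept) / length(kept)
  structure(list(average = avg, peak_index = half + 1L,
                 n_epochs = length(kept), spike_type = spike_type,
                 sampling_rate_hz = fs,
                 baseline_window = c(-1.0, -0.1),
                 channel_names = rec$channel_names,
                 patient_id = patient_id, study_id = study_id),
            class = "averaged_study")
}

#' @export
print.averaged_study <- function(x, ...) {
  cat(sprintf("averaged_study %s/%s: %d epochs of type '%s', %d channels @ %g Hz\n",
              x$patient_id, x$study_id, x$n_epochs, x$spike_type,
              nrow(x$average), x$sampling_rate_hz))
  invisible(x)
}

#' Baseline noise covariance of an averaged study
#'
#' Sample covariance of the averaged signal over a spike-free baseline
#' window, with diagonal loading for numerical rank safety. The default
#' window is \[-1.0, -0.1) s relative to the peak: within the epoch and
#' guarded away from peri-spike activity.
#'
#' @param study an [averaged_study()], or a channels x samples baseline
#'   matrix.
#' @param baseline_window length-2 window in seconds relative to the peak
#'   (used when `study` is an `averaged_study`).
#' @param loading diagonal loading as a fraction of the mean diagonal
#'   (default 0.1); 0 disables regularization.
#' @return Object of class `noise_covariance`: `values` (channels x
#'   channels, symmetric positive definite after loading),
#'   `regularization_applied`, `n_samples`.
#' @export
estimate_noise_covariance <- function(study, baseline_window = NULL,
                                      loading = 0.1) {
  if (inherits(study, "averaged_study")) {
    bw <- baseline_window %||% study$baseline_window
    fs <- study$sampling_rate_hz
    i0 <- study$peak_index + as.integer(round(bw[1L] * fs))
    i1 <- study$peak_index + as.integer(round(bw[2L] * fs)) - 1L
    if (i0 < 1L || i1 > ncol(study$average)) stop("baseline window outside epoch")
    x <- study$average[, i0:i1, drop = FALSE]
  } else {
    x <- as.matrix(study)
  }
  n_ch <- nrow(x)
  n_s <- ncol(x)
  if (n_s < n_ch && loading <= 0) {
    stop("baseline has fewer samples (", n_s, ") than channels (", n_ch,
         "); enable diagonal loading")
  }
  xc <- x - rowMeans(x)
  cv <- tcrossprod(xc) / (n_s - 1L)
  if (loading <= 0 && any(diag(cv) == 0)) {
    stop("zero-variance channel in baseline and no regularization")
  }
  if (loading > 0) {
    cv <- cv + diag(loading * mean(diag(cv)), n_ch)
  }
  cv <- (cv + t(cv)) / 2
  structure(list(values = cv, regularization_applied = loading,
                 n_samples = n_s), class = "noise_covariance")
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat("noise_covariance:", nrow(x$values), "channels,",
      x$n_samples, "baseline samples, loading", x$regularization_applied, "\n")
  invisible(x)
}
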