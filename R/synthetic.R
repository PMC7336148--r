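#' Specification of a synthetic interictal-spike cohort
#'
#' Bundles the parameters of the synthetic cohort generator: a cohort of
#' patients, each with a focal cortical generator (a contiguous patch), and
#' several "studies" per patient — recordings containing repeated
#' interictal spikes that are later epoched and averaged. Defaults emulate
#' the structure of a clinical MEG cohort: 28 patients contributing about
#' 206 studies in total, 275 sensors, 600 Hz, focal patches of 10 mm
#' radius.
#'
#' @param n_patients number of patients (default 28).
#' @param mean_studies_per_patient mean of the truncated-geometric
#'   studies-per-patient distribution (default 7.36, so the expected total
#'   is about 206).
#' @param max_studies_per_patient truncation bound (default 25).
#' @param studies_per_patient optional fixed number of studies for every
#'   patient; overrides the geometric draw when not `NULL`.
#' @param focus_radius_mm radius of the ground-truth patch (default 10).
#' @param spike_amplitude peak source amplitude at the patch centre, in the
#'   (arbitrary but consistent) source units of the gain matrix
#'   (default 10).
#' @param snr target signal-to-noise ratio of each simulated recording:
#'   RMS of the noiseless sensor signal within +/-25 ms of spike peaks over
#'   the RMS of the added sensor noise (default 5).
#' @param n_epochs_per_study spikes per study (default 20; at least 5).
#' @param sampling_rate_hz sampling rate (default 600).
#' @param n_sensors channel count (default 275).
#' @param mesh_vertices source-space size (default 8000; use 2000 for
#'   desk-scale runs).
#' @param master_seed integer seed from which all per-study seeds derive.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 28L,
                        mean_studies_per_patient = 7.36,
                        max_studies_per_patient = 25L,
                        studies_per_patient = NULL,
                        focus_radius_mm = 10,
                        spike_amplitude = 10,
                        snr = 5,
                        n_epochs_per_study = 20L,
                        sampling_rate_hz = 600L,
                        n_sensors = 275L,
                        mesh_vertices = 8000L,
                        master_seed = 1L) {
  stopifnot(n_patients >= 1, mean_studies_per_patient >= 1,
            focus_radius_mm > 0, spike_amplitude > 0,
            n_epochs_per_study >= 5, sampling_rate_hz > 0,
            n_sensors >= 1, mesh_vertices >= 12)
  if (snr <= 0) stop("snr must be > 0")
  structure(list(n_patients = as.integer(n_patients),
                 mean_studies_per_patient = mean_studies_per_patient,
                 max_studies_per_patient = as.integer(max_studies_per_patient),
                 studies_per_patient = if (is.null(studies_per_patient))
                   NULL else as.integer(studies_per_patient),
                 focus_radius_mm = focus_radius_mm,
                 spike_amplitude = spike_amplitude, snr = snr,
                 n_epochs_per_study = as.integer(n_epochs_per_study),
                 sampling_rate_hz = as.integer(sampling_rate_hz),
                 n_sensors = as.integer(n_sensors),
                 mesh_vertices = as.integer(mesh_vertices),
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("cohort_spec: %d patients, ~%.1f studies each, ",
                     "%d-vertex mesh, %d sensors @ %d Hz, SNR %g, seed %d\n"),
              x$n_patients, x$mean_studies_per_patient, x$mesh_vertices,
              x$n_sensors, x$sampling_rate_hz, x$snr, x$master_seed))
  invisible(x)
}

# canonical biphasic spike: central positive lobe with flanking negativity
# (difference of Gaussians), peak exactly at t = 0, total duration ~70 ms
.spike_waveform <- function(t_s, tau_s = 0.009) {
  core <- exp(-t_s^2 / (2 * tau_s^2)) - 0.5 * exp(-t_s^2 / (2 * (2 * tau_s)^2))
  core / 0.5                                # unit peak at t = 0
}

#' Simulate one spike study as a raw sensor recording
#'
#' Places `n_epochs` biphasic spikes (~70 ms, unit peak at the marker time)
#' on the focus vertices with amplitude tapering from the patch seed
#' (Gaussian taper, scale half the patch radius), projects them through the
#' gain matrix, and adds independent white sensor noise scaled to the
#' target SNR (signal RMS within +/-25 ms of peaks over noise RMS). Spike
#' times are jittered around a regular 3 s grid; markers record the true
#' peaks.
#'
#' @param focus a [focus_region()].
#' @param gain a `gain_matrix`.
#' @param mesh the [cortical_mesh()].
#' @param spec a [cohort_spec()].
#' @param seed_vertex the patch seed vertex (amplitude taper origin);
#'   defaults to the first focus vertex.
#' @param spike_type marker label (default `"type1"`).
#' @return A [sensor_recording()] with one marker per simulated spike.
#' @export
simulate_study <- function(focus, gain, mesh, spec,
                           seed_vertex = focus$vertex_ids[1L],
                           spike_type = "type1") {
  if (spec$snr <= 0) stop("snr must be > 0")
  fs <- spec$sampling_rate_hz
  n_ep <- spec$n_epochs_per_study
  spacing <- 3
  dur_s <- spacing * n_ep + 2
  n_t <- as.integer(dur_s * fs)
  # spike peak times: 3 s grid, +/-0.4 s uniform jitter, snapped to samples
  peaks_s <- spacing * seq_len(n_ep) + stats::runif(n_ep, -0.4, 0.4)
  peaks_s <- round(peaks_s * fs) / fs
  # amplitude taper from the seed vertex over the patch
  dseed <- sqrt(colSums((t(mesh$vertices[focus$vertex_ids, , drop = FALSE]) -
                           mesh$vertices[seed_vertex, ])^2))
  amp <- spec$spike_amplitude * exp(-dseed^2 / (2 * (spec$focus_radius_mm / 2)^2))
  # per-sensor clean signal: sum over spikes of waveform x (gain %*% amp)
  topo <- as.vector(gain$values[, focus$vertex_ids, drop = FALSE] %*% amp)
  tgrid <- (seq_len(n_t) - 1L) / fs
  drive <- numeric(n_t)
  for (pk in peaks_s) {
    ix <- which(abs(tgrid - pk) <= 0.06)
    drive[ix] <- drive[ix] + .spike_waveform(tgrid[ix] - pk)
  }
  clean <- tcrossprod(topo, drive)
  # noise scaled to the peri-peak SNR definition
  peri <- unique(unlist(lapply(peaks_s, function(pk)
    which(abs(tgrid - pk) <= 0.025))))
  sig_rms <- sqrt(mean(clean[, peri]^2))
  sigma <- sig_rms / spec$snr
  noisy <- clean + matrix(stats::rnorm(length(clean), 0, sigma),
                          nrow(clean), ncol(clean))
  sensor_recording(noisy, fs, gain$channel_names,
                   data.frame(time_s = peaks_s, spike_type = spike_type))
}

#' Generate a full synthetic cohort
#'
#' Builds the shared anatomy (cortex-like mesh, helmet sensor array,
#' spherical gain), then per patient draws a focal patch seeded at a
#' magnetically visible vertex (tangential gain-column norm above the
#' median) and per study simulates a spike recording. Every random draw
#' derives from `spec$master_seed`, so the cohort is reproducible
#' bit-for-bit; studies get independent child seeds.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `dmsi_cohort`: `mesh`, `sensors`, `gain`,
#'   `adjacency`, `patients` (list with `patient_id`, `focus`,
#'   `seed_vertex`, `study_seeds`), `spec`. Recordings are generated lazily
#'   by [cohort_recording()] to keep memory bounded.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  mesh <- mesh_sphere(spec$mesh_vertices)
  if (spec$focus_radius_mm > 2 * max(sqrt(rowSums(mesh$vertices^2)))) {
    stop("focus radius exceeds the mesh extent")
  }
  sensors <- sensor_array(spec$n_sensors)
  gain <- spherical_meg_gain(mesh, sensors)
  adjacency <- build_adjacency(mesh)
  cn <- sqrt(colSums(gain$values^2))
  visible <- which(cn > stats::median(cn))
  set.seed(spec$master_seed)
  # studies per patient: fixed, or geometric (shifted to >= 1), truncated
  n_studies <- if (!is.null(spec$studies_per_patient)) {
    rep(spec$studies_per_patient, spec$n_patients)
  } else {
    pmin(stats::rgeom(spec$n_patients,
                      1 / spec$mean_studies_per_patient) + 1L,
         spec$max_studies_per_patient)
  }
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    seed_vertex <- sample(visible, 1L)
    focus <- grow_patch(mesh, seed_vertex, spec$focus_radius_mm,
                        adjacency = adjacency,
                        label = sprintf("focus_P%02d", i))
    study_seeds <- sample.int(.Machine$integer.max - 1L, n_studies[i])
    patients[[i]] <- list(patient_id = sprintf("P%02d", i), focus = focus,
                          seed_vertex = seed_vertex,
                          study_seeds = study_seeds)
  }
  structure(list(mesh = mesh, sensors = sensors, gain = gain,
                 adjacency = adjacency, patients = patients, spec = spec),
            class = "dmsi_cohort")
}

#' @export
print.dmsi_cohort <- function(x, ...) {
  n_st <- sum(vapply(x$patients, function(p) length(p$study_seeds), 0L))
  cat(sprintf("dmsi_cohort: %d patients, %d studies, %d-vertex mesh, %d sensors\n",
              length(x$patients), n_st, nrow(x$mesh$vertices),
              length(x$sensors$names)))
  invisible(x)
}

#' Materialize one study's recording from a cohort
#'
#' Re-simulates the recording of patient `i_patient`, study `i_study` from
#' its stored child seed — deterministic for a fixed cohort.
#'
#' @param cohort a [generate_cohort()] result.
#' @param i_patient,i_study indices into the cohort.
#' @return A [sensor_recording()].
#' @export
cohort_recording <- function(cohort, i_patient, i_study) {
  pat <- cohort$patients[[i_patient]]
  if (i_study > length(pat$study_seeds)) stop("study index out of range")
  set.seed(pat$study_seeds[i_study])
  simulate_study(pat$focus, cohort$gain, cohort$mesh, cohort$spec,
                 seed_vertex = pat$seed_vertex)
}
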