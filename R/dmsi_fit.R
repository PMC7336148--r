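#' Fit a distributed source imaging model to an averaged study
#'
#' The central fitting function: estimates a cortical source map at the
#' spike peak of an averaged study with one of the four distributed
#' inverse methods. Linear methods (`"MNE"`, `"dSPM"`, `"sLORETA"`) share a
#' depth-weighted minimum-norm kernel; `"cMEM"` fits the
#' maximum-entropy-on-the-mean parcel model. Returns a classed object with
#' the usual accessor methods (`print`, `summary`, `coef`, `fitted`,
#' `residuals`, `plot`).
#'
#' @param study an [epoch_and_average()] result (or a raw sensor data
#'   vector at the peak).
#' @param gain a `gain_matrix`.
#' @param noise_cov a `noise_covariance`; when `NULL` and `study` is an
#'   `averaged_study`, it is estimated from the study baseline.
#' @param method `"MNE"`, `"dSPM"`, `"sLORETA"` or `"cMEM"`.
#' @param mesh the [cortical_mesh()]; required for `"cMEM"`.
#' @param depth_exponent,snr minimum-norm kernel parameters (see
#'   [build_wmne_kernel()]).
#' @param adjacency optional precomputed adjacency (cMEM only).
#' @param ... further arguments passed to [solve_cmem()].
#' @return Object of class `dmsi`: the source map plus fit diagnostics.
#' @examples
#' mesh <- mesh_sphere(200)
#' sens <- sensor_array(60)
#' gain <- spherical_meg_gain(mesh, sens)
#' m <- gain$values[, 17] + rnorm(60, 0, 1e-14)
#' fit <- dmsi(m, gain, diag(1e-28, 60), method = "sLORETA")
#' which.max(coef(fit))
#' @export
dmsi <- function(study, gain, noise_cov = NULL,
                 method = c("MNE", "dSPM", "sLORETA", "cMEM"), mesh = NULL,
                 depth_exponent = 0.5, snr = 3, adjacency = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(gain, "gain_matrix"))
  if (is.null(noise_cov)) {
    if (!inherits(study, "averaged_study")) {
      stop("noise_cov is required when study is a raw data vector")
    }
    noise_cov <- estimate_noise_covariance(study)
  }
  cv <- if (inherits(noise_cov, "noise_covariance")) noise_cov$values else
    as.matrix(noise_cov)
  m_peak <- .peak_data(study)
  if (method == "cMEM") {
    if (is.null(mesh)) stop("cMEM requires the mesh")
    model <- parcellate_cortex(mesh, gain, study, C = cv,
                               adjacency = adjacency)
    map <- solve_cmem(model, gain, cv, study, mesh, adjacency = adjacency,
                      depth_exponent = depth_exponent, snr = snr, ...)
    j_signed <- attr(map, "posterior_mean")
    kernel <- NULL
  } else {
    kernel <- build_wmne_kernel(gain, cv, depth_exponent = depth_exponent,
                                snr = snr)
    map <- switch(method,
                  MNE = solve_mne(kernel, study),
                  dSPM = solve_dspm(kernel, cv, study),
                  sLORETA = solve_sloreta(kernel, gain, study))
    j_signed <- as.vector(kernel$kernel %*% m_peak)
    model <- NULL
  }
  fitted_sensors <- as.vector(gain$values %*% j_signed)
  structure(list(map = map, method = method, data = m_peak,
                 fitted_sensors = fitted_sensors,
                 residual_sensors = m_peak - fitted_sensors,
                 j_signed = j_signed, kernel = kernel, parcel_model = model,
                 noise_cov = noise_cov, n_sources = ncol(gain$values),
                 n_channels = nrow(gain$values)),
            class = "dmsi")
}

#' @export
print.dmsi <- function(x, ...) {
  cat(sprintf("dmsi fit [%s]: %d sources from %d channels; map maximum %.3g at vertex %d\n",
              x$method, x$n_sources, x$n_channels, max(x$map$amplitudes),
              which.max(x$map$amplitudes)))
  invisible(x)
}

#' @export
summary.dmsi <- function(object, n_top = 5L, ...) {
  a <- object$map$amplitudes
  top <- order(a, decreasing = TRUE)[seq_len(min(n_top, length(a)))]
  out <- list(method = object$method,
              top_vertices = data.frame(vertex = top, amplitude = a[top]),
              residual_norm = sqrt(sum(object$residual_sensors^2)),
              data_norm = sqrt(sum(object$data^2)),
              lambda = object$kernel$lambda,
              n_parcels_on = if (!is.null(attr(object$map, "parcel_active")))
                sum(attr(object$map, "parcel_active") >= 1e-3) else NA_integer_)
  class(out) <- "summary.dmsi"
  out
}

#' @export
print.summary.dmsi <- function(x, ...) {
  cat(sprintf("dmsi fit [%s]\n", x$method))
  cat(sprintf("  sensor-space residual/data norm: %.3g / %.3g\n",
              x$residual_norm, x$data_norm))
  if (!is.null(x$lambda)) cat(sprintf("  regularization lambda: %.4g\n", x$lambda))
  if (!is.na(x$n_parcels_on)) cat(sprintf("  parcels on: %d\n", x$n_parcels_on))
  cat("  top vertices:\n")
  print(x$top_vertices, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dmsi <- function(object, ...) object$map$amplitudes

#' @export
fitted.dmsi <- function(object, ...) object$fitted_sensors

#' @export
residuals.dmsi <- function(object, ...) object$residual_sensors

#' @export
plot.dmsi <- function(x, ...) {
  a <- x$map$amplitudes
  graphics::plot(a, type = "h", xlab = "vertex", ylab = "amplitude",
                 main = sprintf("%s source map", x$method), ...)
  graphics::points(which.max(a), max(a), pch = 19, col = "red")
  invisible(x)
}

#' @export
plot.threshold_curves <- function(x, which = c("sd_mm", "size_vertices",
                                               "map_dmin_mm"), ...) {
  which <- match.arg(which)
  ylab <- c(sd_mm = "spatial dispersion (mm)",
            size_vertices = "map size (vertices)",
            map_dmin_mm = "Map_Dmin (mm)")[which]
  graphics::plot(x$threshold_pct, x[[which]], type = "b",
                 xlab = "threshold (%)", ylab = ylab,
                 main = attr(x, "method_label"), ...)
  invisible(x)
}
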