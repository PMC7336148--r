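#' Min-max rescale a source map to \[0, 1\]
#'
#' `(v - min) / (max - min)` per vertex, so 0 means no activity and 1 the
#' map maximum. A constant map (no contrast) rescales to all zeros.
#'
#' @param map a [source_map()].
#' @return A rescaled [source_map()] (same method label).
#' @export
rescale_map <- function(map) {
  a <- map$amplitudes
  rng <- range(a)
  a <- if (diff(rng) == 0) rep(0, length(a)) else (a - rng[1L]) / diff(rng)
  out <- map
  out$amplitudes <- a
  out$units_note <- "rescaled [0,1]"
  out
}

#' Average of rescaled method maps (Ave)
#'
#' Per-vertex arithmetic mean of the input maps, each first min-max
#' rescaled. Combining the four individual methods this way tests whether a
#' consensus map localizes better than any single method.
#'
#' @param maps list of [source_map()]s on the same mesh (typically the four
#'   individual methods).
#' @return A [source_map()] labelled `"Ave"`.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 2L)
  n <- length(maps[[1L]]$amplitudes)
  if (any(vapply(maps, function(m) length(m$amplitudes), 0L) != n)) {
    stop("maps have differing vertex counts")
  }
  scaled <- lapply(maps, function(m) rescale_map(m)$amplitudes)
  source_map(Reduce(`+`, scaled) / length(scaled), "Ave",
             study_id = maps[[1L]]$study_id, units_note = "mean of rescaled maps")
}

#' Threshold a source map
#'
#' Retains vertices with amplitude `>= (t_pct/100) * max(amplitudes)` and
#' sets the rest to zero. At 100% only the maximum survives (all tied
#' maxima, if any). A vertex is *active* if it survives the threshold with
#' a strictly positive value.
#'
#' @param map a [source_map()].
#' @param t_pct threshold percentage in \[0, 100\].
#' @return A [source_map()] with sub-threshold vertices zeroed and an
#'   `active` attribute (logical vector).
#' @export
threshold_map <- function(map, t_pct) {
  if (t_pct < 0 || t_pct > 100) stop("t_pct must be in [0, 100]")
  a <- map$amplitudes
  cutoff <- (t_pct / 100) * max(a)
  keep <- a >= cutoff
  out <- map
  out$amplitudes <- ifelse(keep, a, 0)
  attr(out, "active") <- keep & a > 0
  attr(out, "threshold_pct") <- t_pct
  out
}

# argmax with deterministic lowest-index tie-break
.map_argmax <- function(map) which.max(map$amplitudes)

#' Localization error of the map maximum (Dmin)
#'
#' Euclidean distance in mm from the map's maximum-amplitude vertex to the
#' nearest vertex of the reference focus; 0 iff the maximum falls inside
#' the focus. Amplitude ties resolve to the lowest vertex index.
#'
#' @param map a [source_map()].
#' @param focus a [focus_region()].
#' @param mesh the [cortical_mesh()].
#' @return Distance in mm.
#' @export
dmin <- function(map, focus, mesh) {
  if (all(map$amplitudes == 0)) stop("Dmin undefined for an all-zero map")
  am <- .map_argmax(map)
  min(sqrt(colSums((t(mesh$vertices[focus$vertex_ids, , drop = FALSE]) -
                      mesh$vertices[am, ])^2)))
}

#' Within-group interquartile range of Dmin (reproducibility)
#'
#' For each patient x method group with at least two studies, the IQR
#' (Q3 - Q1, linear-interpolation quantiles) of the group's Dmin values.
#' Singleton groups are excluded and reported in the `excluded` attribute.
#'
#' @param dmin_mm numeric vector of Dmin values.
#' @param patient_id,method grouping vectors aligned with `dmin_mm`.
#' @return data.frame with `patient_id`, `method`, `n_studies`, `iqr_mm`;
#'   excluded singleton groups listed in `attr(,"excluded")`.
#' @export
dmin_reproducibility <- function(dmin_mm, patient_id, method) {
  stopifnot(length(dmin_mm) == length(patient_id),
            length(dmin_mm) == length(method))
  key <- interaction(patient_id, method, drop = TRUE)
  groups <- split(seq_along(dmin_mm), key)
  rows <- lapply(groups, function(ix) {
    data.frame(patient_id = patient_id[ix[1L]], method = method[ix[1L]],
               n_studies = length(ix),
               iqr_mm = if (length(ix) >= 2L) {
                 stats::IQR(dmin_mm[ix], type = 7)
               } else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excluded <- out[is.na(out$iqr_mm), c("patient_id", "method")]
  out <- out[!is.na(out$iqr_mm), , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Spatial concordance across methods (Inter-dMSI distance)
#'
#' For each method, the mean Euclidean distance between its map maximum and
#' the maxima of all the other methods' maps for the same study. Missing
#' maps are skipped with an adjusted divisor (and a warning).
#'
#' @param maxima_xyz numeric matrix, one row per method, columns x/y/z (mm);
#'   rows of `NA` mark missing methods.
#' @param methods method labels, one per row.
#' @return Named numeric vector of mean distances (mm), one per available
#'   method.
#' @export
inter_dmsi_distance <- function(maxima_xyz, methods = rownames(maxima_xyz)) {
  maxima_xyz <- as.matrix(maxima_xyz)
  ok <- stats::complete.cases(maxima_xyz)
  if (sum(ok) < 2L) stop("need maxima from at least two methods")
  if (any(!ok)) {
    warning("missing maps for: ", paste(methods[!ok], collapse = ", "),
            "; pairs skipped, divisor adjusted")
  }
  xyz <- maxima_xyz[ok, , drop = FALSE]
  dd <- as.matrix(stats::dist(xyz))
  res <- rowSums(dd) / (nrow(xyz) - 1L)
  stats::setNames(res, methods[ok])
}

#' Spatial dispersion of a source map (SD)
#'
#' Amplitude-weighted root-mean-square distance of the map's energy from
#' the reference region `theta`:
#' `SD = sqrt( sum_i d_i^2 j_i^2 / sum_i j_i^2 )`, where
#' `d_i = min_{j in theta} D_ij` is each vertex's Euclidean distance to the
#' region. In mm; low SD means a compact map centred on the focus, and high
#' SD indicates spread or mislocalized activity. For a thresholded map only
#' surviving amplitudes carry weight (zeros contribute nothing either way).
#'
#' @param map a [source_map()] (possibly thresholded).
#' @param focus a [focus_region()].
#' @param mesh the [cortical_mesh()].
#' @param dist_field optional precomputed [distance_to_region()] output.
#' @param squared return the squared quantity (mm^2) instead of its root
#'   (default `FALSE`).
#' @return SD in mm.
#' @export
spatial_dispersion <- function(map, focus, mesh, dist_field = NULL,
                               squared = FALSE) {
  a <- map$amplitudes
  if (all(a == 0)) stop("spatial dispersion undefined for an all-zero map")
  d <- dist_field %||% distance_to_region(mesh, focus)
  val <- sum(d^2 * a^2) / sum(a^2)
  if (squared) val else sqrt(val)
}

#' Number of active vertices of a thresholded map
#'
#' A vertex is active if it survived the threshold with a strictly positive
#' value; on a strictly positive unthresholded map every vertex is active,
#' and at the 100% threshold only the maximum is.
#'
#' @param map a [threshold_map()] output (an unthresholded map counts its
#'   positive vertices).
#' @return Integer count.
#' @export
map_size <- function(map) {
  act <- attr(map, "active")
  if (is.null(act)) act <- map$amplitudes > 0
  sum(act)
}

#' Distance from a binarized map to the focus (Map_Dmin)
#'
#' Minimum Euclidean distance between any active vertex of the thresholded
#' (binarized) map and the focus: unlike [dmin()] this accounts for the
#' whole extent of the imaged generator. 0 iff the active set intersects
#' the focus.
#'
#' @inheritParams spatial_dispersion
#' @return Distance in mm.
#' @export
map_dmin <- function(map, focus, mesh, dist_field = NULL) {
  act <- attr(map, "active")
  if (is.null(act)) act <- map$amplitudes > 0
  if (!any(act)) stop("Map_Dmin undefined for an empty active set")
  d <- dist_field %||% distance_to_region(mesh, focus)
  min(d[act])
}

#' Metric curves as a function of map threshold
#'
#' Evaluates spatial dispersion, map size, and Map_Dmin at thresholds 0,
#' 10, ..., 100%. Map size is nonincreasing and Map_Dmin nondecreasing in
#' the threshold by construction.
#'
#' @inheritParams spatial_dispersion
#' @param thresholds threshold grid in percent (default `seq(0, 100, 10)`).
#' @return Object of class `threshold_curves`: data.frame with columns
#'   `threshold_pct`, `sd_mm`, `size_vertices`, `map_dmin_mm` plus
#'   `study_id` and `method_label` attributes.
#' @export
threshold_curves <- function(map, focus, mesh, thresholds = seq(0, 100, 10),
                             dist_field = NULL) {
  d <- dist_field %||% distance_to_region(mesh, focus)
  rows <- lapply(thresholds, function(t_pct) {
    tm <- threshold_map(map, t_pct)
    data.frame(threshold_pct = t_pct,
               sd_mm = spatial_dispersion(tm, focus, mesh, dist_field = d),
               size_vertices = map_size(tm),
               map_dmin_mm = map_dmin(tm, focus, mesh, dist_field = d))
  })
  out <- do.call(rbind, rows)
  attr(out, "study_id") <- map$study_id
  attr(out, "method_label") <- map$method_label
  class(out) <- c("threshold_curves", "data.frame")
  out
}

#' Full metric set for one study's method maps
#'
#' Computes Dmin per method plus the threshold-resolved metrics (spatial
#' dispersion, map size, Map_Dmin), returning the long-format table that
#' the group statistics consume: one row per method x threshold.
#'
#' @param maps named list of [source_map()]s (typically MNE, sLORETA, dSPM,
#'   cMEM and Ave).
#' @param focus the study's [focus_region()].
#' @param mesh the [cortical_mesh()].
#' @param patient_id,study_id identifiers stored in the rows.
#' @param thresholds threshold grid in percent.
#' @return data.frame with columns `patient_id`, `study_id`, `method`,
#'   `threshold_pct`, `dmin_mm`, `sd_mm`, `size_vertices`, `map_dmin_mm`.
#' @export
study_metrics <- function(maps, focus, mesh, patient_id = NA_character_,
                          study_id = NA_character_,
                          thresholds = seq(0, 100, 10)) {
  d <- distance_to_region(mesh, focus)
  rows <- lapply(maps, function(mp) {
    cv <- threshold_curves(mp, focus, mesh, thresholds = thresholds,
                           dist_field = d)
    data.frame(patient_id = patient_id, study_id = study_id,
               method = mp$method_label, threshold_pct = cv$threshold_pct,
               dmin_mm = dmin(mp, focus, mesh), sd_mm = cv$sd_mm,
               size_vertices = cv$size_vertices, map_dmin_mm = cv$map_dmin_mm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
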