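#' MEG sensor array
#'
#' A set of point magnetometers with positions and orientations. The default
#' layout places `n` sensors quasi-uniformly (Fibonacci lattice) on a
#' spherical cap covering the upper head, oriented radially — an idealized
#' whole-head helmet.
#'
#' @param n number of channels (default 275).
#' @param radius helmet radius in mm.
#' @param center helmet center (mm).
#' @param coverage fraction of the sphere covered by the cap, measured from
#'   the vertex downward (0.65 reaches below the head's equator).
#' @return Object of class `sensor_array`: `positions` (n x 3, mm),
#'   `orientations` (n x 3, unit), `names` (unique channel labels).
#' @export
sensor_array <- function(n = 275, radius = 120, center = c(0, 0, 0),
                         coverage = 0.65) {
  stopifnot(n >= 1, radius > 0, coverage > 0, coverage <= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * coverage * i / n          # cos(theta) from 1 down the cap
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  s <- sqrt(pmax(1 - z^2, 0))
  orient <- cbind(s * cos(phi), s * sin(phi), z)
  pos <- sweep(radius * orient, 2L, center, "+")
  out <- list(positions = pos, orientations = orient,
              names = sprintf("MEG%03d", seq_len(n)), center = center)
  class(out) <- "sensor_array"
  out
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("sensor_array:", length(x$names), "radial point magnetometers\n")
  invisible(x)
}

#' Analytic single-sphere MEG gain matrix
#'
#' Closed-form magnetic field of a current dipole inside a homogeneous
#' conducting sphere (Sarvas solution), evaluated at each sensor and
#' projected on the sensor orientation. One column per mesh vertex, with the
#' dipole moment along the vertex normal (unit moment). Radially oriented
#' dipoles and dipoles at the sphere center produce exactly zero field; the
#' conductivity value does not enter the magnetic field of this model and is
#' carried as metadata only.
#'
#' @param mesh a [cortical_mesh()]; dipoles sit at the vertices, oriented
#'   along vertex normals.
#' @param sensors a [sensor_array()].
#' @param sphere_center conductor sphere center (mm); default the centroid
#'   of the mesh vertices.
#' @param conductivity S/m, metadata only (default 0.33).
#' @return Object of class `gain_matrix`: `values` (channels x sources),
#'   `channel_names`, `source_count`, `units`.
#' @export
spherical_meg_gain <- function(mesh, sensors, sphere_center = NULL,
                               conductivity = 0.33) {
  stopifnot(inherits(mesh, "cortical_mesh"), inherits(sensors, "sensor_array"))
  if (is.null(sphere_center)) sphere_center <- colMeans(mesh$vertices)
  rs <- sweep(sensors$positions, 2L, sphere_center)        # sensors rel. center
  src <- sweep(mesh$vertices, 2L, sphere_center)
  sensor_rad <- sqrt(rowSums(rs^2))
  src_rad <- sqrt(rowSums(src^2))
  if (any(src_rad >= min(sensor_rad))) {
    stop("all sources must lie strictly inside the sensor shell")
  }
  n_ch <- nrow(rs)
  p <- nrow(src)
  values <- matrix(0, n_ch, p)
  for (i in seq_len(p)) {
    values[, i] <- .sarvas_field(rs, sensors$orientations, src[i, ],
                                 mesh$normals[i, ])
  }
  structure(list(values = values, channel_names = sensors$names,
                 source_count = p, units = "T per unit dipole moment",
                 conductivity = conductivity, sphere_center = sphere_center),
            class = "gain_matrix")
}

# Sarvas formula: field of dipole q at r0 inside a conducting sphere,
# measured at sensor positions r (rows), projected on orientations o.
.sarvas_field <- function(r, o, r0, q) {
  mu0_4pi <- 1e-7
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  if (sum(qxr0^2) == 0) return(numeric(nrow(r)))   # radial or central dipole
  a <- sweep(r, 2L, r0)                            # r - r0
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  ar <- rowSums(a * r)
  rr0 <- as.vector(r %*% r0)
  f <- an * (rn * an + rn^2 - rr0)
  # grad F = (a^2/r + a.r/a + 2a + 2r) r - (a + 2r + a.r/a) r0
  c1 <- an^2 / rn + ar / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + ar / an
  gradf <- r * c1 - tcrossprod(c2, r0)
  b <- (tcrossprod(rep(1, nrow(r)), qxr0) * f -
          gradf * as.vector(r %*% qxr0)) * (mu0_4pi / f^2)
  rowSums(b * o)
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat("gain_matrix:", nrow(x$values), "channels x", x$source_count,
      "sources [", x$units, "]\n")
  invisible(x)
}

#' Validate a gain matrix against a mesh and sensor set
#'
#' @param gain a `gain_matrix`.
#' @param mesh optional mesh; column count must equal the vertex count.
#' @return `gain` invisibly; errors on violation.
#' @export
validate_gain <- function(gain, mesh = NULL) {
  if (!all(is.finite(gain$values))) stop("gain contains non-finite entries")
  if (!is.null(mesh) && ncol(gain$values) != nrow(mesh$vertices)) {
    stop("gain has ", ncol(gain$values), " source columns but mesh has ",
         nrow(mesh$vertices), " vertices")
  }
  if (any(rowSums(abs(gain$values)) == 0)) {
    stop("gain has an all-zero sensor row")
  }
  invisible(gain)
}

#' Write / read a gain matrix as tab-separated text
#'
#' Dense TSV with a metadata header (`# key=value` lines: units,
#' source_count) and one row per channel, first column the channel name.
#'
#' @param gain a `gain_matrix`.
#' @param path file path.
#' @return `write_gain` returns `path` invisibly; `load_gain` returns a
#'   validated `gain_matrix`.
#' @export
write_gain <- function(gain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# units=%s", gain$units),
               sprintf("# source_count=%d", gain$source_count)), con)
  df <- data.frame(channel = gain$channel_names,
                   format(gain$values, digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param mesh optional [cortical_mesh()] used to validate the source count.
#' @rdname write_gain
#' @export
load_gain <- function(path, mesh = NULL) {
  if (!file.exists(path)) stop("gain file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  body <- lines[!grepl("^#", lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  channel_names <- vapply(parts, `[[`, "", 1L)
  values <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                     numeric(length(parts[[1L]]) - 1L)))
  if (anyNA(values)) stop("gain file contains NA/NaN entries")
  if (!is.null(meta$source_count) &&
      as.integer(meta$source_count) != ncol(values)) {
    stop("gain file metadata source_count does not match matrix columns")
  }
  gain <- structure(list(values = values, channel_names = channel_names,
                         source_count = ncol(values),
                         units = meta$units %||% "unknown"),
                    class = "gain_matrix")
  validate_gain(gain, mesh)
  gain
}

`%||%` <- function(a, b) if (is.null(a)) b else a
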