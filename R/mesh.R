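#' Triangulated cortical surface mesh
#'
#' Constructs a `cortical_mesh`: a triangulated surface with one dipolar
#' source site per vertex, oriented along the vertex normal. Coordinates are
#' in millimetres throughout the package.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param normals optional numeric matrix, n x 3, unit vertex normals. When
#'   omitted they are computed as area-weighted averages of incident face
#'   normals, oriented away from the vertex centroid.
#' @return An object of class `cortical_mesh` with components `vertices`,
#'   `faces`, `normals`.
#' @examples
#' m <- mesh_sphere(122, radius = 70)
#' nrow(m$vertices)
#' @export
cortical_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) {
    stop("face indices out of range 1..", n)
  }
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("vertex coordinates must be finite")
  }
  # duplicate faces (same vertex triple in any order) are non-manifold here
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  if (anyDuplicated(key)) stop("duplicate faces detected: mesh is non-manifold")
  if (!all(seq_len(n) %in% as.vector(faces))) {
    stop("every vertex must belong to at least one face")
  }
  if (is.null(normals)) {
    normals <- .vertex_normals(vertices, faces)
  } else {
    normals <- as.matrix(normals)
    if (!identical(dim(normals), dim(vertices))) {
      stop("normals must match vertices in dimension")
    }
    nrm <- sqrt(rowSums(normals^2))
    if (any(abs(nrm - 1) > 1e-9)) stop("vertex normals must have unit norm")
  }
  out <- list(vertices = vertices, faces = faces, normals = normals)
  class(out) <- "cortical_mesh"
  out
}

# area-weighted vertex normals, oriented outward from the centroid
.vertex_normals <- function(vertices, faces) {
  n <- nrow(vertices)
  acc <- matrix(0, n, 3L)
  v1 <- vertices[faces[, 1L], , drop = FALSE]
  v2 <- vertices[faces[, 2L], , drop = FALSE]
  v3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  for (k in 1:3) {
    for (d in 1:3) {
      acc[, d] <- acc[, d] + tabulate2(faces[, k], fn[, d], n)
    }
  }
  centroid <- colMeans(vertices)
  out <- acc / pmax(sqrt(rowSums(acc^2)), .Machine$double.eps)
  flip <- rowSums(out * sweep(vertices, 2L, centroid)) < 0
  out[flip, ] <- -out[flip, ]
  out / sqrt(rowSums(out^2))
}

# sum weights w by integer bin idx into a length-n vector
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, group = idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat("cortical_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces (mm units)\n")
  invisible(x)
}

#' Vertex adjacency of a triangulated mesh
#'
#' Two vertices are neighbours iff they share a triangle edge. The returned
#' structure is symmetric by construction and is required to be connected:
#' a disconnected source space would make graph-constrained patch growing
#' ill-defined.
#'
#' @param mesh a [cortical_mesh()].
#' @return A list of integer vectors, `adj[[i]]` giving the sorted neighbour
#'   indices of vertex `i`.
#' @export
build_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  f <- mesh$faces
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  edges <- rbind(edges, edges[, c(2L, 1L)])
  edges <- unique(edges)
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(nrow(mesh$vertices))))
  adj <- lapply(adj, function(v) sort(as.integer(v)))
  names(adj) <- NULL
  if (!.is_connected(adj)) stop("mesh adjacency graph is not connected")
  adj
}

.is_connected <- function(adj) {
  n <- length(adj)
  if (n == 0L) return(FALSE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    nb <- unique(unlist(adj[queue], use.names = FALSE))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- nb
  }
  all(seen)
}

#' Ground-truth focus region on a mesh
#'
#' A focus region is a nonempty, graph-connected set of mesh vertices. It
#' plays the role of the reference region (an epileptic focus in clinical
#' use) against which all spatial-accuracy metrics are computed.
#'
#' @param vertex_ids integer vector of mesh vertex indices.
#' @param mesh the [cortical_mesh()] the indices refer to.
#' @param label free-text label.
#' @param adjacency optional precomputed [build_adjacency()] result.
#' @return An object of class `focus_region` with fields `vertex_ids`,
#'   `label`.
#' @export
focus_region <- function(vertex_ids, mesh, label = "focus", adjacency = NULL) {
  vertex_ids <- sort(unique(as.integer(vertex_ids)))
  if (length(vertex_ids) == 0L) stop("focus region must be nonempty")
  n <- nrow(mesh$vertices)
  if (any(vertex_ids < 1L) || any(vertex_ids > n)) {
    stop("focus vertex ids out of mesh range")
  }
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  if (!.region_connected(vertex_ids, adjacency)) {
    stop("focus region is not connected in the mesh adjacency graph")
  }
  structure(list(vertex_ids = vertex_ids, label = label),
            class = "focus_region")
}

.region_connected <- function(ids, adj) {
  if (length(ids) == 1L) return(TRUE)
  inset <- logical(length(adj))
  inset[ids] <- TRUE
  seen <- logical(length(adj))
  queue <- ids[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    nb <- unique(unlist(adj[queue], use.names = FALSE))
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- nb
  }
  all(seen[ids])
}

#' @export
print.focus_region <- function(x, ...) {
  cat("focus_region '", x$label, "': ", length(x$vertex_ids),
      " vertices\n", sep = "")
  invisible(x)
}

#' Euclidean distance field to a region
#'
#' For every mesh vertex `i`, the minimum straight-line (chord) distance in
#' mm to the closest vertex of the region: `min_{j in region} D_ij`.
#' Distances are Euclidean, not geodesic, matching the distance convention
#' used by all metrics in this package.
#'
#' @param mesh a [cortical_mesh()].
#' @param region a [focus_region()] or an integer vector of vertex ids.
#' @return Numeric vector, one distance (mm) per mesh vertex; exactly 0 for
#'   region members.
#' @export
distance_to_region <- function(mesh, region) {
  ids <- if (inherits(region, "focus_region")) region$vertex_ids else as.integer(region)
  if (length(ids) == 0L) stop("region must be nonempty")
  v <- mesh$vertices
  r <- v[ids, , drop = FALSE]
  # ||v_i - r_j||^2 = |v|^2 + |r|^2 - 2 v.r, minimized over j
  cross <- v %*% t(r)
  d2 <- outer(rowSums(v^2), rowSums(r^2), "+") - 2 * cross
  d <- sqrt(pmax(apply(d2, 1L, min), 0))
  d[ids] <- 0
  d
}

#' Grow a connected patch around a seed vertex
#'
#' Breadth-first growth through the adjacency graph keeping every vertex
#' within `radius_mm` Euclidean distance of the seed. The result is the
#' maximal connected vertex set containing the seed that is reachable
#' through in-radius vertices — a contiguous cortical patch, mimicking a
#' region drawn along the cortical surface.
#'
#' @param mesh a [cortical_mesh()].
#' @param seed seed vertex index.
#' @param radius_mm patch radius in mm (> 0).
#' @param adjacency optional precomputed adjacency.
#' @param label label for the resulting region.
#' @return A [focus_region()].
#' @export
grow_patch <- function(mesh, seed, radius_mm, adjacency = NULL, label = "patch") {
  seed <- as.integer(seed)
  n <- nrow(mesh$vertices)
  if (seed < 1L || seed > n) stop("seed out of range")
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("radius_mm must be > 0")
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  d <- sqrt(colSums((t(mesh$vertices) - mesh$vertices[seed, ])^2))
  inradius <- d <= radius_mm
  seen <- logical(n)
  seen[seed] <- TRUE
  queue <- seed
  while (length(queue)) {
    nb <- unique(unlist(adjacency[queue], use.names = FALSE))
    nb <- nb[inradius[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- nb
  }
  focus_region(which(seen), mesh, label = label, adjacency = adjacency)
}

#' Synthetic cortex-like spherical surface
#'
#' Builds a closed triangulated surface with approximately `n_vertices`
#' vertices: a latitude/longitude sphere whose radius is modulated by smooth
#' low-order angular bumps. The modulation tilts vertex normals away from
#' the radial direction so that normally-oriented dipoles are magnetically
#' visible in a spherical conductor model (a perfect sphere would make every
#' source radial, hence silent). The surface shape is deterministic.
#'
#' @param n_vertices exact vertex count (>= 12): two poles plus latitude
#'   rings whose per-ring counts follow an equal-area allocation, so any
#'   count is realized exactly.
#' @param radius base radius in mm.
#' @param bumpiness relative amplitude of the radial modulation; 0 gives a
#'   perfect sphere.
#' @return A [cortical_mesh()].
#' @export
mesh_sphere <- function(n_vertices, radius = 70, bumpiness = 1) {
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 12L) stop("n_vertices must be at least 12")
  m <- n_vertices - 2L
  n_rings <- max(3L, round(sqrt(m * pi / 4)))
  theta <- pi * seq_len(n_rings) / (n_rings + 1)
  # vertices per ring proportional to circumference, totals fixed exactly
  w <- sin(theta)
  counts <- pmax(3L, floor(m * w / sum(w)))
  while (sum(counts) > m) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < m) counts[which.min(counts / w)] <- counts[which.min(counts / w)] + 1L
  ring_start <- 1L + cumsum(c(0L, counts[-n_rings]))  # after north pole (vertex 1)
  pts <- vector("list", n_rings)
  phis <- vector("list", n_rings)
  for (i in seq_len(n_rings)) {
    ph <- 2 * pi * (seq_len(counts[i]) - 1L + 0.5 * (i %% 2L)) / counts[i]
    th <- theta[i]
    mod <- bumpiness * sin(th) * (0.16 * sin(3 * th) * cos(2 * ph) +
                                  0.13 * cos(2 * th) * sin(3 * ph) +
                                  0.10 * sin(5 * th) * cos(3 * ph + 1))
    r <- radius * (1 + mod)
    pts[[i]] <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
    phis[[i]] <- ph
  }
  vertices <- rbind(c(0, 0, radius), do.call(rbind, pts), c(0, 0, -radius))
  south <- n_vertices
  faces <- vector("list", n_rings + 1L)
  # polar fans
  id1 <- ring_start[1L] + seq_len(counts[1L])        # global ids of ring 1
  faces[[1L]] <- cbind(1L, c(id1[-1L], id1[1L]), id1)
  idL <- ring_start[n_rings] + seq_len(counts[n_rings])
  faces[[n_rings + 1L]] <- cbind(south, idL, c(idL[-1L], idL[1L]))
  # stitch consecutive rings by merged angular order
  for (i in seq_len(n_rings - 1L)) {
    faces[[i + 1L]] <- .stitch_rings(ring_start[i], counts[i], phis[[i]],
                                     ring_start[i + 1L], counts[i + 1L], phis[[i + 1L]])
  }
  cortical_mesh(vertices, do.call(rbind, faces))
}

# triangulate the band between two vertex rings (global offsets sa, sb)
.stitch_rings <- function(sa, na, pha, sb, nb, phb) {
  ia <- 0L; ib <- 0L
  tri <- matrix(0L, na + nb, 3L)
  k <- 0L
  ga <- function(i) sa + (i %% na) + 1L
  gb <- function(i) sb + (i %% nb) + 1L
  next_ang <- function(ph, i, n) ph[(i %% n) + 1L] + 2 * pi * (i %/% n)
  while (ia < na || ib < nb) {
    advance_a <- ib >= nb ||
      (ia < na && next_ang(pha, ia + 1L, na) <= next_ang(phb, ib + 1L, nb))
    if (advance_a) {
      k <- k + 1L; tri[k, ] <- c(ga(ia), ga(ia + 1L), gb(ib))
      ia <- ia + 1L
    } else {
      k <- k + 1L; tri[k, ] <- c(ga(ia), gb(ib + 1L), gb(ib))
      ib <- ib + 1L
    }
  }
  tri[seq_len(k), , drop = FALSE]
}
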