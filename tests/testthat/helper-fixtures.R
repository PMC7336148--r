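# Shared small fixtures, built once per test run.

# tiny meshes
triangle_mesh <- function() {
  cortical_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                rbind(c(1L, 2L, 3L)))
}

tetra_mesh <- function() {
  cortical_mesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                rbind(c(1L, 2L, 3L), c(1L, 4L, 2L), c(1L, 3L, 4L), c(2L, 4L, 3L)))
}

# memoized medium fixtures
.fix <- new.env()

fix_mesh <- function(n = 500) {
  key <- paste0("mesh", n)
  if (is.null(.fix[[key]])) .fix[[key]] <- mesh_sphere(n)
  .fix[[key]]
}

fix_adj <- function(n = 500) {
  key <- paste0("adj", n)
  if (is.null(.fix[[key]])) .fix[[key]] <- build_adjacency(fix_mesh(n))
  .fix[[key]]
}

fix_gain <- function(n = 500, n_sens = 80) {
  key <- paste0("gain", n, "_", n_sens)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- spherical_meg_gain(fix_mesh(n), sensor_array(n_sens))
  }
  .fix[[key]]
}

# a simulated focal study on the 500-vertex mesh: returns list with all the
# pieces downstream tests need
fix_sim_study <- function(seed = 11, snr = 5, radius = 15) {
  key <- paste0("sim", seed, "_", snr, "_", radius)
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  set.seed(seed)
  mesh <- fix_mesh(500)
  adj <- fix_adj(500)
  gain <- fix_gain(500, 80)
  cn <- sqrt(colSums(gain$values^2))
  seed_v <- sample(which(cn > quantile(cn, 0.3)), 1)
  focus <- grow_patch(mesh, seed_v, radius, adjacency = adj)
  dseed <- sqrt(colSums((t(mesh$vertices[focus$vertex_ids, , drop = FALSE]) -
                           mesh$vertices[seed_v, ])^2))
  jtrue <- numeric(500)
  jtrue[focus$vertex_ids] <- 10 * exp(-dseed^2 / (2 * (radius / 2)^2))
  clean <- as.vector(gain$values %*% jtrue)
  sigma <- sqrt(mean(clean^2)) / snr
  dat <- clean + rnorm(length(clean), 0, sigma)
  ncov <- structure(list(values = diag(sigma^2, length(clean)),
                         regularization_applied = 0,
                         n_samples = length(clean)),
                    class = "noise_covariance")
  .fix[[key]] <- list(mesh = mesh, adj = adj, gain = gain, focus = focus,
                      seed_vertex = seed_v, jtrue = jtrue, data = dat,
                      clean = clean, sigma = sigma, ncov = ncov)
  .fix[[key]]
}

# random nonnegative source map
random_map <- function(n, method = "MNE", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  source_map(abs(rnorm(n)), method)
}
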