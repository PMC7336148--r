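toy_gain <- function(values) {
  structure(list(values = values,
                 channel_names = sprintf("C%d", seq_len(nrow(values))),
                 source_count = ncol(values), units = "a"),
            class = "gain_matrix")
}

test_that("parcellation is a partition of connected parcels", {
  sim <- fix_sim_study()
  pm <- parcellate_cortex(sim$mesh, sim$gain, sim$data, C = sim$ncov,
                          adjacency = sim$adj)
  # partition: disjoint, covering
  expect_equal(sort(unlist(pm$parcels)), seq_len(500))
  expect_equal(length(unlist(pm$parcels)), 500L)
  expect_equal(pm$membership[unlist(pm$parcels)],
               rep(seq_along(pm$parcels), lengths(pm$parcels)))
  # each parcel connected in the adjacency graph
  for (v in pm$parcels) {
    seen <- v[1]
    frontier <- v[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(sim$adj[frontier]), v), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    expect_setequal(seen, v)
  }
  expect_true(all(pm$alpha >= 0 & pm$alpha <= 1))
})

test_that("parcellation degenerate cases", {
  sim <- fix_sim_study()
  # order 0: every vertex its own parcel
  pm0 <- parcellate_cortex(sim$mesh, sim$gain, sim$data, C = sim$ncov,
                           order = 0L, adjacency = sim$adj)
  expect_equal(length(pm0$parcels), 500L)
  # zero data: uniform scores and alpha
  pmz <- parcellate_cortex(sim$mesh, sim$gain, numeric(80), C = sim$ncov,
                           adjacency = sim$adj)
  expect_equal(pmz$score, rep(1, 500))
  expect_equal(pmz$alpha, rep(0.5, length(pmz$parcels)))
})

test_that("the parcel containing a dominant source has the highest alpha", {
  sim <- fix_sim_study(seed = 41)
  pm <- parcellate_cortex(sim$mesh, sim$gain, sim$clean, C = sim$ncov,
                          adjacency = sim$adj)
  best <- which.max(pm$alpha)
  expect_true(sim$seed_vertex %in% pm$parcels[[best]])
})

test_that("zero data yields an all-zero cMEM map with all parcels off", {
  sim <- fix_sim_study()
  pm <- parcellate_cortex(sim$mesh, sim$gain, numeric(80), C = sim$ncov,
                          adjacency = sim$adj)
  cm <- solve_cmem(pm, sim$gain, sim$ncov, numeric(80), sim$mesh,
                   adjacency = sim$adj)
  expect_equal(cm$amplitudes, numeric(500))
  expect_true(all(attr(cm, "parcel_active") < 1e-3))
})

test_that("cMEM dual optimum matches exhaustive grid search on a 2-parcel toy", {
  # 2 channels, 4 sources in 2 parcels of 2; mesh is a quad (two triangles)
  verts <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0))
  mesh <- cortical_mesh(verts, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  gv <- rbind(c(1.0, 0.8, 0.1, 0.05),
              c(0.1, 0.2, 0.9, 1.1))
  g <- toy_gain(gv)
  cv <- diag(0.2, 2)
  dat <- c(1.4, -0.3)
  pm <- structure(list(membership = c(1L, 1L, 2L, 2L),
                       parcels = list(1:2, 3:4), alpha = c(0.7, 0.4),
                       score = rep(1, 4)), class = "parcel_model")
  cm <- solve_cmem(pm, g, cv, dat, mesh, neighbor_coherence = 0,
                   grad_tol = 1e-12)
  dual_opt <- attr(cm, "dual_value")

  # oracle: iteratively refined exhaustive grid search over the 2 multipliers
  prep <- dmsi:::.cmem_prepare(pm, g, cv, dat, mesh, neighbor_coherence = 0,
                               prior_scale = 1)
  f <- function(l1, l2) dmsi:::.cmem_dual_value(c(l1, l2), prep$gw, prep$mw,
                                                prep$parcels, prep$m_list,
                                                prep$alpha)
  ctr <- c(0, 0); span <- 20
  for (round in 1:12) {
    g1 <- seq(ctr[1] - span, ctr[1] + span, length.out = 41)
    g2 <- seq(ctr[2] - span, ctr[2] + span, length.out = 41)
    vals <- outer(g1, g2, Vectorize(f))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    ctr <- c(g1[ix[1]], g2[ix[2]])
    span <- span / 8
  }
  expect_equal(dual_opt, f(ctr[1], ctr[2]), tolerance = 1e-6)
  # and the solver's multipliers agree with the grid argmax
  expect_equal(attr(cm, "dual_multipliers"), ctr, tolerance = 1e-4)
})

test_that("cMEM concentrates energy on the active patch and switches distant parcels off", {
  sim <- fix_sim_study(seed = 42)
  pm <- parcellate_cortex(sim$mesh, sim$gain, sim$data, C = sim$ncov,
                          adjacency = sim$adj)
  cm <- solve_cmem(pm, sim$gain, sim$ncov, sim$data, sim$mesh,
                   adjacency = sim$adj)
  # some parcels are switched off exactly
  expect_gt(sum(cm$amplitudes == 0), 0)
  expect_lt(sum(attr(cm, "parcel_active") >= 1e-3), length(pm$parcels))

  d2f <- distance_to_region(sim$mesh, sim$focus)
  # >= 80% of energy within the true parcel and its graph neighbours
  kp <- unique(pm$membership[sim$focus$vertex_ids])
  nb_parcels <- unique(pm$membership[unlist(
    sim$adj[which(pm$membership %in% kp)])])
  inside <- which(pm$membership %in% union(kp, nb_parcels))
  etotal <- sum(cm$amplitudes^2)
  expect_gte(sum(cm$amplitudes[inside]^2) / etotal, 0.8)
  # parcels farther than 30 mm from the focus carry < 5% of the energy
  pdist <- vapply(pm$parcels, function(v) min(d2f[v]), 0)
  efar <- sum(vapply(which(pdist > 30), function(k)
    sum(cm$amplitudes[pm$parcels[[k]]]^2), 0)) / etotal
  expect_lt(efar, 0.05)
})

test_that("cMEM reproduces the data nearly as well as wMNE", {
  for (seed in c(43, 44, 45)) {
    sim <- fix_sim_study(seed = seed)
    pm <- parcellate_cortex(sim$mesh, sim$gain, sim$data, C = sim$ncov,
                            adjacency = sim$adj)
    cm <- solve_cmem(pm, sim$gain, sim$ncov, sim$data, sim$mesh,
                     adjacency = sim$adj)
    res_cmem <- sqrt(sum(attr(cm, "residual_whitened")^2))
    kern <- build_wmne_kernel(sim$gain, sim$ncov)
    j_w <- as.vector(kern$kernel %*% sim$data)
    wh <- dmsi:::.inv_sqrt(sim$ncov$values)
    res_wmne <- sqrt(sum((wh %*% (sim$data - sim$gain$values %*% j_w))^2))
    expect_lte(res_cmem, res_wmne * 1.1)
  }
})

test_that("cMEM map is invariant to parcel relabeling", {
  sim <- fix_sim_study(seed = 46)
  pm <- parcellate_cortex(sim$mesh, sim$gain, sim$data, C = sim$ncov,
                          adjacency = sim$adj)
  cm1 <- solve_cmem(pm, sim$gain, sim$ncov, sim$data, sim$mesh,
                    adjacency = sim$adj)
  # reverse the parcel order
  nk <- length(pm$parcels)
  perm <- rev(seq_len(nk))
  pm2 <- pm
  pm2$parcels <- pm$parcels[perm]
  pm2$alpha <- pm$alpha[perm]
  pm2$membership <- match(pm$membership, perm)
  cm2 <- solve_cmem(pm2, sim$gain, sim$ncov, sim$data, sim$mesh,
                    adjacency = sim$adj)
  expect_equal(cm2$amplitudes, cm1$amplitudes, tolerance = 1e-8)
  expect_equal(attr(cm2, "parcel_active"), attr(cm1, "parcel_active")[perm],
               tolerance = 1e-8)
})

test_that("extended-patch simulations give cMEM lower dispersion than the linear methods", {
  wins <- 0L
  n_rep <- 5L
  for (seed in 50 + seq_len(n_rep)) {
    sim <- fix_sim_study(seed = seed)
    pm <- parcellate_cortex(sim$mesh, sim$gain, sim$data, C = sim$ncov,
                            adjacency = sim$adj)
    cm <- solve_cmem(pm, sim$gain, sim$ncov, sim$data, sim$mesh,
                     adjacency = sim$adj)
    kern <- build_wmne_kernel(sim$gain, sim$ncov)
    others <- list(solve_mne(kern, sim$data),
                   solve_dspm(kern, sim$ncov, sim$data),
                   solve_sloreta(kern, sim$gain, sim$data))
    sd_cmem <- spatial_dispersion(cm, sim$focus, sim$mesh)
    sd_other <- vapply(others, spatial_dispersion, 0,
                       focus = sim$focus, mesh = sim$mesh)
    if (all(sd_cmem < sd_other)) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})
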