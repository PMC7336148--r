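test_that("min-max rescaling maps onto [0,1] with declared degenerate rule", {
  m <- source_map(c(2, 4, 6, 8, 10), "MNE")
  r <- rescale_map(m)
  expect_equal(r$amplitudes, c(0, 0.25, 0.5, 0.75, 1))
  # already-[0,1] map unchanged
  m01 <- source_map(c(0, 0.3, 1), "MNE")
  expect_equal(rescale_map(m01)$amplitudes, m01$amplitudes)
  # constant map -> all zeros
  expect_equal(rescale_map(source_map(rep(4, 5), "MNE"))$amplitudes, rep(0, 5))
})

test_that("Ave is the element-wise mean of rescaled maps", {
  # four identical maps -> Ave equals each (rescaled) input
  m <- source_map(c(0, 0.5, 1), "MNE")
  av <- average_maps(list(m, m, m, m))
  expect_equal(av$amplitudes, m$amplitudes)
  expect_equal(av$method_label, "Ave")

  # one-hot maps at two different vertices
  e1 <- source_map(c(1, 0, 0), "MNE")
  e2 <- source_map(c(0, 0, 1), "dSPM")
  av <- average_maps(list(e1, e1, e2, e2))
  expect_equal(av$amplitudes, c(0.5, 0, 0.5))

  # random maps vs direct recomputation
  set.seed(61)
  maps <- lapply(c("MNE", "sLORETA", "dSPM", "cMEM"), function(lab)
    random_map(50, lab))
  av <- average_maps(maps)
  oracle <- rowMeans(vapply(maps, function(m) {
    a <- m$amplitudes
    (a - min(a)) / (max(a) - min(a))
  }, numeric(50)))
  expect_equal(av$amplitudes, oracle, tolerance = 1e-12)

  expect_error(average_maps(list(e1, source_map(c(1, 0), "MNE"))),
               "vertex counts")
})

test_that("thresholding keeps the >= t*max rule and endpoint semantics", {
  m <- source_map(c(0.1, 0.4, 0.5, 1.0), "MNE")
  t50 <- threshold_map(m, 50)
  expect_equal(t50$amplitudes, c(0, 0, 0.5, 1.0))
  expect_equal(map_size(t50), 2L)

  # 0%: everything positive survives; 100%: only the maximum
  expect_equal(map_size(threshold_map(m, 0)), 4L)
  expect_equal(map_size(threshold_map(m, 100)), 1L)
  # tied maxima all survive at 100%
  tie <- source_map(c(1, 0.2, 1), "MNE")
  expect_equal(map_size(threshold_map(tie, 100)), 2L)
  expect_error(threshold_map(m, 150), "t_pct")
})

test_that("Dmin is the distance from the argmax to the focus", {
  mesh <- fix_mesh(200)
  adj <- fix_adj(200)
  focus <- grow_patch(mesh, 60L, 30, adjacency = adj)
  # argmax inside the focus -> 0
  a <- numeric(200); a[focus$vertex_ids[1]] <- 1
  expect_equal(dmin(source_map(a, "MNE"), focus, mesh), 0)
  expect_error(dmin(source_map(numeric(200), "MNE"), focus, mesh),
               "all-zero")

  # hand case on a custom mesh: argmax at (10,0,0), focus at (2,0,0)
  m2 <- cortical_mesh(rbind(c(10, 0, 0), c(2, 0, 0), c(2, 1, 0)),
                      rbind(c(1L, 2L, 3L)))
  f2 <- focus_region(2L, m2)
  expect_equal(dmin(source_map(c(5, 1, 0), "MNE"), f2, m2), 8)

  # random maps vs brute-force min over focus vertices
  set.seed(62)
  for (rep in 1:20) {
    mp <- random_map(200)
    am <- which.max(mp$amplitudes)
    brute <- min(vapply(focus$vertex_ids, function(j)
      sqrt(sum((mesh$vertices[am, ] - mesh$vertices[j, ])^2)), 0))
    expect_equal(dmin(mp, focus, mesh), brute, tolerance = 1e-12)
  }
})

test_that("Dmin reproducibility is the within-group IQR", {
  # identical values -> 0
  r <- dmin_reproducibility(rep(3, 4), rep("P1", 4), rep("MNE", 4))
  expect_equal(r$iqr_mm, 0)
  # linear-interpolation quantiles: {1,2,3,4} -> 1.5
  r <- dmin_reproducibility(1:4, rep("P1", 4), rep("MNE", 4))
  expect_equal(r$iqr_mm, 1.5)
  # order invariance
  set.seed(63)
  v <- runif(7); perm <- sample(7)
  r1 <- dmin_reproducibility(v, rep("P1", 7), rep("MNE", 7))
  r2 <- dmin_reproducibility(v[perm], rep("P1", 7), rep("MNE", 7))
  expect_equal(r1$iqr_mm, r2$iqr_mm)
  # singleton groups are excluded and flagged
  r <- dmin_reproducibility(c(1, 2, 5), c("P1", "P1", "P2"),
                            rep("MNE", 3))
  expect_equal(nrow(r), 1L)
  expect_equal(attr(r, "excluded")$patient_id, "P2")
})

test_that("inter-method distance averages pairwise maxima distances", {
  # all maxima coincide -> 0 for every method
  xyz <- matrix(rep(c(1, 2, 3), 5), 5, byrow = TRUE,
                dimnames = list(c("MNE", "sLORETA", "dSPM", "cMEM", "Ave")))
  expect_equal(unname(inter_dmsi_distance(xyz)), rep(0, 5))

  # collinear points at 0, 3, 6 mm -> averages 4.5, 3, 4.5
  xyz <- rbind(A = c(0, 0, 0), B = c(3, 0, 0), C = c(6, 0, 0))
  expect_equal(unname(inter_dmsi_distance(xyz)), c(4.5, 3, 4.5))

  # random maxima vs brute-force pairwise mean
  set.seed(64)
  xyz <- matrix(rnorm(15), 5,
                dimnames = list(c("MNE", "sLORETA", "dSPM", "cMEM", "Ave")))
  res <- inter_dmsi_distance(xyz)
  for (i in 1:5) {
    brute <- mean(vapply(setdiff(1:5, i), function(j)
      sqrt(sum((xyz[i, ] - xyz[j, ])^2)), 0))
    expect_equal(unname(res[i]), brute, tolerance = 1e-12)
  }

  # a missing method is skipped with adjusted divisor
  xyz[2, ] <- NA
  expect_warning(res <- inter_dmsi_distance(xyz), "missing")
  expect_equal(length(res), 4L)
  brute <- mean(vapply(c(3, 4, 5), function(j)
    sqrt(sum((xyz[1, ] - xyz[j, ])^2)), 0))
  expect_equal(unname(res["MNE"]), brute)
  expect_error(inter_dmsi_distance(xyz[2:2, , drop = FALSE]), "two methods")
})

test_that("spatial dispersion follows the amplitude-weighted RMS formula", {
  mesh <- fix_mesh(200)
  adj <- fix_adj(200)
  focus <- grow_patch(mesh, 60L, 30, adjacency = adj)

  # all energy on one focus vertex -> 0
  a <- numeric(200); a[focus$vertex_ids[2]] <- 3
  expect_equal(spatial_dispersion(source_map(a, "MNE"), focus, mesh), 0)
  expect_error(spatial_dispersion(source_map(numeric(200), "MNE"),
                                  focus, mesh), "all-zero")

  # hand case: equal amplitudes at d = 0 and d = 10 -> sqrt(50)
  m2 <- cortical_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 1, 0)),
                      rbind(c(1L, 2L, 3L)))
  f2 <- focus_region(1L, m2)
  expect_equal(spatial_dispersion(source_map(c(1, 1, 0), "MNE"), f2, m2),
               sqrt(50), tolerance = 1e-12)

  # random maps vs term-by-term brute force
  set.seed(65)
  d <- distance_to_region(mesh, focus)
  for (rep in 1:20) {
    mp <- random_map(200)
    brute <- sqrt(sum(d^2 * mp$amplitudes^2) / sum(mp$amplitudes^2))
    expect_equal(spatial_dispersion(mp, focus, mesh), brute,
                 tolerance = 1e-9)
  }

  # scale invariance
  mp <- random_map(200, seed = 66)
  mp2 <- mp; mp2$amplitudes <- mp$amplitudes * 37
  expect_equal(spatial_dispersion(mp2, focus, mesh),
               spatial_dispersion(mp, focus, mesh), tolerance = 1e-12)
})

test_that("Map_Dmin is the distance from the active set to the focus", {
  mesh <- fix_mesh(200)
  adj <- fix_adj(200)
  focus <- grow_patch(mesh, 60L, 30, adjacency = adj)
  d <- distance_to_region(mesh, focus)

  # any active vertex in the focus -> 0
  a <- numeric(200); a[focus$vertex_ids[1]] <- 0.4; a[1] <- 1
  tm <- threshold_map(source_map(a, "MNE"), 30)
  expect_equal(map_dmin(tm, focus, mesh), 0)

  # single active vertex reduces to dmin of that vertex
  b <- numeric(200); b[5] <- 1
  expect_equal(map_dmin(source_map(b, "MNE"), focus, mesh), d[5])

  # random thresholded maps vs brute force over active x focus pairs
  set.seed(67)
  for (rep in 1:10) {
    mp <- threshold_map(random_map(200), sample(seq(0, 90, 10), 1))
    act <- which(attr(mp, "active"))
    brute <- min(vapply(act, function(i)
      min(vapply(focus$vertex_ids, function(j)
        sqrt(sum((mesh$vertices[i, ] - mesh$vertices[j, ])^2)), 0)), 0))
    expect_equal(map_dmin(mp, focus, mesh), brute, tolerance = 1e-12)
  }
})

test_that("threshold curves have 11 points, correct monotonicity, and match pointwise recomputation", {
  mesh <- fix_mesh(200)
  adj <- fix_adj(200)
  focus <- grow_patch(mesh, 60L, 30, adjacency = adj)
  set.seed(68)
  mp <- rescale_map(random_map(200))
  cv <- threshold_curves(mp, focus, mesh)
  expect_equal(nrow(cv), 11L)
  expect_equal(cv$threshold_pct, seq(0, 100, 10))
  expect_true(all(diff(cv$size_vertices) <= 0))
  expect_true(all(diff(cv$map_dmin_mm) >= -1e-12))
  # pointwise oracle
  for (i in seq_len(11)) {
    tm <- threshold_map(mp, cv$threshold_pct[i])
    expect_equal(cv$sd_mm[i], spatial_dispersion(tm, focus, mesh))
    expect_equal(cv$size_vertices[i], map_size(tm))
    expect_equal(cv$map_dmin_mm[i], map_dmin(tm, focus, mesh))
  }
  # identity at 100%: SD of the single surviving vertex equals Dmin
  expect_equal(cv$sd_mm[11], dmin(mp, focus, mesh), tolerance = 1e-12)
})

test_that("study_metrics assembles one row per method and threshold", {
  mesh <- fix_mesh(200)
  adj <- fix_adj(200)
  focus <- grow_patch(mesh, 60L, 30, adjacency = adj)
  set.seed(69)
  maps <- list(MNE = random_map(200, "MNE"), dSPM = random_map(200, "dSPM"))
  tab <- study_metrics(maps, focus, mesh, patient_id = "P1", study_id = "S1")
  expect_equal(nrow(tab), 2L * 11L)
  expect_setequal(unique(tab$method), c("dSPM", "MNE"))
  expect_true(all(tab$dmin_mm >= 0) && all(tab$sd_mm >= 0))
  # Dmin is threshold-independent within a method
  expect_equal(length(unique(tab$dmin_mm[tab$method == "MNE"])), 1L)
})

test_that("if all four maps share an argmax, Ave shares it too", {
  set.seed(70)
  base <- abs(rnorm(100))
  base[42] <- max(base) + 1
  maps <- lapply(c("MNE", "sLORETA", "dSPM", "cMEM"), function(lab) {
    a <- abs(rnorm(100))
    a[42] <- max(a) + 1       # common argmax, different elsewhere
    source_map(a, lab)
  })
  av <- average_maps(maps)
  expect_equal(which.max(av$amplitudes), 42L)
})
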