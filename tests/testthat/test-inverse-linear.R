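test_that("scalar minimum-norm case reproduces the closed form", {
  # g = 2, R = 1, C = 1, lambda = 1: estimate = rg/(g^2 r + lambda c) m = 0.4 m
  g <- structure(list(values = matrix(2, 1, 1), channel_names = "CH01",
                      source_count = 1L, units = "a"), class = "gain_matrix")
  # snr chosen so lambda = tr(GRG')/(tr(C) snr^2) = 4/snr^2 = 1
  kern <- build_wmne_kernel(g, matrix(1, 1, 1), depth_exponent = 0, snr = 2)
  expect_equal(kern$lambda, 1)
  expect_equal(as.vector(kern$kernel), 0.4)
  m <- 3.7
  expect_equal(solve_mne(kern, m)$amplitudes, 0.4 * m)
})

test_that("depth weights follow the inverse column-norm rule", {
  # two sources with column norms 1 and 2, exponent 0.5 -> weights 1 and 1/2,
  # ratio 2:1 before unit-mean normalization
  g <- structure(list(values = cbind(c(1, 0), c(0, 2)),
                      channel_names = c("A", "B"), source_count = 2L,
                      units = "a"), class = "gain_matrix")
  kern <- build_wmne_kernel(g, diag(2), depth_exponent = 0.5)
  expect_equal(kern$depth_weights[1] / kern$depth_weights[2], 2)
  expect_equal(mean(kern$depth_weights), 1)
})

test_that("wMNE solves the Tikhonov problem (direct optimizer oracle)", {
  set.seed(31)
  n_ch <- 5; p <- 8
  g <- structure(list(values = matrix(rnorm(n_ch * p), n_ch),
                      channel_names = sprintf("C%d", 1:n_ch),
                      source_count = p, units = "a"), class = "gain_matrix")
  a <- matrix(rnorm(n_ch^2), n_ch)
  cv <- crossprod(a) + diag(n_ch)
  m <- rnorm(n_ch)
  kern <- build_wmne_kernel(g, cv, depth_exponent = 0.5, snr = 3)
  j_kernel <- as.vector(kern$kernel %*% m)

  # oracle: minimize ||C^-1/2 (m - GJ)||^2 + lambda ||R^-1/2 J||^2 by
  # general-purpose quadratic optimization, independent of the kernel path
  cinv <- solve(cv)
  obj <- function(j) {
    r <- m - g$values %*% j
    as.vector(t(r) %*% cinv %*% r) + kern$lambda * sum(j^2 / kern$depth_weights)
  }
  opt <- optim(rep(0, p), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_equal(j_kernel, opt$par, tolerance = 1e-5)
  expect_equal(solve_mne(kern, m)$amplitudes, abs(j_kernel))
})

test_that("linear solvers scale correctly with the data", {
  sim <- fix_sim_study()
  kern <- build_wmne_kernel(sim$gain, sim$ncov)
  zero <- solve_mne(kern, numeric(80))
  expect_equal(zero$amplitudes, numeric(500))

  m1 <- solve_mne(kern, sim$data)
  mk <- solve_mne(kern, -2.5 * sim$data)
  expect_equal(mk$amplitudes, 2.5 * m1$amplitudes, tolerance = 1e-12)

  d1 <- solve_dspm(kern, sim$ncov, sim$data)
  dk <- solve_dspm(kern, sim$ncov, -2.5 * sim$data)
  expect_equal(dk$amplitudes, 2.5 * d1$amplitudes, tolerance = 1e-12)

  s1 <- solve_sloreta(kern, sim$gain, sim$data)
  sk <- solve_sloreta(kern, sim$gain, 7 * sim$data)
  expect_equal(which.max(sk$amplitudes), which.max(s1$amplitudes))

  expect_error(solve_mne(kern, numeric(12)), "mismatch")
})

test_that("dSPM matches its normalization formula (direct oracle)", {
  set.seed(32)
  n_ch <- 6; p <- 10
  g <- structure(list(values = matrix(rnorm(n_ch * p), n_ch),
                      channel_names = sprintf("C%d", 1:n_ch),
                      source_count = p, units = "a"), class = "gain_matrix")
  a <- matrix(rnorm(n_ch^2), n_ch)
  cv <- crossprod(a) + diag(n_ch)
  m <- rnorm(n_ch)
  kern <- build_wmne_kernel(g, cv)
  ds <- solve_dspm(kern, cv, m)
  oracle <- vapply(seq_len(p), function(i) {
    w_i <- kern$kernel[i, ]
    abs(sum(w_i * m)) / sqrt(as.vector(t(w_i) %*% cv %*% w_i))
  }, 0)
  expect_equal(ds$amplitudes, oracle, tolerance = 1e-12)

  # with C = I and unit-norm kernel rows, dSPM equals |MNE|
  kern_unit <- kern
  kern_unit$kernel <- kern$kernel / sqrt(rowSums(kern$kernel^2))
  d2 <- solve_dspm(kern_unit, diag(n_ch), m)
  expect_equal(d2$amplitudes, abs(as.vector(kern_unit$kernel %*% m)),
               tolerance = 1e-12)
})

test_that("sLORETA matches the model-variance diagonal (dense oracle)", {
  set.seed(33)
  n_ch <- 6; p <- 10
  g <- structure(list(values = matrix(rnorm(n_ch * p), n_ch),
                      channel_names = sprintf("C%d", 1:n_ch),
                      source_count = p, units = "a"), class = "gain_matrix")
  cv <- diag(n_ch)
  m <- rnorm(n_ch)
  kern <- build_wmne_kernel(g, cv)
  sl <- solve_sloreta(kern, g, m)
  s_full <- kern$kernel %*% g$values %*% diag(kern$depth_weights)
  oracle <- abs(as.vector(kern$kernel %*% m)) / sqrt(diag(s_full))
  expect_equal(sl$amplitudes, oracle, tolerance = 1e-12)
})

test_that("depth weighting changes the map unless column norms are equal", {
  sim <- fix_sim_study()
  k0 <- build_wmne_kernel(sim$gain, sim$ncov, depth_exponent = 0)
  k5 <- build_wmne_kernel(sim$gain, sim$ncov, depth_exponent = 0.5)
  m0 <- solve_mne(k0, sim$data)
  m5 <- solve_mne(k5, sim$data)
  expect_gt(max(abs(m0$amplitudes - m5$amplitudes)) / max(m0$amplitudes),
            1e-3)

  # equal-norm gain: depth weighting is a no-op
  set.seed(34)
  gv <- matrix(rnorm(5 * 8), 5)
  gv <- sweep(gv, 2, sqrt(colSums(gv^2)), "/")
  g <- structure(list(values = gv, channel_names = sprintf("C%d", 1:5),
                      source_count = 8L, units = "a"), class = "gain_matrix")
  m <- rnorm(5)
  j0 <- solve_mne(build_wmne_kernel(g, diag(5), depth_exponent = 0), m)
  j5 <- solve_mne(build_wmne_kernel(g, diag(5), depth_exponent = 0.5), m)
  expect_equal(j0$amplitudes, j5$amplitudes, tolerance = 1e-12)
})

test_that("with equal-norm columns and white noise the three maxima coincide on noiseless data", {
  set.seed(35)
  gv <- matrix(rnorm(20 * 40), 20)
  gv <- sweep(gv, 2, sqrt(colSums(gv^2)), "/")
  g <- structure(list(values = gv, channel_names = sprintf("C%d", 1:20),
                      source_count = 40L, units = "a"), class = "gain_matrix")
  i_true <- 17
  m <- gv[, i_true]
  kern <- build_wmne_kernel(g, diag(1e-6, 20), snr = 3)
  am <- vapply(list(solve_mne(kern, m),
                    solve_dspm(kern, diag(1e-6, 20), m),
                    solve_sloreta(kern, g, m)),
               function(mp) which.max(mp$amplitudes), 0L)
  expect_equal(am, rep(which.max(vapply(seq_len(40), function(i)
    abs(sum(gv[, i] * m)), 0)), 3))
})

test_that("sLORETA localizes noiseless single sources exactly", {
  # zero-error property on the 500-vertex fixture, visible sources only
  mesh <- fix_mesh(500)
  gain <- fix_gain(500, 80)
  cn <- sqrt(colSums(gain$values^2))
  eligible <- which(cn > quantile(cn, 0.10))
  kern <- build_wmne_kernel(gain, diag(80), snr = 3)
  s_diag <- rowSums(kern$kernel * t(gain$values)) * kern$depth_weights
  set.seed(36)
  hits <- 0L
  n_sim <- 25L
  for (i in sample(eligible, n_sim)) {
    sl <- solve_sloreta(kern, gain, gain$values[, i] * runif(1, 0.5, 5))
    if (which.max(sl$amplitudes) == i) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.95)
})
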