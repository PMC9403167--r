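# Dual mesh, sensitivity assembly, Tikhonov-CG inversion, hemoglobin
# unmixing.

fake_sensitivity <- function(W, z = NULL) {
  n <- ncol(W)
  structure(list(W = W,
                 mesh = list(centers = cbind(0, 0, if (is.null(z)) 1:n else z),
                             fine = rep(TRUE, n),
                             volumes = rep(1, n)),
                 background = NULL),
            class = "sensitivity_matrix")
}

test_that("a whole-volume ROI yields an all-fine mesh", {
  vb <- c(-2, 2, -2, 2, 0, 2)
  mesh <- build_dual_mesh(vb, vb)
  expect_true(all(mesh$fine))
  expect_equal(sum(mesh$volumes), 4 * 4 * 2, tolerance = 1e-9)
})

test_that("fine and coarse voxels tile the imaging volume exactly", {
  mesh <- build_dual_mesh(c(-1.2, 0.7, -0.3, 1.1, 0.8, 2.2))
  expect_equal(sum(mesh$volumes), 8 * 8 * 4, tolerance = 1e-9)
  # disjointness: no fine center inside a coarse voxel and vice versa
  fine <- mesh$centers[mesh$fine, , drop = FALSE]
  coarse <- mesh$centers[!mesh$fine, , drop = FALSE]
  for (i in seq_len(nrow(coarse))) {
    inside <- abs(fine[, 1] - coarse[i, 1]) < 0.5 &
              abs(fine[, 2] - coarse[i, 2]) < 0.5 &
              abs(fine[, 3] - coarse[i, 3]) < 0.5
    expect_false(any(inside))
  }
})

test_that("voxel counts match direct enumeration for an aligned ROI", {
  mesh <- build_dual_mesh(c(-1, 1, -1, 1, 1, 2))
  # fine 0.25 x 0.25 x 0.5 in a 2 x 2 x 1 box: 8 * 8 * 2
  expect_equal(sum(mesh$fine), 8 * 8 * 2)
  # coarse 1-cm voxels: 8*8*4 total minus the 2*2*1 covered by the ROI
  expect_equal(sum(!mesh$fine), 8 * 8 * 4 - 4)
})

test_that("out-of-volume ROIs are refused", {
  expect_error(build_dual_mesh(c(-5, 0, 0, 1, 0, 1)), "inside")
  expect_error(build_dual_mesh(c(1, 1, 0, 1, 0, 1)), "non-empty")
})

test_that("sensitivity matrix shares its kernel with the Born forward model", {
  g <- tiny_geometry()
  props <- optical_properties(0.02, 7)
  mesh <- build_dual_mesh(c(-1, 1, -1, 1, 1, 2))
  W <- assemble_sensitivity(mesh, g, props)
  expect_true(all(is.finite(Re(W$W))), all(is.finite(Im(W$W))))
  sel <- which(W$mesh$fine)[1:40]
  dm <- numeric(ncol(W$W)); dm[sel] <- 0.07
  m <- simulate_with_inclusions(
    g, props,
    list(list(centers = W$mesh$centers[sel, ], volumes = W$mesh$volumes[sel],
              delta_mua = 0.07)),
    linearization = "born")
  u0 <- simulate_homogeneous(g, props)
  expect_equal(as.vector(W$W %*% dm), (m$U - u0$U) / u0$U,
               tolerance = 1e-13)
})

test_that("sensitivity decays with voxel depth and scales with voxel volume", {
  g <- tiny_geometry()
  props <- optical_properties(0.02, 7)
  mesh <- build_dual_mesh(c(-1, 1, -1, 1, 1, 2))
  W <- assemble_sensitivity(mesh, g, props)
  cn <- sqrt(colSums(abs(W$W)^2))
  z <- W$mesh$centers[, 3]
  fine <- W$mesh$fine
  layer_peak <- tapply(cn[fine], z[fine], max)
  expect_true(all(diff(layer_peak) < 0))  # deeper layers are less visible
  K1 <- born_kernel(g, matrix(c(0.3, 0.2, 1.4), 1), 0.1, props)
  K2 <- born_kernel(g, matrix(c(0.3, 0.2, 1.4), 1), 0.2, props)
  expect_equal(K2, 2 * K1, tolerance = 1e-14)
})

test_that("zero perturbation reconstructs to exactly zero", {
  set.seed(3)
  W <- fake_sensitivity(matrix(complex(real = rnorm(60), imaginary = rnorm(60)),
                               10, 6))
  rec <- reconstruct(rep(0 + 0i, 10), W, lam = 0.3)
  expect_equal(rec$delta_mua, rep(0, 6))
})

test_that("the CG solution matches the dense closed-form Tikhonov solution", {
  set.seed(7)
  # small system with a complex perturbation
  Wc <- matrix(complex(real = rnorm(24), imaginary = rnorm(24)), 6, 4)
  pert <- complex(real = rnorm(6), imaginary = rnorm(6))
  lam <- 0.4
  rec <- reconstruct(pert, fake_sensitivity(Wc), lam = lam, tol = 1e-12)
  A <- rbind(Re(Wc), Im(Wc)); b <- c(Re(pert), Im(pert))
  closed <- solve(crossprod(A) + lam^2 * diag(4), crossprod(A, b))
  expect_equal(rec$delta_mua, as.vector(closed), tolerance = 1e-8)

  # randomized larger systems
  for (dims in list(c(40, 100), c(200, 500))) {
    A <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    Wc <- A[seq_len(dims[1] / 2), ] +
      1i * A[dims[1] / 2 + seq_len(dims[1] / 2), ]
    pert <- complex(real = rnorm(dims[1] / 2), imaginary = rnorm(dims[1] / 2))
    lam <- 0.2 * svd(A, nu = 0, nv = 0)$d[1]
    rec <- reconstruct(pert, fake_sensitivity(Wc), lam = lam,
                       max_iter = 500, tol = 1e-10)
    As <- rbind(Re(Wc), Im(Wc)); b <- c(Re(pert), Im(pert))
    closed <- solve(crossprod(As) + lam^2 * diag(dims[2]), crossprod(As, b))
    rel <- sqrt(sum((rec$delta_mua - closed)^2)) / sqrt(sum(closed^2))
    expect_lt(rel, 1e-6)
  }
})

test_that("reconstruction is exactly linear in the perturbation", {
  set.seed(5)
  Wc <- matrix(complex(real = rnorm(80), imaginary = rnorm(80)), 10, 8)
  pert <- complex(real = rnorm(10), imaginary = rnorm(10))
  W <- fake_sensitivity(Wc)
  r1 <- reconstruct(pert, W, lam = 0.5, tol = 1e-12)
  r3 <- reconstruct(3 * pert, W, lam = 0.5, tol = 1e-12)
  expect_equal(r3$delta_mua, 3 * r1$delta_mua, tolerance = 1e-9)
})

test_that("reconstructing data generated by the matrix itself recovers the truth", {
  # self-consistent (inverse-crime) data: the only error left is the
  # Tikhonov bias, which the closed form predicts exactly
  g <- probe_geometry()
  mesh <- build_dual_mesh(c(-1, 1, -1, 1, 1, 2),
                          fine_size = c(0.5, 0.5, 0.5))
  W <- assemble_sensitivity(mesh, g, optical_properties(0.02, 7))
  truth <- numeric(ncol(W$W))
  ctr_idx <- which(W$mesh$fine &
                     rowSums(sweep(W$mesh$centers, 2, c(0, 0, 1.5))^2) < 0.3)
  truth[ctr_idx] <- 0.1
  pert <- as.vector(W$W %*% truth)
  rec <- reconstruct(pert, W, background_mua = 0.02, max_iter = 500,
                     tol = 1e-10)
  A <- rbind(Re(W$W), Im(W$W)); b <- c(Re(pert), Im(pert))
  closed <- solve(crossprod(A) + rec$lambda^2 * diag(ncol(A)),
                  crossprod(A, b))
  bias <- sqrt(sum((closed - truth)^2)) / sqrt(sum(truth^2))
  rel <- sqrt(sum((rec$delta_mua - truth)^2)) / sqrt(sum(truth^2))
  expect_lte(rel, bias + 1e-6)
  # and the brightest fine voxel is in the seeded region
  fine_idx <- which(W$mesh$fine)
  expect_true(fine_idx[which.max(rec$delta_mua[fine_idx])] %in% ctr_idx)
})

test_that("matched reconstructions localize spherical lesions inside the target", {
  g <- probe_geometry()
  for (depth in c(1.6, 2.0, 2.4)) {
    sc <- plain_sphere_scene(center = c(0.2, -0.1, depth), radius = 1)
    sm <- make_training_sample(sc, g, noise_fraction = 0, phase_noise_sd = 0,
                               rng_seed = 1)
    roi <- c(-1.7, 2.1, -2, 1.8, max(0, depth - 1.5), min(4, depth + 1.5))
    W <- assemble_sensitivity(build_dual_mesh(roi), g, sc$background)
    rec <- suppressWarnings(
      reconstruct(sm$pert, W, background_mua = sc$background$mua,
                  column_weighting = "layer", max_iter = 500))
    fine <- rec$mesh$fine
    am <- rec$mesh$centers[fine, , drop = FALSE][
      which.max(rec$delta_mua[fine]), ]
    expect_lt(sqrt(sum((am - sc$target$center)^2)), 1)
    com_err <- centroid_distance(pmax(rec$delta_mua[fine], 0),
                                 rec$mesh$centers[fine, ],
                                 sc$target$center[c(1, 3)])
    expect_lt(com_err, 1)
  }
})

test_that("reconstructed contrast rises with true target absorption", {
  g <- probe_geometry()
  maxima <- sapply(c(0.10, 0.18, 0.28), function(mua_t) {
    sc <- plain_sphere_scene(target_mua = mua_t)
    sm <- make_training_sample(sc, g, noise_fraction = 0, phase_noise_sd = 0,
                               rng_seed = 1)
    roi <- c(-1.5, 1.5, -1.5, 1.5, 0.5, 2.5)
    W <- assemble_sensitivity(build_dual_mesh(roi), g, sc$background)
    rec <- suppressWarnings(
      reconstruct(sm$pert, W, background_mua = sc$background$mua,
                  column_weighting = "layer", max_iter = 500))
    rec$max_mua
  })
  expect_true(all(diff(maxima) > 0))
})

test_that("hemoglobin unmixing is exact on noiseless constructed maps", {
  set.seed(6)
  E <- log(10) * 1e-6 * cbind(dotdiff:::.hb_extinction$hbo2,
                              dotdiff:::.hb_extinction$hb)
  conc <- cbind(runif(20, 0, 40), runif(20, 0, 30))   # uM
  mua <- conc %*% t(E)
  maps <- lapply(1:4, function(j) mua[, j])
  r <- compute_thb(maps)
  expect_equal(r$hbo2, conc[, 1], tolerance = 1e-9)
  expect_equal(r$hb, conc[, 2], tolerance = 1e-9)
  expect_equal(r$thb, rowSums(conc), tolerance = 1e-9)
  z <- compute_thb(lapply(1:4, function(j) rep(0, 5)))
  expect_equal(z$thb, rep(0, 5))
  expect_error(compute_thb(maps[1:3], c(730, 785, 808)), "missing")
})

test_that("hemoglobin unmixing is nonnegative and noise-stable", {
  set.seed(9)
  E <- log(10) * 1e-6 * cbind(dotdiff:::.hb_extinction$hbo2,
                              dotdiff:::.hb_extinction$hb)
  conc <- cbind(runif(200, 0, 40), runif(200, 0, 30))
  sigma <- 0.002   # 1/cm absorption noise
  mua <- conc %*% t(E) + matrix(rnorm(800, 0, sigma), 200, 4)
  r <- compute_thb(lapply(1:4, function(j) mua[, j]))
  expect_true(all(r$hbo2 >= 0), all(r$hb >= 0))
  # error bound from propagating the absorption noise through the
  # pseudo-inverse
  amp <- norm(solve(crossprod(E), t(E)), "2") * sigma
  expect_lt(mean(abs(r$thb - rowSums(conc))), 4 * amp)
})
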