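# Forward model: geometry, Green's function, homogeneous and perturbed
# simulation.

test_that("probe geometry pairs up sources and detectors consistently", {
  g <- probe_geometry()
  expect_equal(g$n_pairs, g$n_sources * g$n_detectors)
  expect_equal(2 * g$n_pairs, 252)  # the network interface width
  expect_true(all(g$source_positions[, 3] == 0))
  expect_true(all(g$detector_positions[, 3] == 0))
  d <- sqrt((g$source_positions[g$pairs$source_id, 1] -
               g$detector_positions[g$pairs$detector_id, 1])^2 +
            (g$source_positions[g$pairs$source_id, 2] -
               g$detector_positions[g$pairs$detector_id, 2])^2)
  expect_equal(g$pairs$rho, d)
  expect_error(probe_geometry(source_positions = cbind(1, 1, 0.5)),
               "z = 0")
})

test_that("optical property validation rejects non-physical media", {
  expect_error(optical_properties(-0.01, 7), "positive")
  expect_error(optical_properties(0.02, 0), "positive")
  expect_warning(optical_properties(0.5, 1), "diffusion")
})

test_that("Green's function is reciprocal for buried points", {
  props <- optical_properties(0.03, 6)
  set.seed(4)
  for (i in 1:5) {
    a <- c(runif(2, -3, 3), runif(1, 0.5, 3))
    b <- c(runif(2, -3, 3), runif(1, 0.5, 3))
    expect_equal(semi_infinite_green(a, b, props),
                 semi_infinite_green(b, a, props), tolerance = 1e-14)
  }
})

test_that("zero modulation frequency gives a real positive DC field", {
  props <- optical_properties(0.02, 7)
  gdc <- semi_infinite_green(c(0, 0, 0), c(3, 0, 0), props, omega = 0)
  expect_equal(Im(gdc), 0)
  expect_gt(Re(gdc), 0)
  # continuity: the FD solution approaches the DC solution as omega -> 0
  gsmall <- semi_infinite_green(c(0, 0, 0), c(3, 0, 0), props, omega = 2 * pi * 10)
  expect_equal(Mod(gsmall), Re(gdc), tolerance = 1e-6)
})

test_that("Green's function matches an independently coded image-source formula", {
  # textbook extrapolated-boundary solution written out longhand,
  # independent of the package internals
  mua <- 0.02; musp <- 7; n <- 1.333; rho <- 3; f <- 140e6
  cvac <- 2.99792458e10
  D <- 1 / (3 * (mua + musp))
  k <- sqrt((mua - 1i * 2 * pi * f * n / cvac) / D)
  if (Re(k) < 0) k <- -k
  Reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  zb <- 2 * D * (1 + Reff) / (1 - Reff)
  z0 <- 1 / musp
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  expected <- (exp(-k * r1) / r1 - exp(-k * r2) / r2) / (4 * pi * D)

  got <- semi_infinite_green(c(0, 0, 0), c(rho, 0, 0),
                             optical_properties(mua, musp),
                             omega = 2 * pi * f)
  expect_equal(got, expected, tolerance = 1e-13)
})

test_that("Green's function rejects singular and invalid configurations", {
  props <- optical_properties(0.02, 7)
  expect_error(semi_infinite_green(c(0, 0, 1), c(0, 0, 1), props),
               "singular")
  expect_error(semi_infinite_green(c(0, 0, -0.1), c(1, 0, 0), props),
               "z >= 0")
})

test_that("homogeneous simulation equals per-pair Green's function calls", {
  g <- tiny_geometry()
  props <- optical_properties(0.025, 5.5)
  m <- simulate_homogeneous(g, props)
  for (i in seq_len(g$n_pairs)) {
    u <- semi_infinite_green(g$source_positions[g$pairs$source_id[i], ],
                             g$detector_positions[g$pairs$detector_id[i], ],
                             props, omega = 2 * pi * g$modulation_frequency)
    expect_equal(m$U[i], u, tolerance = 1e-14)
  }
})

test_that("homogeneous field attenuates and delays with distance", {
  g <- probe_geometry()
  m <- simulate_homogeneous(g, optical_properties(0.02, 7))
  for (s in 1:g$n_sources) {
    idx <- which(m$source_id == s)
    idx <- idx[order(m$rho[idx])]
    idx <- idx[!duplicated(round(m$rho[idx], 9))]  # symmetric pairs tie
    expect_true(all(diff(m$amplitude[idx] * m$rho[idx]^2) < 0))
    expect_true(all(diff(m$phase[idx]) > 0))
  }
})

test_that("raising absorption lowers amplitude at every pair", {
  g <- tiny_geometry()
  m1 <- simulate_homogeneous(g, optical_properties(0.02, 7))
  m2 <- simulate_homogeneous(g, optical_properties(0.04, 7))
  expect_true(all(m2$amplitude < m1$amplitude))
})

test_that("Born kernel matches the global-absorption derivative of log U", {
  # summing the kernel over a discretized half space must reproduce
  # d log(U) / d mua of the homogeneous solution (finite difference)
  g <- tiny_geometry()
  props <- optical_properties(0.02, 7)
  h <- 0.5
  s <- seq(-6 + h / 2, 6 - h / 2, by = h)
  zz <- seq(h / 2, 6, by = h)
  gr <- as.matrix(expand.grid(x = s, y = s, z = zz))
  b <- as.vector(born_kernel(g, gr, h^3, props) %*% rep(1, nrow(gr)))
  eps <- 1e-4
  fd <- (log(simulate_homogeneous(g, optical_properties(0.02 + eps, 7))$U) -
           log(simulate_homogeneous(g, props)$U)) / eps
  expect_equal(Re(b), Re(fd), tolerance = 0.08)
  expect_equal(Im(b), Im(fd), tolerance = 0.08)
})

test_that("empty inclusion list reproduces the homogeneous field", {
  g <- tiny_geometry()
  props <- optical_properties(0.02, 7)
  for (lin in c("rytov", "born")) {
    m <- simulate_with_inclusions(g, props, list(), linearization = lin)
    expect_equal(m$U, simulate_homogeneous(g, props)$U, tolerance = 1e-14)
  }
})

test_that("an absorbing sphere darkens the pairs above it", {
  g <- probe_geometry()
  props <- optical_properties(0.02, 7)
  inc <- sphere_inclusion(c(0, 0, 1.5), 0.8, 0.1)
  m0 <- simulate_homogeneous(g, props)
  # pairs above the sphere: source-detector midpoint over the target
  mid <- (g$source_positions[g$pairs$source_id, 1:2] +
            g$detector_positions[g$pairs$detector_id, 1:2]) / 2
  above <- sqrt(rowSums(mid^2)) < 2.5
  for (lin in c("rytov", "born")) {
    m <- simulate_with_inclusions(g, props, list(inc), linearization = lin)
    pert <- (m$U - m0$U) / m0$U
    expect_true(all(Re(pert[above]) < 0))
  }
  # the saturating forward keeps every pair's real part non-positive
  mr <- simulate_with_inclusions(g, props, list(inc))
  expect_true(all(Re((mr$U - m0$U) / m0$U) <= 0))
})

test_that("the Born perturbation is linear and additive in delta mua", {
  g <- tiny_geometry()
  props <- optical_properties(0.02, 7)
  inc1 <- sphere_inclusion(c(-0.8, 0, 1.2), 0.5, 0.1)
  inc2 <- sphere_inclusion(c(1.2, 0.5, 2.0), 0.6, 0.06)
  u0 <- simulate_homogeneous(g, props)$U
  pert_of <- function(incs) {
    (simulate_with_inclusions(g, props, incs, linearization = "born")$U - u0) / u0
  }
  half <- inc1; half$delta_mua <- inc1$delta_mua / 2
  expect_equal(pert_of(list(half)), pert_of(list(inc1)) / 2,
               tolerance = 1e-12)
  expect_equal(pert_of(list(inc1, inc2)),
               pert_of(list(inc1)) + pert_of(list(inc2)),
               tolerance = 1e-12)
})

test_that("inclusion voxels must sit strictly inside the medium", {
  g <- tiny_geometry()
  props <- optical_properties(0.02, 7)
  bad <- list(centers = matrix(c(0, 0, 0), 1), volumes = 0.01,
              delta_mua = 0.1)
  expect_error(simulate_with_inclusions(g, props, list(bad)), "z > 0")
})
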