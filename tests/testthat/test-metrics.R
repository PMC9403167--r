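# Image-quality metrics: SSIM, target-to-artifact ratio, centroid
# distance, and the held-out test summary.

test_that("SSIM is 1 for identical images and below 1 for dissimilar ones", {
  set.seed(2)
  m <- matrix(runif(15 * 15), 15, 15)
  expect_equal(ssim_map(m, m), 1)
  flipped <- max(m) + min(m) - m   # range-symmetric negation
  expect_lt(ssim_map(flipped, m), 1)
  expect_lt(ssim_map(flipped, m), 0.5)
  expect_error(ssim_map(m[1:4, 1:4], m), "shapes")
})

test_that("SSIM is symmetric for images sharing a dynamic range", {
  set.seed(3)
  a <- matrix(runif(100), 10, 10); a[1] <- 0; a[100] <- 1
  b <- matrix(runif(100), 10, 10); b[1] <- 0; b[100] <- 1
  expect_equal(ssim_map(a, b), ssim_map(b, a), tolerance = 1e-12)
})

test_that("SSIM matches a longhand windowed computation on a small pair", {
  set.seed(4)
  x <- matrix(runif(64), 8, 8)
  y <- x + matrix(rnorm(64, 0, 0.1), 8, 8)
  # independent longhand implementation: explicit per-pixel window loops
  win <- 7; sigma <- 1.5
  off <- -(win %/% 2):(win %/% 2)
  wv <- outer(exp(-off^2 / (2 * sigma^2)), exp(-off^2 / (2 * sigma^2)))
  L <- diff(range(y)); C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  svals <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    acc <- c(w = 0, x = 0, y = 0, xx = 0, yy = 0, xy = 0)
    for (a in off) for (b in off) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8) {
        w <- wv[a + 4, b + 4]
        acc <- acc + c(w, w * x[ii, jj], w * y[ii, jj],
                       w * x[ii, jj]^2, w * y[ii, jj]^2,
                       w * x[ii, jj] * y[ii, jj])
      }
    }
    mx <- acc["x"] / acc["w"]; my <- acc["y"] / acc["w"]
    vx <- acc["xx"] / acc["w"] - mx^2; vy <- acc["yy"] / acc["w"] - my^2
    cxy <- acc["xy"] / acc["w"] - mx * my
    svals[i, j] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  expect_equal(ssim_map(x, y, window_size = 7), mean(svals),
               tolerance = 1e-12)
})

test_that("target-to-artifact ratio handles the canonical cases", {
  centers <- as.matrix(expand.grid(x = seq(-3.5, 3.5), y = seq(-3.5, 3.5),
                                   z = c(1, 2)))
  inside <- abs(centers[, 1]) <= 1.5 & abs(centers[, 2]) <= 1.5
  v <- numeric(nrow(centers))
  # all signal inside, outside zero -> infinity sentinel
  v[inside] <- 4
  expect_identical(target_artifact_ratio(v, centers, c(0, 0), 0.5), Inf)
  # uniform map -> ratio 1
  expect_equal(target_artifact_ratio(rep(2, nrow(centers)), centers,
                                     c(0, 0), 0.5), 1)
  # inside max 10, outside max 2 -> 5
  v2 <- numeric(nrow(centers)); v2[inside] <- 10; v2[!inside][3] <- 2
  expect_equal(target_artifact_ratio(v2, centers, c(0, 0), 0.5), 5)
  # negative values are clipped before maxima
  v3 <- v2; v3[!inside] <- -5
  expect_identical(target_artifact_ratio(v3, centers, c(0, 0), 0.5), Inf)
  # lesion area swallowing the map is undefined
  expect_error(target_artifact_ratio(v2, centers, c(0, 0), 10), "whole map")
})

test_that("per-depth footprints widen the lesion area depth by depth", {
  centers <- as.matrix(expand.grid(x = seq(-3.5, 3.5), y = 0, z = c(1, 2)))
  hw <- cbind(c(1, 2), c(0.2, 1))   # narrow at z=1, wide at z=2
  v <- numeric(nrow(centers))
  v[centers[, 1] == 2.5 & centers[, 3] == 1] <- 7  # outside 3*0.2 at z=1
  v[centers[, 1] == 2.5 & centers[, 3] == 2] <- 9  # inside 3*1 at z=2
  expect_equal(target_artifact_ratio(v, centers, c(0, 0), hw), 9 / 7)
})

test_that("centroid distance measures center-of-mass offsets", {
  centers <- as.matrix(expand.grid(x = seq(-2, 2, 0.5), y = seq(-2, 2, 0.5),
                                   z = seq(0.5, 3, 0.5)))
  # delta map at the truth centroid
  v <- numeric(nrow(centers))
  v[centers[, 1] == 1 & centers[, 2] == 0 & centers[, 3] == 2] <- 5
  expect_equal(centroid_distance(v, centers, c(1, 2)), 0)
  # delta 1 cm off in x
  v2 <- numeric(nrow(centers))
  v2[centers[, 1] == 2 & centers[, 2] == 0 & centers[, 3] == 2] <- 5
  expect_equal(centroid_distance(v2, centers, c(1, 2)), 1)
  # two voxels, hand-computed weighted mean
  v3 <- numeric(nrow(centers))
  v3[centers[, 1] == 0 & centers[, 2] == 0 & centers[, 3] == 1] <- 1
  v3[centers[, 1] == 1 & centers[, 2] == 0 & centers[, 3] == 2] <- 3
  com <- c(3 / 4 * 1, 0, 1 * 1 / 4 + 2 * 3 / 4)
  expect_equal(centroid_distance(v3, centers, c(0.5, 1.5)),
               sqrt((com[1] - 0.5)^2 + (com[3] - 1.5)^2))
  # negative weights are clipped, all-zero is an error
  expect_error(centroid_distance(numeric(nrow(centers)), centers, c(0, 0)),
               "all-zero")
})

test_that("rendered ground truth marks exactly the voxels inside the target", {
  sc <- plain_sphere_scene(center = c(0, 0, 1.5), radius = 0.8)
  centers <- as.matrix(expand.grid(x = seq(-2, 2, 0.25),
                                   y = seq(-2, 2, 0.25),
                                   z = seq(0.25, 3, 0.25)))
  truth <- render_truth(sc, centers)
  d <- sqrt(rowSums(sweep(centers, 2, sc$target$center)^2))
  expect_equal(truth > 0, d <= 0.8)
  expect_equal(max(truth), sc$target$mua - sc$background$mua)
})

test_that("an oracle model that returns the matched perturbation scores zero", {
  g <- probe_geometry()
  registerS3method("predict", "oracle_model",
                   function(object, newdata, ...) {
                     perturbation((newdata$U - newdata$oracle_ref$U) /
                                    newdata$oracle_ref$U,
                                  wavelength = newdata$wavelength,
                                  provenance = "ann_predicted",
                                  geometry = newdata$geometry)
                   })
  oracle <- structure(list(), class = "oracle_model")
  samples <- lapply(c(2, 9), function(seed) {
    sm <- make_training_sample(sample_scene(seed), g, rng_seed = seed)
    sm$Ul$oracle_ref <- sm$Ur    # the oracle sees the matched reference
    sm
  })
  rep <- simulation_test_summary(samples, oracle, g, n_boot = 50)
  expect_equal(rep$cases$abs_diff, c(0, 0), tolerance = 1e-12)
  expect_equal(rep$mean_abs_diff, 0, tolerance = 1e-12)
})

test_that("the test summary is invariant to case ordering", {
  g <- probe_geometry()
  corp <- build_corpus(10, g, rng_seed = 3)
  m <- pert_ann(corp$train, corp$validation, epochs = 2, rng_seed = 1)
  samples <- lapply(c(4, 15, 33), function(seed)
    make_training_sample(sample_scene(seed), g, rng_seed = seed))
  r1 <- simulation_test_summary(samples, m, g, n_boot = 50)
  r2 <- simulation_test_summary(rev(samples), m, g, n_boot = 50)
  expect_equal(r1$mean_abs_diff, r2$mean_abs_diff, tolerance = 1e-12)
  expect_equal(sort(r1$cases$abs_diff), sort(r2$cases$abs_diff),
               tolerance = 1e-12)
})
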