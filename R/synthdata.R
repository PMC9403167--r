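# Synthetic corpus generator: randomized breast-like scenes (lesion target,
# optional chest-wall slab, smooth tissue heterogeneity), paired
# lesion/reference measurements, matched perturbation ground truth, and
# measurement noise.

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit sub-seed for stage `key` of a run seeded with `seed`.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(key, ":", seed)))
    h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

#' Sample a random imaging scene
#'
#' Draws one scene from the simulation corpus distribution: uniform target
#' radius 0.375 to 1.5 cm, center depth 0.6 to 2.7 cm (resampled until the
#' target lies fully below the surface), target absorption 0.08 to
#' 0.30 1/cm, background absorption 0.01 to 0.06 1/cm, reduced scattering
#' 4 to 8 1/cm for target and background; an optional chest wall
#' (probability `chest_wall_prob`) at depth 1.6 to 5 cm below the surface
#' (resampled until it clears the target bottom), tilt -10 to 10 degrees,
#' absorption 0.1 to 0.2 1/cm; and a smooth random background-absorption
#' heterogeneity field with relative amplitude up to 20%.  Target shape is
#' a sphere or a low-order spherical-harmonic perturbed sphere (irregular
#' lesion stand-in) with equal probability; for irregular shapes the
#' nominal radius is half the largest z extent.
#'
#' @param rng_seed integer seed; the same seed reproduces the same scene.
#' @param chest_wall_prob probability that the scene has a chest wall.
#' @return object of class `dot_scene`.
#' @export
sample_scene <- function(rng_seed, chest_wall_prob = 0.5) {
  with_seed(rng_seed, {
    radius <- runif(1, 0.375, 1.5)
    repeat {
      depth <- runif(1, 0.6, 2.7)
      if (depth - radius > 0.05) break
    }
    shape <- sample(c("sphere", "perturbed-ellipsoid"), 1)
    harmonics <- if (shape == "perturbed-ellipsoid")
      pmax(pmin(stats::rnorm(5, 0, 0.12), 0.3), -0.3) else numeric(5)
    target <- list(shape = shape,
                   center = c(runif(1, -1, 1), runif(1, -1, 1), depth),
                   radius = radius,
                   mua = runif(1, 0.08, 0.30),
                   musp = runif(1, 4, 8),
                   harmonics = harmonics)
    background <- optical_properties(runif(1, 0.01, 0.06), runif(1, 4, 8))
    chest_wall <- NULL
    if (runif(1) < chest_wall_prob) {
      repeat {
        cw_depth <- runif(1, 1.6, 5)
        if (cw_depth > depth + radius + 0.2) break
      }
      chest_wall <- list(depth = cw_depth,
                         tilt = runif(1, -10, 10),
                         mua = runif(1, 0.1, 0.2),
                         musp = runif(1, 4, 8))
    }
    structure(list(background = background, target = target,
                   chest_wall = chest_wall,
                   heterogeneity = list(amplitude_frac = runif(1, 0, 0.2),
                                        corr_length = runif(1, 1, 2),
                                        seed = sample.int(2^31 - 1, 1)),
                   seed = rng_seed),
              class = "dot_scene")
  })
}

#' @export
print.dot_scene <- function(x, ...) {
  t <- x$target
  cat(sprintf("scene: %s target r=%.2f cm at (%.2f, %.2f, %.2f), mua=%.3f /cm\n",
              t$shape, t$radius, t$center[1], t$center[2], t$center[3], t$mua))
  cat(sprintf("  background mua=%.3f musp=%.2f; chest wall: %s; heterogeneity %.0f%%\n",
              x$background$mua, x$background$musp,
              if (is.null(x$chest_wall)) "none" else
                sprintf("depth %.2f cm, tilt %.1f deg, mua %.3f",
                        x$chest_wall$depth, x$chest_wall$tilt, x$chest_wall$mua),
              100 * x$heterogeneity$amplitude_frac))
  invisible(x)
}

# Voxelize the scene target.  Membership test against a direction-dependent
# radius: r(u) = radius * (1 + sum of low-order real spherical harmonics),
# which reduces to a sphere when all harmonic coefficients are zero.
target_voxels <- function(target, h = 0.25) {
  r0 <- target$radius
  rmax <- r0 * (1 + sum(abs(target$harmonics)))
  s <- seq(-rmax - h / 2, rmax + h / 2, by = h)
  gr <- as.matrix(expand.grid(x = s, y = s, z = s))
  d <- sqrt(rowSums(gr^2))
  u <- gr / pmax(d, 1e-12)
  a <- target$harmonics
  # real spherical harmonics l = 1, 2 (unnormalized angular factors)
  rdir <- r0 * (1 + a[1] * u[, 3] + a[2] * u[, 1] +
                  a[3] * (3 * u[, 3]^2 - 1) / 2 +
                  a[4] * (u[, 1]^2 - u[, 2]^2) +
                  a[5] * u[, 1] * u[, 2])
  keep <- d <= rdir
  centers <- sweep(gr[keep, , drop = FALSE], 2, target$center, "+")
  inside <- centers[, 3] > h / 4   # clip anything poking above the surface
  list(centers = centers[inside, , drop = FALSE], volumes = h^3)
}

# Chest-wall slab: voxels between the tilted top plane
# z = depth + x tan(tilt) and a parallel plane `thickness` below it.
chest_wall_voxels <- function(chest_wall, h = 0.5, lateral = 5,
                              thickness = 2, zmax = 8) {
  s <- seq(-lateral + h / 2, lateral - h / 2, by = h)
  zz <- seq(h / 2, zmax, by = h)
  gr <- as.matrix(expand.grid(x = s, y = s, z = zz))
  ztop <- chest_wall$depth + gr[, 1] * tanpi(chest_wall$tilt / 180)
  keep <- gr[, 3] >= ztop & gr[, 3] < ztop + thickness & gr[, 3] > 0
  list(centers = gr[keep, , drop = FALSE], volumes = h^3)
}

# Smooth Gaussian random absorption field on a coarse grid: white noise
# smoothed with a squared-exponential kernel of the scene's correlation
# length, rescaled so max |delta mua| = amplitude_frac * background mua.
heterogeneity_field <- function(het, background, h = 1.0,
                                bounds = c(-4, 4, -4, 4, 0, 4)) {
  if (het$amplitude_frac <= 0) return(NULL)
  xs <- seq(bounds[1] + h / 2, bounds[2] - h / 2, by = h)
  ys <- seq(bounds[3] + h / 2, bounds[4] - h / 2, by = h)
  zs <- seq(bounds[5] + h / 2, bounds[6] - h / 2, by = h)
  gr <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  w <- with_seed(het$seed, stats::rnorm(nrow(gr)))
  d2 <- as.matrix(stats::dist(gr))^2
  field <- as.vector(exp(-d2 / (2 * het$corr_length^2)) %*% w)
  field <- field / max(abs(field)) * het$amplitude_frac * background$mua
  list(centers = gr, volumes = h^3, delta_mua = field)
}

# Assemble the Born inclusion list of a scene.  `include_target` FALSE gives
# the matched reference side (same background, chest wall, heterogeneity).
scene_inclusions <- function(scene, include_target = TRUE,
                             chest_wall_depth = NULL) {
  inc <- list()
  if (include_target) {
    tv <- target_voxels(scene$target)
    inc <- c(inc, list(list(centers = tv$centers, volumes = tv$volumes,
                            delta_mua = scene$target$mua - scene$background$mua)))
  }
  if (!is.null(scene$chest_wall)) {
    cw <- scene$chest_wall
    if (!is.null(chest_wall_depth)) cw$depth <- chest_wall_depth
    cv <- chest_wall_voxels(cw)
    inc <- c(inc, list(list(centers = cv$centers, volumes = cv$volumes,
                            delta_mua = cw$mua - scene$background$mua)))
  }
  hf <- heterogeneity_field(scene$heterogeneity, scene$background)
  if (!is.null(hf)) inc <- c(inc, list(hf))
  inc
}

#' Simulate one training sample from a scene
#'
#' Runs the forward model for the lesion side (target + chest wall +
#' heterogeneity) and the matched reference side (identical background
#' without the target), adds measurement noise to the lesion-side
#' amplitudes (multiplicative Gaussian, sd `noise_fraction`) and phases
#' (additive Gaussian, sd `phase_noise_sd` rad), and computes the matched
#' normalized perturbation from the noise-free fields as the learning
#' target.
#'
#' @param scene a [sample_scene()] result.
#' @param geometry a [probe_geometry()].
#' @param noise_fraction relative amplitude noise sd (default 2%).
#' @param phase_noise_sd additive phase noise sd, rad.
#' @param rng_seed seed for the noise draw.
#' @param wavelength nm (metadata; the generator is wavelength-agnostic,
#'   properties span the plausible range of all four system wavelengths).
#' @return object of class `training_sample`: noisy lesion measurement
#'   `Ul`, noise-free `Ul_clean` and matched reference `Ur`, matched
#'   perturbation `pert`, the scene, and the seed record.
#' @export
make_training_sample <- function(scene, geometry, noise_fraction = 0.02,
                                 phase_noise_sd = 0.02, rng_seed = 1,
                                 wavelength = 785) {
  # the Rytov exponent is additive over inclusions, so the shared
  # background structures (chest wall, heterogeneity) are computed once
  # and reused for both sides
  fp <- forward_model_params(scene$background,
                             2 * pi * geometry$modulation_frequency)
  u0 <- .homogeneous_pairs(geometry, fp)
  tv <- target_voxels(scene$target)
  b_target <- born_exponent(geometry, scene$background,
                            list(list(centers = tv$centers,
                                      volumes = tv$volumes,
                                      delta_mua = scene$target$mua -
                                        scene$background$mua)),
                            amplitude_at_dc = TRUE)
  b_shared <- born_exponent(geometry, scene$background,
                            scene_inclusions(scene, include_target = FALSE),
                            amplitude_at_dc = TRUE)
  ul_clean <- fd_measurement(geometry, u0 * exp(b_target + b_shared),
                             wavelength)
  ur_clean <- fd_measurement(geometry, u0 * exp(b_shared), wavelength)
  ul_noisy <- with_seed(rng_seed, add_measurement_noise(ul_clean,
                                                        noise_fraction,
                                                        phase_noise_sd))
  structure(list(scene = scene,
                 Ul = ul_noisy, Ul_clean = ul_clean, Ur = ur_clean,
                 pert = compute_perturbation(ul_clean, ur_clean),
                 noise_fraction = noise_fraction,
                 phase_noise_sd = phase_noise_sd,
                 wavelength = wavelength,
                 rng_seed = rng_seed),
            class = "training_sample")
}

#' Add measurement noise to a frequency-domain measurement
#'
#' Multiplicative Gaussian amplitude noise (relative sd `noise_fraction`)
#' and additive Gaussian phase noise (`phase_noise_sd` rad), drawn
#' independently per source-detector pair.
#'
#' @param measurement an [fd_measurement()].
#' @param noise_fraction relative amplitude noise sd.
#' @param phase_noise_sd phase noise sd, rad.
#' @return a noisy [fd_measurement()].
#' @export
add_measurement_noise <- function(measurement, noise_fraction = 0.02,
                                  phase_noise_sd = 0.02) {
  n <- length(measurement$U)
  amp <- measurement$amplitude * (1 + stats::rnorm(n, 0, noise_fraction))
  amp <- pmax(amp, .Machine$double.eps * measurement$amplitude)
  ph <- measurement$phase + stats::rnorm(n, 0, phase_noise_sd)
  fd_measurement(measurement$geometry,
                 complex(modulus = amp, argument = ph),
                 measurement$wavelength)
}

#' Build a lesion/reference measurement triple with chest-wall mismatch
#'
#' Reproduces the mismatch scenario used to stress difference imaging: the
#' reference breast's chest wall sits shallower than the lesion side's by
#' `chest_wall_shift_cm` (3 cm vs 2 cm in the canonical case), while the
#' matched reference shares the lesion side's background exactly.
#'
#' @param scene a scene with a chest wall.
#' @param geometry a [probe_geometry()].
#' @param chest_wall_shift_cm how much shallower the mismatched reference
#'   chest wall is, cm.
#' @param noise_fraction relative amplitude noise sd for the lesion side.
#' @param phase_noise_sd phase noise sd, rad.
#' @param rng_seed seed for the noise draw.
#' @return list with noisy `Ul`, `Ur_mismatched`, `Ur_matched`, and the
#'   scene.
#' @export
make_mismatch_pair <- function(scene, geometry, chest_wall_shift_cm = 1,
                               noise_fraction = 0.02, phase_noise_sd = 0.02,
                               rng_seed = 1) {
  if (is.null(scene$chest_wall))
    stop("mismatch scenario requires a scene with a chest wall")
  shifted <- scene$chest_wall$depth - chest_wall_shift_cm
  if (shifted < scene$target$center[3] + scene$target$radius)
    warning("shifted chest wall is shallower than the target bottom")
  fp <- forward_model_params(scene$background,
                             2 * pi * geometry$modulation_frequency)
  u0 <- .homogeneous_pairs(geometry, fp)
  bexp <- function(inc) born_exponent(geometry, scene$background, inc,
                                      amplitude_at_dc = TRUE)
  tv <- target_voxels(scene$target)
  b_t <- bexp(list(list(centers = tv$centers, volumes = tv$volumes,
                        delta_mua = scene$target$mua - scene$background$mua)))
  hf <- heterogeneity_field(scene$heterogeneity, scene$background)
  b_h <- if (is.null(hf)) 0 else bexp(list(hf))
  cw <- function(depth) {
    w <- scene$chest_wall; w$depth <- depth
    cv <- chest_wall_voxels(w)
    bexp(list(list(centers = cv$centers, volumes = cv$volumes,
                   delta_mua = w$mua - scene$background$mua)))
  }
  b_cw <- cw(scene$chest_wall$depth)
  b_cw_shifted <- if (chest_wall_shift_cm == 0) b_cw else cw(shifted)
  ul <- fd_measurement(geometry, u0 * exp(b_t + b_cw + b_h))
  ur_m <- fd_measurement(geometry, u0 * exp(b_cw + b_h))
  ur_mm <- fd_measurement(geometry, u0 * exp(b_cw_shifted + b_h))
  ul_noisy <- with_seed(rng_seed, add_measurement_noise(ul, noise_fraction,
                                                        phase_noise_sd))
  list(Ul = ul_noisy, Ur_mismatched = ur_mm, Ur_matched = ur_m,
       scene = scene)
}

# Deterministic disjoint train/validation index split: floor(fraction * n)
# training rows, the remainder validation.
corpus_split <- function(n, train_fraction = 0.8, rng_seed = 1) {
  n_train <- floor(train_fraction * n)
  idx <- with_seed(rng_seed, sample.int(n))
  list(train = sort(idx[seq_len(n_train)]),
       validation = sort(idx[-seq_len(n_train)]))
}

#' Generate a training/validation corpus
#'
#' Samples `n_total` scenes, simulates one noisy training sample per scene,
#' encodes network inputs (offset log-amplitudes and phases) and targets
#' (real and imaginary matched perturbation), and splits the rows into
#' disjoint training (`floor(train_fraction * n_total)`) and validation
#' sets.  Fully determined by `rng_seed`.
#'
#' @param n_total number of scenes (>= 2).
#' @param geometry a [probe_geometry()].
#' @param train_fraction fraction of samples used for training.
#' @param rng_seed master seed.
#' @param noise_fraction relative amplitude noise sd.
#' @param chest_wall_prob probability of a chest wall per scene.
#' @param keep_samples keep the full per-sample simulation objects
#'   (measurements, scenes) in the returned corpora; disable to save
#'   memory for large corpora.
#' @return list with `train` and `validation`, each a `dot_corpus` holding
#'   the input matrix `X` (n x 252), target matrix `Y` (n x 252), and
#'   per-sample metadata.
#' @export
build_corpus <- function(n_total, geometry = probe_geometry(),
                         train_fraction = 0.8, rng_seed = 1,
                         noise_fraction = 0.02, chest_wall_prob = 0.5,
                         keep_samples = FALSE) {
  if (n_total < 2) stop("need at least 2 samples to split")
  scene_seeds <- vapply(seq_len(n_total),
                        function(i) derive_seed(rng_seed, paste0("scene", i)),
                        integer(1))
  noise_seeds <- vapply(seq_len(n_total),
                        function(i) derive_seed(rng_seed, paste0("noise", i)),
                        integer(1))
  X <- matrix(NA_real_, n_total, 2 * geometry$n_pairs)
  Y <- matrix(NA_real_, n_total, 2 * geometry$n_pairs)
  samples <- if (keep_samples) vector("list", n_total) else NULL
  scenes <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sc <- sample_scene(scene_seeds[i], chest_wall_prob = chest_wall_prob)
    sm <- make_training_sample(sc, geometry, noise_fraction = noise_fraction,
                               rng_seed = noise_seeds[i])
    X[i, ] <- encode_network_input(sm$Ul)
    Y[i, ] <- encode_network_target(sm$pert)
    scenes[[i]] <- sc
    if (keep_samples) samples[[i]] <- sm
  }
  split <- corpus_split(n_total, train_fraction,
                        derive_seed(rng_seed, "split"))
  subset_corpus <- function(idx) {
    structure(list(X = X[idx, , drop = FALSE], Y = Y[idx, , drop = FALSE],
                   scenes = scenes[idx],
                   samples = if (keep_samples) samples[idx] else NULL,
                   geometry = geometry,
                   noise_fraction = noise_fraction,
                   rng_seed = rng_seed, index = idx),
              class = "dot_corpus")
  }
  list(train = subset_corpus(split$train),
       validation = subset_corpus(split$validation))
}

#' @export
print.dot_corpus <- function(x, ...) {
  cat(sprintf("dot_corpus: %d samples x %d features (seed %s)\n",
              nrow(x$X), ncol(x$X), format(x$rng_seed)))
  invisible(x)
}
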