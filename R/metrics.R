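# Image-quality metrics for reconstructed absorption maps: structural
# similarity against rendered ground truth, target-to-artifact ratio
# inside/outside a widened lesion footprint, center-of-mass localization
# error, and the held-out simulation test summary.

# 2D Gaussian-window local mean with edge renormalization (the window is
# re-normalized where it overhangs the image border).
.local_mean <- function(img, win) {
  nr <- nrow(img); nc <- ncol(img)
  h <- (nrow(win) - 1) / 2
  out <- matrix(0, nr, nc); wsum <- matrix(0, nr, nc)
  for (di in -h:h) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    rs <- ri - di
    for (dj in -h:h) {
      cj <- max(1, 1 + dj):min(nc, nc + dj)
      cs <- cj - dj
      wv <- win[di + h + 1, dj + h + 1]
      out[rs, cs] <- out[rs, cs] + wv * img[ri, cj]
      wsum[rs, cs] <- wsum[rs, cs] + wv
    }
  }
  out / wsum
}

.gaussian_window <- function(size = 11, sigma = 1.5) {
  r <- seq(-(size - 1) / 2, (size - 1) / 2)
  w <- exp(-r^2 / (2 * sigma^2))
  W <- outer(w, w)
  W / sum(W)
}

#' Structural similarity between a reconstructed layer and its truth
#'
#' Standard windowed SSIM: local means, variances, and covariance under a
#' Gaussian window (11 x 11, sigma 1.5 by default), stabilized with
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2` where the dynamic range `L` is taken
#' from the truth image.  The mean of the local SSIM map is returned.
#'
#' @param recon_layer,truth_layer numeric matrices of equal shape.
#' @param window_size,sigma Gaussian window size (odd) and width.
#' @param K1,K2 stabilization constants.
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim_map <- function(recon_layer, truth_layer, window_size = 11,
                     sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  x <- as.matrix(recon_layer); y <- as.matrix(truth_layer)
  if (!identical(dim(x), dim(y)))
    stop("reconstruction and truth layers have different shapes")
  L <- diff(range(y))
  if (L == 0) L <- max(abs(y), 1e-12)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  win <- .gaussian_window(min(window_size, 2 * floor((min(dim(x)) - 1) / 2) + 1),
                          sigma)
  mx <- .local_mean(x, win); my <- .local_mean(y, win)
  vx <- .local_mean(x * x, win) - mx^2
  vy <- .local_mean(y * y, win) - my^2
  cxy <- .local_mean(x * y, win) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Target-to-artifact ratio of a reconstructed map
#'
#' Ratio of the maximum reconstructed value inside the lesion area to the
#' maximum outside it.  Mirroring the clinical definition, the lesion area
#' at each depth is the lateral box extending `factor` times the lesion
#' half-width from the lesion x/y center.  Negative values are clipped to
#' zero before taking maxima.  An all-zero outside region gives `Inf`; an
#' empty outside region is an error.
#'
#' @param values per-voxel map values.
#' @param centers voxel centers (n x 3), cm.
#' @param center_xy lesion x/y center, cm.
#' @param half_width lesion lateral half-width, cm (scalar, or a
#'   two-column matrix `cbind(z, half_width)` giving the per-depth
#'   footprint).
#' @param factor widening factor applied to the half-width (default 3).
#' @return scalar ratio (possibly `Inf`).
#' @export
target_artifact_ratio <- function(values, centers, center_xy, half_width,
                                  factor = 3) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  v <- pmax(as.numeric(values), 0)
  hw <- if (is.matrix(half_width)) {
    stats::approx(half_width[, 1], half_width[, 2], xout = centers[, 3],
                  rule = 2)$y
  } else rep(half_width, nrow(centers))
  inside <- abs(centers[, 1] - center_xy[1]) <= factor * hw &
            abs(centers[, 2] - center_xy[2]) <= factor * hw
  if (!any(!inside)) stop("lesion area covers the whole map: ratio undefined")
  if (!any(inside)) stop("lesion area contains no voxels")
  out_max <- max(v[!inside])
  if (out_max == 0) return(Inf)
  max(v[inside]) / out_max
}

#' Localization error of a reconstructed map
#'
#' Euclidean distance between the intensity-weighted center of mass of the
#' map (negative values clipped to zero) and the true lesion centroid,
#' whose y coordinate is taken as 0 (the ultrasound B-scan convention of
#' reporting x/z centroids only).
#'
#' @param values per-voxel map values.
#' @param centers voxel centers (n x 3), cm.
#' @param truth_centroid numeric length 2, the true `(x, z)` centroid, cm.
#' @return distance in cm.
#' @export
centroid_distance <- function(values, centers, truth_centroid) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  w <- pmax(as.numeric(values), 0)
  if (sum(w) == 0) stop("all-zero map: center of mass undefined")
  com <- colSums(centers * w) / sum(w)
  sqrt((com[1] - truth_centroid[1])^2 + com[2]^2 +
       (com[3] - truth_centroid[2])^2)
}

#' Render the ground-truth absorption map of a scene on a mesh
#'
#' Voxel-center membership test against the scene target: voxels whose
#' center falls inside the (possibly harmonically perturbed) target get
#' the target-background absorption contrast, others zero.
#'
#' @param scene a [sample_scene()] scene.
#' @param centers voxel centers (n x 3), cm.
#' @return per-voxel true `delta_mua`, 1/cm.
#' @export
render_truth <- function(scene, centers) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  rel <- sweep(centers, 2, scene$target$center)
  d <- sqrt(rowSums(rel^2))
  u <- rel / pmax(d, 1e-12)
  a <- scene$target$harmonics
  rdir <- scene$target$radius *
    (1 + a[1] * u[, 3] + a[2] * u[, 1] +
       a[3] * (3 * u[, 3]^2 - 1) / 2 +
       a[4] * (u[, 1]^2 - u[, 2]^2) + a[5] * u[, 1] * u[, 2])
  ifelse(d <= rdir, scene$target$mua - scene$background$mua, 0)
}

#' Reconstruct one held-out sample along the three perturbation pathways
#'
#' For a simulated sample, computes the measured matched perturbation
#' (noisy lesion measurement against the matched reference), the network
#' prediction (from the noisy lesion measurement alone), and optionally a
#' mismatched measured perturbation, and reconstructs each on a dual mesh
#' whose ROI is the scene's known target bounding box (the synthetic
#' stand-in for ultrasound guidance).
#'
#' @param sample a [make_training_sample()] result (or the list from
#'   [make_mismatch_pair()], which adds the mismatched pathway).
#' @param model a fitted [pert_ann()].
#' @param geometry a [probe_geometry()].
#' @param roi_margin margin added around the target bounding box, cm.
#' @param lam regularization (NULL for the default rule).
#' @param column_weighting passed to [reconstruct()]; the evaluation
#'   pipeline uses depth compensation by default.
#' @param max_iter conjugate-gradient iteration cap.
#' @return list of `dot_recon` objects (`matched`, `ann`, and possibly
#'   `mismatched`) plus the sensitivity matrix used.
#' @export
evaluate_sample <- function(sample, model, geometry, roi_margin = 0.5,
                            lam = NULL, column_weighting = "layer",
                            max_iter = 500) {
  scene <- sample$scene
  ctr <- scene$target$center; r <- scene$target$radius
  roi <- c(ctr[1] - r - roi_margin, ctr[1] + r + roi_margin,
           ctr[2] - r - roi_margin, ctr[2] + r + roi_margin,
           max(0, ctr[3] - r - roi_margin), ctr[3] + r + roi_margin)
  vb <- c(-4, 4, -4, 4, 0, 4)
  roi <- c(max(roi[1], vb[1]), min(roi[2], vb[2]),
           max(roi[3], vb[3]), min(roi[4], vb[4]),
           max(roi[5], vb[5]), min(roi[6], vb[6]))
  mesh <- build_dual_mesh(roi, vb)
  W <- assemble_sensitivity(mesh, geometry, scene$background)
  ur_matched <- if (!is.null(sample$Ur)) sample$Ur else sample$Ur_matched
  pert_matched <- compute_perturbation(sample$Ul, ur_matched)
  pert_ann_pred <- predict(model, sample$Ul)
  rec <- function(p) suppressWarnings(
    reconstruct(p, W, lam = lam, background_mua = scene$background$mua,
                column_weighting = column_weighting, max_iter = max_iter))
  out <- list(matched = rec(pert_matched), ann = rec(pert_ann_pred),
              W = W)
  out$lambda <- out$matched$lambda
  if (!is.null(sample$Ur_mismatched)) {
    pert_mm <- compute_perturbation(sample$Ul, sample$Ur_mismatched,
                                    provenance = "measured_mismatched")
    out$mismatched <- rec(pert_mm)
    out$pert_mismatched <- pert_mm
  }
  out$pert_matched <- pert_matched
  out$pert_ann <- pert_ann_pred
  out
}

#' Held-out simulation test summary
#'
#' For every held-out sample, reconstructs the absorption map from the
#' network-predicted perturbation and from the measured matched
#' perturbation, and reports the per-case absolute difference of the
#' maximum reconstructed absorption, aggregated as a mean with a seeded
#' bootstrap 95% confidence interval.
#'
#' @param samples list of held-out [make_training_sample()] samples.
#' @param model a fitted [pert_ann()].
#' @param geometry a [probe_geometry()].
#' @param n_boot bootstrap resamples for the confidence interval.
#' @param rng_seed bootstrap seed.
#' @param ... passed to [evaluate_sample()].
#' @return object of class `dot_eval_report`: per-case table and the
#'   aggregate `mean_abs_diff` with `ci95`.
#' @export
simulation_test_summary <- function(samples, model,
                                    geometry = probe_geometry(),
                                    n_boot = 1000, rng_seed = 1, ...) {
  rows <- lapply(seq_along(samples), function(i) {
    ev <- evaluate_sample(samples[[i]], model, geometry, ...)
    scene <- samples[[i]]$scene
    data.frame(case = i,
               true_mua = scene$target$mua,
               max_mua_matched = ev$matched$max_mua,
               max_mua_ann = ev$ann$max_mua,
               abs_diff = abs(ev$ann$max_mua - ev$matched$max_mua),
               centroid_ann = centroid_distance(
                 ev$ann$delta_mua[ev$ann$mesh$fine],
                 ev$ann$mesh$centers[ev$ann$mesh$fine, ],
                 scene$target$center[c(1, 3)]))
  })
  tab <- do.call(rbind, rows)
  boots <- with_seed(rng_seed, {
    replicate(n_boot, mean(sample(tab$abs_diff, replace = TRUE)))
  })
  structure(list(cases = tab,
                 mean_abs_diff = mean(tab$abs_diff),
                 ci95 = stats::quantile(boots, c(0.025, 0.975),
                                        names = FALSE)),
            class = "dot_eval_report")
}

#' @export
print.dot_eval_report <- function(x, ...) {
  cat(sprintf("held-out simulation test: %d cases\n", nrow(x$cases)))
  cat(sprintf("  mean |max mua (ANN) - max mua (matched)| = %.4f /cm (95%% CI %.4f-%.4f)\n",
              x$mean_abs_diff, x$ci95[1], x$ci95[2]))
  invisible(x)
}
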