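# End-to-end orchestration: corpus -> training -> held-out evaluation of
# the three perturbation pathways (matched, mismatched, network-predicted),
# with stage checkpoints under an output directory so a run can resume.

#' Pipeline configuration
#'
#' A config plus its seed fully determines every artifact the pipeline
#' writes (corpus, model, reports).
#'
#' @param out_dir output directory for stage artifacts.
#' @param n_corpus total corpus size (80/20 train/validation split).
#' @param n_test held-out test scenes for the simulation summary.
#' @param n_mismatch chest-wall-mismatch demo scenes.
#' @param rng_seed master seed; all stage seeds derive from it.
#' @param noise_fraction relative amplitude noise sd.
#' @param epochs,batch_size training settings (see [pert_ann()]).
#' @param chest_wall_shift_cm mismatch demo chest-wall offset, cm.
#' @param reuse named logical: reuse existing stage artifacts on disk
#'   (`corpus`, `model`) instead of recomputing.
#' @param figures write demo figures (PNG) for the mismatch scenes.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("dotdiff-run-"),
                       n_corpus = 5000, n_test = 60, n_mismatch = 20,
                       rng_seed = 1, noise_fraction = 0.02,
                       epochs = 200, batch_size = 64,
                       chest_wall_shift_cm = 1,
                       reuse = c(corpus = FALSE, model = FALSE),
                       figures = FALSE) {
  structure(list(out_dir = out_dir, n_corpus = n_corpus, n_test = n_test,
                 n_mismatch = n_mismatch, rng_seed = rng_seed,
                 noise_fraction = noise_fraction, epochs = epochs,
                 batch_size = batch_size,
                 chest_wall_shift_cm = chest_wall_shift_cm,
                 reuse = reuse, figures = figures),
            class = "run_config")
}

.stage_log <- function(stage, t0) {
  message(sprintf("[dotdiff] %-10s %6.1f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full simulate / train / evaluate pipeline
#'
#' Stages: (1) generate the seeded training/validation corpus; (2) train
#' the perturbation-prediction network; (3) simulate held-out test scenes
#' and summarize the network-vs-matched reconstruction agreement;
#' (4) simulate chest-wall-mismatch scenes and compare the mismatched,
#' matched, and predicted pathways.  Each stage writes its artifact under
#' `config$out_dir`; `reuse` flags skip stages whose artifact exists.
#'
#' @param config a [run_config()].
#' @return list with the trained `model`, the held-out `summary`
#'   (a `dot_eval_report`), the `mismatch` comparison table, and artifact
#'   paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- probe_geometry()
  paths <- list(corpus = file.path(config$out_dir, "corpus.rds"),
                model = file.path(config$out_dir, "model.json"),
                cases = file.path(config$out_dir, "test_cases.csv"),
                mismatch = file.path(config$out_dir, "mismatch_cases.csv"),
                manifest = file.path(config$out_dir, "manifest.json"))

  t0 <- as.numeric(Sys.time())
  if (isTRUE(config$reuse[["corpus"]]) && file.exists(paths$corpus)) {
    corpus <- readRDS(paths$corpus)
  } else {
    corpus <- build_corpus(config$n_corpus, geometry,
                           rng_seed = derive_seed(config$rng_seed, "corpus"),
                           noise_fraction = config$noise_fraction)
    saveRDS(corpus, paths$corpus)
  }
  .stage_log("corpus", t0)

  t0 <- as.numeric(Sys.time())
  if (isTRUE(config$reuse[["model"]]) && file.exists(paths$model)) {
    model <- read_pert_ann(paths$model)
  } else {
    model <- pert_ann(corpus$train, corpus$validation,
                      epochs = config$epochs,
                      batch_size = config$batch_size,
                      rng_seed = derive_seed(config$rng_seed, "train"))
    write_pert_ann(model, paths$model)
  }
  .stage_log("train", t0)

  t0 <- as.numeric(Sys.time())
  test_samples <- lapply(seq_len(config$n_test), function(i) {
    sc <- sample_scene(derive_seed(config$rng_seed, paste0("test", i)))
    make_training_sample(sc, geometry,
                         noise_fraction = config$noise_fraction,
                         rng_seed = derive_seed(config$rng_seed,
                                                paste0("testnoise", i)))
  })
  summary <- simulation_test_summary(test_samples, model, geometry,
                                     rng_seed = derive_seed(config$rng_seed,
                                                            "boot"))
  utils::write.csv(summary$cases, paths$cases, row.names = FALSE)
  .stage_log("evaluate", t0)

  t0 <- as.numeric(Sys.time())
  mismatch <- demo_mismatch(model, geometry, n = config$n_mismatch,
                            chest_wall_shift_cm = config$chest_wall_shift_cm,
                            noise_fraction = config$noise_fraction,
                            rng_seed = derive_seed(config$rng_seed, "mismatch"),
                            figure_dir = if (config$figures) config$out_dir)
  utils::write.csv(mismatch, paths$mismatch, row.names = FALSE)
  .stage_log("mismatch", t0)

  jsonlite::write_json(list(format = "dotdiff-manifest", version = 1L,
                            config = unclass(config)[setdiff(names(config),
                                                             "reuse")],
                            mean_abs_diff = summary$mean_abs_diff,
                            ci95 = summary$ci95),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  list(model = model, summary = summary, mismatch = mismatch, paths = paths)
}

#' Chest-wall-mismatch comparison
#'
#' Simulates scenes whose reference-side chest wall sits shallower than
#' the lesion side's (the canonical case: 3 cm on the lesion side, 2 cm
#' on the reference side) and compares the three perturbation pathways:
#' measured against the mismatched reference, measured against the
#' matched reference, and predicted by the network from the lesion
#' measurement alone.  For each scene the table records the mean real
#' perturbation of each pathway and the localization error of each
#' reconstruction.
#'
#' @param model a fitted [pert_ann()].
#' @param geometry a [probe_geometry()].
#' @param n number of scenes.
#' @param chest_wall_depth lesion-side chest wall depth, cm.
#' @param chest_wall_shift_cm reference-side chest wall shallower by, cm.
#' @param noise_fraction relative amplitude noise sd.
#' @param rng_seed master seed.
#' @param figure_dir if non-NULL, write a perturbation-scatter +
#'   layered-reconstruction PNG per first few scenes into this directory.
#' @return data.frame, one row per scene.
#' @export
demo_mismatch <- function(model, geometry = probe_geometry(), n = 20,
                          chest_wall_depth = 3, chest_wall_shift_cm = 1,
                          noise_fraction = 0.02, rng_seed = 1,
                          figure_dir = NULL) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- sample_scene(derive_seed(rng_seed, paste0("mm", i)),
                       chest_wall_prob = 1)
    sc$chest_wall$depth <- chest_wall_depth
    sc$chest_wall$tilt <- 0
    pair <- make_mismatch_pair(sc, geometry,
                               chest_wall_shift_cm = chest_wall_shift_cm,
                               noise_fraction = noise_fraction,
                               rng_seed = derive_seed(rng_seed,
                                                      paste0("mmnoise", i)))
    ev <- evaluate_sample(pair, model, geometry)
    loc <- function(rec) centroid_distance(rec$delta_mua[rec$mesh$fine],
                                           rec$mesh$centers[rec$mesh$fine, ],
                                           sc$target$center[c(1, 3)])
    rows[[i]] <- data.frame(
      case = i, target_radius = sc$target$radius,
      mean_re_matched = mean(Re(ev$pert_matched$values)),
      mean_re_mismatched = mean(Re(ev$pert_mismatched$values)),
      mean_re_ann = mean(Re(ev$pert_ann$values)),
      centroid_matched = loc(ev$matched),
      centroid_mismatched = loc(ev$mismatched),
      centroid_ann = loc(ev$ann))
    if (!is.null(figure_dir) && i <= 3)
      .mismatch_figure(ev, sc, file.path(figure_dir,
                                         sprintf("mismatch_case%02d.png", i)))
  }
  do.call(rbind, rows)
}

# Perturbation scatter (matched / mismatched / predicted) over one row of
# layered reconstructions, echoing the usual presentation of mismatch
# case studies.
.mismatch_figure <- function(ev, scene, path) {
  grDevices::png(path, width = 1400, height = 900, res = 120)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  perts <- list(matched = ev$pert_matched,
                mismatched = ev$pert_mismatched,
                predicted = ev$pert_ann)
  for (nm in names(perts)) {
    v <- perts[[nm]]$values
    graphics::plot(Re(v), Im(v), pch = 20, col = "steelblue",
                   xlab = "Re(pert)", ylab = "Im(pert)", main = nm)
    graphics::abline(v = 0, h = 0, col = "grey70")
  }
  recs <- list(matched = ev$matched, mismatched = ev$mismatched,
               predicted = ev$ann)
  for (nm in names(recs)) {
    rec <- recs[[nm]]
    zs <- sort(unique(rec$mesh$centers[rec$mesh$fine, 3]))
    zmid <- zs[ceiling(length(zs) / 2)]
    sel <- rec$mesh$fine & abs(rec$mesh$centers[, 3] - zmid) < 1e-9
    xs <- sort(unique(rec$mesh$centers[sel, 1]))
    ys <- sort(unique(rec$mesh$centers[sel, 2]))
    m <- matrix(0, length(xs), length(ys))
    m[cbind(match(rec$mesh$centers[sel, 1], xs),
            match(rec$mesh$centers[sel, 2], ys))] <- rec$delta_mua[sel]
    graphics::image(xs, ys, m, asp = 1, main = sprintf("%s, z=%.1f", nm, zmid),
                    xlab = "x (cm)", ylab = "y (cm)",
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  }
  invisible(path)
}
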