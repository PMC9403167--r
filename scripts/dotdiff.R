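#!/usr/bin/env Rscript

# Thin command-line wrapper over the dotdiff package.
#
#   Rscript scripts/dotdiff.R simulate  --seed 1 --out measurement.csv
#   Rscript scripts/dotdiff.R train     --seed 1 --n 5000 --epochs 200 --out model.json
#   Rscript scripts/dotdiff.R predict   --model model.json --measurement m.csv --out pert.csv
#   Rscript scripts/dotdiff.R reconstruct --pert pert.csv --roi "x0,x1,y0,y1,z0,z1" \
#       --mua 0.02 --musp 7 --out recon.csv
#   Rscript scripts/dotdiff.R evaluate  --seed 1 --out run-dir
#   Rscript scripts/dotdiff.R demo-mismatch --seed 1 --model model.json --out mm.csv

suppressPackageStartupMessages(library(dotdiff))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: dotdiff.R <subcommand> [--flag value ...]")
cmd <- argv[1]
flags <- list()
i <- 2
while (i < length(argv) + 1) {
  if (!startsWith(argv[i], "--")) stop("expected --flag, got: ", argv[i])
  flags[[substring(argv[i], 3)]] <- argv[i + 1]
  i <- i + 2
}
flag <- function(name, default = NULL) {
  if (!is.null(flags[[name]])) flags[[name]] else
    if (!is.null(default)) default else stop("missing --", name)
}
num <- function(name, default = NULL)
  as.numeric(flag(name, if (is.null(default)) NULL else as.character(default)))

geometry <- probe_geometry()

switch(cmd,
  simulate = {
    scene <- sample_scene(as.integer(num("seed", 1)))
    sm <- make_training_sample(scene, geometry,
                               rng_seed = as.integer(num("seed", 1)) + 1)
    write_measurement(sm$Ul, flag("out"))
    write_perturbation(sm$pert, sub("\\.csv$", "_matched_pert.csv",
                                    flag("out")))
    print(scene)
    message("wrote ", flag("out"))
  },
  train = {
    corpus <- build_corpus(as.integer(num("n", 5000)), geometry,
                           rng_seed = as.integer(num("seed", 1)))
    model <- pert_ann(corpus$train, corpus$validation,
                      epochs = as.integer(num("epochs", 200)),
                      rng_seed = as.integer(num("seed", 1)) + 1,
                      verbose = TRUE)
    write_pert_ann(model, flag("out"))
    print(model)
  },
  predict = {
    model <- read_pert_ann(flag("model"))
    m <- read_measurement(flag("measurement"), geometry)
    write_perturbation(predict(model, m), flag("out"))
    message("wrote ", flag("out"))
  },
  reconstruct = {
    pert <- read_perturbation(flag("pert"), geometry)
    roi <- as.numeric(strsplit(flag("roi"), ",")[[1]])
    W <- assemble_sensitivity(build_dual_mesh(roi), geometry,
                              optical_properties(num("mua", 0.02),
                                                 num("musp", 7)))
    rec <- reconstruct(pert, W, background_mua = num("mua", 0.02),
                       column_weighting = "layer", max_iter = 500)
    print(rec)
    df <- data.frame(rec$mesh$centers, fine = rec$mesh$fine,
                     delta_mua = rec$delta_mua)
    utils::write.csv(df, flag("out"), row.names = FALSE)
    message("wrote ", flag("out"))
  },
  evaluate = {
    res <- run_pipeline(run_config(out_dir = flag("out"),
                                   rng_seed = as.integer(num("seed", 1)),
                                   n_corpus = as.integer(num("n", 5000)),
                                   n_test = as.integer(num("ntest", 60)),
                                   figures = TRUE))
    print(res$summary)
  },
  `demo-mismatch` = {
    model <- read_pert_ann(flag("model"))
    mm <- demo_mismatch(model, geometry,
                        n = as.integer(num("n", 20)),
                        rng_seed = as.integer(num("seed", 1)),
                        figure_dir = dirname(flag("out")))
    utils::write.csv(mm, flag("out"), row.names = FALSE)
    print(mm)
  },
  stop("unknown subcommand: ", cmd)
)
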