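# dotdiff

Reference-free difference imaging for ultrasound-guided diffuse optical
tomography (DOT) of the breast.

Difference imaging reconstructs a lesion's absorption from the normalized
perturbation between a lesion-side and a reference-side frequency-domain
measurement,

    pert = (Ul - Ur) / Ur
         = (Al/Ar cos(phi_l - phi_r) - 1) + j Al/Ar sin(phi_l - phi_r),

which cancels instrument coupling common to both sides — but costs a
second acquisition and breaks down when the two breasts differ, most
visibly when the reference-side chest wall is shallower than the
lesion-side one (the perturbation's real part shifts positive and the
lesion vanishes from the image). `dotdiff` implements the learning-based
alternative: a 252-256-128-256-252 multilayer perceptron, trained on
simulated scenes, predicts the *matched* perturbation from the lesion-side
measurement alone. The prediction is inverted with the usual linearized
machinery,

    argmin_dmua  || pert - W dmua ||^2  +  lambda^2 || dmua ||^2,

where `W` is the Born sensitivity matrix on an ultrasound-guided dual mesh
(fine voxels in the lesion region, coarse elsewhere), solved by conjugate
gradient; multi-wavelength absorption maps unmix into total hemoglobin.

The package is the complete loop — analytic semi-infinite diffusion
forward model with Born/Rytov perturbations, scene generator emulating the
published simulation corpus (property ranges, chest wall, tissue
heterogeneity, 2% measurement noise), network training under the published
protocol (Adam, lr 1e-4, weight decay 1e-5, 200 epochs, batch 64, plateau
learning-rate decay), reconstruction, and image-quality metrics (SSIM,
target-to-artifact ratio, centroid distance). See the methods vignette
(`vignettes/difference-imaging-methods.Rmd`) for the models, parameter
choices, and limitations.

## Worked example

Simulate a lesion scene, train a small demonstration model, and compare
the three perturbation pathways:

```r
library(dotdiff)

geometry <- probe_geometry()
geometry
#> DOT probe geometry
#>   9 sources x 14 detectors = 126 pairs
#>   modulation: 140 MHz; wavelengths: 730, 785, 808, 830 nm
#>   source-detector separation: 1.80 to 6.20 cm

scene <- sample_scene(42)
scene
#> scene: sphere target r=1.40 cm at (0.66, 0.28, 2.57), mua=0.194 /cm
#>   background mua=0.017 musp=6.63; chest wall: none; heterogeneity 9%

sample <- make_training_sample(scene, geometry, rng_seed = 7)
sample$pert
#> perturbation (measured_matched), 126 pairs at 785 nm
#>   Re: [-0.824, -0.004]  Im: [-0.192, -0.001]
```

The real parts are negative — the lesion only removes light — and
bounded below by −1, the physical signature of a matched absorption-only
perturbation.

The full study is one call (about four minutes on one CPU: 5,000-scene
corpus, 200-epoch training, 60 held-out scenes, 20 chest-wall-mismatch
scenes):

```r
res <- run_pipeline(run_config(out_dir = "run1", rng_seed = 1))
res$summary
#> held-out simulation test: 60 cases
#>   mean |max mua (ANN) - max mua (matched)| = 0.0125 /cm (95% CI 0.0100-0.0154)
```

The headline number is the mean absolute difference between the maximum
reconstructed absorption obtained from the network-predicted perturbation
and from the measured matched perturbation over held-out scenes — the
agreement between reference-free and conventional difference imaging when
a good reference exists. `res$mismatch` tabulates the chest-wall-mismatch
comparison: mismatched references shift the perturbation positive and
mislocalize the target, while the network prediction, computed from the
lesion measurement alone, stays matched.

A thin command-line wrapper (`scripts/dotdiff.R`) exposes `simulate`,
`train`, `predict`, `reconstruct`, `evaluate`, and `demo-mismatch`
subcommands over the same functions.

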