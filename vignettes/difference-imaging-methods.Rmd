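---
title: "Reference-free difference imaging for US-guided DOT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free difference imaging for US-guided DOT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Ultrasound-guided diffuse optical tomography (DOT) of the breast
reconstructs a lesion's absorption coefficient from frequency-domain
reflectance measured by a hand-held probe. Because absolute DOT imaging is
hypersensitive to modelling errors, clinical practice uses *difference
imaging*: the lesion-side measurement `Ul` is normalized to a reference
measurement `Ur` taken on the contralateral breast, producing the
normalized perturbation

    pert = (Ul - Ur) / Ur
         = (Al/Ar cos(phi_l - phi_r) - 1) + j Al/Ar sin(phi_l - phi_r),

which cancels optode coupling factors common to both sides. The price is a
second acquisition and the assumption that both breasts share the same
background. When the reference side's chest wall sits at a different depth
than the lesion side's, the perturbation is corrupted — its real part
shifts positive — and the lesion fails to reconstruct.

`dotdiff` implements the learning-based alternative: a multilayer
perceptron (MLP) trained on simulated scenes predicts the *matched*
perturbation from the lesion-side measurement alone, and the prediction is
inverted exactly like a measured perturbation. The package contains the
whole loop — forward simulation, corpus generation, training, prediction,
reconstruction, and evaluation — so the simulation study can be replicated
end to end on a desk machine.

# Forward model

The probe is modelled as 9 source fibres on an 8 cm ring and 14 detector
fibres on a 4.4 cm ring, all on the tissue surface, sources modulated at
140 MHz, with the centre left free for the ultrasound transducer; 9 x 14 =
126 source-detector pairs give the 252-wide network interface (126
log-amplitudes + 126 phases in, 126 real + 126 imaginary perturbation
values out). The clinical system this emulates states its detector count
and the 252-neuron interface but not the source layout; the 9 x 14
arrangement is the package's choice and is configurable in
`probe_geometry()`.

Homogeneous tissue is a semi-infinite diffusive medium. The fluence of a
modulated point source is the extrapolated-boundary (image-source)
Green's function

    G = ( exp(-k r1)/r1 - exp(-k r2)/r2 ) / (4 pi D),

with diffusion coefficient `D = 1/(3 (mua + musp))`, complex wavenumber
`k = sqrt((mua - i w n / c) / D)`, `Re(k) > 0` (the `exp(-i w t)` time
convention: unwrapped phase grows with distance), isotropic source depth
`z0 = 1/musp`, refractive index 1.333, and the standard polynomial
effective-reflection approximation for the boundary distance `zb`. Units
are cm, cm^-1, radians, Hz, with depth as positive `z`.

Heterogeneities (lesion, chest wall, background texture) enter through the
first-order Born kernel: the normalized weight of voxel `v` for pair
`(s, d)` is

    K = - G(s -> v) G(v -> d) vol_v / U0(s, d),

which integrates to the derivative of `log U` with respect to a global
absorption change (this identity is verified against a finite-difference
derivative in the test suite; early development caught a double `1/D`
normalization error precisely this way).

Two linearizations are exposed:

* **`"born"`** — `Ul = U0 (1 + K dmua)`. Exactly linear in `dmua` and
  identical, entry by entry, to the reconstruction sensitivity matrix.
  Used for solver-consistency checks and valid for weak contrast.
* **`"rytov"`** (generator default) — `Ul = U0 exp(b)`. Breast lesions
  have `mua` up to 30x background; the linear form then produces
  perturbations tens of times outside the physical range, while the
  exponential (Rytov-type) form saturates the way measured data do. The
  real (amplitude) part of the exponent is evaluated at zero modulation
  frequency, where the Born kernel is strictly positive: in transport
  physics added absorption strictly reduces detected amplitude, but the
  140-MHz first-order kernel has small oscillatory side lobes that would
  let the amplitude grow by ~1e-3..1e-2 at a few weakly coupled pairs.
  With the DC amplitude exponent and the FD phase exponent, matched
  pure-absorption perturbations satisfy `Re(pert)` in `[-1, 0]` at every
  pair, as observed clinically; the phase perturbation |Im b| stayed
  below pi/2 on 300 randomized scenes. A further convenience of the
  exponential form is that structures shared by the lesion and reference
  side (chest wall, background texture) cancel *exactly* in `Ul/Ur` —
  the idealized premise of difference imaging.

This analytic engine deliberately replaces the finite-element and Monte
Carlo solvers used to build the original simulation corpus; it reproduces
the phenomenology (bounded perturbations, chest-wall mismatch signatures)
but not transport-accurate amplitudes for strong, shallow lesions. Results
that depend on the forward engine are therefore comparable to the
published ones in order of magnitude, not digit by digit.

# The simulation corpus

`sample_scene()` draws scenes uniformly from the published property
ranges: target radius 0.375–1.5 cm (resampled until fully submerged),
centre depth 0.6–2.7 cm, lateral position within +/-1 cm of the probe
axis, target `mua` 0.08–0.30 cm^-1, background `mua` 0.01–0.06 cm^-1,
`musp` 4–8 cm^-1 for both; half the scenes have a chest wall (depth
1.6–5 cm, resampled to clear the target bottom, tilt +/-10 deg, `mua`
0.1–0.2 cm^-1) modelled as a 2 cm thick tilted Born slab. Irregular
lesions are spheres whose radius is modulated by random low-order real
spherical harmonics (coefficients ~N(0, 0.12), clipped at 0.3) — a
parametric stand-in for anatomical lesion-shape software, with the
nominal radius read as half the largest z-extent. Background texture is a
smooth Gaussian random `mua` field (squared-exponential correlation,
length 1–2 cm, amplitude up to 20% of background `mua`) standing in for
digital-breast heterogeneity; it emulates smooth fibroglandular contrast
but not ducts, skin, or sharp tissue boundaries, so passing tests bound
behaviour on smooth backgrounds only.

`make_training_sample()` adds 2% multiplicative Gaussian amplitude noise
and 0.02 rad additive phase noise to the lesion-side measurement (the
published protocol states "2% random Gaussian noise"; amplitude-relative
noise is the standard reading, and the phase noise level was chosen to
match a well-calibrated instrument). The learning target is the
*noise-free* matched perturbation; the held-out evaluation compares
reconstructions from the network prediction against the *measured*
matched perturbation (noisy lesion side over clean matched reference),
which is what a clinical acquisition would give.

The generator is wavelength-agnostic: optical properties span the
plausible range of all four system wavelengths (730/785/808/830 nm) and a
single model serves them all, mirroring the fact that the published
architecture does not branch per wavelength.

# Network and training

The MLP is 252-256-128-256-252 with rectified-linear activations after
every affine layer except the last (~195k parameters). Inputs are
`log(A rho^2)` and unwrapped phase, each additively offset per measurement
set so the log-amplitude maximum and the phase minimum sit at fixed
anchors (both 0 here; the protocol requires only that they be common).
Offsets are the only normalization — they absorb instrument gain, which
is why a global gain on the measurement provably leaves the prediction
unchanged. Input ordering (amplitudes then phases, pairs source-major;
outputs real then imaginary) is fixed and versioned in the model
artifact.

Training follows the published protocol exactly: mean squared error, Adam
with learning rate 1e-4 and weight decay 1e-5 (added to the gradients),
200 epochs of shuffled minibatches of 64, learning rate multiplied by 0.2
whenever the validation loss has not improved for three consecutive
epochs, parameters checkpointed at the best validation loss.
Initialization is seeded uniform fan-in (the protocol does not state
one); all randomness funnels through one seed hierarchy, so a corpus seed
plus a training seed reproduces the model bit for bit.

One scale interaction matters: with ~31 minibatches per epoch
(2,000-sample corpus) the validation trace is noisy enough to trigger the
plateau schedule within the first ~15 epochs, and the model underfits
(best validation MSE ~6.8x better than the constant-mean predictor).
At 5,000 samples (63 batches/epoch) the schedule first fires around epoch
45 and the ratio exceeds 11x. The published corpus is 43,398 samples, 20x
larger still. The package therefore uses a 5,000-sample corpus (4,000
train / 1,000 validation) as its standard study condition — about three
minutes of corpus generation and training on one CPU — and treats the
2,000-sample setting as a documented underfitting regime of the fixed
protocol, not a usable default.

# Reconstruction

The inverse problem is the linearized difference-imaging formulation:
minimize `||pert - W dmua||^2 + lambda^2 ||dmua||^2` over real-valued
per-voxel absorption changes, with the complex system stacked into real
and imaginary blocks and solved by conjugate gradient on the normal
equations (zero start, iteration cap 200 by default, relative-residual
tolerance 1e-6; the solver is verified against dense closed-form
solutions to <=1e-6 relative error). `lambda` defaults to
`0.1 * sigma_max` of the stacked matrix — the published work states no
selection rule, and this fraction was stable across scenes. Scattering
changes are out of scope (absorption-only inversion).

The dual mesh realizes the ultrasound prior: fine 0.25 x 0.25 x 0.5 cm
voxels inside the lesion ROI (in the synthetic study, the known target
bounding box plus a 0.5 cm margin, snapped outward to the coarse lattice)
and coarse 1 cm^3 voxels tiling the rest of an 8 x 8 x 4 cm imaging
volume under the probe. The fine/coarse sizes and volume extent are
package choices; the source publications do not state theirs.

Reflection-geometry DOT has a well-known depth bias: sensitivity decays
roughly exponentially with depth, so the minimum-norm solution piles into
the shallowest fine layer — on this system the unweighted argmax lands
~1–2 cm shallow even for noiseless data. `reconstruct()` therefore offers
the standard remedy, depth-compensating column weighting: each voxel
column is divided by its depth layer's peak column norm raised to an
exponent, the weighted system is solved, and the solution is mapped back.
The exponent 0.8 was calibrated on matched-reference reconstructions of
1-cm calibration spheres at 1.5–2.5 cm depth (argmax error <= 0.75 cm,
versus >= 1 cm at exponents 0 or 1); full equalization (exponent 1)
over-boosts the deepest, least-informed voxels. The evaluation pipeline
uses this weighting; the plain unweighted problem remains the default of
`reconstruct()` itself and is what the closed-form oracle tests check.
Even compensated, depth localization to better than about one voxel
cannot be guaranteed for this measurement geometry — a genuine physical
limitation, not an implementation artifact.

Total hemoglobin maps come from per-voxel nonnegative least squares of
the four wavelength `mua` maps against tabulated oxy-/deoxy-hemoglobin
molar extinction coefficients (`mua = ln(10) eps C`), `tHb = HbO2 + Hb`
in uM.

# Evaluation metrics

* **SSIM** between a reconstructed depth layer and the ground truth
  rendered at the same resolution by voxel-centre membership; Gaussian
  11 x 11 window (sigma 1.5), stabilizers `(0.01 L)^2`, `(0.03 L)^2`
  with the dynamic range `L` taken from the truth layer; layers are
  compared 2-D and averaged (the published figures are per-layer images).
* **Target-to-artifact ratio**: maximum inside the lesion footprint
  widened 3x laterally, over the maximum outside; all-zero outside maps
  report `Inf`.
* **Centroid distance**: intensity-weighted centre of mass (negative
  voxels clipped to zero, for the metrics only — stored maps are
  unclipped) to the true centroid, whose y coordinate is 0 by the B-scan
  convention.
* **Held-out summary**: per-case `|max mua(ANN) - max mua(matched)|`,
  aggregated as a mean with a seeded 1,000-resample bootstrap 95% CI (the
  published work does not state its CI method).

`run_pipeline()` wires corpus -> training -> held-out evaluation ->
chest-wall-mismatch comparison with stage checkpoints under one output
directory, fully determined by a config and a seed. The desk-scale run
(5,000-sample corpus, 60 held-out scenes, 20 mismatch scenes) takes about
four minutes on one CPU.

# Numerical and degenerate-input choices

Phase unwrapping walks each source's detectors in order of increasing
separation, snapping each phase to the nearest 2 pi multiple of its
predecessor. Voxels coinciding with an optode singular point are excluded
from the sensitivity matrix with a warning. A perturbation of exactly
zero reconstructs to exactly zero (the CG loop is skipped). All-zero maps
make the centroid undefined (error) and an all-covering lesion footprint
makes the artifact ratio undefined (error). The chest-wall-mismatch
generator warns, but proceeds, when the shifted reference wall would sit
above the target bottom. Tie-breaks in `which.max` follow R's first-index
rule; equal-`rho` detector pairs are genuine ties and are deduplicated in
monotonicity checks rather than ordered arbitrarily.

# Known limitations

* The analytic Born/Rytov engine reproduces mismatch phenomenology, not
  transport-accurate amplitudes; quantitative agreement with published
  absolute numbers is order-of-magnitude by design.
* Depth localization is limited by reflection-geometry physics; the
  argmax of a reconstruction is reliable to about the lesion scale, not
  to a single voxel.
* The network underfits under the fixed training protocol if the corpus
  is much smaller than ~5,000 samples (see above).
* Scattering perturbations, nonlinear/iterative Born updates, real
  ultrasound segmentation, and patient-cohort statistics are out of
  scope.
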