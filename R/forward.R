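#' Frequency-domain Green's function for a semi-infinite medium
#'
#' Evaluates the extrapolated-boundary (image source) solution of the
#' frequency-domain photon diffusion equation.  A point at depth `z`
#' contributes a real source at `(x, y, z)` and a negative image source
#' mirrored across the extrapolated boundary plane `z = -zb`, i.e. at
#' `z = -(z + 2 zb)`:
#'
#'   G = ( exp(-k r1) / r1 - exp(-k r2) / r2 ) / (4 pi D)
#'
#' Under the `exp(-i w t)` time convention used throughout the package the
#' complex wavenumber is `k = sqrt((mua - i w / v) / D)` with `Re(k) > 0`,
#' so the unwrapped phase of the fluence increases with distance and the
#' DC (`w = 0`) limit is purely real and positive.
#'
#' A source given on the surface (`z = 0`) is buried at the standard
#' isotropic-source depth `z0 = 1/musp`; a source given at `z > 0` is used
#' as-is, which makes the function symmetric in its two arguments for
#' buried points (reciprocity).
#'
#' @param source numeric length-3 position, cm (`z >= 0`).
#' @param field_point numeric length-3 position, cm (`z >= 0`).
#' @param props an [optical_properties()] object.
#' @param omega angular modulation frequency, rad/s.
#' @return complex fluence (photon density per unit source power).
#' @export
semi_infinite_green <- function(source, field_point, props,
                                omega = 2 * pi * 140e6) {
  stopifnot(length(source) == 3, length(field_point) == 3)
  if (source[3] < 0 || field_point[3] < 0)
    stop("points must be on or below the surface (z >= 0)")
  fp <- forward_model_params(props, omega)
  if (source[3] == 0) source[3] <- fp$z0
  g <- .green_matrix(matrix(source, 1), matrix(field_point, 1), fp)
  as.complex(g[1, 1])
}

# Vectorized image-source Green's function: a (n x 3) source points at their
# actual depths, b (m x 3) field points; returns n x m complex matrix.
.green_matrix <- function(a, b, fp) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  r1 <- sqrt(dx^2 + dy^2 + dz^2)
  # image of a across the extrapolated boundary z = -zb
  dzi <- outer(a[, 3] + 2 * fp$zb, b[, 3], "+")
  r2 <- sqrt(dx^2 + dy^2 + dzi^2)
  if (any(r1 < 1e-9))
    stop("field point coincides with a source (singularity)")
  (exp(-fp$k * r1) / r1 - exp(-fp$k * r2) / r2) / (4 * pi * fp$D)
}

#' Frequency-domain measurement container
#'
#' Wraps one complex reflectance value per source-detector pair at a single
#' wavelength.  Amplitude is `|U|`; phase is `Arg(U)` unwrapped along
#' increasing separation within each source (nearest-multiple-of-2pi
#' unwrapping), so that in a homogeneous medium the stored phase increases
#' monotonically with `rho`.
#'
#' @param geometry a [probe_geometry()].
#' @param U complex vector, one value per pair in the geometry's pair order.
#' @param wavelength nm.
#' @return object of class `fd_measurement` with fields `U`, `amplitude`,
#'   `phase` (unwrapped, radians), `rho`, and the pair table.
#' @export
fd_measurement <- function(geometry, U, wavelength = 785) {
  stopifnot(inherits(geometry, "probe_geometry"))
  if (length(U) != geometry$n_pairs)
    stop("U must have one value per source-detector pair")
  amp <- Mod(U)
  if (any(amp <= 0)) stop("zero-amplitude measurement")
  ph <- .unwrap_by_source(Arg(U), geometry$pairs$rho, geometry$pairs$source_id)
  structure(list(geometry = geometry, wavelength = wavelength,
                 U = U, amplitude = amp, phase = ph,
                 rho = geometry$pairs$rho,
                 source_id = geometry$pairs$source_id,
                 detector_id = geometry$pairs$detector_id),
            class = "fd_measurement")
}

#' @export
print.fd_measurement <- function(x, ...) {
  cat(sprintf("fd_measurement: %d pairs at %g nm\n", length(x$U), x$wavelength))
  cat(sprintf("  log10 amplitude: %.2f to %.2f; phase: %.2f to %.2f rad\n",
              log10(min(x$amplitude)), log10(max(x$amplitude)),
              min(x$phase), max(x$phase)))
  invisible(x)
}

# 1D phase unwrapping within each source, walking pairs in order of
# increasing rho and snapping each phase to the nearest 2*pi multiple of
# its predecessor.
.unwrap_by_source <- function(phase, rho, source_id) {
  out <- phase
  for (s in unique(source_id)) {
    idx <- which(source_id == s)
    idx <- idx[order(rho[idx])]
    p <- phase[idx]
    for (i in seq_along(p)[-1]) {
      jump <- round((p[i] - p[i - 1]) / (2 * pi))
      p[i] <- p[i] - 2 * pi * jump
    }
    out[idx] <- p
  }
  out
}

#' Simulate homogeneous semi-infinite reflectance
#'
#' One complex reflectance per source-detector pair: the Green's function
#' from the buried source to the detector position on the surface.
#'
#' @inheritParams fd_measurement
#' @param props background [optical_properties()].
#' @return an [fd_measurement()].
#' @export
simulate_homogeneous <- function(geometry, props, wavelength = 785) {
  stopifnot(inherits(geometry, "probe_geometry"))
  fp <- forward_model_params(props, 2 * pi * geometry$modulation_frequency)
  U <- .homogeneous_pairs(geometry, fp)
  fd_measurement(geometry, U, wavelength)
}

.buried_sources <- function(geometry, fp) {
  s <- geometry$source_positions
  s[, 3] <- fp$z0
  s
}

.homogeneous_pairs <- function(geometry, fp) {
  g <- .green_matrix(.buried_sources(geometry, fp),
                     geometry$detector_positions, fp)
  g[cbind(geometry$pairs$source_id, geometry$pairs$detector_id)]
}

#' First-order Born kernel for a set of voxels
#'
#' The shared kernel behind both the perturbed forward model
#' ([simulate_with_inclusions()]) and the reconstruction sensitivity matrix
#' ([assemble_sensitivity()]).  Entry `(i, j)` is the normalized Born
#' weight of voxel `j` for pair `i`:
#'
#'   K_ij = - G(s_i -> v_j) G(v_j -> d_i) vol_j / U0_i
#'
#' so that the normalized perturbation of an absorption change `dmua` is
#' `K %*% dmua` and is negative in its real part for absorbing inclusions.
#' `G` here is the diffusion Green's function normalized with the
#' `1/(4 pi D r)` prefactor, which is why no explicit `1/D` appears;
#' the kernel reproduces the derivative of `log U` with respect to a
#' global absorption change when summed over the whole half space.
#'
#' @param geometry a [probe_geometry()].
#' @param centers numeric matrix (n_voxels x 3) of voxel centers, cm,
#'   `z > 0`.
#' @param volumes voxel volumes, cm^3 (scalar or per-voxel vector).
#' @param props background [optical_properties()].
#' @return complex matrix, `n_pairs` x `n_voxels`.
#' @export
born_kernel <- function(geometry, centers, volumes, props, omega = NULL) {
  stopifnot(inherits(geometry, "probe_geometry"))
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (any(centers[, 3] <= 0))
    stop("inclusion voxels must be strictly inside the medium (z > 0)")
  volumes <- rep_len(volumes, nrow(centers))
  if (is.null(omega)) omega <- 2 * pi * geometry$modulation_frequency
  fp <- forward_model_params(props, omega)
  gs <- .green_matrix(.buried_sources(geometry, fp), centers, fp)  # nsrc x nvox
  gd <- .green_matrix(centers, geometry$detector_positions, fp)    # nvox x ndet
  u0 <- .homogeneous_pairs(geometry, fp)
  i_s <- geometry$pairs$source_id
  i_d <- geometry$pairs$detector_id
  num <- gs[i_s, , drop = FALSE] * t(gd)[i_d, , drop = FALSE]
  -sweep(num, 2, volumes, "*") / u0
}

#' Simulate reflectance with absorbing inclusions
#'
#' Computes the perturbed field of a set of voxelized absorption inclusions
#' (lesion target, chest-wall slab, smooth tissue heterogeneity) on top of
#' the homogeneous semi-infinite background.  Two linearizations of the
#' perturbed diffusion equation are available:
#'
#' * `"rytov"` (default): `Ul = U0 * exp(b)`, the exponential (Rytov-type)
#'   saturation of the first-order Born exponent, which keeps perturbations
#'   bounded for the high lesion contrasts seen in breast imaging (target
#'   `mua` many times background).  The amplitude part of the exponent is
#'   evaluated at zero modulation frequency, where the Born kernel is
#'   strictly positive, enforcing the transport-physics property that
#'   added absorption strictly reduces detected amplitude (the
#'   140-MHz first-order kernel has small oscillatory lobes that would
#'   otherwise let amplitude grow at a few weakly coupled pairs); the
#'   phase part is the imaginary FD exponent.  Matched-reference
#'   difference imaging is exact under this form: inclusions shared by
#'   lesion and reference side cancel identically in `Ul / Ur`, and
#'   matched pure-absorption perturbations satisfy `Re(pert)` in
#'   `[-1, 0]` at every pair.
#' * `"born"`: `Ul = U0 * (1 + b)`.  Exactly linear and additive in
#'   `dmua`, and consistent to machine precision with the sensitivity
#'   matrix of [assemble_sensitivity()]; accurate only for weak contrasts.
#'
#' @param geometry a [probe_geometry()].
#' @param background background [optical_properties()].
#' @param inclusions list of inclusions, each a list with `centers`
#'   (n x 3 matrix, cm), `volumes` (cm^3), and `delta_mua` (1/cm, scalar or
#'   per-voxel).
#' @param wavelength nm.
#' @param linearization `"rytov"` or `"born"` (see Details).
#' @return an [fd_measurement()] of the perturbed field.
#' @export
simulate_with_inclusions <- function(geometry, background, inclusions,
                                     wavelength = 785,
                                     linearization = c("rytov", "born")) {
  linearization <- match.arg(linearization)
  fp <- forward_model_params(background, 2 * pi * geometry$modulation_frequency)
  u0 <- .homogeneous_pairs(geometry, fp)
  b <- born_exponent(geometry, background, inclusions,
                     amplitude_at_dc = linearization == "rytov")
  U <- if (linearization == "rytov") u0 * exp(b) else u0 * (1 + b)
  fd_measurement(geometry, U, wavelength)
}

#' First-order Born exponent of a set of inclusions
#'
#' The summed normalized Born perturbation `b = sum_j K_j dmua_j` over all
#' inclusion voxels (see [born_kernel()]); the quantity that enters both
#' linearizations of [simulate_with_inclusions()].
#'
#' @inheritParams simulate_with_inclusions
#' @param amplitude_at_dc replace the real part by the zero-frequency Born
#'   exponent (strictly negative for absorbers), keeping the FD imaginary
#'   part; the exponent used by the `"rytov"` forward.
#' @return complex vector, one value per source-detector pair.
#' @export
born_exponent <- function(geometry, background, inclusions,
                          amplitude_at_dc = FALSE) {
  b <- rep(0 + 0i, geometry$n_pairs)
  bdc <- rep(0, geometry$n_pairs)
  for (inc in inclusions) {
    if (is.null(inc$centers) || nrow(as.matrix(inc$centers)) == 0) next
    K <- born_kernel(geometry, inc$centers, inc$volumes, background)
    dm <- rep_len(inc$delta_mua, ncol(K))
    b <- b + as.vector(K %*% dm)
    if (amplitude_at_dc) {
      K0 <- born_kernel(geometry, inc$centers, inc$volumes, background,
                        omega = 0)
      bdc <- bdc + Re(as.vector(K0 %*% dm))
    }
  }
  if (amplitude_at_dc) complex(real = bdc, imaginary = Im(b)) else b
}
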