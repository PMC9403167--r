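#' Probe geometry for a reflectance-mode DOT system
#'
#' Constructs the hand-held probe layout: source and detector fibres on the
#' `z = 0` tissue surface, with the central area left free for the
#' coregistered ultrasound transducer.  The default layout places 9 sources
#' on a 8 cm diameter ring and 14 detectors on a 4.4 cm diameter ring,
#' giving 126 source-detector pairs; with two real numbers per pair
#' (log-amplitude + phase on the input side, real + imaginary perturbation
#' on the output side) this matches the 252-wide network interface.
#'
#' Coordinates are in cm.  The `z` axis points into the tissue, so all
#' optode positions have `z = 0` and depths are positive.
#'
#' @param source_positions numeric matrix (n_src x 3) of source positions on
#'   the `z = 0` plane, cm.
#' @param detector_positions numeric matrix (n_det x 3) of detector
#'   positions on the `z = 0` plane, cm.
#' @param modulation_frequency source modulation frequency in Hz
#'   (default 140 MHz).
#' @param wavelengths laser diode wavelengths in nm.
#' @return An object of class `probe_geometry` with the pair table
#'   (`source_id`, `detector_id`, `rho`) in fixed order (sources major,
#'   detectors minor).
#' @examples
#' g <- probe_geometry()
#' g$n_pairs                # 126
#' range(g$pairs$rho)       # source-detector separations, cm
#' @export
probe_geometry <- function(source_positions = NULL,
                           detector_positions = NULL,
                           modulation_frequency = 140e6,
                           wavelengths = c(730, 785, 808, 830)) {
  if (is.null(source_positions)) {
    ang <- 2 * pi * (0:8) / 9
    source_positions <- cbind(4.0 * cos(ang), 4.0 * sin(ang), 0)
  }
  if (is.null(detector_positions)) {
    ang <- 2 * pi * (0:13) / 14 + pi / 14
    detector_positions <- cbind(2.2 * cos(ang), 2.2 * sin(ang), 0)
  }
  source_positions <- as.matrix(source_positions)
  detector_positions <- as.matrix(detector_positions)
  stopifnot(ncol(source_positions) == 3, ncol(detector_positions) == 3)
  if (any(abs(source_positions[, 3]) > 1e-12) ||
      any(abs(detector_positions[, 3]) > 1e-12))
    stop("optode positions must lie on the z = 0 surface")
  if (modulation_frequency < 0) stop("modulation frequency must be >= 0")

  ns <- nrow(source_positions)
  nd <- nrow(detector_positions)
  pairs <- expand.grid(detector_id = seq_len(nd), source_id = seq_len(ns))
  pairs <- pairs[, c("source_id", "detector_id")]  # source-major ordering
  dx <- source_positions[pairs$source_id, 1] - detector_positions[pairs$detector_id, 1]
  dy <- source_positions[pairs$source_id, 2] - detector_positions[pairs$detector_id, 2]
  pairs$rho <- sqrt(dx^2 + dy^2)
  rownames(pairs) <- NULL

  structure(list(
    source_positions = source_positions,
    detector_positions = detector_positions,
    modulation_frequency = modulation_frequency,
    wavelengths = wavelengths,
    n_sources = ns, n_detectors = nd,
    n_pairs = ns * nd,
    pairs = pairs
  ), class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("DOT probe geometry\n")
  cat(sprintf("  %d sources x %d detectors = %d pairs\n",
              x$n_sources, x$n_detectors, x$n_pairs))
  cat(sprintf("  modulation: %.0f MHz; wavelengths: %s nm\n",
              x$modulation_frequency / 1e6,
              paste(x$wavelengths, collapse = ", ")))
  cat(sprintf("  source-detector separation: %.2f to %.2f cm\n",
              min(x$pairs$rho), max(x$pairs$rho)))
  invisible(x)
}

#' Optical properties of a turbid medium
#'
#' @param mua absorption coefficient, 1/cm.
#' @param musp reduced scattering coefficient, 1/cm.
#' @param refractive_index tissue refractive index (default 1.333,
#'   Intralipid / soft-tissue like).
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(mua, musp, refractive_index = 1.333) {
  if (!is.numeric(mua) || !is.numeric(musp) || mua <= 0 || musp <= 0)
    stop("optical properties must be positive: mua > 0, musp > 0")
  if (musp < 10 * mua)
    warning("musp is not much larger than mua; diffusion approximation is dubious")
  structure(list(mua = mua, musp = musp,
                 refractive_index = refractive_index),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mua = %.4g /cm, musp = %.4g /cm, n = %.4g\n",
              x$mua, x$musp, x$refractive_index))
  invisible(x)
}

# speed of light in vacuum, cm/s
.c0 <- 2.99792458e10

#' Derived diffusion-model parameters
#'
#' Computes the quantities entering the frequency-domain diffusion Green's
#' function for a semi-infinite medium with an extrapolated boundary:
#' diffusion coefficient `D = 1/(3 (mua + musp))` (cm), complex wavenumber
#' `k = sqrt((mua - i w / v) / D)` with `Re(k) > 0` (the `exp(-i w t)` time
#' convention, so unwrapped phase increases with distance), isotropic source
#' depth `z0 = 1/musp`, and extrapolated boundary distance
#' `zb = 2 D (1 + Reff) / (1 - Reff)` with the effective reflection
#' coefficient from the standard polynomial fit in the internal reflection
#' literature.
#'
#' @param props an [optical_properties()] object.
#' @param omega angular modulation frequency, rad/s.
#' @return list with `D`, `k` (complex), `z0`, `zb`, `Reff`, `v`.
#' @export
forward_model_params <- function(props, omega = 2 * pi * 140e6) {
  stopifnot(inherits(props, "optical_properties"))
  n <- props$refractive_index
  v <- .c0 / n
  D <- 1 / (3 * (props$mua + props$musp))
  k <- sqrt(complex(real = props$mua, imaginary = -omega / v) / D)
  if (Re(k) < 0) k <- -k
  Reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  zb <- 2 * D * (1 + Reff) / (1 - Reff)
  list(D = D, k = k, z0 = 1 / props$musp, zb = zb, Reff = Reff, v = v)
}
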