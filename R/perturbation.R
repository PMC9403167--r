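#' Normalized perturbation from paired measurements
#'
#' The quantity driving difference imaging: per source-detector pair,
#'
#'   pert = (Ul - Ur) / Ur
#'        = (Al/Ar cos(phil - phir) - 1) + j Al/Ar sin(phil - phir)
#'
#' where `Ul` is the lesion-side and `Ur` the reference-side measurement.
#' Multiplicative coupling coefficients shared by the two sides (fibre
#' gains, contact losses) cancel exactly, which is the rationale for
#' difference imaging.  For a pure-absorption lesion over a matched
#' reference the real part is expected in `[-1, 0]` (amplitude can only
#' decrease and the phase rotation stays below 90 degrees); the analytic
#' first-order forward model in this package honours this only
#' approximately at high lesion contrast (see the methods vignette).
#'
#' @param Ul lesion-side [fd_measurement()].
#' @param Ur reference-side [fd_measurement()] on the same geometry and
#'   wavelength.
#' @param provenance one of `"measured_matched"`, `"measured_mismatched"`,
#'   `"ann_predicted"`.
#' @return object of class `perturbation`: complex `values` (one per
#'   pair), `wavelength`, `provenance`, and the pair table.
#' @export
compute_perturbation <- function(Ul, Ur,
                                 provenance = c("measured_matched",
                                                "measured_mismatched",
                                                "ann_predicted")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(Ul, "fd_measurement"), inherits(Ur, "fd_measurement"))
  if (!isTRUE(all.equal(Ul$geometry$pairs, Ur$geometry$pairs)) ||
      !isTRUE(all.equal(Ul$geometry$source_positions, Ur$geometry$source_positions)))
    stop("lesion and reference measurements are on different geometries")
  if (!identical(Ul$wavelength, Ur$wavelength))
    stop("lesion and reference measurements are at different wavelengths")
  if (any(Mod(Ur$U) == 0)) stop("reference amplitude is zero at some pair")
  perturbation((Ul$U - Ur$U) / Ur$U, wavelength = Ul$wavelength,
               provenance = provenance, geometry = Ul$geometry)
}

#' Perturbation container
#'
#' @param values complex vector, one entry per source-detector pair.
#' @param wavelength nm.
#' @param provenance origin of the values (measured against a matched or a
#'   mismatched reference, or predicted by the network).
#' @param geometry optional [probe_geometry()] the values belong to.
#' @return object of class `perturbation`.
#' @export
perturbation <- function(values, wavelength = 785,
                         provenance = "measured_matched", geometry = NULL) {
  if (!is.null(geometry) && length(values) != geometry$n_pairs)
    stop("perturbation length does not match the geometry's pair count")
  structure(list(values = as.complex(values), wavelength = wavelength,
                 provenance = provenance, geometry = geometry),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf("perturbation (%s), %d pairs at %g nm\n",
              x$provenance, length(x$values), x$wavelength))
  cat(sprintf("  Re: [%.3f, %.3f]  Im: [%.3f, %.3f]\n",
              min(Re(x$values)), max(Re(x$values)),
              min(Im(x$values)), max(Im(x$values))))
  invisible(x)
}

#' Offset-normalize a measurement for the network
#'
#' The network consumes the lesion-side log amplitude `log(A rho^2)` and
#' unwrapped phase.  Absolute levels of both depend on instrument gains
#' that carry no lesion information, so each measurement set is offset
#' additively: log-amplitudes so their maximum equals a fixed common
#' maximum, phases so their minimum equals a fixed common minimum (both 0
#' by default).  Offsets are additive only (shape-preserving) and are
#' returned so the operation can be inverted.
#'
#' @param measurement an [fd_measurement()].
#' @param common_max_logamp the common maximum for `log(A rho^2)`.
#' @param common_min_phase the common minimum for the unwrapped phase, rad.
#' @return object of class `normalized_input` with `log_amp`, `phase`,
#'   and the applied `offsets = c(amp_offset, phase_offset)`.
#' @export
normalize_for_network <- function(measurement, common_max_logamp = 0,
                                  common_min_phase = 0) {
  stopifnot(inherits(measurement, "fd_measurement"))
  if (any(measurement$amplitude <= 0)) stop("non-positive amplitude")
  la <- log(measurement$amplitude * measurement$rho^2)
  amp_offset <- common_max_logamp - max(la)
  phase_offset <- common_min_phase - min(measurement$phase)
  structure(list(log_amp = la + amp_offset,
                 phase = measurement$phase + phase_offset,
                 offsets = c(amp_offset = amp_offset,
                             phase_offset = phase_offset)),
            class = "normalized_input")
}

#' Invert the network normalization offsets
#'
#' @param x a `normalized_input` from [normalize_for_network()].
#' @return list with the de-offset `log_amp` and `phase` vectors.
#' @export
denormalize_input <- function(x) {
  stopifnot(inherits(x, "normalized_input"))
  list(log_amp = x$log_amp - x$offsets[["amp_offset"]],
       phase = x$phase - x$offsets[["phase_offset"]])
}

# Fixed layouts of the network interface: inputs are the 126 offset
# log-amplitudes (pairs in source-major order) followed by the 126 offset
# phases; outputs are the 126 real parts followed by the 126 imaginary
# parts of the normalized perturbation.  Versioned in the model artifact.
encode_network_input <- function(measurement, common_max_logamp = 0,
                                 common_min_phase = 0) {
  ni <- normalize_for_network(measurement, common_max_logamp, common_min_phase)
  c(ni$log_amp, ni$phase)
}

encode_network_target <- function(pert) {
  v <- if (inherits(pert, "perturbation")) pert$values else as.complex(pert)
  c(Re(v), Im(v))
}

decode_network_output <- function(y, wavelength = 785, geometry = NULL) {
  n <- length(y) / 2
  perturbation(complex(real = y[seq_len(n)], imaginary = y[n + seq_len(n)]),
               wavelength = wavelength, provenance = "ann_predicted",
               geometry = geometry)
}
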