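# Plain-text serialization: measurements and perturbations as headed
# delimited tables, the trained network as a versioned JSON artifact.
# Every reader checks the format tag and refuses silently misparsed input.

.measurement_header <- "# dotdiff-measurement v1"
.perturbation_header <- "# dotdiff-perturbation v1"

#' Write / read a frequency-domain measurement
#'
#' Tabular text format with one row per source-detector pair and columns
#' `wavelength, source_id, detector_id, rho, amplitude, phase`, preceded
#' by a format-version header line.  The round trip is lossless to
#' full double precision.
#'
#' @param measurement an [fd_measurement()].
#' @param path file path.
#' @export
write_measurement <- function(measurement, path) {
  stopifnot(inherits(measurement, "fd_measurement"))
  df <- data.frame(wavelength = measurement$wavelength,
                   source_id = measurement$source_id,
                   detector_id = measurement$detector_id,
                   rho = measurement$rho,
                   amplitude = format(measurement$amplitude, digits = 17),
                   phase = format(measurement$phase, digits = 17))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.measurement_header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurement
#' @param geometry the [probe_geometry()] the file belongs to.
#' @return `read_measurement` returns an [fd_measurement()].
#' @export
read_measurement <- function(path, geometry) {
  first <- readLines(path, n = 1)
  if (!identical(first, .measurement_header))
    stop("not a dotdiff measurement file (bad or missing format header)")
  df <- utils::read.csv(path, skip = 1)
  need <- c("wavelength", "source_id", "detector_id", "rho", "amplitude", "phase")
  if (!all(need %in% names(df))) stop("measurement file is missing columns")
  if (nrow(df) != geometry$n_pairs)
    stop("measurement file does not match the geometry's pair count")
  ord <- order(df$source_id, df$detector_id)
  df <- df[ord, ]
  fd_measurement(geometry,
                 complex(modulus = df$amplitude, argument = df$phase),
                 wavelength = df$wavelength[1])
}

#' Write / read a perturbation
#'
#' Columns `source_id, detector_id, real, imag, provenance` with a
#' format-version header.
#'
#' @param pert a [perturbation()].
#' @param path file path.
#' @export
write_perturbation <- function(pert, path) {
  stopifnot(inherits(pert, "perturbation"))
  ids <- if (!is.null(pert$geometry)) pert$geometry$pairs else
    data.frame(source_id = NA_integer_,
               detector_id = seq_along(pert$values))
  df <- data.frame(source_id = ids$source_id,
                   detector_id = ids$detector_id,
                   real = format(Re(pert$values), digits = 17),
                   imag = format(Im(pert$values), digits = 17),
                   provenance = pert$provenance)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.perturbation_header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_perturbation
#' @param geometry optional [probe_geometry()] to attach.
#' @param wavelength nm.
#' @return `read_perturbation` returns a [perturbation()].
#' @export
read_perturbation <- function(path, geometry = NULL, wavelength = 785) {
  first <- readLines(path, n = 1)
  if (!identical(first, .perturbation_header))
    stop("not a dotdiff perturbation file (bad or missing format header)")
  df <- utils::read.csv(path, skip = 1)
  if (!all(c("real", "imag", "provenance") %in% names(df)))
    stop("perturbation file is missing columns")
  perturbation(complex(real = df$real, imaginary = df$imag),
               wavelength = wavelength,
               provenance = df$provenance[1], geometry = geometry)
}

#' Write / read a trained network artifact
#'
#' Single-file JSON artifact carrying the format version, architecture,
#' weights at full precision, normalization constants, input/output
#' layout tags, training configuration, and seed, so a reloaded model
#' reproduces the original's predictions exactly.
#'
#' @param model a fitted [pert_ann()].
#' @param path file path (`.json`).
#' @export
write_pert_ann <- function(model, path) {
  stopifnot(inherits(model, "pert_ann"))
  obj <- list(format = "dotdiff-pert-ann", version = 1L,
              layer_widths = model$spec$layer_widths,
              params = lapply(model$params, function(l)
                list(W = as.vector(l$W), dim = dim(l$W), b = l$b)),
              normalization = as.list(model$normalization),
              input_layout = model$input_layout,
              output_layout = model$output_layout,
              config = model$config, rng_seed = model$rng_seed,
              best_epoch = model$best_epoch, best_loss = model$best_loss,
              history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pert_ann
#' @return `read_pert_ann` returns the reloaded `pert_ann` model.
#' @export
read_pert_ann <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model artifact: ",
                                           conditionMessage(e)))
  if (!identical(obj$format, "dotdiff-pert-ann"))
    stop("not a dotdiff model artifact (bad or missing format tag)")
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported model artifact version: ", obj$version)
  params <- lapply(seq_len(nrow(obj$params)), function(i) {
    list(W = matrix(obj$params$W[[i]], obj$params$dim[[i]][1],
                    obj$params$dim[[i]][2]),
         b = obj$params$b[[i]])
  })
  structure(list(params = params,
                 spec = ann_spec(as.integer(obj$layer_widths)),
                 best_epoch = obj$best_epoch, best_loss = obj$best_loss,
                 history = as.data.frame(obj$history),
                 normalization = unlist(obj$normalization),
                 input_layout = obj$input_layout,
                 output_layout = obj$output_layout,
                 config = obj$config, rng_seed = obj$rng_seed),
            class = "pert_ann")
}
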