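# Image and metadata I/O. Images travel as 32-bit TIFF (phase in
# radians, intensity dimensionless); the physical acquisition metadata
# rides in a sidecar JSON with fixed keys {wavelength_m, pitch_m,
# distance_m} next to the image file.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an image as 32-bit TIFF with sidecar metadata
#'
#' @param values Numeric matrix (phase in radians or dimensionless
#'   intensity).
#' @param path Output TIFF path.
#' @param spec Optional [propagation_spec()]; when given, a sidecar JSON
#'   `<path minus extension>.json` with keys `wavelength_m`, `pitch_m`,
#'   `distance_m` is written alongside.
#' @details The TIFF container stores samples on the `[0, 1]` scale. Values
#'   outside that range (phase maps in radians, typically) are mapped
#'   affinely into it and the mapping is recorded in the sidecar under
#'   `value_offset` / `value_scale`, which the readers undo transparently;
#'   such files therefore need their sidecar to be meaningful.
#' @return `path`, invisibly.
#' @export
write_image <- function(values, path, spec = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) stop("`values` must be a numeric matrix")
  rng <- range(values)
  offset <- 0; scale <- 1
  if (rng[1] < 0 || rng[2] > 1) {
    offset <- rng[1]
    scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    values <- (values - offset) / scale
  }
  tiff::writeTIFF(values, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list()
  if (!is.null(spec))
    meta <- list(wavelength_m = spec$wavelength, pitch_m = spec$pitch,
                 distance_m = spec$distance)
  if (scale != 1 || offset != 0)
    meta <- c(meta, list(value_offset = offset, value_scale = scale))
  if (length(meta))
    jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grayscale image (TIFF or PNG)
#'
#' Shared reader for intensity and phase images. Float TIFF values pass
#' through unchanged (the sidecar `value_offset`/`value_scale`, when
#' present, is applied to undo the `[0, 1]` container mapping of
#' [write_image()]); integer PNG is rescaled to `[0, 1]`. Multichannel
#' images are averaged to one channel.
#'
#' @param path Image path (`.tif`/`.tiff`/`.png`).
#' @return Numeric matrix.
#' @export
read_image_gray <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = FALSE)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the `png` package")
    png::readPNG(path)
  } else stop(sprintf("unsupported image format: .%s (use TIFF or PNG)", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)  # collapse channels
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$value_scale))
      img <- img * as.numeric(meta$value_scale) + as.numeric(meta$value_offset %||% 0)
  }
  img
}

#' Read a diffraction intensity with its acquisition metadata
#'
#' Reads a TIFF (float values pass through unchanged; 32-bit writes quantize at 2^-32) or an 8/16-bit PNG
#' (rescaled to `[0, 1]`). Metadata comes from the sidecar JSON written by
#' [write_image()] unless all three values are supplied as arguments.
#' Negative float values are clipped to zero with a warning.
#'
#' @param path Image path (`.tif`/`.tiff`/`.png`).
#' @param wavelength,pitch,distance Optional metadata overrides (meters);
#'   each overrides the corresponding sidecar key.
#' @return A list: `intensity` (nonnegative matrix) and `spec`
#'   ([propagation_spec()]).
#' @export
read_intensity <- function(path, wavelength = NULL, pitch = NULL,
                           distance = NULL) {
  img <- read_image_gray(path)
  if (any(img < 0)) {
    warning(sprintf("%d negative pixels clipped to 0", sum(img < 0)))
    img[img < 0] <- 0
  }
  meta <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc)
  wavelength <- wavelength %||% meta$wavelength_m
  pitch <- pitch %||% meta$pitch_m
  distance <- distance %||% meta$distance_m %||% 0
  missing_keys <- c(if (is.null(wavelength)) "wavelength_m",
                    if (is.null(pitch)) "pitch_m")
  if (length(missing_keys))
    stop(sprintf("missing metadata for %s: provide %s via the sidecar JSON or arguments",
                 path, paste(missing_keys, collapse = ", ")))
  list(intensity = img,
       spec = propagation_spec(as.numeric(wavelength), as.numeric(pitch),
                               as.numeric(distance)))
}

#' Parse a length with unit suffix to meters
#'
#' Accepts plain numbers (meters) or suffixed strings such as `"10mm"`,
#' `"8um"`, `"632.8nm"`.
#'
#' @param x Numeric or string scalar.
#' @return Length in meters.
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^(-?[0-9.eE+-]+)\\s*(nm|um|mm|cm|m)?$", x))[[1]]
  if (length(m) == 0L || m[2] == "")
    stop(sprintf("cannot parse length '%s' (use e.g. 10mm, 8um, 632.8nm)", x))
  val <- as.numeric(m[2])
  mult <- switch(if (m[3] == "") "m" else m[3],
                 nm = 1e-9, um = 1e-6, mm = 1e-3, cm = 1e-2, m = 1)
  val * mult
}
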