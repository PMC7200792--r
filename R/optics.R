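# Angular-spectrum free-space propagation: the exact scalar diffraction
# transfer function G(fx, fy) = exp[i k d sqrt(1 - lambda^2 fx^2 - lambda^2 fy^2)]
# applied in the DFT domain (unshifted layout, DC at index [1,1]; forward
# transform with negative exponent, i.e. stats::fft). All lengths in meters.

#' Propagation geometry for the scalar diffraction model
#'
#' Bundles the physical parameters of the imaging geometry: illumination
#' wavelength, detector pixel pitch and the object-to-detector distance.
#' The wavenumber `k = 2*pi/wavelength` is derived where needed, never stored.
#'
#' @param wavelength Illumination wavelength in meters (e.g. `632.8e-9` for a
#'   He-Ne laser).
#' @param pitch Sampling pitch (pixel size) in meters.
#' @param distance Signed propagation distance in meters; negative values
#'   back-propagate.
#' @param pad_factor Integer zero-padding factor (>= 1) applied around the
#'   field before the DFT. `1` (default) keeps the implicit periodic
#'   (circular) boundary model; `2` suppresses wraparound for large distances.
#'   The result is cropped back to the original grid.
#' @return An object of class `"propagation_spec"`.
#' @examples
#' spec <- propagation_spec(632.8e-9, 8e-6, 10e-3)
#' @export
propagation_spec <- function(wavelength, pitch, distance = 0, pad_factor = 1L) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, is.finite(wavelength),
            is.numeric(pitch), length(pitch) == 1L, is.finite(pitch),
            is.numeric(distance), length(distance) == 1L, is.finite(distance))
  if (wavelength <= 0) stop("`wavelength` must be > 0 (meters)")
  if (pitch <= 0) stop("`pitch` must be > 0 (meters)")
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L) stop("`pad_factor` must be an integer >= 1")
  structure(list(wavelength = wavelength, pitch = pitch,
                 distance = distance, pad_factor = pad_factor),
            class = "propagation_spec")
}

#' @export
print.propagation_spec <- function(x, ...) {
  cat(sprintf("propagation_spec: lambda = %.4g nm, pitch = %.4g um, d = %.4g mm, pad = %d\n",
              x$wavelength * 1e9, x$pitch * 1e6, x$distance * 1e3, x$pad_factor))
  invisible(x)
}

#' Complex optical field with sampling metadata
#'
#' A thin container for a 2D complex amplitude grid together with its
#' physical sampling pitch and wavelength, so propagation needs no further
#' context.
#'
#' @param values 2D complex (or real, promoted) matrix.
#' @param pitch Sampling pitch in meters.
#' @param wavelength Wavelength in meters.
#' @return An object of class `"complex_field"` with elements `values`,
#'   `pitch`, `wavelength`.
#' @export
complex_field <- function(values, pitch, wavelength) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("`values` must be finite everywhere")
  if (pitch <= 0 || wavelength <= 0) stop("`pitch` and `wavelength` must be > 0")
  storage.mode(values) <- "complex"
  structure(list(values = values, pitch = pitch, wavelength = wavelength),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field: %d x %d, pitch %.4g um, lambda %.4g nm\n",
              nrow(x$values), ncol(x$values), x$pitch * 1e6, x$wavelength * 1e9))
  invisible(x)
}

#' Unit-amplitude object field of a pure phase object
#'
#' A thin transparent sample delays the wavefront without absorbing it, so
#' the complex amplitude immediately behind it under unit plane-wave
#' illumination is `exp(1i * phase)`: unit modulus everywhere, all the
#' information in the argument.
#'
#' @param phase 2D real matrix of phase values in radians.
#' @param spec A [propagation_spec()] supplying pitch and wavelength.
#' @return A [complex_field()] with `|values| == 1`.
#' @export
phase_to_field <- function(phase, spec) {
  phase <- as_phase_map(phase)
  complex_field(exp(1i * phase), spec$pitch, spec$wavelength)
}

# Coerce and validate a phase map: finite 2D real matrix (radians).
as_phase_map <- function(phase) {
  if (is.list(phase) && !is.null(phase$values)) phase <- phase$values
  if (!is.matrix(phase) || !is.numeric(phase))
    stop("phase map must be a numeric matrix (radians)")
  if (!all(is.finite(phase))) stop("phase map must be finite everywhere")
  phase
}

# Validate an intensity image: finite, nonnegative 2D real matrix.
as_intensity_image <- function(intensity) {
  if (is.list(intensity) && !is.null(intensity$values)) intensity <- intensity$values
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity image must be a numeric matrix")
  if (!all(is.finite(intensity))) stop("intensity image must be finite everywhere")
  if (any(intensity < 0)) stop("intensity image must be nonnegative")
  intensity
}

#' Unshifted DFT spatial-frequency grid
#'
#' Frequency samples in cycles per meter matching the layout of [stats::fft()]:
#' DC at index 1, spacing `1/(n*pitch)`, negative frequencies in the upper
#' half. The largest magnitude is the Nyquist frequency `1/(2*pitch)`.
#'
#' @param n Grid size (samples per side), `n >= 1`.
#' @param pitch Sample spacing in meters.
#' @return A list with `fx`, `fy`: n x n matrices (cycles/m). `fx` varies
#'   along rows (first index), `fy` along columns.
#' @export
make_frequency_grid <- function(n, pitch) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be an integer >= 1")
  if (pitch <= 0) stop("`pitch` must be > 0")
  k <- 0:(n - 1L)
  f <- ifelse(k < (n + 1L) %/% 2L, k, k - n) / (n * pitch)
  list(fx = matrix(f, n, n, byrow = FALSE), fy = matrix(f, n, n, byrow = TRUE))
}

#' Angular-spectrum transfer function
#'
#' `G = exp[i k d sqrt(1 - lambda^2 (fx^2 + fy^2))]` on the propagating band.
#' Evanescent components (`lambda^2 f^2 > 1`), which decay over sub-wavelength
#' distances, are zeroed so that `|G|` is exactly 1 or 0.
#'
#' @param grid A frequency grid from [make_frequency_grid()].
#' @param spec A [propagation_spec()]; its `distance` is used.
#' @param distance Optional override of `spec$distance` (meters).
#' @return Complex matrix `G` with `|G| %in% c(0, 1)`.
#' @export
transfer_function <- function(grid, spec, distance = spec$distance) {
  lam <- spec$wavelength
  k <- 2 * pi / lam
  radicand <- 1 - lam^2 * (grid$fx^2 + grid$fy^2)
  G <- matrix(0 + 0i, nrow(grid$fx), ncol(grid$fx))
  prop <- radicand >= 0
  G[prop] <- exp(1i * k * distance * sqrt(radicand[prop]))
  G
}

#' Propagate a complex field through free space
#'
#' Multiplies the field's angular spectrum by the exact transfer function and
#' transforms back: `U_d = IDFT( DFT(U_0) * G )`. Negative distances
#' back-propagate. With `pad_factor > 1` the field is zero-padded before the
#' transform and cropped afterwards to attenuate periodic wraparound.
#'
#' @param field A [complex_field()].
#' @param distance Signed propagation distance in meters.
#' @param pad_factor Zero-padding factor (integer >= 1), default 1.
#' @return A [complex_field()] with unchanged sampling metadata.
#' @export
propagate <- function(field, distance, pad_factor = 1L) {
  if (!inherits(field, "complex_field")) stop("`field` must be a complex_field")
  if (field$pitch >= field$wavelength / 2) {
    # pitch below lambda/2 can never occur at optical wavelengths and camera
    # pitches; the opposite (usual) case is fine because the evanescent
    # cutoff never enters the sampled band.
  } else {
    warning("pitch < wavelength/2: evanescent band reaches into the sampled grid")
  }
  U <- field$values
  n1 <- nrow(U); n2 <- ncol(U)
  pad_factor <- as.integer(pad_factor)
  if (pad_factor > 1L) {
    N1 <- n1 * pad_factor; N2 <- n2 * pad_factor
    Up <- matrix(0 + 0i, N1, N2)
    Up[seq_len(n1), seq_len(n2)] <- U
    U <- Up
  }
  if (nrow(U) != ncol(U)) {
    # non-square grids: build G from per-axis frequency vectors
    G <- .transfer_rect(nrow(U), ncol(U), field$pitch, field$wavelength, distance)
  } else {
    grid <- make_frequency_grid(nrow(U), field$pitch)
    G <- transfer_function(grid,
                           propagation_spec(field$wavelength, field$pitch, distance),
                           distance)
  }
  V <- stats::fft(U)
  out <- stats::fft(V * G, inverse = TRUE) / length(U)
  if (pad_factor > 1L) out <- out[seq_len(n1), seq_len(n2)]
  complex_field(out, field$pitch, field$wavelength)
}

.transfer_rect <- function(n1, n2, pitch, wavelength, distance) {
  fv <- function(n) {
    k <- 0:(n - 1L)
    ifelse(k < (n + 1L) %/% 2L, k, k - n) / (n * pitch)
  }
  fx <- matrix(fv(n1), n1, n2, byrow = FALSE)
  fy <- matrix(fv(n2), n1, n2, byrow = TRUE)
  k <- 2 * pi / wavelength
  radicand <- 1 - wavelength^2 * (fx^2 + fy^2)
  G <- matrix(0 + 0i, n1, n2)
  prop <- radicand >= 0
  G[prop] <- exp(1i * k * distance * sqrt(radicand[prop]))
  G
}

#' Simulated diffraction-pattern intensity of a phase object
#'
#' The full forward model `H`: object phase to unit-modulus field, free-space
#' propagation over `spec$distance`, squared modulus at the detector. This is
#' the map whose mismatch against a measured pattern drives every
#' reconstruction method in the package.
#'
#' @param phase 2D real matrix of phase values (radians).
#' @param spec A [propagation_spec()].
#' @return Nonnegative real matrix of detector intensities (dimensionless;
#'   unit mean for an undisturbed plane wave).
#' @export
forward_intensity <- function(phase, spec) {
  U0 <- phase_to_field(phase, spec)
  Ud <- propagate(U0, spec$distance, spec$pad_factor)
  Mod(Ud$values)^2
}

# Fused forward pass + adjoint for optimization: returns the predicted
# intensity and a closure mapping dLoss/dIntensity back to dLoss/dPhase.
# The adjoint of (crop . IDFT . G . DFT . pad) is the same pipeline with
# conj(G), i.e. propagation over -distance restricted to the same band.
forward_intensity_grad <- function(phase, spec) {
  U0 <- phase_to_field(phase, spec)
  Ud <- propagate(U0, spec$distance, spec$pad_factor)
  I_pred <- Mod(Ud$values)^2
  list(
    intensity = I_pred,
    backward = function(g_intensity) {
      gU <- complex_field(g_intensity * Ud$values, spec$pitch, spec$wavelength)
      gU0 <- propagate(gU, -spec$distance, spec$pad_factor)
      2 * Im(gU0$values * Conj(U0$values))
    }
  )
}
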