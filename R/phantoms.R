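# Synthetic phase objects and simulated measurements. The default scene
# mimics a thin transparent biological sample under He-Ne illumination:
# a smooth sub-2*pi phase map on a 256x256 grid with 8 um pitch. Smoothness
# keeps the phantom spectrum well below Nyquist, which matters both
# physically (thin-sample regime) and numerically (band-limited propagation
# is exact under the periodic model).

#' Specification of a synthetic phase phantom
#'
#' @param kind One of `"gaussian_blobs"` (sum of random smooth bumps, the
#'   default surrogate for cell-like objects), `"smooth_noise"`
#'   (low-pass-filtered white noise), `"binary_shapes"` (random filled
#'   rectangles and disks; hard edges, off the band-limited path), or
#'   `"imported_image"` (a user-supplied image file rescaled to phase).
#' @param size Grid side length in pixels (>= 8).
#' @param peak_phase Maximum phase in radians; values above `2*pi` are
#'   permitted only to exercise the documented large-modulation failure mode.
#' @param n_features Number of features (bumps / shapes) for the random kinds.
#' @param seed Integer seed making the phantom fully reproducible.
#' @param path File path, only for `kind = "imported_image"`.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(kind = "gaussian_blobs", size = 256L, peak_phase = 1,
                         n_features = 5L, seed = 1L, path = NULL) {
  kind <- match.arg(kind, c("gaussian_blobs", "smooth_noise", "binary_shapes",
                            "imported_image"))
  size <- as.integer(size)
  if (is.na(size) || size < 8L) stop("`size` must be an integer >= 8")
  if (!is.numeric(peak_phase) || peak_phase <= 0) stop("`peak_phase` must be > 0")
  n_features <- as.integer(n_features)
  if (is.na(n_features) || n_features < 0L) stop("`n_features` must be >= 0")
  structure(list(kind = kind, size = size, peak_phase = peak_phase,
                 n_features = n_features, seed = as.integer(seed), path = path),
            class = "phantom_spec")
}

#' Generate a synthetic phase object
#'
#' Deterministic under a fixed seed. Random kinds are normalized so the
#' phase ranges over exactly `[0, peak_phase]` (flat zero when
#' `n_features = 0`).
#'
#' @param spec A [phantom_spec()].
#' @return A `size x size` numeric matrix of phase values in radians.
#' @examples
#' phi <- generate_phantom(phantom_spec(size = 64, seed = 7))
#' range(phi)  # 0 .. 1
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  n <- spec$size
  phi <- switch(spec$kind,
    gaussian_blobs = with_seed(spec$seed, .phantom_blobs(n, spec$n_features)),
    smooth_noise   = with_seed(spec$seed, .phantom_smooth_noise(n)),
    binary_shapes  = with_seed(spec$seed, .phantom_binary(n, spec$n_features)),
    imported_image = .phantom_imported(spec$path, n)
  )
  if (max(phi) > min(phi)) phi <- rescale_range(phi, 0, spec$peak_phase)
  phi
}

# Sum of n Gaussian bumps with sigma drawn in [n/16, n/4] px and centers
# in the middle 60% of the grid. A raised-cosine border taper removes the
# periodization jump of truncated tails, keeping the spectrum below half
# Nyquist (asserted in the tests) so propagation stays oracle-exact.
.phantom_blobs <- function(n, n_features) {
  phi <- matrix(0, n, n)
  if (n_features == 0L) return(phi)
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  for (i in seq_len(n_features)) {
    cx <- stats::runif(1, 0.2 * n, 0.8 * n)
    cy <- stats::runif(1, 0.2 * n, 0.8 * n)
    sg <- stats::runif(1, n / 16, n / 4)
    amp <- stats::runif(1, 0.4, 1)
    phi <- phi + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2))
  }
  phi * .edge_taper(n)
}

# Separable raised-cosine (Tukey) window falling to zero over the outer
# eighth of each edge.
.edge_taper <- function(n) {
  w <- rep(1, n)
  m <- max(2L, round(n / 8))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
  w[seq_len(m)] <- ramp
  w[n + 1L - seq_len(m)] <- ramp
  outer(w, w)
}

# White noise pushed through a hard spectral low-pass at Nyquist/4.
.phantom_smooth_noise <- function(n) {
  w <- matrix(stats::rnorm(n * n), n, n)
  grid <- make_frequency_grid(n, 1)       # cycles per pixel
  keep <- (grid$fx^2 + grid$fy^2) <= (0.125)^2
  Re(stats::fft(stats::fft(w) * keep, inverse = TRUE)) / (n * n)
}

.phantom_binary <- function(n, n_features) {
  phi <- matrix(0, n, n)
  if (n_features == 0L) return(phi)
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  for (i in seq_len(n_features)) {
    if (stats::runif(1) < 0.5) {
      cx <- stats::runif(1, 0.2 * n, 0.8 * n)
      cy <- stats::runif(1, 0.2 * n, 0.8 * n)
      r <- stats::runif(1, n / 16, n / 6)
      phi[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 1
    } else {
      x0 <- sort(stats::runif(2, 0.15 * n, 0.85 * n))
      y0 <- sort(stats::runif(2, 0.15 * n, 0.85 * n))
      phi[xs >= x0[1] & xs <= x0[2] & ys >= y0[1] & ys <= y0[2]] <- 1
    }
  }
  phi
}

.phantom_imported <- function(path, n) {
  if (is.null(path) || !file.exists(path))
    stop("imported_image phantom requires an existing `path`")
  img <- read_image_gray(path)
  if (nrow(img) != n || ncol(img) != n)
    img <- .resize_bilinear(img, n)
  img
}

# Minimal bilinear resize for imported images (no image package dependency).
.resize_bilinear <- function(img, n) {
  src <- dim(img)
  xi <- seq(1, src[1], length.out = n)
  yi <- seq(1, src[2], length.out = n)
  x0 <- pmin(floor(xi), src[1] - 1); fx <- xi - x0
  y0 <- pmin(floor(yi), src[2] - 1); fy <- yi - y0
  a <- img[x0, y0] * outer(1 - fx, 1 - fy) + img[x0 + 1, y0] * outer(fx, 1 - fy) +
       img[x0, y0 + 1] * outer(1 - fx, fy) + img[x0 + 1, y0 + 1] * outer(fx, fy)
  a
}

#' Measurement-noise specification
#'
#' @param model `"none"`, `"gaussian"` (additive, `parameter` = standard
#'   deviation on the detector-normalized intensity scale) or `"poisson"`
#'   (`parameter` = expected photon count per unit intensity per pixel).
#' @param parameter Nonnegative noise parameter (ignored for `"none"`).
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(model = "none", parameter = 0) {
  model <- match.arg(model, c("none", "gaussian", "poisson"))
  if (!is.numeric(parameter) || parameter < 0) stop("`parameter` must be >= 0")
  structure(list(model = model, parameter = parameter), class = "noise_spec")
}

#' Simulate a detector measurement of a phase object
#'
#' Runs the angular-spectrum forward model and applies the selected noise
#' model; the result is clipped at zero (a detector never reports negative
#' counts).
#'
#' @param phase Phase map (radians), a numeric matrix.
#' @param spec A [propagation_spec()] giving wavelength, pitch and distance.
#' @param noise A [noise_spec()]; default noise-free.
#' @param seed Integer seed for the noise draw.
#' @return Nonnegative intensity matrix.
#' @export
simulate_measurement <- function(phase, spec, noise = noise_spec(), seed = 1L) {
  I0 <- forward_intensity(phase, spec)
  In <- switch(noise$model,
    none = I0,
    gaussian = I0 + with_seed(seed,
      matrix(stats::rnorm(length(I0), 0, noise$parameter), nrow(I0))),
    poisson = {
      if (noise$parameter <= 0) stop("poisson noise needs `parameter` > 0 photons")
      with_seed(seed,
        matrix(stats::rpois(length(I0), noise$parameter * I0), nrow(I0))) /
        noise$parameter
    })
  pmax(In, 0)
}
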