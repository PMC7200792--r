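# Independent oracles and shared fixtures, built in code at test time.

# Default acquisition geometry used throughout: He-Ne illumination on an
# 8 um camera, 10 mm object-to-detector distance.
default_spec <- function(distance = 10e-3, pad_factor = 1L) {
  propagation_spec(632.8e-9, 8e-6, distance, pad_factor)
}

# Brute-force angular-spectrum propagation via explicit DFT matrices
# (direct summation; no call to stats::fft). O(n^3) per matrix product,
# equivalent to the O(n^4) double-sum definition of the 2D DFT.
oracle_propagate <- function(U, pitch, wavelength, distance) {
  n <- nrow(U)
  j <- 0:(n - 1)
  Fm <- exp(-2i * pi * outer(j, j) / n)          # forward DFT, negative exponent
  Uhat <- Fm %*% U %*% Fm
  f <- ifelse(j < (n + 1) %/% 2, j, j - n) / (n * pitch)
  fx <- matrix(f, n, n); fy <- t(fx)
  rad <- 1 - wavelength^2 * (fx^2 + fy^2)
  G <- ifelse(rad >= 0, exp(2i * pi / wavelength * distance * sqrt(pmax(rad, 0))), 0 + 0i)
  Fi <- Conj(Fm)                                  # inverse DFT (unscaled)
  (Fi %*% (Uhat * G) %*% Fi) / n^2
}

# Band-limited random complex field: white noise restricted to the lowest
# quarter of the frequency band, so no evanescent content at any distance.
bandlimited_field <- function(n, pitch, wavelength, seed = 1) {
  set.seed(seed)
  W <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  j <- 0:(n - 1)
  f <- ifelse(j < (n + 1) %/% 2, j, j - n) / n   # cycles per sample
  fx <- matrix(f, n, n); fy <- t(fx)
  keep <- (fx^2 + fy^2) <= 0.125^2
  U <- stats::fft(stats::fft(W) * keep, inverse = TRUE) / n^2
  complex_field(U, pitch, wavelength)
}

# Pixelwise mean square error by explicit double loop.
oracle_mse <- function(a, b) {
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    acc <- acc + (a[i, j] - b[i, j])^2
  acc / (nrow(a) * ncol(a))
}

rel_err <- function(x, y) max(Mod(x - y)) / max(Mod(y))
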