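test_that("phase objects map to unit-modulus fields", {
  spec <- default_spec()
  z <- matrix(0, 8, 8)
  expect_equal(phase_to_field(z, spec)$values, matrix(1 + 0i, 8, 8))
  expect_equal(phase_to_field(z + pi / 2, spec)$values, matrix(0 + 1i, 8, 8),
               tolerance = 1e-15)
  set.seed(1)
  phi <- matrix(rnorm(64, 0, 5), 8)
  expect_equal(Mod(phase_to_field(phi, spec)$values), matrix(1, 8, 8))
  expect_error(phase_to_field(matrix(c(NA, 1, 2, 3), 2), spec), "finite")
})

test_that("frequency grid follows the unshifted DFT convention", {
  g1 <- make_frequency_grid(1, 1)
  expect_equal(g1$fx, matrix(0, 1, 1))
  g4 <- make_frequency_grid(4, 1)
  expect_equal(g4$fx[, 1], c(0, 0.25, -0.5, -0.25))
  expect_equal(g4$fy[1, ], c(0, 0.25, -0.5, -0.25))
  # Nyquist bound for even and odd sizes
  for (n in c(4, 5, 8)) {
    g <- make_frequency_grid(n, 2e-6)
    expect_lte(max(abs(g$fx)), 1 / (2 * 2e-6))
    expect_equal(g$fx[1, 1], 0)
  }
  expect_error(make_frequency_grid(0, 1), ">= 1")
})

test_that("transfer function: DC term, zero distance, evanescent cutoff", {
  spec <- default_spec(distance = 3e-3)
  g <- make_frequency_grid(16, spec$pitch)
  G <- transfer_function(g, spec)
  k <- 2 * pi / spec$wavelength
  expect_equal(G[1, 1], exp(1i * k * spec$distance))
  G0 <- transfer_function(g, spec, distance = 0)
  expect_equal(G0, matrix(1 + 0i, 16, 16))
  # artificial geometry whose band reaches past the evanescent cutoff
  spec_e <- propagation_spec(1e-6, 0.4e-6, 1e-3)
  ge <- make_frequency_grid(16, spec_e$pitch)
  Ge <- transfer_function(ge, spec_e)
  evan <- spec_e$wavelength^2 * (ge$fx^2 + ge$fy^2) > 1
  expect_true(any(evan))
  expect_true(all(Ge[evan] == 0))
  expect_equal(Mod(Ge[!evan]), rep(1, sum(!evan)))
})

test_that("propagation reduces to identity at d = 0 and a phase factor for DC", {
  U <- bandlimited_field(16, 8e-6, 632.8e-9, seed = 2)
  expect_equal(propagate(U, 0)$values, U$values, tolerance = 1e-12)
  Uc <- complex_field(matrix(2.5 + 0i, 16, 16), 8e-6, 632.8e-9)
  d <- 7e-3
  out <- propagate(Uc, d)$values
  expect_equal(out, matrix(2.5 * exp(1i * 2 * pi / 632.8e-9 * d), 16, 16),
               tolerance = 1e-12)
})

test_that("propagation matches the direct DFT-summation oracle", {
  pitch <- 8e-6; lam <- 632.8e-9
  for (n in c(16, 32)) for (d in c(10e-3, -5e-3, 95e-3)) {
    U <- bandlimited_field(n, pitch, lam, seed = n + round(1e3 * d))
    got <- propagate(U, d)$values
    want <- oracle_propagate(U$values, pitch, lam, d)
    expect_lt(rel_err(got, want), 1e-10)
  }
})

test_that("propagation conserves energy, inverts, and composes", {
  U <- bandlimited_field(32, 8e-6, 632.8e-9, seed = 9)
  e0 <- sum(Mod(U$values)^2)
  for (d in c(10e-3, 180e-3)) {
    Ud <- propagate(U, d)
    expect_lt(abs(sum(Mod(Ud$values)^2) - e0) / e0, 1e-10)        # unitarity
    back <- propagate(Ud, -d)
    expect_lt(rel_err(back$values, U$values), 1e-10)              # round trip
  }
  d1 <- 10e-3; d2 <- 17e-3
  onehop <- propagate(U, d1 + d2)$values
  twohop <- propagate(propagate(U, d1), d2)$values
  expect_lt(rel_err(twohop, onehop), 1e-10)                       # semigroup
})

test_that("forward intensity: plane-wave invariance, nonnegativity, oracle", {
  spec <- default_spec()
  n <- 32
  expect_equal(forward_intensity(matrix(0, n, n), spec), matrix(1, n, n),
               tolerance = 1e-12)
  expect_equal(forward_intensity(matrix(0.73, n, n), spec), matrix(1, n, n),
               tolerance = 1e-12)
  phi <- generate_phantom(phantom_spec(size = n, seed = 3))
  I <- forward_intensity(phi, spec)
  expect_true(all(I >= 0))
  want <- Mod(oracle_propagate(exp(1i * phi), spec$pitch, spec$wavelength,
                               spec$distance))^2
  expect_lt(max(abs(I - want)) / max(want), 1e-10)
})

test_that("padding crops back to the original grid and tames wraparound", {
  phi <- generate_phantom(phantom_spec(size = 32, seed = 4))
  # distance short enough that diffraction stays local (Fresnel zone ~1 px):
  # the periodic and padded models must then agree away from the border
  spec1 <- default_spec(distance = 0.2e-3, pad_factor = 1L)
  spec2 <- default_spec(distance = 0.2e-3, pad_factor = 2L)
  I1 <- forward_intensity(phi, spec1)
  I2 <- forward_intensity(phi, spec2)
  expect_identical(dim(I2), dim(phi))
  expect_lt(max(abs(I1 - I2)[9:24, 9:24]), 0.02)
})

test_that("the fused physics gradient matches finite differences", {
  spec <- default_spec()
  set.seed(6)
  phi <- matrix(rnorm(64, 0, 0.4), 8)
  I_meas <- forward_intensity(matrix(rnorm(64, 0, 0.4), 8), spec)
  fg <- holophase:::forward_intensity_grad(phi, spec)
  g <- fg$backward(2 * (fg$intensity - I_meas) / 64)
  lossf <- function(p) mean((forward_intensity(p, spec) - I_meas)^2)
  eps <- 1e-6
  for (idx in sample(64, 10)) {
    pp <- phi; pp[idx] <- pp[idx] + eps
    pm <- phi; pm[idx] <- pm[idx] - eps
    fd <- (lossf(pp) - lossf(pm)) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-5)
  }
})

test_that("invalid geometries are rejected", {
  expect_error(propagation_spec(-1, 8e-6, 0), "wavelength")
  expect_error(propagation_spec(632.8e-9, 0, 0), "pitch")
  expect_error(propagation_spec(632.8e-9, 8e-6, 0, pad_factor = 0), "pad_factor")
})
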