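## ---- Gerchberg-Saxton ----

test_that("a uniform pattern with zero-phase init is a fixed point of GS", {
  spec <- default_spec()
  n <- 32
  planes <- lapply(c(10e-3, 20e-3), function(d)
    list(intensity = matrix(1, n, n), distance = d))
  phi <- gs_retrieve(gs_config(planes, n_iterations = 5L), spec)
  expect_lt(max(abs(phi)), 1e-10)
})

test_that("single-plane GS error reduction is monotone on noise-free data", {
  spec <- default_spec()
  truth <- generate_phantom(phantom_spec(size = 32, seed = 17))
  I <- forward_intensity(truth, spec)
  phi <- gs_retrieve(gs_config(list(list(intensity = I, distance = spec$distance)),
                               n_iterations = 60L), spec)
  err <- attr(phi, "plane_error")
  expect_true(all(diff(err) <= 1e-12))
})

test_that("gs_retrieve output is zero-mean and configs validate", {
  spec <- default_spec()
  truth <- generate_phantom(phantom_spec(size = 32, seed = 18))
  planes <- lapply(c(10e-3, 15e-3), function(d) {
    s <- spec; s$distance <- d
    list(intensity = forward_intensity(truth, s), distance = d)
  })
  phi <- gs_retrieve(gs_config(planes, n_iterations = 20L), spec)
  expect_equal(mean(phi), 0, tolerance = 1e-12)
  expect_error(gs_config(list()), "at least one")
  expect_error(gs_config(list(list(intensity = matrix(1, 4, 4), distance = 1e-3),
                              list(intensity = matrix(1, 4, 4), distance = 1e-3))),
               "distinct")
})

## ---- Transport of intensity ----

test_that("a zero axial derivative yields a flat phase", {
  spec <- default_spec()
  I <- matrix(1, 32, 32) + 0.1 * generate_phantom(phantom_spec(size = 32, seed = 2))
  phi <- tie_solve(tie_input(I, I, I, 0.5e-3), spec)
  expect_lt(max(phi) - min(phi), 1e-12)
})

test_that("the solver is linear in the intensity difference", {
  spec <- default_spec()
  truth <- generate_phantom(phantom_spec(size = 32, seed = 3))
  dz <- 0.5e-3
  Im <- forward_intensity(truth, default_spec(-dz))
  Ip <- forward_intensity(truth, default_spec(dz))
  I0 <- matrix(1, 32, 32)
  phi1 <- tie_solve(tie_input(Im, I0, Ip, dz), spec)
  alpha <- 3.7
  Im2 <- I0 + alpha * (Im - I0)
  Ip2 <- I0 + alpha * (Ip - I0)
  phi2 <- tie_solve(tie_input(pmax(Im2, 0), I0, pmax(Ip2, 0), dz), spec)
  expect_lt(max(abs(phi2 - alpha * phi1)) / max(abs(phi1)), 1e-8)
})

test_that("a weak quadratic phase is recovered with the right curvature", {
  # phi = a * r^2 around the grid center; in the paraxial small-defocus
  # regime the recovered phase must carry the same curvature. The fit is
  # restricted to the central quarter, away from the periodic boundary.
  n <- 64; pitch <- 8e-6
  spec <- propagation_spec(632.8e-9, pitch, 0)
  x <- (seq_len(n) - n / 2 - 0.5) * pitch
  r2 <- outer(x^2, x^2, "+")
  a <- 0.4 / max(r2)                 # peak 0.4 rad at the corners: no wrap
  phi_true <- a * r2
  dz <- 0.2e-3
  U <- phase_to_field(phi_true, spec)
  Im <- Mod(propagate(U, -dz)$values)^2
  Ip <- Mod(propagate(U, dz)$values)^2
  phi <- tie_solve(tie_input(Im, matrix(1, n, n), Ip, dz), spec)
  sel <- (n / 2 - 15):(n / 2 + 16)
  fit <- stats::lm(as.vector(phi[sel, sel]) ~ as.vector(r2[sel, sel]))
  a_hat <- stats::coef(fit)[2]
  expect_lt(abs(a_hat - a) / a, 0.05)
})

test_that("tie inputs validate", {
  I <- matrix(1, 8, 8)
  expect_error(tie_input(I, I, I, 0), "delta_z")
  expect_error(tie_input(I, I, matrix(1, 4, 4), 1e-3), "share one shape")
  expect_error(tie_input(I - 2, I, I, 1e-3), "nonnegative")
})

## ---- Regularization by denoising ----

test_that("the identity denoiser makes the penalty vanish identically", {
  cfg <- red_config(lambda_red = 0.7, denoiser = denoiser_identity())
  set.seed(4)
  phi <- matrix(rnorm(64), 8)
  expect_equal(red_penalty(phi, cfg), 0)
  expect_equal(red_penalty_grad(phi, cfg), matrix(0, 8, 8))
})

test_that("the analytic RED gradient matches finite differences for a
           fixed Gaussian denoiser", {
  cfg <- red_config(lambda_red = 0.3, denoiser = denoiser_gaussian(1.0))
  set.seed(5)
  phi <- matrix(rnorm(64), 8)
  g <- red_penalty_grad(phi, cfg)
  gscale <- max(abs(g))
  eps <- 1e-6
  for (idx in seq_len(64)) {
    pp <- phi; pp[idx] <- pp[idx] + eps
    pm <- phi; pm[idx] <- pm[idx] - eps
    fd <- (red_penalty(pp, cfg) - red_penalty(pm, cfg)) / (2 * eps)
    expect_lt(abs(g[idx] - fd) / gscale, 1e-5)
  }
})

test_that("lambda = 0 reduces RED to the plain reconstruction bit-for-bit", {
  truth <- generate_phantom(phantom_spec(size = 32, seed = 6))
  spec <- default_spec()
  I <- forward_intensity(truth, spec)
  net <- network_spec(n_scales = 2L, base_channels = 4L)
  cfg <- optim_config(epochs = 30L, record_every = 10L, seed = 8)
  plain <- reconstruct(I, spec, net, cfg)
  red0 <- red_reconstruct(I, spec, net, red_config(lambda_red = 0), cfg)
  expect_identical(plain$phase, red0$phase)
  expect_identical(plain$loss_trace, red0$loss_trace)
})

test_that("stronger regularization pulls the output toward denoiser fixed points", {
  truth <- generate_phantom(phantom_spec(size = 32, seed = 7))
  spec <- default_spec()
  I <- forward_intensity(truth, spec)
  net <- network_spec(n_scales = 2L, base_channels = 4L)
  cfg <- optim_config(epochs = 250L, record_every = 50L, seed = 9)
  den <- denoiser_gaussian(2)
  pen <- vapply(c(0.01, 1, 100), function(lam) {
    r <- red_reconstruct(I, spec, net, red_config(lam, den), cfg)
    mean(r$phase * (r$phase - den(r$phase)))   # unweighted roughness energy
  }, 0)
  expect_true(all(diff(pen) <= 1e-8))
})
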