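# Properties of the untrained-network reconstruction engine at small scale
# (32 px scenes, short optimizations): determinism, objective purity, the
# multi-measurement generalization. Full-scale reconstruction quality is
# exercised in test-acceptance.R.

small_scene <- function(seed = 11, size = 32L, peak = 1) {
  truth <- generate_phantom(phantom_spec(size = size, peak_phase = peak,
                                         n_features = 5, seed = seed))
  spec <- default_spec()
  list(truth = truth, spec = spec, I = forward_intensity(truth, spec))
}

small_net <- network_spec(n_scales = 2L, base_channels = 4L)

test_that("input jitter obeys its uniform law and degenerate limit", {
  I <- matrix(runif(64), 8)
  expect_identical(perturb_input(I, 0), I)
  set.seed(1)
  J <- perturb_input(I, 1 / 30)
  expect_true(all(J >= I & J <= I + 1 / 30))
  set.seed(7); d1 <- perturb_input(I, 0.1)
  set.seed(7); d2 <- perturb_input(I, 0.1)
  expect_identical(d1, d2)
  expect_error(perturb_input(I, -1), ">= 0")
})

test_that("reconstruction is bit-reproducible and never reads the ground truth", {
  sc <- small_scene()
  cfg <- optim_config(epochs = 40L, record_every = 20L, seed = 99)
  r1 <- reconstruct(sc$I, sc$spec, small_net, cfg)
  r2 <- reconstruct(sc$I, sc$spec, small_net, cfg)
  expect_identical(r1$phase, r2$phase)
  r3 <- reconstruct(sc$I, sc$spec, small_net, cfg, ground_truth = sc$truth)
  expect_identical(r1$phase, r3$phase)        # objective purity
  expect_null(r1$mse_trace)
  expect_equal(nrow(r3$mse_trace), nrow(r3$loss_trace))
  expect_true(all(r3$loss_trace$loss >= 0))
})

test_that("the optimization actually reduces the data fidelity", {
  sc <- small_scene()
  r <- reconstruct(sc$I, sc$spec, small_net,
                   optim_config(epochs = 600L, record_every = 1L, seed = 2))
  first <- r$loss_trace$loss[1]
  final <- tail(r$loss_trace$loss, 1)
  expect_lt(final, 0.1 * first)
})

test_that("a single-element measurement list reduces exactly to reconstruct", {
  sc <- small_scene()
  cfg <- optim_config(epochs = 30L, record_every = 10L, seed = 5)
  r1 <- reconstruct(sc$I, sc$spec, small_net, cfg)
  rm1 <- reconstruct_multi(list(sc$I), list(sc$spec), small_net, cfg)
  expect_identical(r1$phase, rm1$phase)
  expect_identical(r1$loss_trace, rm1$loss_trace)
})

test_that("duplicating a measurement exactly doubles the first-epoch loss", {
  sc <- small_scene()
  cfg <- optim_config(epochs = 1L, record_every = 1L, seed = 5)
  single <- reconstruct_multi(list(sc$I), list(sc$spec), small_net, cfg)
  double <- reconstruct_multi(list(sc$I, sc$I), list(sc$spec, sc$spec),
                              small_net, cfg)
  expect_equal(double$loss_trace$loss[1], 2 * single$loss_trace$loss[1],
               tolerance = 1e-14)
})

test_that("measurement diversity does not hurt the reconstruction", {
  sc <- small_scene()
  spec2 <- default_spec(20e-3)
  I2 <- forward_intensity(sc$truth, spec2)
  cfg <- optim_config(epochs = 500L, record_every = 100L, seed = 13)
  one <- reconstruct_multi(list(sc$I), list(sc$spec), small_net, cfg,
                           ground_truth = sc$truth)
  two <- reconstruct_multi(list(sc$I, I2), list(sc$spec, spec2), small_net, cfg,
                           ground_truth = sc$truth)
  m1 <- as.numeric(mse(one$phase, sc$truth))
  m2 <- as.numeric(mse(two$phase, sc$truth))
  expect_lte(m2, 1.2 * m1)
})

test_that("shape and length mismatches are rejected", {
  sc <- small_scene()
  expect_error(reconstruct_multi(list(sc$I), list(sc$spec, sc$spec)),
               "propagation specs")
  expect_error(reconstruct_multi(list(sc$I, matrix(1, 8, 8)),
                                 list(sc$spec, sc$spec), small_net),
               "share one shape")
  expect_error(reconstruct(sc$I, sc$spec, network_spec(n_scales = 6L)),
               "divisible")
})

test_that("restart probes select by data fidelity and stay reproducible", {
  sc <- small_scene()
  cfg <- optim_config(epochs = 60L, record_every = 20L, seed = 31,
                      n_restarts = 2L, restart_epochs = 20L)
  r1 <- reconstruct(sc$I, sc$spec, small_net, cfg)
  r2 <- reconstruct(sc$I, sc$spec, small_net, cfg)
  expect_identical(r1$phase, r2$phase)
  expect_length(r1$restart_losses, 2L)
  expect_true(all(is.finite(r1$restart_losses)))
  # ground truth must not influence the selection either
  r3 <- reconstruct(sc$I, sc$spec, small_net, cfg, ground_truth = sc$truth)
  expect_identical(r1$phase, r3$phase)
  expect_error(optim_config(epochs = 100L, n_restarts = 2L, restart_epochs = 100L),
               "restart_epochs")
})

test_that("a non-finite loss aborts with a diagnostic naming the epoch", {
  # the unit-modulus forward model bounds the fidelity for any phase and
  # batch normalization renormalizes arbitrarily scaled weights, so the
  # plain loop cannot blow up on its own; the guard protects against
  # non-finite values entering through a pluggable component
  sc <- small_scene()
  bad_denoiser <- function(phi) phi * NaN
  expect_error(
    red_reconstruct(sc$I, sc$spec, small_net,
                    red_config(lambda_red = 0.1, denoiser = bad_denoiser),
                    optim_config(epochs = 10L, seed = 1)),
    "diverged.*epoch")
})

test_that("the plateau criterion stops early on a converged run", {
  sc <- small_scene()
  r <- reconstruct(sc$I, sc$spec, small_net,
                   optim_config(epochs = 5000L, record_every = 100L, seed = 3,
                                plateau_patience = 50L, plateau_tol = 1e-3))
  expect_lt(r$epochs_run, 5000L)
})
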