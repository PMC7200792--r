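# Untrained-network phase retrieval: a randomly initialized encoder-decoder
# R_theta maps the measured diffraction intensity I to a candidate phase;
# theta is optimized so that the physical forward model applied to that
# phase reproduces I,
#
#     theta* = argmin_theta || H(R_theta(I)) - I ||^2 ,
#
# and the reconstruction is phi = R_theta*(I) after a final noise-free pass.
# The ground-truth phase never enters the objective; the convolutional
# structure of the network is the only prior (deep image prior), and the
# diffraction physics supplies the data constraint.

#' Optimization settings for network-based reconstruction
#'
#' @param learning_rate Adam learning rate (default 0.01).
#' @param epochs Number of optimization steps (default 10000; each step is
#'   one forward/backward pass on the single measurement).
#' @param noise_amplitude Amplitude of the uniform noise added to the fixed
#'   network input at every step (default 1/30, on the unit-mean normalized
#'   intensity scale); jittering the input regularizes the optimization.
#'   The final reconstruction pass uses the clean input.
#' @param seed Master seed; independent streams for parameter
#'   initialization and input noise are derived from it.
#' @param record_every Record the loss (and ground-truth error, when
#'   available) every this many epochs.
#' @param loss_reduction `"mean"` (default) or `"sum"` over pixels.
#' @param plateau_patience,plateau_tol Optional early stop: halt when the
#'   relative loss change over `plateau_patience` epochs falls below
#'   `plateau_tol`. `plateau_patience = 0` (default) disables it and the
#'   full epoch budget is used.
#' @param n_restarts Number of independent initializations probed before the
#'   main run (default 1 = none). With more than one, each candidate is
#'   optimized for `restart_epochs` steps and the one with the lowest
#'   data-fidelity loss (averaged over its last 50 probe epochs) continues
#'   for the remaining budget. The non-convex optimization occasionally
#'   stalls in a flat-phase local minimum whose fidelity stays orders of
#'   magnitude above a converging run, so the probe loss identifies it
#'   reliably — and uses no ground truth.
#' @param restart_epochs Probe length per candidate when `n_restarts > 1`.
#' @return An object of class `"optim_config"`.
#' @export
optim_config <- function(learning_rate = 0.01, epochs = 10000L,
                         noise_amplitude = 1 / 30, seed = 1L,
                         record_every = 50L, loss_reduction = "mean",
                         plateau_patience = 0L, plateau_tol = 1e-6,
                         n_restarts = 1L, restart_epochs = 500L) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("`epochs` must be >= 1")
  if (noise_amplitude < 0) stop("`noise_amplitude` must be >= 0")
  loss_reduction <- match.arg(loss_reduction, c("mean", "sum"))
  n_restarts <- as.integer(n_restarts)
  restart_epochs <- as.integer(restart_epochs)
  if (is.na(n_restarts) || n_restarts < 1L) stop("`n_restarts` must be >= 1")
  if (n_restarts > 1L && restart_epochs >= epochs)
    stop("`restart_epochs` must be smaller than `epochs`")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 noise_amplitude = noise_amplitude, optimizer = "adam",
                 seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 loss_reduction = loss_reduction,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_tol = plateau_tol,
                 n_restarts = n_restarts, restart_epochs = restart_epochs),
            class = "optim_config")
}

#' Jitter a network input with uniform noise
#'
#' Adds an i.i.d. draw from `U[0, amplitude]` to every pixel; a fresh draw
#' is taken from the current RNG stream on each call.
#'
#' @param intensity Numeric matrix.
#' @param amplitude Upper bound of the uniform noise (>= 0).
#' @return Matrix of the same shape.
#' @export
perturb_input <- function(intensity, amplitude) {
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (amplitude == 0) return(intensity)
  intensity + matrix(stats::runif(length(intensity), 0, amplitude),
                     nrow(intensity))
}

#' Reconstruct a phase map from a single diffraction pattern
#'
#' Optimizes a randomly initialized encoder-decoder against the measured
#' intensity through the differentiable angular-spectrum forward model.
#' Two normalizations are applied: the fidelity compares predictions with
#' the measurement divided by its mean (the scale on which the forward
#' model of a unit-amplitude object lives), while the network input is the
#' measurement min-max scaled to `[0, 1]` (the image scale on which the
#' default 1/30 input jitter is a small perturbation). After the last
#' epoch a clean (noise-free) forward pass produces the returned phase.
#'
#' @param intensity Measured/simulated diffraction intensity (nonnegative
#'   matrix).
#' @param spec A [propagation_spec()] describing the acquisition geometry.
#' @param network A [network_spec()]; the image side length must be
#'   divisible by `2^n_scales`.
#' @param config An [optim_config()].
#' @param ground_truth Optional true phase map: if supplied, a rescaled-MSE
#'   trace against it is recorded for diagnostics. It never influences the
#'   optimization (the result is bit-identical with or without it).
#' @param verbose Print progress every `record_every` epochs.
#' @return A `"reconstruction_result"`: `phase` (matrix, radians),
#'   `loss_trace` (data.frame `epoch, loss`), `mse_trace` (or `NULL`),
#'   `network_spec`, `optim_config`, `prop_spec`, `seed`, `epochs_run`.
#' @seealso [reconstruct_multi()] for several measurement planes,
#'   [gs_retrieve()], [tie_solve()], [red_reconstruct()] for the classical
#'   baselines.
#' @export
reconstruct <- function(intensity, spec, network = network_spec(),
                        config = optim_config(), ground_truth = NULL,
                        verbose = FALSE) {
  .pr_engine(list(intensity), list(spec), network, config,
             ground_truth = ground_truth, red = NULL, verbose = verbose)
}

#' Reconstruct a phase map from measurements at several distances
#'
#' Generalizes [reconstruct()] to a set of diffraction patterns of the same
#' object recorded at different distances: the objective becomes the sum of
#' the per-plane fidelities `sum_i || H_i(R_theta(I_1)) - I_i ||^2`. The
#' first measurement in the list is the fixed network input. With a single
#' measurement this reduces exactly to [reconstruct()].
#'
#' @param intensities List of nonnegative matrices, all the same shape.
#' @param specs List of [propagation_spec()], one per measurement.
#' @inheritParams reconstruct
#' @return A `"reconstruction_result"` (see [reconstruct()]).
#' @export
reconstruct_multi <- function(intensities, specs, network = network_spec(),
                              config = optim_config(), ground_truth = NULL,
                              verbose = FALSE) {
  .pr_engine(intensities, specs, network, config,
             ground_truth = ground_truth, red = NULL, verbose = verbose)
}

# Shared optimization engine; `red` (NULL or list(lambda, denoiser)) adds the
# regularization-by-denoising penalty used by red_reconstruct().
.pr_engine <- function(intensities, specs, network, config, ground_truth,
                       red, verbose = FALSE) {
  if (!is.list(intensities) || length(intensities) < 1L)
    stop("need at least one intensity image")
  if (length(intensities) != length(specs))
    stop(sprintf("%d intensity images but %d propagation specs",
                 length(intensities), length(specs)))
  intensities <- lapply(intensities, as_intensity_image)
  shp <- dim(intensities[[1]])
  for (I in intensities)
    if (!identical(dim(I), shp)) stop("all intensity images must share one shape")
  for (s in specs)
    if (!inherits(s, "propagation_spec")) stop("`specs` must hold propagation_spec objects")
  if (!is.null(ground_truth)) ground_truth <- as_phase_map(ground_truth)

  # fidelity targets: unit-mean normalization (the forward model of a
  # unit-amplitude object produces unit-mean intensity exactly)
  Inorm <- lapply(intensities, function(I) {
    m <- mean(I)
    if (m <= 0) stop("intensity image has nonpositive mean")
    I / m
  })
  # network input: the reference measurement on the [0, 1] image scale, so
  # the default 1/30 input jitter is a small perturbation of the signal
  x0 <- rescale_range(intensities[[1]], 0, 1)
  npix <- prod(shp)
  scale_g <- if (config$loss_reduction == "mean") 1 / npix else 1
  n_cand <- config$n_restarts
  seeds <- derive_seeds(config$seed, 2L * n_cand)

  # preserve the caller's RNG state; candidate streams are managed below
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old_rng <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old_rng, envir = globalenv()))

  new_candidate <- function(k) {
    net <- build_network(network, shp, seed = seeds[2L * k - 1L])
    set.seed(seeds[2L * k])
    list(net = net, state = adam_init(net$layers), t = 0L,
         rng = get(".Random.seed", envir = globalenv()),
         tr_epoch = integer(0), tr_loss = numeric(0), tr_mse = numeric(0),
         recent = numeric(0), stopped = FALSE, diverged = FALSE,
         loss_window = numeric(0))
  }

  # advance a candidate by up to `n` epochs; during probes (`probe = TRUE`)
  # divergence marks the candidate instead of aborting
  run_epochs <- function(cand, n, probe = FALSE) {
    assign(".Random.seed", cand$rng, envir = globalenv())
    net <- cand$net; state <- cand$state
    for (s in seq_len(n)) {
      t <- cand$t + s
      x <- perturb_input(x0, config$noise_amplitude)
      fw <- net_forward(net, x)
      phi <- fw$phi
      loss <- 0
      gphi <- matrix(0, shp[1], shp[2])
      for (j in seq_along(Inorm)) {
        fg <- forward_intensity_grad(phi, specs[[j]])
        resid <- fg$intensity - Inorm[[j]]
        loss <- loss + sum(resid^2) * scale_g
        gphi <- gphi + fg$backward(2 * resid * scale_g)
      }
      if (!is.null(red) && red$lambda > 0) {
        dphi <- red$denoiser(phi)
        loss <- loss + red$lambda / 2 * sum(phi * (phi - dphi)) * scale_g
        gphi <- gphi + red$lambda * (phi - dphi) * scale_g
      }
      if (!is.finite(loss)) {
        if (probe) { cand$diverged <- TRUE; break }
        stop(sprintf(paste0("optimization diverged: non-finite loss at epoch %d ",
                            "(learning rate %.3g); reduce the learning rate"),
                     t, config$learning_rate))
      }
      grads <- net_backward(net, fw, gphi)
      up <- adam_step(net$layers, grads, state, config$learning_rate, t)
      net$layers <- up$layers
      state <- up$state
      cand$recent <- c(utils::tail(cand$recent, 49L), loss)
      if (t == 1L || t %% config$record_every == 0L) {
        cand$tr_epoch <- c(cand$tr_epoch, t)
        cand$tr_loss <- c(cand$tr_loss, loss)
        if (!is.null(ground_truth))
          cand$tr_mse <- c(cand$tr_mse, mse(phi, ground_truth, rescale = TRUE))
        if (verbose)
          message(sprintf("epoch %6d  loss %.4e", t, loss))
      }
      if (config$plateau_patience > 0L && !probe) {
        cand$loss_window <- c(cand$loss_window, loss)
        if (length(cand$loss_window) > config$plateau_patience)
          cand$loss_window <- cand$loss_window[-1L]
        if (length(cand$loss_window) == config$plateau_patience) {
          rel <- abs(cand$loss_window[1] - loss) /
            max(cand$loss_window[1], .Machine$double.eps)
          if (rel < config$plateau_tol) {
            cand$t <- t; cand$stopped <- TRUE
            break
          }
        }
      }
      if (s == n) cand$t <- t
    }
    cand$net <- net; cand$state <- state
    cand$rng <- get(".Random.seed", envir = globalenv())
    cand
  }

  restart_losses <- NULL
  if (n_cand == 1L) {
    best <- run_epochs(new_candidate(1L), config$epochs)
  } else {
    cands <- lapply(seq_len(n_cand), function(k)
      run_epochs(new_candidate(k), config$restart_epochs, probe = TRUE))
    restart_losses <- vapply(cands, function(cd)
      if (cd$diverged) Inf else mean(cd$recent), 0)
    if (all(!is.finite(restart_losses)))
      stop("all restart probes diverged; reduce the learning rate")
    pick <- which.min(restart_losses)
    if (verbose)
      message(sprintf("restart probes: %s -> continuing #%d",
                      paste(sprintf("%.3e", restart_losses), collapse = ", "), pick))
    best <- run_epochs(cands[[pick]], config$epochs - config$restart_epochs)
  }

  fw <- net_forward(best$net, x0)   # clean pass, input noise removed
  res <- list(phase = fw$phi,
              loss_trace = data.frame(epoch = best$tr_epoch, loss = best$tr_loss),
              mse_trace = if (is.null(ground_truth)) NULL
                          else data.frame(epoch = best$tr_epoch, mse = best$tr_mse),
              network_spec = network, optim_config = config,
              prop_spec = specs, seed = config$seed, epochs_run = best$t,
              restart_losses = restart_losses)
  class(res) <- "reconstruction_result"
  res
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("reconstruction_result: %d x %d phase map, %d epochs, final loss %.4e\n",
              nrow(x$phase), ncol(x$phase), x$epochs_run,
              utils::tail(x$loss_trace$loss, 1)))
  if (!is.null(x$mse_trace))
    cat(sprintf("  final rescaled MSE vs ground truth: %.4g rad\n",
                utils::tail(x$mse_trace$mse, 1)))
  invisible(x)
}

#' Running-median smoothing of a loss trace
#'
#' Convergence monitoring helper: a centered running median over a window of
#' epochs, robust to the step-to-step jitter that the noisy input injects.
#'
#' @param trace Data frame with columns `epoch` and `loss` (or `mse`).
#' @param window Window width in recorded samples (odd; default 21).
#' @return The trace with an added `smoothed` column.
#' @export
smooth_trace <- function(trace, window = 21L) {
  y <- trace[[ncol(trace)]]
  window <- min(as.integer(window), length(y))
  if (window %% 2L == 0L) window <- window - 1L
  if (window < 1L) window <- 1L
  sm <- stats::runmed(y, window, endrule = "median")
  trace$smoothed <- as.numeric(sm)
  trace
}
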