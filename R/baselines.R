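# Classical phase-retrieval baselines: multi-plane Gerchberg-Saxton
# alternating projections, a spectral transport-of-intensity solver, and
# regularization by denoising layered on the network engine.

## ---- Gerchberg-Saxton ----

#' Configuration for Gerchberg-Saxton phase retrieval
#'
#' @param planes List of measurement planes, each a list with elements
#'   `intensity` (nonnegative matrix) and `distance` (meters). At least one.
#' @param n_iterations Number of full cycles through all planes (>= 1).
#' @param init_phase `"zeros"` (deterministic default) or `"random"`.
#' @param seed Seed for the random initialization.
#' @return An object of class `"gs_config"`.
#' @export
gs_config <- function(planes, n_iterations = 200L, init_phase = "zeros",
                      seed = 1L) {
  if (!is.list(planes) || length(planes) < 1L) stop("need at least one plane")
  for (p in planes) {
    if (is.null(p$intensity) || is.null(p$distance))
      stop("each plane needs `intensity` and `distance`")
    as_intensity_image(p$intensity)
  }
  d <- vapply(planes, function(p) p$distance, 0)
  if (anyDuplicated(d)) stop("plane distances must be distinct")
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L) stop("`n_iterations` must be >= 1")
  init_phase <- match.arg(init_phase, c("zeros", "random"))
  structure(list(planes = planes[order(d)], n_iterations = n_iterations,
                 init_phase = init_phase, seed = as.integer(seed)),
            class = "gs_config")
}

#' Multi-plane Gerchberg-Saxton phase retrieval
#'
#' Alternating projections with the phase-only constraint on the object
#' plane: in every cycle, for each measurement plane in ascending distance,
#' the current unit-modulus object field is propagated to the plane, its
#' modulus is replaced by the square root of the measured intensity (phase
#' kept), and the field is propagated back, where the unit-modulus
#' constraint is re-imposed. The object-plane phase after the final cycle
#' is returned with its mean subtracted (the iteration has a free global
#' offset).
#'
#' @param config A [gs_config()].
#' @param spec A [propagation_spec()] providing wavelength and pitch (its
#'   `distance` is ignored; the planes carry their own).
#' @return Phase matrix (radians, zero mean) with attribute
#'   `plane_error`: per-cycle root-mean-square modulus mismatch
#'   `sqrt(mean((sqrt(I_model) - sqrt(I_meas))^2))` at the first plane,
#'   useful for monitoring (it is non-increasing for single-plane
#'   error reduction).
#' @export
gs_retrieve <- function(config, spec) {
  if (!inherits(config, "gs_config")) stop("`config` must be a gs_config")
  planes <- config$planes
  amps <- lapply(planes, function(p) sqrt(as_intensity_image(p$intensity)))
  shp <- dim(amps[[1]])
  phi <- if (config$init_phase == "zeros") matrix(0, shp[1], shp[2])
         else with_seed(config$seed,
                        matrix(stats::runif(prod(shp), -pi, pi), shp[1]))
  err <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    for (j in seq_along(planes)) {
      U0 <- complex_field(exp(1i * phi), spec$pitch, spec$wavelength)
      Ud <- propagate(U0, planes[[j]]$distance, spec$pad_factor)
      if (j == 1L)
        err[it] <- sqrt(mean((Mod(Ud$values) - amps[[j]])^2))
      Ud$values <- amps[[j]] * exp(1i * Arg(Ud$values))
      Ub <- propagate(Ud, -planes[[j]]$distance, spec$pad_factor)
      phi <- Arg(Ub$values)   # phase-only constraint: modulus back to 1
    }
  }
  out <- phi - mean(phi)
  attr(out, "plane_error") <- err
  out
}

## ---- Transport of intensity ----

#' Inputs for the transport-of-intensity solver
#'
#' @param I_minus,I_0,I_plus Intensities recorded at distances
#'   `d - delta_z`, `d`, `d + delta_z` (nonnegative matrices of one shape).
#' @param delta_z Axial separation in meters (> 0).
#' @param regularization_eps Relative Tikhonov floor for the singular DC
#'   division in the spectral Poisson inverse (default `1e-9`, times the
#'   maximum squared frequency).
#' @return An object of class `"tie_input"`.
#' @export
tie_input <- function(I_minus, I_0, I_plus, delta_z,
                      regularization_eps = 1e-9) {
  I_minus <- as_intensity_image(I_minus)
  I_0 <- as_intensity_image(I_0)
  I_plus <- as_intensity_image(I_plus)
  if (!identical(dim(I_minus), dim(I_0)) || !identical(dim(I_plus), dim(I_0)))
    stop("the three intensity images must share one shape")
  if (!is.numeric(delta_z) || delta_z <= 0) stop("`delta_z` must be > 0")
  if (regularization_eps <= 0) stop("`regularization_eps` must be > 0")
  structure(list(I_minus = I_minus, I_0 = I_0, I_plus = I_plus,
                 delta_z = delta_z, regularization_eps = regularization_eps),
            class = "tie_input")
}

#' Transport-of-intensity phase recovery
#'
#' Solves `-k dI/dz = div(I grad(phi))` for the phase from a
#' central-difference estimate of the axial intensity derivative,
#' `(I_plus - I_minus) / (2 delta_z)`, using FFT-based Poisson inversion
#' with Tikhonov regularization of the singular DC division. Two modes:
#'
#' * `"uniform"` (default): the illumination is taken as uniform with level
#'   `mean(I_0)`, reducing the equation to a single Poisson solve
#'   `lap(phi) = -k (dI/dz) / I0bar` -- appropriate for the phase-only,
#'   near-unit-intensity objects this package targets;
#' * `"full"`: the variable-intensity form via the auxiliary-potential
#'   two-step (solve for `psi` with `lap(psi) = -k dI/dz`, divide
#'   `grad(psi)` by `I_0`, take the divergence, solve again).
#'
#' @param input A [tie_input()].
#' @param spec A [propagation_spec()] (wavelength and pitch; distances are
#'   carried by the inputs).
#' @param mode `"uniform"` or `"full"`.
#' @return Phase matrix (radians); the DC component is set to zero (piston
#'   is unobservable).
#' @export
tie_solve <- function(input, spec, mode = "uniform") {
  if (!inherits(input, "tie_input")) stop("`input` must be a tie_input")
  mode <- match.arg(mode, c("uniform", "full"))
  k <- 2 * pi / spec$wavelength
  dIdz <- (input$I_plus - input$I_minus) / (2 * input$delta_z)
  rhs <- -k * dIdz
  if (mode == "uniform") {
    I0bar <- mean(input$I_0)
    if (I0bar <= 0) stop("mean illumination must be > 0")
    return(.inv_laplacian(rhs / I0bar, spec$pitch, input$regularization_eps))
  }
  psi <- .inv_laplacian(rhs, spec$pitch, input$regularization_eps)
  g <- .spectral_gradient(psi, spec$pitch)
  I0 <- pmax(input$I_0, 1e-6 * mean(input$I_0))  # guard divisions
  dvg <- .spectral_divergence(g$gx / I0, g$gy / I0, spec$pitch)
  .inv_laplacian(dvg, spec$pitch, input$regularization_eps)
}

# FFT Poisson inverse: solve lap(phi) = rhs on the periodic domain.
# In the DFT domain lap -> -q^2 with q^2 = 4 pi^2 (fx^2 + fy^2); the DC
# division is regularized and the DC output pinned to zero.
.inv_laplacian <- function(rhs, pitch, rel_eps) {
  n1 <- nrow(rhs); n2 <- ncol(rhs)
  fv <- function(n) {
    kk <- 0:(n - 1L)
    ifelse(kk < (n + 1L) %/% 2L, kk, kk - n) / (n * pitch)
  }
  fx <- matrix(fv(n1), n1, n2)
  fy <- matrix(fv(n2), n1, n2, byrow = TRUE)
  q2 <- 4 * pi^2 * (fx^2 + fy^2)
  eps <- rel_eps * max(q2)
  R <- stats::fft(rhs)
  P <- -R / (q2 + eps)
  P[1, 1] <- 0 + 0i
  Re(stats::fft(P, inverse = TRUE)) / (n1 * n2)
}

.spectral_gradient <- function(x, pitch) {
  n1 <- nrow(x); n2 <- ncol(x)
  fv <- function(n) {
    kk <- 0:(n - 1L)
    ifelse(kk < (n + 1L) %/% 2L, kk, kk - n) / (n * pitch)
  }
  X <- stats::fft(x)
  fx <- matrix(fv(n1), n1, n2)
  fy <- matrix(fv(n2), n1, n2, byrow = TRUE)
  list(gx = Re(stats::fft(2i * pi * fx * X, inverse = TRUE)) / (n1 * n2),
       gy = Re(stats::fft(2i * pi * fy * X, inverse = TRUE)) / (n1 * n2))
}

.spectral_divergence <- function(gx, gy, pitch) {
  n1 <- nrow(gx); n2 <- ncol(gx)
  fv <- function(n) {
    kk <- 0:(n - 1L)
    ifelse(kk < (n + 1L) %/% 2L, kk, kk - n) / (n * pitch)
  }
  fx <- matrix(fv(n1), n1, n2)
  fy <- matrix(fv(n2), n1, n2, byrow = TRUE)
  Re(stats::fft(2i * pi * fx * stats::fft(gx) +
                2i * pi * fy * stats::fft(gy), inverse = TRUE)) / (n1 * n2)
}

## ---- Regularization by denoising ----

#' Built-in denoisers for regularization by denoising
#'
#' Pluggable mappings from a phase map to a denoised phase map:
#' `denoiser_identity()` returns its input (zero penalty everywhere),
#' `denoiser_gaussian(sigma)` is circular convolution with an isotropic
#' Gaussian of standard deviation `sigma` pixels (a fixed linear symmetric
#' operator, handy for gradient checks), and `denoiser_tv(weight, n_steps)`
#' performs `n_steps` explicit descent steps on a smoothed total-variation
#' energy (edge-preserving).
#'
#' @param sigma Gaussian width in pixels.
#' @param weight Step size of the TV descent.
#' @param n_steps Number of TV descent steps.
#' @param eps Smoothing floor inside the TV norm.
#' @return A function `phase matrix -> phase matrix`.
#' @name denoisers
NULL

#' @rdname denoisers
#' @export
denoiser_identity <- function() function(phi) phi

#' @rdname denoisers
#' @export
denoiser_gaussian <- function(sigma = 1.5) {
  force(sigma)
  function(phi) {
    n1 <- nrow(phi); n2 <- ncol(phi)
    fv <- function(n) {
      kk <- 0:(n - 1L)
      ifelse(kk < (n + 1L) %/% 2L, kk, kk - n) / n
    }
    fx <- matrix(fv(n1), n1, n2)
    fy <- matrix(fv(n2), n1, n2, byrow = TRUE)
    Hk <- exp(-2 * pi^2 * sigma^2 * (fx^2 + fy^2))
    Re(stats::fft(stats::fft(phi) * Hk, inverse = TRUE)) / (n1 * n2)
  }
}

#' @rdname denoisers
#' @export
denoiser_tv <- function(weight = 0.1, n_steps = 10L, eps = 1e-6) {
  force(weight); force(n_steps); force(eps)
  function(phi) {
    u <- phi
    for (s in seq_len(n_steps)) {
      dx <- u[c(2:nrow(u), 1), ] - u
      dy <- u[, c(2:ncol(u), 1)] - u
      mag <- sqrt(dx^2 + dy^2 + eps)
      px <- dx / mag; py <- dy / mag
      div <- px - px[c(nrow(u), 1:(nrow(u) - 1)), ] +
             py - py[, c(ncol(u), 1:(ncol(u) - 1))]
      u <- u + weight * div
    }
    u
  }
}

#' Configuration for regularization by denoising
#'
#' @param lambda_red Regularization strength (>= 0); 0 recovers the plain
#'   untrained-network reconstruction exactly.
#' @param denoiser A denoiser function (see [denoisers]); default Gaussian.
#' @return An object of class `"red_config"`.
#' @export
red_config <- function(lambda_red = 0.05, denoiser = denoiser_gaussian()) {
  if (!is.numeric(lambda_red) || lambda_red < 0) stop("`lambda_red` must be >= 0")
  if (!is.function(denoiser)) stop("`denoiser` must be a function")
  structure(list(lambda_red = lambda_red, denoiser = denoiser),
            class = "red_config")
}

#' RED penalty value
#'
#' The regularization-by-denoising energy
#' `lambda/2 * mean(phi * (phi - D(phi)))` on the per-pixel (mean) scale
#' used by the optimization engine.
#'
#' @param phi Phase matrix.
#' @param config A [red_config()].
#' @return Scalar penalty.
#' @export
red_penalty <- function(phi, config) {
  d <- config$denoiser(phi)
  config$lambda_red / 2 * mean(phi * (phi - d))
}

#' RED penalty gradient
#'
#' `lambda * (phi - D(phi)) / npix`, exact for fixed linear symmetric
#' denoisers and the standard surrogate gradient otherwise.
#'
#' @inheritParams red_penalty
#' @return Matrix gradient of [red_penalty()] with respect to `phi`.
#' @export
red_penalty_grad <- function(phi, config) {
  config$lambda_red * (phi - config$denoiser(phi)) / length(phi)
}

#' Untrained-network reconstruction with a denoiser prior
#'
#' Minimizes the data fidelity of [reconstruct()] plus the
#' regularization-by-denoising penalty
#' `lambda/2 * phi^T (phi - D(phi))` with `phi = R_theta(I)`, using the same
#' Adam loop. With `lambda_red = 0` the result is bit-identical to
#' [reconstruct()] under equal seeds.
#'
#' @inheritParams reconstruct
#' @param config A [red_config()].
#' @param optim An [optim_config()].
#' @return A `"reconstruction_result"` (see [reconstruct()]).
#' @export
red_reconstruct <- function(intensity, spec, network = network_spec(),
                            config = red_config(), optim = optim_config(),
                            ground_truth = NULL, verbose = FALSE) {
  if (!inherits(config, "red_config")) stop("`config` must be a red_config")
  red <- if (config$lambda_red > 0)
    list(lambda = config$lambda_red, denoiser = config$denoiser) else NULL
  .pr_engine(list(intensity), list(spec), network, optim,
             ground_truth = ground_truth, red = red, verbose = verbose)
}
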