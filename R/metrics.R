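# Evaluation protocol: intensity-only measurements are blind to a global
# phase offset (piston) and, in symmetric configurations, to complex
# conjugation (the twin image). Reconstruction quality is therefore scored
# after an affine min-max rescale of the reconstruction onto the range of
# the ground truth, taking the better of the direct and sign-flipped
# branches; the score is the pixelwise mean square error, reported in "rad"
# following the field's convention for phase maps.

#' Affine-rescale a phase map onto the range of a reference
#'
#' Maps `x` linearly so that its minimum and maximum coincide with those of
#' `ref`, removing the piston (offset) and gain ambiguities before
#' comparison.
#'
#' @param x Phase map (numeric matrix) to rescale.
#' @param ref Reference phase map.
#' @return A list: `values` (rescaled matrix), `gain`, `offset` (such that
#'   `values = gain * x + offset`) and `degenerate` (`TRUE` when `x` is
#'   constant but `ref` is not, in which case `values` is filled with
#'   `min(ref)` and a warning is raised; no affine map can recover range
#'   from a constant).
#' @export
rescale_to_reference <- function(x, ref) {
  x <- as_phase_map(x); ref <- as_phase_map(ref)
  rx <- range(x); rr <- range(ref)
  if (rr[2] - rr[1] <= 0) {
    # constant reference: offset-only match
    return(list(values = x - mean(x) + rr[1], gain = 1,
                offset = rr[1] - mean(x), degenerate = FALSE))
  }
  if (rx[2] - rx[1] <= 0) {
    warning("constant input cannot be rescaled to a non-constant reference")
    return(list(values = matrix(rr[1], nrow(x), ncol(x)), gain = 0,
                offset = rr[1], degenerate = TRUE))
  }
  gain <- (rr[2] - rr[1]) / (rx[2] - rx[1])
  offset <- rr[1] - gain * rx[1]
  list(values = gain * x + offset, gain = gain, offset = offset,
       degenerate = FALSE)
}

#' Mean square error between two phase maps
#'
#' With `rescale = TRUE` (the reconstruction-scoring mode) the first
#' argument is min-max rescaled onto the range of the second, both directly
#' and with its sign flipped (the conjugate-twin branch), and the smaller
#' error is returned with attribute `negated` marking which branch won.
#' With `rescale = FALSE` it is the plain pixelwise mean of squared
#' differences (and the only symmetric mode).
#'
#' @param a Phase map under evaluation (numeric matrix).
#' @param b Reference phase map, same shape.
#' @param rescale Apply the affine range matching first (default `TRUE`).
#' @return Nonnegative scalar; with `rescale = TRUE` it carries a logical
#'   attribute `negated`.
#' @export
mse <- function(a, b, rescale = TRUE) {
  a <- as_phase_map(a); b <- as_phase_map(b)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %d x %d vs %d x %d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  if (!rescale) return(mean((a - b)^2))
  direct <- suppressWarnings(rescale_to_reference(a, b))
  flipped <- suppressWarnings(rescale_to_reference(-a, b))
  e_direct <- mean((direct$values - b)^2)
  e_flipped <- mean((flipped$values - b)^2)
  out <- min(e_direct, e_flipped)
  attr(out, "negated") <- e_flipped < e_direct
  out
}

#' Full evaluation report for a reconstruction
#'
#' @param recon Reconstructed phase map.
#' @param truth Ground-truth phase map.
#' @param method Label recorded in the report.
#' @param scene Optional scene descriptor (free-form list or string).
#' @return A list of class `"evaluation_report"`: `mse` (rescaled, twin
#'   handled), `rescale_gain`, `rescale_offset`, `negated`, `method`,
#'   `scene`.
#' @export
evaluate_phase <- function(recon, truth, method = "unknown", scene = NULL) {
  m <- mse(recon, truth, rescale = TRUE)
  neg <- isTRUE(attr(m, "negated"))
  sc <- suppressWarnings(rescale_to_reference(if (neg) -recon else recon, truth))
  structure(list(mse = as.numeric(m), rescale_gain = sc$gain,
                 rescale_offset = sc$offset, negated = neg,
                 method = method, scene = scene),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report [%s]: rescaled MSE = %.4g rad%s\n",
              x$method, x$mse, if (x$negated) " (sign-flipped branch)" else ""))
  invisible(x)
}
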