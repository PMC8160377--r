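## Intrafractional motion: the dose matrix is blurred with an anisotropic
## Gaussian kernel while the structure masks stay fixed. Convolution is the
## expectation of the delivered dose over random Gaussian displacements of
## the target relative to the dose matrix.

## 1D blur operator as an n x n matrix with replicate-edge padding:
## row i holds the (renormalised, truncated) kernel weights, with weight
## falling outside [1, n] accumulated onto the clamped boundary index.
.blurMatrix1d <- function(n, sigmaVox, truncation) {
  if (sigmaVox <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(truncation * sigmaVox)))
  w <- stats::dnorm(-r:r, sd = sigmaVox)
  w <- w / sum(w)
  M <- matrix(0, n, n)
  for (t in seq_along(w)) {
    j <- pmin(pmax(seq_len(n) + (t - r - 1L), 1L), n)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + w[t]
  }
  M
}

## apply a matrix along one axis of a 3D array
.applyAlongAxis <- function(a, M, axis) {
  d <- dim(a)
  if (axis == 1L) {
    array(M %*% matrix(a, d[1]), d)
  } else if (axis == 2L) {
    p <- aperm(a, c(2L, 1L, 3L))
    aperm(array(M %*% matrix(p, d[2]), dim(p)), c(2L, 1L, 3L))
  } else {
    p <- aperm(a, c(3L, 1L, 2L))
    aperm(array(M %*% matrix(p, d[3]), dim(p)), c(2L, 3L, 1L))
  }
}

#' Blur a dose grid with a Gaussian motion kernel
#'
#' Separable discrete Gaussian convolution of the dose values. The kernel
#' standard deviations (mm) are converted to voxels per axis, truncated at
#' `truncation` sigma and renormalised to unit sum; edges use replicate
#' padding so no dose is artificially lost at the grid border. Geometry and
#' fraction count are unchanged; a zero sigma on an axis leaves that axis
#' untouched.
#'
#' An alternative `"sample"` mode draws one random rigid displacement per
#' fraction from the same Gaussian (rounded to whole voxels) and averages
#' the shifted dose matrices — the finite-fraction reading of the same
#' motion model.
#'
#' @param dose A [DoseGrid-class].
#' @param kernel A [MotionKernel-class].
#' @param mode `"convolve"` (default, expectation over displacements) or
#'   `"sample"`.
#' @param seed Integer seed for `"sample"` mode.
#' @return A blurred [DoseGrid-class].
#' @export
blurDose <- function(dose, kernel, mode = c("convolve", "sample"),
                     seed = NULL) {
  mode <- match.arg(mode)
  sigmaVox <- kernel@sigma / dose@spacing
  v <- dose@values
  d <- dim(v)
  if (mode == "convolve") {
    for (ax in 1:3) {
      if (sigmaVox[ax] > 0)
        v <- .applyAlongAxis(v, .blurMatrix1d(d[ax], sigmaVox[ax],
                                              kernel@truncation), ax)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    n <- nFractions(dose)
    acc <- array(0, d)
    for (f in seq_len(n)) {
      sh <- round(stats::rnorm(3, sd = sigmaVox))
      acc <- acc + .shiftReplicate(dose@values, sh)
    }
    v <- acc / n
  }
  doseGrid(pmax(v, 0), spacing = dose@spacing, origin = dose@origin,
           nFractions = dose@nFractions)
}

## rigid integer shift with replicate padding
.shiftReplicate <- function(a, sh) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) pmin(pmax(seq_len(d[k]) - sh[k], 1L), d[k]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Evaluate a plan case with and without intrafractional motion
#'
#' Runs the full radiobiological evaluation (see [evaluateCase()]) twice —
#' on the original dose and on the motion-blurred dose — against the same,
#' fixed structure masks.
#'
#' @param case A [PlanCase-class].
#' @param kernel A [MotionKernel-class].
#' @param params A [RadiobioParams-class].
#' @param constraints Optional constraint table (see [defaultConstraints()]).
#' @return `data.frame` of two outcome records, `motion = FALSE` then
#'   `TRUE`.
#' @export
evaluateWithMotion <- function(case, kernel, params = defaultRadiobioParams(),
                               constraints = defaultConstraints()) {
  evaluateCase(case, params, kernel = kernel, constraints = constraints)
}
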