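## Isoeffect conversion and the three dose-response models.
##
## TCP: linear-quadratic Poisson model on EQD0 voxel doses,
##   TCP = prod_i exp(-rho * v_i * exp(-alpha * EQD0_i)).
## NTCP urethra: Lyman-Kutcher-Burman probit in gEUD of EQD2 voxel doses.
## NTCP bladder/rectum: relative seriality (Kallman Poisson form) on EQD2.

#' Isoeffective dose at a reference fraction size (EQDx)
#'
#' Converts a total dose `D` delivered in fractions of size `d` to the
#' isoeffective total dose at reference fraction size `x` under the
#' linear-quadratic model:
#' \deqn{EQDx = D \frac{1 + d/(\alpha/\beta)}{1 + x/(\alpha/\beta)}.}
#' `x = 0` gives the biologically effective dose BED = D (1 + d/(a/b));
#' `x = 2` gives EQD2.
#'
#' @param totalDose Total physical dose D in Gy (vectorised).
#' @param dosePerFraction Dose per fraction d in Gy (vectorised).
#' @param abRatio Tissue alpha/beta ratio in Gy, > 0.
#' @param referenceFractionSize Reference fraction size x in Gy, >= 0
#'   (default 0).
#' @return Isoeffective dose in Gy, same length as the inputs.
#' @examples
#' eqd(60, 3, abRatio = 1.6)                            # 172.5 Gy (EQD0)
#' eqd(70, 3.5, abRatio = 1.6, referenceFractionSize = 2) # ~99.2 Gy (EQD2)
#' @export
eqd <- function(totalDose, dosePerFraction, abRatio,
                referenceFractionSize = 0) {
  if (!is.finite(abRatio) || abRatio <= 0)
    stop("'abRatio' must be a positive number of Gy", call. = FALSE)
  if (any(totalDose < 0) || any(dosePerFraction < 0) ||
      referenceFractionSize < 0)
    stop("doses must be non-negative", call. = FALSE)
  totalDose * (1 + dosePerFraction / abRatio) /
    (1 + referenceFractionSize / abRatio)
}

#' Voxelwise isoeffect conversion of a dose grid
#'
#' Applies [eqd()] per voxel with d_i = D_i / N, N the grid's fraction
#' count. Geometry and fraction count are unchanged; only the voxel values
#' are re-expressed on the EQDx scale.
#'
#' @param dose A [DoseGrid-class] of total physical dose.
#' @param abRatio Tissue alpha/beta (Gy).
#' @param referenceFractionSize Reference fraction size x (Gy), default 0.
#' @return A [DoseGrid-class] of EQDx values.
#' @export
voxelEQD <- function(dose, abRatio, referenceFractionSize = 0) {
  n <- nFractions(dose)
  if (n < 1L) stop("dose grid has no fraction count", call. = FALSE)
  v <- dose@values
  out <- eqd(v, v / n, abRatio, referenceFractionSize)
  doseGrid(out, spacing = dose@spacing, origin = dose@origin, nFractions = n)
}

#' Poisson linear-quadratic tumour control probability
#'
#' Voxelised LQ-Poisson TCP over a target mask:
#' \deqn{TCP = \prod_i \exp(-\rho\, v_i\, e^{-\alpha\, EQD0_i})}
#' with clonogen density rho (cells/cm^3), voxel volume v_i (cm^3) and the
#' voxel dose already converted to EQD0 with the tumour alpha/beta
#' (see [voxelEQD()]). Accumulation is done as a sum of expected surviving
#' clonogens in the log domain.
#'
#' @param eqd0 A [DoseGrid-class] of EQD0 voxel doses.
#' @param target Non-empty [StructureMask-class] of the tumour.
#' @param params [LQParams-class].
#' @return TCP in \[0, 1\].
#' @export
tcpPoisson <- function(eqd0, target, params) {
  .stopIfGeometryMismatch(target, eqd0, "target mask and dose grid")
  sel <- target@occupancy
  if (!any(sel)) stop("target mask is empty", call. = FALSE)
  v <- voxelVolume(eqd0)
  survivors <- params@rho * v * exp(-params@alpha * eqd0@values[sel])
  exp(-sum(survivors))
}

#' Generalised equivalent uniform dose (gEUD)
#'
#' Power mean of a dose distribution with exponent 1/n:
#' \deqn{gEUD = \left(\sum_i \Delta v_i D_i^{1/n}\right)^{n}}
#' where the fractional volumes sum to 1. Computed with the doses scaled by
#' their maximum so large 1/n exponents cannot overflow.
#'
#' @param doses Numeric vector of doses (Gy).
#' @param n Volume-effect exponent in (0, 1]; `n = 1` gives the mean dose.
#' @param volumes Fractional volumes (default equal); must sum to 1 within
#'   1e-6.
#' @return gEUD in Gy, between `min(doses)` and `max(doses)`.
#' @export
gEUD <- function(doses, n, volumes = NULL) {
  if (!length(doses)) stop("empty dose vector", call. = FALSE)
  if (!is.finite(n) || n <= 0 || n > 1)
    stop("'n' must lie in (0, 1]", call. = FALSE)
  if (is.null(volumes)) volumes <- rep(1 / length(doses), length(doses))
  if (abs(sum(volumes) - 1) > 1e-6)
    stop("fractional volumes must sum to 1", call. = FALSE)
  m <- max(doses)
  if (m == 0) return(0)
  m * sum(volumes * (doses / m)^(1 / n))^n
}

#' Lyman-Kutcher-Burman NTCP
#'
#' Probit dose response in the generalised equivalent uniform dose of the
#' organ's EQD2-converted voxel doses:
#' \deqn{NTCP = \Phi\left(\frac{gEUD - D_{50}}{m\, D_{50}}\right)}
#' with Phi the standard normal CDF. Voxel doses are first converted to
#' EQD2 with the organ's alpha/beta (set `convert = FALSE` if the grid is
#' already on the scale the parameters expect).
#'
#' @param dose A [DoseGrid-class] of total physical dose.
#' @param organ Non-empty [StructureMask-class].
#' @param params [LKBParams-class].
#' @param convert Convert voxel doses to EQD2 first (default TRUE).
#' @return NTCP in (0, 1).
#' @export
ntcpLKB <- function(dose, organ, params, convert = TRUE) {
  .stopIfGeometryMismatch(organ, dose, "organ mask and dose grid")
  sel <- organ@occupancy
  if (!any(sel)) stop("organ mask is empty", call. = FALSE)
  dg <- if (convert) voxelEQD(dose, params@abRatio, 2) else dose
  g <- gEUD(dg@values[sel], n = params@n)
  stats::pnorm((g - params@d50) / (params@m * params@d50))
}

## Kallman Poisson single-voxel response: P(D) = 2^{-exp(e*gamma*(1 - D/D50))}
## Returned on the log scale (natural log of P) for underflow safety.
.serialityLogP <- function(d, d50, gamma) {
  -exp(exp(1) * gamma * (1 - d / d50)) * log(2)
}

#' Relative-seriality NTCP
#'
#' Kallman relative-seriality model on EQD2-converted voxel doses:
#' \deqn{NTCP = \left[1 - \prod_i \left(1 - P(D_i)^s\right)^{\Delta v_i}\right]^{1/s}}
#' with per-voxel response \eqn{P(D) = 2^{-\exp(e\gamma(1 - D/D_{50}))}} and
#' relative seriality s (s near 1: serial architecture; s near 0: parallel).
#'
#' @param dose A [DoseGrid-class] of total physical dose.
#' @param organ Non-empty [StructureMask-class].
#' @param params [SerialityParams-class].
#' @param convert Convert voxel doses to EQD2 first (default TRUE).
#' @return NTCP in \[0, 1\].
#' @export
ntcpRelativeSeriality <- function(dose, organ, params, convert = TRUE) {
  .stopIfGeometryMismatch(organ, dose, "organ mask and dose grid")
  sel <- organ@occupancy
  if (!any(sel)) stop("organ mask is empty", call. = FALSE)
  dg <- if (convert) voxelEQD(dose, params@abRatio, 2) else dose
  d <- dg@values[sel]
  dv <- rep(1 / length(d), length(d))
  .serialityCombine(d, dv, params)
}

## shared by the voxel path and the uncertainty tests' compartment path
.serialityCombine <- function(d, dv, params) {
  logP <- .serialityLogP(d, params@d50, params@gamma)
  ## log(1 - P^s) computed stably: P^s = exp(s * logP)
  log1mPs <- log1p(-pmin(exp(params@s * logP), 1 - 1e-16))
  ## 1 - prod (1 - P^s)^{dv} via expm1 so tiny NTCPs keep full precision
  (max(0, -expm1(sum(dv * log1mPs))))^(1 / params@s)
}

#' Relative-seriality NTCP from dose-volume compartments
#'
#' Same model as [ntcpRelativeSeriality()] but applied to explicit
#' (dose, fractional volume) compartments, e.g. from a DVH.
#'
#' @param doses Compartment doses (Gy, on the scale the parameters expect).
#' @param volumes Fractional volumes summing to 1.
#' @param params [SerialityParams-class].
#' @return NTCP in \[0, 1\].
#' @export
ntcpSerialityCompartments <- function(doses, volumes, params) {
  if (length(doses) != length(volumes) || !length(doses))
    stop("doses and volumes must be equal-length, non-empty", call. = FALSE)
  if (abs(sum(volumes) - 1) > 1e-6)
    stop("fractional volumes must sum to 1", call. = FALSE)
  .serialityCombine(doses, volumes, params)
}

#' Calibrate the LQ alpha to a target TCP under uniform irradiation
#'
#' Finds the linear kill coefficient alpha such that a cohort of tumour
#' volumes uniformly irradiated with a reference schedule reaches a target
#' TCP — e.g. alpha fitted so that 70% TCP is reached at 60 Gy in 3 Gy
#' fractions. Two aggregation rules are offered: `"mean"` solves for the
#' single alpha at which the cohort *mean* TCP equals the target (monotone
#' bisection); `"per_volume"` returns one closed-form alpha per volume,
#' \eqn{\alpha_k = \ln(\rho V_k / (-\ln T)) / EQD0}.
#'
#' @param volumes Tumour volumes in cm^3.
#' @param totalDose,dosePerFraction Reference schedule (Gy).
#' @param abRatio Tumour alpha/beta (Gy).
#' @param rho Clonogen density (cells/cm^3).
#' @param targetTcp Target TCP in (0, 1).
#' @param aggregation `"mean"` or `"per_volume"`.
#' @param tol Bisection tolerance on alpha (default 1e-8).
#' @return A single alpha (1/Gy) for `"mean"`; a vector for `"per_volume"`.
#' @examples
#' calibrateAlpha(1, 60, 3, abRatio = 1.6, targetTcp = 0.7)  # ~0.11873
#' @export
calibrateAlpha <- function(volumes, totalDose, dosePerFraction, abRatio,
                           rho = 2.8e8, targetTcp = 0.7,
                           aggregation = c("mean", "per_volume"),
                           tol = 1e-8) {
  aggregation <- match.arg(aggregation)
  if (!length(volumes) || any(volumes <= 0))
    stop("'volumes' must be positive and non-empty", call. = FALSE)
  if (targetTcp <= 0 || targetTcp >= 1)
    stop("'targetTcp' must lie strictly in (0, 1)", call. = FALSE)
  eqd0 <- eqd(totalDose, dosePerFraction, abRatio, 0)
  if (aggregation == "per_volume")
    return(log(rho * volumes / (-log(targetTcp))) / eqd0)
  f <- function(a) mean(exp(-rho * volumes * exp(-a * eqd0))) - targetTcp
  lo <- 1e-6; hi <- 1
  tries <- 0L
  while (f(hi) < 0 && tries < 60L) { hi <- hi * 2; tries <- tries + 1L }
  while (f(lo) > 0 && tries < 120L) { lo <- lo / 2; tries <- tries + 1L }
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(
      "target TCP %.3f unreachable for alpha in [%.3g, %.3g]",
      targetTcp, lo, hi), call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
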