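## Composite outcome: total probability of injury, complication-free tumour
## control P+, and the robustness scans.

#' Total probability of injury across organs at risk
#'
#' \deqn{P_I = 1 - \prod_j w_j (1 - NTCP_j)}
#' with dimensionless clinical-importance weights w_j in (0, 1]. The weights
#' sit inside the product, so any w_j < 1 makes P_I positive even at zero
#' NTCP; a message flags that case. The default (all weights 1) reduces to
#' the usual independent-organ complement product.
#'
#' @param ntcps Numeric vector of per-organ NTCPs in \[0, 1\] (optionally
#'   named).
#' @param weights Weights w_j in (0, 1], recycled if scalar; default 1.
#' @return P_I.
#' @export
probabilityOfInjury <- function(ntcps, weights = 1) {
  if (any(!is.finite(ntcps)) || any(ntcps < 0) || any(ntcps > 1))
    stop("NTCP values must lie in [0, 1]", call. = FALSE)
  if (length(weights) == 1L) weights <- rep(weights, length(ntcps))
  if (length(weights) != length(ntcps))
    stop("one weight per NTCP required", call. = FALSE)
  if (any(weights <= 0) || any(weights > 1))
    stop("weights must lie in (0, 1]", call. = FALSE)
  if (any(weights < 1))
    message("weights < 1 make P_I positive even at zero NTCP ",
            "(weights multiply inside the product)")
  1 - prod(weights * (1 - ntcps))
}

#' Complication-free tumour control probability P+
#'
#' Under independence of tumour and organ-at-risk response,
#' \deqn{P_+ = P_B (1 - P_I)}
#' with P_B the tumour control probability and P_I the total probability of
#' injury.
#'
#' @param tcp Tumour control probability in \[0, 1\].
#' @param pInjury Total probability of injury in \[0, 1\].
#' @return P+ in \[0, 1\]; always `<= tcp`.
#' @export
pPlus <- function(tcp, pInjury) {
  if (any(!is.finite(c(tcp, pInjury))) || any(c(tcp, pInjury) < 0) ||
      any(c(tcp, pInjury) > 1))
    stop("inputs must lie in [0, 1]", call. = FALSE)
  tcp * (1 - pInjury)
}

## inclusive grid from lo by integer multiples of step (no FP drift)
.inclusiveGrid <- function(lo, hi, step) {
  if (!is.finite(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  if (hi < lo) stop("degenerate range", call. = FALSE)
  k <- floor((hi - lo) / step + 1e-9)
  lo + (0:k) * step
}

#' Parameter-uncertainty scan of the LKB NTCP
#'
#' Evaluates [ntcpLKB()] on the Cartesian grid of (D50, m) values spanned by
#' inclusive ranges with fixed steps — e.g. a 68% confidence-interval scan
#' with 1 Gy D50 steps and 0.01 m steps. Grid values are generated from the
#' lower bound by integer multiples of the step.
#'
#' @param dose A [DoseGrid-class].
#' @param organ [StructureMask-class].
#' @param d50Range,mRange Length-2 inclusive ranges.
#' @param d50Step,mStep Step sizes (default 1 Gy and 0.01).
#' @param n Volume-effect exponent held fixed.
#' @param abRatio Organ alpha/beta for the EQD2 conversion.
#' @return `data.frame` with columns `d50`, `m`, `ntcp`; one row per
#'   combination (rows = #d50 values x #m values).
#' @export
lkbUncertaintyScan <- function(dose, organ, d50Range, mRange,
                               d50Step = 1.0, mStep = 0.01,
                               n = 0.3, abRatio = 5.0) {
  d50s <- .inclusiveGrid(d50Range[1], d50Range[2], d50Step)
  ms <- .inclusiveGrid(mRange[1], mRange[2], mStep)
  ## gEUD is independent of (d50, m): compute once
  eqd2 <- voxelEQD(dose, abRatio, 2)
  sel <- organ@occupancy
  if (!any(sel)) stop("organ mask is empty", call. = FALSE)
  g <- gEUD(eqd2@values[sel], n = n)
  grid <- expand.grid(d50 = d50s, m = ms, KEEP.OUT.ATTRS = FALSE)
  grid$ntcp <- stats::pnorm((g - grid$d50) / (grid$m * grid$d50))
  grid
}

#' TCP robustness over alternative LQ parameter sets
#'
#' Recomputes the tumour control probability of a plan case for each
#' parameter set, using that set's alpha/beta in the EQD0 conversion and its
#' alpha in the Poisson model. The default sets span the published
#' alpha/beta range (1.2, 1.6, 2.7 Gy) with alpha each calibrated to 70%
#' TCP at 60 Gy in 3 Gy fractions.
#'
#' @param case A [PlanCase-class] containing a GTV mask.
#' @param parameterSets Named list of [LQParams-class]; default
#'   [tcpParameterSets()].
#' @param targetRole Role of the tumour mask (default `"GTV_HISTO"`).
#' @return Named numeric vector of TCPs, one per parameter set.
#' @export
alphaBetaRobustness <- function(case, parameterSets = tcpParameterSets(),
                                targetRole = "GTV_HISTO") {
  if (!length(parameterSets)) stop("no parameter sets given", call. = FALSE)
  target <- getStructure(case, targetRole)
  out <- vapply(parameterSets, function(p) {
    tcpPoisson(voxelEQD(case@dose, p@abRatio, 0), target, p)
  }, numeric(1))
  names(out) <- names(parameterSets)
  out
}

#' Published LQ parameter sets for the TCP robustness analysis
#'
#' Three (alpha/beta, alpha) pairs at clonogen density 2.8e8 cells/cm^3:
#' alpha/beta 1.2, 1.6 and 2.7 Gy with alpha 0.10099, 0.12050 and 0.15740
#' respectively (each alpha calibrated so a 60 Gy / 3 Gy uniform schedule
#' yields 70% cohort TCP).
#'
#' @return Named list of [LQParams-class] objects.
#' @export
tcpParameterSets <- function() {
  list(set1 = lqParams(rho = 2.8e8, alpha = 0.10099, abRatio = 1.2),
       set2 = lqParams(rho = 2.8e8, alpha = 0.12050, abRatio = 1.6),
       set3 = lqParams(rho = 2.8e8, alpha = 0.15740, abRatio = 2.7))
}
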