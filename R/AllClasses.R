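## Central S4 containers. All grids are axis-aligned in the patient frame,
## axes ordered (LR, AP, CC), units mm, voxel-centre convention.

#' Recognised structure roles
#'
#' Role labels attachable to a [StructureMask-class]. They identify targets
#' (GTVs, PTVs), organs at risk (urethra, bladder, rectum) and derived
#' volumes (PRV = organ at risk plus safety margin) to the evaluation
#' pipeline.
#'
#' @return Character vector of valid role labels.
#' @export
structureRoles <- function() {
  c("GTV_HISTO", "GTV_UNION", "GTV_PET", "GTV_MRI", "PROSTATE",
    "URETHRA", "PRV_URETHRA", "BLADDER", "RECTUM",
    "PTV1", "PTV2", "PTV3_1", "PTV3_2", "PTV3_3", "OTHER")
}

#' Plan labels
#'
#' The three simultaneous-integrated-boost plan variants: `plan1` boosts the
#' full imaging-defined boost volume (PTV3_1), `plan2` the boost volume minus
#' the urethra (PTV3_2), `plan3` the boost volume minus the urethral planning
#' organ-at-risk volume (PTV3_3).
#'
#' @return Character vector `c("plan1", "plan2", "plan3")`.
#' @export
planLabels <- function() c("plan1", "plan2", "plan3")

.boostRoleForPlan <- c(plan1 = "PTV3_1", plan2 = "PTV3_2", plan3 = "PTV3_3")

#' DoseGrid: a 3D total-dose matrix with geometry
#'
#' Axis-aligned grid of total physical dose in Gy delivered over
#' `nFractions` equal fractions. `origin` is the position (mm) of the first
#' voxel centre; `spacing` the voxel pitch (mm) per axis; axes are ordered
#' (left-right, anterior-posterior, cranio-caudal).
#'
#' @slot origin Numeric length 3, mm.
#' @slot spacing Numeric length 3, mm, strictly positive.
#' @slot values 3D numeric array of total dose, Gy, finite and non-negative.
#' @slot nFractions Integer >= 1, the number of fractions N of the schedule.
#' @export
setClass("DoseGrid",
  representation(origin = "numeric", spacing = "numeric",
                 values = "array", nFractions = "integer"),
  prototype(origin = c(0, 0, 0), spacing = c(1.5, 1.5, 1.5),
            values = array(0, c(1, 1, 1)), nFractions = 20L)
)

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msg <- c(msg, "'origin' must be a finite numeric triplet (mm)")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be a strictly positive numeric triplet (mm)")
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "'values' must be non-negative (Gy)")
  if (length(object@nFractions) != 1L || is.na(object@nFractions) ||
      object@nFractions < 1L)
    msg <- c(msg, "'nFractions' must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseGrid
#'
#' @param values 3D numeric array of total dose in Gy.
#' @param spacing Voxel spacing in mm, length-3 (LR, AP, CC) or a scalar.
#' @param origin Position of the first voxel centre in mm, length 3.
#' @param nFractions Number of fractions of the schedule.
#' @return A [DoseGrid-class] object.
#' @examples
#' dg <- doseGrid(array(60, c(4, 4, 4)), spacing = 1.5, nFractions = 20)
#' dosePerFraction(dg)[1, 1, 1]
#' @export
doseGrid <- function(values, spacing = c(1.5, 1.5, 1.5), origin = c(0, 0, 0),
                     nFractions = 20L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DoseGrid", origin = as.numeric(origin), spacing = as.numeric(spacing),
      values = values, nFractions = as.integer(nFractions))
}

#' StructureMask: a boolean occupancy mask on a dose-grid geometry
#'
#' @slot name Character label of the region of interest.
#' @slot role One of [structureRoles()].
#' @slot occupancy 3D logical array on the reference grid geometry.
#' @slot origin,spacing Geometry of the reference grid (mm).
#' @export
setClass("StructureMask",
  representation(name = "character", role = "character",
                 occupancy = "array", origin = "numeric", spacing = "numeric"),
  prototype(name = "mask", role = "OTHER",
            occupancy = array(FALSE, c(1, 1, 1)),
            origin = c(0, 0, 0), spacing = c(1.5, 1.5, 1.5))
)

setValidity("StructureMask", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
  if (length(object@role) != 1L || !object@role %in% structureRoles())
    msg <- c(msg, sprintf("'role' must be one of: %s",
                          paste(structureRoles(), collapse = ", ")))
  if (length(dim(object@occupancy)) != 3L || !is.logical(object@occupancy))
    msg <- c(msg, "'occupancy' must be a 3D logical array")
  if (any(is.na(object@occupancy))) msg <- c(msg, "'occupancy' must not contain NA")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be a strictly positive mm triplet")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be a finite mm triplet")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureMask
#'
#' @param occupancy 3D logical array.
#' @param name ROI label.
#' @param role One of [structureRoles()].
#' @param spacing,origin Geometry (mm) of the reference grid; a
#'   [DoseGrid-class] may be given as `geometry` instead.
#' @param geometry Optional DoseGrid supplying origin/spacing.
#' @return A [StructureMask-class].
#' @export
structureMask <- function(occupancy, name = "mask", role = "OTHER",
                          spacing = c(1.5, 1.5, 1.5), origin = c(0, 0, 0),
                          geometry = NULL) {
  if (!is.null(geometry)) {
    spacing <- gridSpacing(geometry)
    origin <- gridOrigin(geometry)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("StructureMask", name = name, role = role, occupancy = occupancy,
      origin = as.numeric(origin), spacing = as.numeric(spacing))
}

#' StructureSet: named collection of masks sharing one geometry
#'
#' @slot masks Named list of [StructureMask-class] objects on identical
#'   geometry.
#' @export
setClass("StructureSet", representation(masks = "list"),
         prototype(masks = list()))

setValidity("StructureSet", function(object) {
  msg <- character()
  if (length(object@masks)) {
    ok <- vapply(object@masks, is, logical(1), "StructureMask")
    if (!all(ok)) msg <- c(msg, "all elements must be StructureMask objects")
    else {
      ref <- object@masks[[1L]]
      same <- vapply(object@masks, function(m) .sameGeometry(m, ref), logical(1))
      if (!all(same)) msg <- c(msg, "all masks must share one grid geometry")
    }
    nm <- names(object@masks)
    if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
      msg <- c(msg, "'masks' must be uniquely named")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StructureSet
#'
#' @param ... [StructureMask-class] objects, or a single list of them.
#' @return A [StructureSet-class]; list names default to mask names.
#' @export
structureSet <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1L]]) && !is(masks[[1L]], "StructureMask"))
    masks <- masks[[1L]]
  if (is.null(names(masks)) || any(names(masks) == ""))
    names(masks) <- vapply(masks, function(m) m@name, character(1))
  new("StructureSet", masks = masks)
}

#' PlanCase: one patient's plan (dose + structures)
#'
#' @slot caseId Character case identifier.
#' @slot planLabel One of [planLabels()].
#' @slot dose A [DoseGrid-class].
#' @slot structures A [StructureSet-class] on the dose geometry.
#' @export
setClass("PlanCase",
  representation(caseId = "character", planLabel = "character",
                 dose = "DoseGrid", structures = "StructureSet"))

setValidity("PlanCase", function(object) {
  msg <- character()
  if (!object@planLabel %in% planLabels())
    msg <- c(msg, "'planLabel' must be one of plan1/plan2/plan3")
  if (length(object@structures@masks) &&
      !.sameGeometry(object@structures@masks[[1L]], object@dose))
    msg <- c(msg, "structures must share the dose grid geometry")
  if (length(msg)) msg else TRUE
})

#' Construct a PlanCase
#'
#' @param caseId Case identifier.
#' @param planLabel One of [planLabels()].
#' @param dose [DoseGrid-class].
#' @param structures [StructureSet-class].
#' @return A [PlanCase-class].
#' @export
planCase <- function(caseId, planLabel, dose, structures)
  new("PlanCase", caseId = caseId, planLabel = planLabel,
      dose = dose, structures = structures)

#' Cohort: a list of PlanCases
#'
#' @slot cases List of [PlanCase-class] objects.
#' @export
setClass("Cohort", representation(cases = "list"), prototype(cases = list()))

setValidity("Cohort", function(object) {
  ok <- vapply(object@cases, is, logical(1), "PlanCase")
  if (all(ok)) TRUE else "all elements must be PlanCase objects"
})

#' @rdname Cohort-class
#' @param cases List of [PlanCase-class] objects.
#' @return `cohort()` returns a [Cohort-class].
#' @export
cohort <- function(cases) new("Cohort", cases = cases)

## ---- Radiobiological parameter classes ----

#' Linear-quadratic Poisson TCP parameters
#'
#' @slot rho Clonogenic cell density, cells per cm^3.
#' @slot alpha Linear cell-kill coefficient, 1/Gy.
#' @slot abRatio Tumour alpha/beta ratio, Gy.
#' @export
setClass("LQParams",
  representation(rho = "numeric", alpha = "numeric", abRatio = "numeric"))

setValidity("LQParams", function(object) {
  v <- c(object@rho, object@alpha, object@abRatio)
  if (length(v) == 3L && all(is.finite(v)) && all(v > 0)) TRUE
  else "rho, alpha and abRatio must each be a single positive number"
})

#' @rdname LQParams-class
#' @param rho Clonogen density (cells/cm^3).
#' @param alpha Linear kill coefficient (1/Gy).
#' @param abRatio Tumour alpha/beta (Gy).
#' @return `lqParams()` returns an [LQParams-class].
#' @export
lqParams <- function(rho = 2.8e8, alpha = 0.12050, abRatio = 1.6)
  new("LQParams", rho = rho, alpha = alpha, abRatio = abRatio)

#' Lyman-Kutcher-Burman NTCP parameters
#'
#' @slot d50 Dose of 50% complication probability (Gy, on the EQDx scale the
#'   model is applied to).
#' @slot m Slope parameter (dimensionless).
#' @slot n Volume-effect exponent in (0, 1].
#' @slot abRatio Organ alpha/beta (Gy) for the EQD2 conversion.
#' @export
setClass("LKBParams",
  representation(d50 = "numeric", m = "numeric", n = "numeric",
                 abRatio = "numeric"))

setValidity("LKBParams", function(object) {
  msg <- character()
  if (!(length(object@d50) == 1L && is.finite(object@d50) && object@d50 > 0))
    msg <- c(msg, "'d50' must be a single positive number (Gy)")
  if (!(length(object@m) == 1L && is.finite(object@m) && object@m > 0))
    msg <- c(msg, "'m' must be a single positive number")
  if (!(length(object@n) == 1L && is.finite(object@n) &&
        object@n > 0 && object@n <= 1))
    msg <- c(msg, "'n' must lie in (0, 1]")
  if (!(length(object@abRatio) == 1L && is.finite(object@abRatio) &&
        object@abRatio > 0))
    msg <- c(msg, "'abRatio' must be a single positive number (Gy)")
  if (length(msg)) msg else TRUE
})

#' @rdname LKBParams-class
#' @param d50,m,n Model parameters; defaults are the urethral-stricture set
#'   (D50 = 116.7 Gy, m = 0.23, n = 0.3).
#' @param abRatio Organ alpha/beta (Gy), default 5.0.
#' @return `lkbParams()` returns an [LKBParams-class].
#' @export
lkbParams <- function(d50 = 116.7, m = 0.23, n = 0.3, abRatio = 5.0)
  new("LKBParams", d50 = d50, m = m, n = n, abRatio = abRatio)

#' Relative-seriality NTCP parameters
#'
#' @slot d50 Dose of 50% response (Gy as EQD2).
#' @slot gamma Normalised dose-response slope (dimensionless).
#' @slot s Relative seriality (s near 1: serial; s near 0: parallel).
#' @slot abRatio Organ alpha/beta (Gy) for the EQD2 conversion.
#' @export
setClass("SerialityParams",
  representation(d50 = "numeric", gamma = "numeric", s = "numeric",
                 abRatio = "numeric"))

setValidity("SerialityParams", function(object) {
  v <- c(object@d50, object@gamma, object@s, object@abRatio)
  if (length(v) == 4L && all(is.finite(v)) && all(v > 0)) TRUE
  else "d50, gamma, s and abRatio must each be a single positive number"
})

#' @rdname SerialityParams-class
#' @param d50,gamma,s Model parameters (default: bladder set, D50 = 80 Gy
#'   EQD2, gamma = 2.59, s = 1.3).
#' @param abRatio Organ alpha/beta (Gy), default 3.0.
#' @return `serialityParams()` returns a [SerialityParams-class].
#' @export
serialityParams <- function(d50 = 80, gamma = 2.59, s = 1.3, abRatio = 3.0)
  new("SerialityParams", d50 = d50, gamma = gamma, s = s, abRatio = abRatio)

#' Bundle of all model parameters used by the evaluation pipeline
#'
#' @slot tumour [LQParams-class] for the TCP model.
#' @slot urethra [LKBParams-class] for urethral stricture.
#' @slot bladder,rectum [SerialityParams-class] for the seriality model.
#' @slot weights Named numeric organ weights w_j in (0, 1], used in the
#'   total probability of injury.
#' @export
setClass("RadiobioParams",
  representation(tumour = "LQParams", urethra = "LKBParams",
                 bladder = "SerialityParams", rectum = "SerialityParams",
                 weights = "numeric"))

setValidity("RadiobioParams", function(object) {
  w <- object@weights
  if (length(w) && (any(!is.finite(w)) || any(w <= 0) || any(w > 1)))
    return("weights must lie in (0, 1]")
  TRUE
})

#' Gaussian intrafractional-motion kernel
#'
#' Standard deviations of the 3D Gaussian blurring kernel describing random
#' intrafractional target motion, per patient axis, in mm. Defaults are the
#' prostate motion amplitudes (0.92, 1.59, 1.54) mm for (LR, AP, CC).
#'
#' @slot sigma Numeric length 3, mm, componentwise >= 0.
#' @slot truncation Kernel support radius in multiples of sigma (>= 3).
#' @export
setClass("MotionKernel",
  representation(sigma = "numeric", truncation = "numeric"),
  prototype(sigma = c(0.92, 1.59, 1.54), truncation = 4))

setValidity("MotionKernel", function(object) {
  msg <- character()
  if (length(object@sigma) != 3L || any(!is.finite(object@sigma)) ||
      any(object@sigma < 0))
    msg <- c(msg, "'sigma' must be a non-negative mm triplet")
  if (length(object@truncation) != 1L || !is.finite(object@truncation) ||
      object@truncation < 3)
    msg <- c(msg, "'truncation' must be a single number >= 3")
  if (length(msg)) msg else TRUE
})

#' @rdname MotionKernel-class
#' @param sigma Kernel standard deviations (LR, AP, CC) in mm; a scalar is
#'   recycled.
#' @param truncation Support radius in multiples of sigma.
#' @return `motionKernel()` returns a [MotionKernel-class].
#' @export
motionKernel <- function(sigma = c(0.92, 1.59, 1.54), truncation = 4) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  new("MotionKernel", sigma = as.numeric(sigma), truncation = truncation)
}

#' @rdname MotionKernel-class
#' @export
defaultMotionKernel <- function() motionKernel()
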