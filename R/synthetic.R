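## Seeded synthetic prostate phantom: geometry (gland, urethra + PRV, one or
## two intraprostatic GTVs, bladder, rectum) and analytic SIB dose painting
## for the three plan variants. The generator emulates the statistical
## structure of a focal-boost planning study — target volumes of a few cm^3
## abutting the urethra, 60 Gy whole-gland / 70 Gy boost in 20 fractions,
## with urethral dose suppression in plans 2 and 3 — so the whole pipeline is
## testable without patient data.

#' Phantom specification
#'
#' All lengths in mm, doses in Gy. Defaults give a ~48 cm^3 gland, a ~5 cm^3
#' imaging-defined GTV-Union abutting the 3 mm urethra (seeded surface gap
#' 0-2 mm), a ground-truth GTV-Histo scaled to ~0.79 of the Union volume and
#' shifted radially so that its coverage by the Union is `histoCoverage`,
#' and 60/70 Gy SIB dose painting with a 3 mm Gaussian penumbra, 0.3 Gy
#' correlated noise and urethral suppression to D2% <=
#' `sparingTarget - sparingHeadroom` for the sparing plans.
#'
#' @slot spacing,dims Grid geometry (mm, voxel counts), default 1.5 mm and
#'   64 x 64 x 80.
#' @slot prostateSemiAxes,urethraRadius,prvMargin Gland and urethra geometry.
#' @slot nGtv 1 or 2 ellipsoidal GTV lobes.
#' @slot gtvSemiAxes GTV lobe semi-axes.
#' @slot gtvGapRange Range of the seeded GTV-to-urethra surface gap.
#' @slot gtvZJitter Max |CC| offset of the GTV centre.
#' @slot histoCoverage Target coverage of GTV-Histo by GTV-Union in (0, 1].
#' @slot histoSizeRatio Linear scale of GTV-Histo semi-axes vs GTV-Union.
#' @slot bladderCenter,bladderSemiAxes,rectumCenterY,rectumSemiAxes,rectumZRange
#'   Organ-at-risk placement.
#' @slot ptvMargin Margin of PTV3_1 around GTV-Union.
#' @slot baseDose,boostDose Prescription levels (Gy); base < boost.
#' @slot penumbraSigma Gaussian penumbra of the painted dose (mm).
#' @slot basePaintMargin,boostPaintMargin Dilation of the painted regions so
#'   prescription levels are held at the structure edge.
#' @slot suppressionSigma Edge steepness of the urethral suppression (mm).
#' @slot sparingTarget D2% sparing constraint (Gy), default 62.4.
#' @slot sparingHeadroom Gy below the target the suppression aims at, so the
#'   constraint also survives motion blurring.
#' @slot noiseSd,noiseCorrMm Smooth dose-noise amplitude and correlation.
#' @slot jitterFrac Relative per-case jitter of the semi-axes.
#' @slot nFractions Fraction count of the schedule.
#' @export
setClass("PhantomSpec",
  representation(spacing = "numeric", dims = "integer",
    prostateSemiAxes = "numeric", urethraRadius = "numeric",
    prvMargin = "numeric", nGtv = "integer", gtvSemiAxes = "numeric",
    gtvGapRange = "numeric", gtvZJitter = "numeric",
    histoCoverage = "numeric", histoSizeRatio = "numeric",
    bladderCenter = "numeric", bladderSemiAxes = "numeric",
    rectumCenterY = "numeric", rectumSemiAxes = "numeric",
    rectumZRange = "numeric", ptvMargin = "numeric",
    baseDose = "numeric", boostDose = "numeric", penumbraSigma = "numeric",
    basePaintMargin = "numeric", boostPaintMargin = "numeric",
    suppressionSigma = "numeric", sparingTarget = "numeric",
    sparingHeadroom = "numeric", noiseSd = "numeric", noiseCorrMm = "numeric",
    jitterFrac = "numeric", nFractions = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  lens <- c(object@spacing, object@prostateSemiAxes, object@urethraRadius,
            object@gtvSemiAxes, object@ptvMargin + 1e-12)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths must be positive")
  if (object@histoCoverage <= 0 || object@histoCoverage > 1)
    msg <- c(msg, "'histoCoverage' must lie in (0, 1]")
  if (object@baseDose >= object@boostDose)
    msg <- c(msg, "'baseDose' must be below 'boostDose'")
  if (!object@nGtv %in% c(1L, 2L)) msg <- c(msg, "'nGtv' must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomSpec-class
#' @param ... Named slot overrides; see the class documentation for slots,
#'   units and defaults.
#' @return `phantomSpec()` returns a [PhantomSpec-class].
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  defaults <- list(
    spacing = c(1.5, 1.5, 1.5), dims = c(64L, 64L, 80L),
    prostateSemiAxes = c(25, 22, 21), urethraRadius = 3, prvMargin = 2,
    nGtv = 1L, gtvSemiAxes = c(12, 10.5, 10), gtvGapRange = c(0, 2),
    gtvZJitter = 5, histoCoverage = 0.79, histoSizeRatio = 0.9245,
    bladderCenter = c(0, -8, 36), bladderSemiAxes = c(26, 24, 17),
    rectumCenterY = 32, rectumSemiAxes = c(10, 11),
    rectumZRange = c(-45, 15), ptvMargin = 2,
    baseDose = 60, boostDose = 70, penumbraSigma = 3,
    basePaintMargin = 7, boostPaintMargin = 4.5, suppressionSigma = 1.5,
    sparingTarget = 62.4, sparingHeadroom = 2,
    noiseSd = 0.3, noiseCorrMm = 4, jitterFrac = 0.10, nFractions = 20L)
  defaults[names(args)] <- args
  defaults$dims <- as.integer(defaults$dims)
  defaults$nGtv <- as.integer(defaults$nGtv)
  defaults$nFractions <- as.integer(defaults$nFractions)
  if (length(defaults$spacing) == 1L)
    defaults$spacing <- rep(defaults$spacing, 3L)
  do.call(new, c(list(Class = "PhantomSpec"), defaults))
}

## centred grid origin and voxel-centre coordinate arrays
.phantomGeometry <- function(spec) {
  d <- spec@dims; sp <- spec@spacing
  org <- -(d - 1) / 2 * sp
  xs <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  list(origin = org,
       X = array(rep(xs, times = d[2] * d[3]), d),
       Y = array(rep(rep(ys, each = d[1]), times = d[3]), d),
       Z = array(rep(zs, each = d[1] * d[2]), d))
}

.ellipsoid <- function(g, center, semi) {
  ((g$X - center[1]) / semi[1])^2 + ((g$Y - center[2]) / semi[2])^2 +
    ((g$Z - center[3]) / semi[3])^2 <= 1
}

## ellipsoid with in-plane axes rotated by theta (axis 1 along the rotated x)
.ellipsoidRot <- function(g, center, semi, theta) {
  dx <- g$X - center[1]; dy <- g$Y - center[2]
  xr <- cos(theta) * dx + sin(theta) * dy
  yr <- -sin(theta) * dx + cos(theta) * dy
  (xr / semi[1])^2 + (yr / semi[2])^2 + ((g$Z - center[3]) / semi[3])^2 <= 1
}

#' Generate a phantom structure set
#'
#' Builds the full structure set: prostate, urethra and its PRV, GTV-Union
#' (imaging-defined, clipped to the gland), GTV-Histo (ground truth, shifted
#' radially away from the urethra until its coverage by GTV-Union matches
#' the spec within ~0.02), the three boost volumes (PTV3_1 = GTV-Union +
#' margin; PTV3_2 minus urethra; PTV3_3 minus PRV), bladder and rectum.
#' Deterministic given the RNG state (or `seed`).
#'
#' @param spec A [PhantomSpec-class].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as [makeCohort()] does).
#' @return A [StructureSet-class].
#' @export
makePhantom <- function(spec = phantomSpec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  jit <- function(x) x * stats::runif(length(x), 1 - spec@jitterFrac,
                                      1 + spec@jitterFrac)
  pSemi <- jit(spec@prostateSemiAxes)
  gSemi <- jit(spec@gtvSemiAxes)
  gap <- stats::runif(1, spec@gtvGapRange[1], spec@gtvGapRange[2])
  theta <- stats::runif(1, 0, 2 * pi)
  z0 <- stats::runif(1, -spec@gtvZJitter, spec@gtvZJitter)
  bSemi <- jit(spec@bladderSemiAxes)

  g <- .phantomGeometry(spec)
  org <- g$origin; sp <- spec@spacing
  if (any(pSemi >= (spec@dims * sp) / 2))
    stop("prostate does not fit the phantom grid", call. = FALSE)
  mk <- function(occ, name, role)
    structureMask(occ, name = name, role = role, spacing = sp, origin = org)

  prostate <- .ellipsoid(g, c(0, 0, 0), pSemi)
  ## tube through the gland, ending short of the apex/base so the sparing
  ## suppression cannot reach into the bladder neck
  urethra <- (g$X^2 + g$Y^2 <= spec@urethraRadius^2) &
    abs(g$Z) <= 0.85 * pSemi[3]

  ## GTV-Union: lobe(s) abutting the urethra with the seeded surface gap.
  ## The lobe's first axis points radially away from the urethra.
  u <- c(cos(theta), sin(theta))
  rho0 <- spec@urethraRadius + gap + gSemi[1]
  gtvCenter <- c(rho0 * u, z0)
  union <- .ellipsoidRot(g, gtvCenter, gSemi, theta) & prostate
  if (spec@nGtv == 2L) {
    c2 <- gtvCenter + c(0.5 * gSemi[1] * u, 0.8 * gSemi[3])
    union <- (union | .ellipsoidRot(g, c2, gSemi * 0.6, theta)) & prostate
  }

  ## GTV-Histo: same centre, volume scaled by histoSizeRatio^3, elongated
  ## tangentially to the urethra until its coverage by GTV-Union matches the
  ## spec. The uncovered part then protrudes as thin lobes hugging the
  ## Union surface (away from the urethra), as a ground-truth tumour
  ## underestimated by imaging would, instead of drifting into the low-dose
  ## bath.
  k <- spec@histoSizeRatio
  histoAt <- function(eps)
    .ellipsoidRot(g, gtvCenter,
                  c(k / (1 + eps) * gSemi[1], k * (1 + eps) * gSemi[2],
                    k * gSemi[3]), theta) & prostate
  coverage <- function(h) {
    nh <- sum(h)
    if (nh == 0) 0 else sum(h & union) / nh
  }
  if (spec@histoCoverage >= 1 || coverage(histoAt(0)) <= spec@histoCoverage) {
    histo <- histoAt(0)
  } else {
    lo <- 0; hi <- 2
    for (i in 1:25) {
      mid <- (lo + hi) / 2
      if (coverage(histoAt(mid)) > spec@histoCoverage) lo <- mid else hi <- mid
    }
    histo <- histoAt((lo + hi) / 2)
  }

  urethraMask <- mk(urethra, "urethra", "URETHRA")
  prv <- expandMask(urethraMask, spec@prvMargin, name = "prv_urethra",
                    role = "PRV_URETHRA")
  unionMask <- mk(union, "gtv_union", "GTV_UNION")
  ptv31 <- expandMask(unionMask, spec@ptvMargin, name = "ptv3_1", role = "PTV3_1")
  ptv32 <- combineMasks(ptv31, urethraMask, "difference",
                        name = "ptv3_2", role = "PTV3_2")
  ptv33 <- combineMasks(ptv31, prv, "difference",
                        name = "ptv3_3", role = "PTV3_3")

  bladder <- .ellipsoid(g, spec@bladderCenter, bSemi) & !prostate
  rectum <- ((g$X / spec@rectumSemiAxes[1])^2 +
             ((g$Y - spec@rectumCenterY) / spec@rectumSemiAxes[2])^2 <= 1) &
    g$Z >= spec@rectumZRange[1] & g$Z <= spec@rectumZRange[2] & !prostate

  structureSet(list(
    prostate = mk(prostate, "prostate", "PROSTATE"),
    urethra = urethraMask,
    prv_urethra = prv,
    gtv_union = unionMask,
    gtv_histo = mk(histo, "gtv_histo", "GTV_HISTO"),
    ptv3_1 = ptv31, ptv3_2 = ptv32, ptv3_3 = ptv33,
    bladder = mk(bladder, "bladder", "BLADDER"),
    rectum = mk(rectum, "rectum", "RECTUM")))
}

## Gaussian blur of a plain array, sigma in mm
.gaussBlurArray <- function(a, sigmaMm, spacing, truncation = 4) {
  d <- dim(a)
  if (length(sigmaMm) == 1L) sigmaMm <- rep(sigmaMm, 3L)
  for (ax in 1:3) {
    sv <- sigmaMm[ax] / spacing[ax]
    if (sv > 0) a <- .applyAlongAxis(a, .blurMatrix1d(d[ax], sv, truncation), ax)
  }
  a
}

.d2pct <- function(values, occ) {
  d <- sort(values[occ], decreasing = TRUE)
  d[ceiling(0.02 * length(d))]
}

#' Paint a SIB dose distribution onto a phantom
#'
#' Analytic dose painting: the base prescription level inside the gland
#' (with a Gaussian penumbra falling off outside), raised to the boost level
#' inside the plan's boost volume (PTV3_1/2/3 by plan label), plus smooth
#' correlated noise. For plans 2 and 3 a multiplicative local suppression is
#' iterated inside the urethra (plan 2) or PRV-urethra (plan 3) until that
#' structure's D2% is at most `sparingTarget - sparingHeadroom`. All doses
#' are non-negative and the grid carries the spec's fraction count.
#'
#' @param structures A [StructureSet-class] from [makePhantom()].
#' @param plan One of [planLabels()].
#' @param spec The [PhantomSpec-class] used for the phantom.
#' @param seed Optional seed for the noise draw.
#' @return A [DoseGrid-class].
#' @export
paintDose <- function(structures, plan, spec = phantomSpec(), seed = NULL) {
  if (!plan %in% planLabels())
    stop("'plan' must be one of plan1/plan2/plan3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  boostRole <- .boostRoleForPlan[[plan]]
  roles <- vapply(structures@masks, maskRole, character(1))
  if (!boostRole %in% roles)
    stop(sprintf("structure set lacks the boost volume %s for %s",
                 boostRole, plan), call. = FALSE)
  prostate <- getStructure(structures, "PROSTATE")
  boost <- getStructure(structures, boostRole)
  sp <- prostate@spacing
  d <- dim(prostate@occupancy)

  baseRegion <- expandMask(prostate, spec@basePaintMargin)
  boostRegion <- expandMask(boost, spec@boostPaintMargin)
  sBase <- .gaussBlurArray(baseRegion@occupancy * 1, spec@penumbraSigma, sp)
  sBoost <- .gaussBlurArray(boostRegion@occupancy * 1, spec@penumbraSigma, sp)
  dose <- spec@baseDose * sBase + (spec@boostDose - spec@baseDose) * sBoost

  if (spec@noiseSd > 0) {
    noise <- .gaussBlurArray(array(stats::rnorm(prod(d)), d),
                             spec@noiseCorrMm, sp)
    dose <- dose + noise * (spec@noiseSd / stats::sd(noise))
  }
  dose <- pmax(dose, 0)

  sparingRole <- switch(plan, plan1 = NULL, plan2 = "URETHRA",
                        plan3 = "PRV_URETHRA")
  if (!is.null(sparingRole)) {
    region <- getStructure(structures, sparingRole)
    sR <- .gaussBlurArray(region@occupancy * 1, spec@suppressionSigma, sp)
    aim <- spec@sparingTarget - spec@sparingHeadroom
    for (it in 1:20) {
      d2 <- .d2pct(dose, region@occupancy)
      if (d2 <= aim) break
      dose <- dose * (1 - (1 - aim / d2) * sR)
    }
  }
  doseGrid(dose, spacing = sp, origin = prostate@origin,
           nFractions = spec@nFractions)
}

#' Generate a seeded phantom cohort
#'
#' `nCases` phantoms, each with per-case jittered geometry and one painted
#' dose per plan variant (the noise field is drawn independently per plan,
#' as separately optimised plans would be). All randomness flows from one
#' RNG stream seeded once, so the cohort is fully reproducible.
#'
#' @param nCases Number of cases (default 10).
#' @param spec A [PhantomSpec-class] template.
#' @param seed Integer seed.
#' @return A [Cohort-class] of `nCases * 3` plan-cases.
#' @export
makeCohort <- function(nCases = 10, spec = phantomSpec(), seed = 1) {
  if (nCases < 1) stop("'nCases' must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  cases <- list()
  for (k in seq_len(nCases)) {
    structures <- makePhantom(spec)
    id <- sprintf("case%02d", k)
    for (plan in planLabels()) {
      cases[[length(cases) + 1L]] <-
        planCase(id, plan, paintDose(structures, plan, spec), structures)
    }
  }
  cohort(cases)
}
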