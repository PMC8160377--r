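## Dose-volume and geometry metrics: DX%, cumulative DVH, constraint
## verdicts, overlap (Dice/coverage) and minimum distances.

#' Dose at volume (DX%)
#'
#' The largest dose level such that at least `percent`% of the structure
#' volume receives that dose or more, computed by exact order statistics on
#' the structure's voxel doses (no DVH binning). `percent = 100` gives the
#' minimum dose, `percent = 0` is treated as the maximum.
#'
#' @param dose A [DoseGrid-class].
#' @param mask Non-empty [StructureMask-class].
#' @param percent Volume percentage in \[0, 100\].
#' @return Dose in Gy.
#' @export
doseAtVolume <- function(dose, mask, percent) {
  .stopIfGeometryMismatch(mask, dose, "mask and dose grid")
  if (percent < 0 || percent > 100)
    stop("'percent' must lie in [0, 100]", call. = FALSE)
  d <- dose@values[mask@occupancy]
  if (!length(d)) stop("mask is empty", call. = FALSE)
  if (percent == 0) return(max(d))
  sorted <- sort(d, decreasing = TRUE)
  sorted[ceiling(percent / 100 * length(d))]
}

#' Cumulative dose-volume histogram
#'
#' Percentage of the structure volume receiving at least each dose level,
#' from 0 Gy (100%) to just above the maximum dose (0%).
#'
#' @param dose A [DoseGrid-class].
#' @param mask Non-empty [StructureMask-class].
#' @param binWidth Dose level step in Gy (> 0), default 0.1.
#' @return `data.frame` with columns `dose` (Gy) and `volume` (% >= dose),
#'   monotone non-increasing.
#' @export
cumulativeDVH <- function(dose, mask, binWidth = 0.1) {
  .stopIfGeometryMismatch(mask, dose, "mask and dose grid")
  if (!is.finite(binWidth) || binWidth <= 0)
    stop("'binWidth' must be > 0", call. = FALSE)
  d <- dose@values[mask@occupancy]
  if (!length(d)) stop("mask is empty", call. = FALSE)
  levels <- seq(0, max(d) + binWidth, by = binWidth)
  vol <- vapply(levels, function(x) 100 * mean(d >= x), numeric(1))
  data.frame(dose = levels, volume = vol)
}

#' Default dose constraints
#'
#' The planning constraints checked by [checkConstraints()]: boost-volume
#' coverage (D98% >= 68.6 Gy) and hotspot (D2% <= 71.4 Gy) for the active
#' PTV3, whole-gland PTV2 D98% >= 58.8 / D2% <= 70 Gy, and the urethral
#' sparing constraints D2% <= 62.4 Gy for urethra and PRV-urethra.
#'
#' @param path Optional YAML file with rows `structure`, `metric`, `bound`,
#'   `threshold` overriding the shipped defaults.
#' @return `data.frame` with columns `structure` (role), `metric`
#'   (`"D<X>%"`), `bound` (`"<="`/`">="`) and `threshold` (Gy).
#' @export
defaultConstraints <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "constraints.yaml", package = "rtOutcome")
  cfg <- yaml::read_yaml(path)
  do.call(rbind, lapply(cfg$constraints, function(x)
    data.frame(structure = x$structure, metric = x$metric, bound = x$bound,
               threshold = as.numeric(x$threshold),
               stringsAsFactors = FALSE)))
}

.parseMetric <- function(metric) {
  mD <- regmatches(metric, regexec("^D([0-9.]+)%$", metric))[[1]]
  if (length(mD) == 2L) return(list(kind = "D", value = as.numeric(mD[2])))
  mV <- regmatches(metric, regexec("^V([0-9.]+)Gy$", metric))[[1]]
  if (length(mV) == 2L) return(list(kind = "V", value = as.numeric(mV[2])))
  stop(sprintf("unrecognised constraint metric '%s'", metric), call. = FALSE)
}

#' Check a plan case against dose constraints
#'
#' Evaluates each constraint (DX% in Gy, or VX Gy in % volume) against the
#' case's dose and structures. A structure missing from the case is
#' reported as not evaluable — never as a pass. The role `PTV3` resolves to
#' the plan's active boost volume (PTV3_1/2/3 by plan label).
#'
#' @param case A [PlanCase-class].
#' @param constraints Constraint table as from [defaultConstraints()].
#' @param dose Optional [DoseGrid-class] overriding the case's dose (e.g. a
#'   motion-blurred grid).
#' @return `data.frame` with one row per constraint: `structure`, `metric`,
#'   `bound`, `threshold`, `measured`, `pass`, `evaluable`.
#' @export
checkConstraints <- function(case, constraints = defaultConstraints(),
                             dose = NULL) {
  if (is.null(dose)) dose <- case@dose
  roles <- vapply(case@structures@masks, maskRole, character(1))
  rows <- lapply(seq_len(nrow(constraints)), function(r) {
    cs <- constraints[r, ]
    role <- cs$structure
    if (role == "PTV3") role <- .boostRoleForPlan[[planLabel(case)]]
    out <- data.frame(structure = cs$structure, metric = cs$metric,
                      bound = cs$bound, threshold = cs$threshold,
                      measured = NA_real_, pass = NA, evaluable = FALSE,
                      stringsAsFactors = FALSE)
    if (!role %in% roles) return(out)
    mask <- getStructure(case, role)
    pm <- .parseMetric(cs$metric)
    measured <- if (pm$kind == "D") {
      doseAtVolume(dose, mask, pm$value)
    } else {
      100 * mean(dose@values[mask@occupancy] >= pm$value)
    }
    out$measured <- measured
    out$evaluable <- TRUE
    out$pass <- if (cs$bound == "<=") measured <= cs$threshold
                else measured >= cs$threshold
    out
  })
  do.call(rbind, rows)
}

#' Overlap metrics between two masks
#'
#' Soerensen-Dice coefficient, intersection volume, intersection as a
#' percentage of `b`, and coverage of `a` by `b` (percentage of `a` inside
#' `b`).
#'
#' @param a,b [StructureMask-class] objects on the same geometry.
#' @return Named list: `dice`, `intersectionCm3`, `intersectionPctOfB`,
#'   `coverageOfAPct`. Two empty masks give Dice 0 with a warning.
#' @export
overlapMetrics <- function(a, b) {
  .stopIfGeometryMismatch(a, b, "masks")
  na <- sum(a@occupancy); nb <- sum(b@occupancy)
  ni <- sum(a@occupancy & b@occupancy)
  vv <- prod(a@spacing) / 1000
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 0")
    return(list(dice = 0, intersectionCm3 = 0, intersectionPctOfB = 0,
                coverageOfAPct = 0))
  }
  list(dice = 2 * ni / (na + nb),
       intersectionCm3 = ni * vv,
       intersectionPctOfB = if (nb > 0) 100 * ni / nb else 0,
       coverageOfAPct = if (na > 0) 100 * ni / na else 0)
}

## mm coordinates of set voxels, one row per voxel
.maskCoords <- function(mask) {
  idx <- which(mask@occupancy, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask@spacing, "*"), 2, mask@origin, "+")
}

## minimum cross distance between two coordinate matrices, chunked
.minCrossDist <- function(A, B, chunk = 2000L) {
  best <- Inf
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ac <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), rowSums(B^2), "+") - 2 * Ac %*% t(B)
    best <- min(best, min(d2))
    if (best <= 0) return(0)
  }
  sqrt(max(best, 0))
}

#' Minimum distance between two structures
#'
#' Minimum Euclidean distance between voxel centres of the two masks, in mm,
#' respecting anisotropic spacing; overlapping masks give 0. In
#' `per_axial_slice` mode both masks are restricted to each CC (axial) slice
#' where both are present and one in-plane minimum is returned per slice,
#' plus the overall per-case minimum. Distances are centre-to-centre, which
#' biases surface distances by up to half a voxel.
#'
#' @param a,b Non-empty [StructureMask-class] objects on the same geometry.
#' @param mode `"3d"` (default) or `"per_axial_slice"`.
#' @return For `"3d"`, a single distance in mm. For `"per_axial_slice"`, a
#'   list with `perSlice` (`data.frame` of `slice`, `distance`) and
#'   `minimum`.
#' @export
minDistance <- function(a, b, mode = c("3d", "per_axial_slice")) {
  mode <- match.arg(mode)
  .stopIfGeometryMismatch(a, b, "masks")
  if (!any(a@occupancy) || !any(b@occupancy))
    stop("both masks must be non-empty", call. = FALSE)
  if (mode == "3d") {
    if (any(a@occupancy & b@occupancy)) return(0)
    return(.minCrossDist(.maskCoords(a), .maskCoords(b)))
  }
  d <- dim(a@occupancy)
  slices <- which(vapply(seq_len(d[3]), function(k)
    any(a@occupancy[, , k]) && any(b@occupancy[, , k]), logical(1)))
  if (!length(slices))
    stop("no axial slice contains both structures", call. = FALSE)
  sp <- a@spacing
  dist <- vapply(slices, function(k) {
    ai <- which(a@occupancy[, , k], arr.ind = TRUE)
    bi <- which(b@occupancy[, , k], arr.ind = TRUE)
    A <- sweep(ai - 1, 2, sp[1:2], "*")
    B <- sweep(bi - 1, 2, sp[1:2], "*")
    .minCrossDist(A, B)
  }, numeric(1))
  list(perSlice = data.frame(slice = slices, distance = dist),
       minimum = min(dist))
}
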