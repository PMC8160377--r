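## Grid geometry operations: resampling, morphological margin expansion,
## boolean mask algebra, and contour rasterization.

#' Resample a dose grid onto a new geometry
#'
#' Trilinear interpolation of the dose at the target voxel centres. Target
#' centres outside the source voxel-centre support receive 0 Gy with a
#' warning (no extrapolation).
#'
#' @param grid A [DoseGrid-class].
#' @param origin,spacing,dims Target geometry (mm, mm, voxel counts).
#' @return A [DoseGrid-class] on the target geometry, same fraction count.
#' @export
resampleTo <- function(grid, origin, spacing, dims) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("target spacing must be strictly positive", call. = FALSE)
  dims <- as.integer(dims)
  src <- grid@values
  sd <- dim(src)

  ## continuous (1-based) source index of each target voxel centre, per axis
  axisIndex <- function(k) {
    coords <- origin[k] + (seq_len(dims[k]) - 1) * spacing[k]
    (coords - grid@origin[k]) / grid@spacing[k] + 1
  }
  tx <- axisIndex(1); ty <- axisIndex(2); tz <- axisIndex(3)

  X <- array(rep(tx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ty, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(tz, each = dims[1] * dims[2]), dims)

  inside <- X >= 1 & X <= sd[1] & Y >= 1 & Y <= sd[2] & Z >= 1 & Z <= sd[3]
  if (!all(inside))
    warning("target voxels outside source support set to 0 Gy")

  i0 <- pmin(pmax(floor(X), 1L), sd[1] - 1L); fx <- X - i0
  j0 <- pmin(pmax(floor(Y), 1L), sd[2] - 1L); fy <- Y - j0
  k0 <- pmin(pmax(floor(Z), 1L), sd[3] - 1L); fz <- Z - k0
  if (sd[1] == 1L) { i0[] <- 1L; fx[] <- 0 }
  if (sd[2] == 1L) { j0[] <- 1L; fy[] <- 0 }
  if (sd[3] == 1L) { k0[] <- 1L; fz[] <- 0 }

  lin <- function(di, dj, dk) {
    ii <- pmin(i0 + di, sd[1]); jj <- pmin(j0 + dj, sd[2]); kk <- pmin(k0 + dk, sd[3])
    src[cbind(as.vector(ii), as.vector(jj), as.vector(kk))]
  }
  out <- (1 - as.vector(fx)) * (1 - as.vector(fy)) * (1 - as.vector(fz)) * lin(0, 0, 0) +
         as.vector(fx) * (1 - as.vector(fy)) * (1 - as.vector(fz)) * lin(1, 0, 0) +
         (1 - as.vector(fx)) * as.vector(fy) * (1 - as.vector(fz)) * lin(0, 1, 0) +
         as.vector(fx) * as.vector(fy) * (1 - as.vector(fz)) * lin(1, 1, 0) +
         (1 - as.vector(fx)) * (1 - as.vector(fy)) * as.vector(fz) * lin(0, 0, 1) +
         as.vector(fx) * (1 - as.vector(fy)) * as.vector(fz) * lin(1, 0, 1) +
         (1 - as.vector(fx)) * as.vector(fy) * as.vector(fz) * lin(0, 1, 1) +
         as.vector(fx) * as.vector(fy) * as.vector(fz) * lin(1, 1, 1)
  out[!as.vector(inside)] <- 0
  doseGrid(array(pmax(out, 0), dims), spacing = spacing, origin = origin,
           nFractions = grid@nFractions)
}

#' Expand a mask by an isotropic margin
#'
#' Morphological dilation with a Euclidean ball of radius `marginMm`
#' measured in millimetres; anisotropic voxel spacing is respected. An
#' output voxel is set iff its centre lies within the margin of some input
#' voxel centre. Used e.g. to derive a planning organ-at-risk volume (PRV)
#' as a 2 mm isotropic extension of the urethra.
#'
#' @param mask A [StructureMask-class].
#' @param marginMm Non-negative margin in mm; 0 returns the input unchanged.
#' @param name,role Label and role of the result (defaults keep the input's).
#' @return The dilated [StructureMask-class].
#' @export
expandMask <- function(mask, marginMm, name = mask@name, role = mask@role) {
  if (!is.finite(marginMm) || marginMm < 0)
    stop("'marginMm' must be a non-negative length in mm", call. = FALSE)
  occ <- mask@occupancy
  if (marginMm > 0) {
    sp <- mask@spacing
    r <- floor(marginMm / sp + 1e-9)
    offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
    d2 <- (offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 + (offs$dz * sp[3])^2
    offs <- offs[d2 <= marginMm^2 * (1 + 1e-12), , drop = FALSE]
    occ <- .shiftUnion(mask@occupancy, offs)
  }
  structureMask(occ, name = name, role = role,
                spacing = mask@spacing, origin = mask@origin)
}

## OR of integer-shifted copies of a logical array (out-of-range drops off)
.shiftUnion <- function(a, offs) {
  d <- dim(a)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(offs))) {
    dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    if (!length(sx) || !length(sy) || !length(sz)) next
    out[sx, sy, sz] <- out[sx, sy, sz] | a[sx - dx, sy - dy, sz - dz]
  }
  out
}

#' Voxelwise boolean combination of two masks
#'
#' @param a,b [StructureMask-class] objects on the same geometry.
#' @param op `"union"`, `"intersection"` or `"difference"` (a minus b).
#' @param name,role Label and role assigned to the result.
#' @return A [StructureMask-class].
#' @export
combineMasks <- function(a, b, op = c("union", "intersection", "difference"),
                         name = NULL, role = "OTHER") {
  op <- match.arg(op)
  .stopIfGeometryMismatch(a, b, "masks")
  occ <- switch(op,
    union = a@occupancy | b@occupancy,
    intersection = a@occupancy & b@occupancy,
    difference = a@occupancy & !b@occupancy)
  if (is.null(name)) name <- sprintf("%s_%s_%s", a@name, op, b@name)
  structureMask(occ, name = name, role = role,
                spacing = a@spacing, origin = a@origin)
}

## ---- Contour rasterization ----

## Even-odd point-in-polygon test, boundary points counted inside.
## px, py: point coords; vx, vy: polygon vertices (closed implicitly).
.pointsInPolygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    ## boundary check: point within eps of segment (i, j)
    dxs <- xj - xi; dys <- yj - yi
    len2 <- dxs^2 + dys^2
    if (len2 > 0) {
      t <- pmin(pmax(((px - xi) * dxs + (py - yi) * dys) / len2, 0), 1)
      d2 <- (px - (xi + t * dxs))^2 + (py - (yi + t * dys))^2
      onEdge <- onEdge | d2 <= eps^2
    } else {
      onEdge <- onEdge | ((px - xi)^2 + (py - yi)^2 <= eps^2)
    }
    ## even-odd crossing
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside | onEdge
}

#' Rasterize planar contours onto a reference grid
#'
#' Each contour is a closed planar polygon at constant CC coordinate, given
#' as an N x 3 matrix of (LR, AP, CC) mm coordinates. A voxel is set iff its
#' centre lies inside the polygon of its slice (even-odd rule, boundary
#' counts as inside); the slice is the one whose CC coordinate is nearest
#' the contour plane, within half a slice spacing. Several contours on one
#' slice toggle by the even-odd rule (holes supported).
#'
#' @param contours List of N x 3 numeric matrices (mm).
#' @param ref A [DoseGrid-class] supplying the geometry.
#' @param name,role Passed to the resulting mask.
#' @return A [StructureMask-class]. Contours with fewer than 3 points are
#'   skipped with a warning; an empty contour list yields an empty mask with
#'   a warning.
#' @export
rasterizeContours <- function(contours, ref, name = "mask", role = "OTHER") {
  d <- gridDims(ref)
  occ <- array(FALSE, d)
  org <- gridOrigin(ref); sp <- gridSpacing(ref)
  if (!length(contours))
    warning(sprintf("ROI '%s' has no contours; returning empty mask", name))
  xc <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  yc <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  zc <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  px <- rep(xc, times = d[2])
  py <- rep(yc, each = d[1])
  for (cm in contours) {
    cm <- as.matrix(cm)
    if (nrow(cm) < 3L) {
      warning(sprintf("degenerate contour (<3 points) in ROI '%s' skipped", name))
      next
    }
    z <- cm[1, 3]
    if (any(abs(cm[, 3] - z) > 1e-6))
      stop(sprintf("ROI '%s': contour is not planar in CC", name), call. = FALSE)
    k <- which.min(abs(zc - z))
    if (abs(zc[k] - z) > sp[3] / 2 + 1e-9 ||
        any(cm[, 1] < xc[1] - sp[1] / 2) || any(cm[, 1] > xc[d[1]] + sp[1] / 2) ||
        any(cm[, 2] < yc[1] - sp[2] / 2) || any(cm[, 2] > yc[d[2]] + sp[2] / 2))
      stop(sprintf("ROI '%s': contour lies outside the reference grid", name),
           call. = FALSE)
    ins <- .pointsInPolygon(px, py, cm[, 1], cm[, 2])
    occ[, , k] <- xor(occ[, , k], matrix(ins, d[1], d[2]))
  }
  structureMask(occ, name = name, role = role, geometry = ref)
}
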