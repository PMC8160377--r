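## Accessors and show methods.

.sameGeometry <- function(a, b, tol = 1e-6) {
  da <- if (is(a, "DoseGrid")) dim(a@values) else dim(a@occupancy)
  db <- if (is(b, "DoseGrid")) dim(b@values) else dim(b@occupancy)
  identical(da, db) &&
    all(abs(a@origin - b@origin) <= tol) &&
    all(abs(a@spacing - b@spacing) <= tol)
}

.stopIfGeometryMismatch <- function(a, b, what = "operands") {
  if (!.sameGeometry(a, b))
    stop(sprintf("geometry mismatch: %s must share origin, spacing and dims",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' @rdname DoseGrid-class
#' @export
setMethod("doseValues", "DoseGrid", function(x) x@values)

#' @rdname DoseGrid-class
#' @export
setMethod("gridOrigin", "DoseGrid", function(x) x@origin)

#' @rdname DoseGrid-class
#' @export
setMethod("gridSpacing", "DoseGrid", function(x) x@spacing)

#' @rdname DoseGrid-class
#' @export
setMethod("gridDims", "DoseGrid", function(x) dim(x@values))

#' @rdname DoseGrid-class
#' @export
setMethod("nFractions", "DoseGrid", function(x) x@nFractions)

## voxel volume in cm^3 (mm^3 / 1000)
#' @rdname DoseGrid-class
#' @export
setMethod("voxelVolume", "DoseGrid", function(x) prod(x@spacing) / 1000)

#' @rdname StructureMask-class
#' @export
setMethod("voxelVolume", "StructureMask", function(x) prod(x@spacing) / 1000)

#' @rdname DoseGrid-class
#' @export
setMethod("dosePerFraction", "DoseGrid",
          function(x) x@values / x@nFractions)

#' @rdname StructureMask-class
#' @export
setMethod("occupancy", "StructureMask", function(x) x@occupancy)

#' @rdname StructureMask-class
#' @export
setMethod("maskRole", "StructureMask", function(x) x@role)

#' @rdname StructureMask-class
#' @export
setMethod("maskVolume", "StructureMask",
          function(x) sum(x@occupancy) * prod(x@spacing) / 1000)

#' @rdname StructureMask-class
#' @export
setMethod("gridOrigin", "StructureMask", function(x) x@origin)

#' @rdname StructureMask-class
#' @export
setMethod("gridSpacing", "StructureMask", function(x) x@spacing)

#' @rdname StructureMask-class
#' @export
setMethod("gridDims", "StructureMask", function(x) dim(x@occupancy))

#' @rdname StructureSet-class
#' @export
setMethod("structureNames", "StructureSet", function(x) names(x@masks))

#' @rdname StructureSet-class
#' @param i Mask name or index.
#' @export
setMethod("[[", "StructureSet", function(x, i) x@masks[[i]])

#' @rdname StructureSet-class
#' @export
setMethod("length", "StructureSet", function(x) length(x@masks))

#' @rdname getStructure
#' @export
setMethod("getStructure", "StructureSet", function(x, role) {
  roles <- vapply(x@masks, maskRole, character(1))
  hit <- which(roles == role)
  if (!length(hit))
    stop(sprintf("no structure with role '%s' in the set (present: %s)",
                 role, paste(unique(roles), collapse = ", ")), call. = FALSE)
  x@masks[[hit[1L]]]
})

#' @rdname getStructure
#' @export
setMethod("getStructure", "PlanCase",
          function(x, role) getStructure(x@structures, role))

#' @rdname PlanCase-class
#' @export
setMethod("caseId", "PlanCase", function(x) x@caseId)

#' @rdname PlanCase-class
#' @export
setMethod("planLabel", "PlanCase", function(x) x@planLabel)

#' @rdname PlanCase-class
#' @export
setMethod("doseValues", "PlanCase", function(x) x@dose@values)

#' @rdname Cohort-class
#' @param x A Cohort.
#' @export
setMethod("length", "Cohort", function(x) length(x@cases))

#' @rdname Cohort-class
#' @param i Case index.
#' @export
setMethod("[[", "Cohort", function(x, i) x@cases[[i]])

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DoseGrid: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  dose range [%.3g, %.3g] Gy in %d fractions\n",
              min(object@values), max(object@values), object@nFractions))
})

setMethod("show", "StructureMask", function(object) {
  cat(sprintf("StructureMask '%s' (role %s): %d voxels, %.2f cm^3\n",
              object@name, object@role, sum(object@occupancy),
              maskVolume(object)))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet with %d structures\n", length(object@masks)))
  for (m in object@masks)
    cat(sprintf("  %-14s %-12s %8.2f cm^3\n", m@name, m@role, maskVolume(m)))
})

setMethod("show", "PlanCase", function(object) {
  cat(sprintf("PlanCase '%s' (%s): %d structures\n",
              object@caseId, object@planLabel,
              length(object@structures@masks)))
  show(object@dose)
})

setMethod("show", "Cohort", function(object) {
  ids <- vapply(object@cases, caseId, character(1))
  plans <- vapply(object@cases, planLabel, character(1))
  cat(sprintf("Cohort: %d plan-cases (%d cases x plans %s)\n",
              length(object@cases), length(unique(ids)),
              paste(sort(unique(plans)), collapse = "/")))
})
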