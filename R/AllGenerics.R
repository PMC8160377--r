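#' @rdname DoseGrid-class
#' @param object,x An object.
#' @export
setGeneric("doseValues", function(x) standardGeneric("doseValues"))

#' @rdname DoseGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname DoseGrid-class
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname DoseGrid-class
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname DoseGrid-class
#' @export
setGeneric("nFractions", function(x) standardGeneric("nFractions"))

#' @rdname DoseGrid-class
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname DoseGrid-class
#' @export
setGeneric("dosePerFraction", function(x) standardGeneric("dosePerFraction"))

#' @rdname StructureMask-class
#' @param x An object.
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname StructureMask-class
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @rdname StructureMask-class
#' @export
setGeneric("maskRole", function(x) standardGeneric("maskRole"))

#' @rdname StructureSet-class
#' @param x An object.
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' Retrieve a structure by role
#'
#' @param x A [StructureSet-class] or [PlanCase-class].
#' @param role One of [structureRoles()].
#' @return The matching [StructureMask-class], or an error listing the role
#'   if absent.
#' @export
setGeneric("getStructure", function(x, role) standardGeneric("getStructure"))

#' @rdname PlanCase-class
#' @param x An object.
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname PlanCase-class
#' @export
setGeneric("planLabel", function(x) standardGeneric("planLabel"))
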