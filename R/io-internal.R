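## Internal case bundle: `case.json` header plus raw array payloads.
## Dose: float64, little-endian, LR index fastest, then AP, then CC
## (i.e. the natural R array order of dims (LR, AP, CC)). Masks: one byte
## per voxel (0/1), same ordering.

.CASE_SCHEMA <- "rtOutcome-case/1"

#' Write a plan case to an internal case bundle
#'
#' Lossless on-disk representation: a JSON header (`case.json`) carrying
#' geometry, schedule, roles and the schema version, a `dose.bin` float64
#' payload and one `<name>.mask.bin` byte payload per structure.
#'
#' @param case A [PlanCase-class].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
writeCase <- function(case, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  masks <- case@structures@masks
  header <- list(
    schema = .CASE_SCHEMA,
    case_id = caseId(case),
    plan_label = planLabel(case),
    origin = gridOrigin(case@dose),
    spacing = gridSpacing(case@dose),
    dims = gridDims(case@dose),
    n_fractions = nFractions(case@dose),
    storage = list(byte_order = "little",
                   dose_dtype = "float64",
                   mask_dtype = "uint8",
                   order = "LR fastest, then AP, then CC"),
    structures = lapply(names(masks), function(nm)
      list(name = nm, role = maskRole(masks[[nm]]),
           file = paste0(nm, ".mask.bin"))))
  jsonlite::write_json(header, file.path(path, "case.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "dose.bin"), "wb")
  writeBin(as.vector(case@dose@values), con, size = 8L, endian = "little")
  close(con)
  for (nm in names(masks)) {
    con <- file(file.path(path, paste0(nm, ".mask.bin")), "wb")
    writeBin(as.raw(as.integer(masks[[nm]]@occupancy)), con)
    close(con)
  }
  invisible(path)
}

#' Read a plan case from an internal case bundle
#'
#' @param path Directory written by [writeCase()].
#' @return The reconstructed [PlanCase-class]. Errors on a schema-version
#'   mismatch or a header missing the fraction count.
#' @export
readCase <- function(path) {
  hf <- file.path(path, "case.json")
  if (!file.exists(hf)) stop(sprintf("no case.json in '%s'", path), call. = FALSE)
  header <- jsonlite::read_json(hf, simplifyVector = TRUE)
  if (is.null(header$schema) || !identical(header$schema, .CASE_SCHEMA))
    stop(sprintf("case bundle schema mismatch: found '%s', expected '%s'",
                 header$schema %||% "<none>", .CASE_SCHEMA), call. = FALSE)
  if (is.null(header$n_fractions))
    stop("case header is missing 'n_fractions'", call. = FALSE)
  dims <- as.integer(header$dims)
  nvox <- prod(dims)
  con <- file(file.path(path, "dose.bin"), "rb")
  vals <- readBin(con, "double", n = nvox, size = 8L, endian = "little")
  close(con)
  dose <- doseGrid(array(vals, dims), spacing = header$spacing,
                   origin = header$origin,
                   nFractions = header$n_fractions)
  st <- header$structures
  masks <- lapply(seq_len(nrow(st)), function(i) {
    con <- file(file.path(path, st$file[i]), "rb")
    occ <- as.integer(readBin(con, "raw", n = nvox))
    close(con)
    structureMask(array(occ > 0L, dims), name = st$name[i], role = st$role[i],
                  spacing = header$spacing, origin = header$origin)
  })
  names(masks) <- st$name
  planCase(header$case_id, header$plan_label, dose, structureSet(masks))
}

#' Write / read a whole cohort of case bundles
#'
#' One subdirectory per plan-case, named `<caseId>_<planLabel>`.
#'
#' @param cohort A [Cohort-class].
#' @param path Directory.
#' @return `writeCohort()`: `path` invisibly; `readCohort()`: the
#'   [Cohort-class].
#' @export
writeCohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort@cases)
    writeCase(case, file.path(path, paste(caseId(case), planLabel(case),
                                          sep = "_")))
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  dirs <- sort(list.dirs(path, recursive = FALSE))
  if (!length(dirs)) stop(sprintf("no case bundles under '%s'", path),
                          call. = FALSE)
  cohort(lapply(dirs, readCase))
}
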