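## Minimal DICOM RT Dose / RT Structure Set I/O for one common dialect:
## explicit VR little endian, axis-aligned (identity orientation) grids,
## uniform frame offsets, grid scaling. Oblique orientations, compressed
## transfer syntaxes and implicit VR are rejected rather than guessed.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
.SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

## ---- low-level raw encoding ----

.rawU16 <- function(x) {
  x <- as.integer(x)
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2L, endian = "little")
}

.rawU32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")

.u16 <- function(raw, pos)
  readBin(raw[pos + 0:1], "integer", size = 2L, signed = FALSE,
          endian = "little")

.u32 <- function(raw, pos) {
  v <- readBin(raw[pos + 0:3], "integer", size = 4L, endian = "little")
  if (v < 0) v + 2^32 else as.double(v)
}

.evenPad <- function(payload, pad = as.raw(0x20))
  if (length(payload) %% 2L) c(payload, pad) else payload

.dicomEl <- function(group, element, vr, payload) {
  head <- c(.rawU16(group), .rawU16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0, 0)), .rawU32(length(payload)), payload)
  else
    c(head, .rawU16(length(payload)), payload)
}

.elStr <- function(group, element, vr, s) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  .dicomEl(group, element, vr, .evenPad(charToRaw(s), pad))
}

.fmtDS <- function(x) {
  s <- vapply(x, function(v) formatC(v, digits = 10, format = "g",
                                     flag = ""), character(1))
  paste(trimws(s), collapse = "\\")
}

.elDS <- function(group, element, x) .elStr(group, element, "DS", .fmtDS(x))
.elIS <- function(group, element, x)
  .elStr(group, element, "IS", paste(as.integer(x), collapse = "\\"))
.elUS <- function(group, element, x) .dicomEl(group, element, "US", .rawU16(x))

.sqItem <- function(content)
  c(.rawU16(0xFFFE), .rawU16(0xE000), .rawU32(length(content)), content)

.elSQ <- function(group, element, items)
  .dicomEl(group, element, "SQ", do.call(c, items))

.dicomFile <- function(path, sopClass, sopInstance, body) {
  meta <- c(.dicomEl(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
            .elStr(0x0002, 0x0002, "UI", sopClass),
            .elStr(0x0002, 0x0003, "UI", sopInstance),
            .elStr(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"),
             .dicomEl(0x0002, 0x0000, "UL", .rawU32(length(meta))),
             meta, body), con)
  invisible(path)
}

## ---- low-level parsing ----

.parseDataset <- function(raw, pos, end) {
  els <- list()
  while (pos < end) {
    g <- .u16(raw, pos); e <- .u16(raw, pos + 2L)
    if (g == 0xFFFE) break            # item/sequence delimiter: caller's job
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- .u32(raw, pos + 8L); hdr <- 12L
    } else {
      len <- .u16(raw, pos + 6L); hdr <- 8L
    }
    tag <- sprintf("%04X%04X", g, e)
    if (vr == "SQ") {
      res <- .parseItems(raw, pos + hdr,
                         if (len == 4294967295) end else pos + hdr + len,
                         undefined = len == 4294967295)
      els[[tag]] <- list(vr = vr, items = res$items)
      pos <- res$pos
    } else {
      if (len == 4294967295)
        stop("undefined length outside a sequence is unsupported",
             call. = FALSE)
      els[[tag]] <- list(vr = vr,
                         value = raw[seq.int(pos + hdr, length.out = len)])
      pos <- pos + hdr + len
    }
  }
  list(els = els, pos = pos)
}

.parseItems <- function(raw, pos, end, undefined) {
  items <- list()
  while (pos < end) {
    g <- .u16(raw, pos); e <- .u16(raw, pos + 2L)
    len <- .u32(raw, pos + 4L)
    if (g == 0xFFFE && e == 0xE0DD) { pos <- pos + 8L; break }
    if (!(g == 0xFFFE && e == 0xE000))
      stop("malformed DICOM sequence item", call. = FALSE)
    if (len == 4294967295) {
      res <- .parseDataset(raw, pos + 8L, end)
      items[[length(items) + 1L]] <- res$els
      pos <- res$pos + 8L              # skip the item delimiter
    } else {
      res <- .parseDataset(raw, pos + 8L, pos + 8L + len)
      items[[length(items) + 1L]] <- res$els
      pos <- pos + 8L + len
    }
  }
  list(items = items, pos = pos)
}

.parseDicomFile <- function(path) {
  if (!file.exists(path))
    stop(sprintf("DICOM file '%s' does not exist", path), call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM file (no DICM marker)", path),
         call. = FALSE)
  ds <- .parseDataset(raw, 133L, length(raw) + 1L)
  ts <- ds$els[["00020010"]]
  if (!is.null(ts) && .valStr(ts) != .TS_EXPLICIT_LE)
    stop(sprintf("unsupported transfer syntax '%s' (only explicit VR little endian)",
                 .valStr(ts)), call. = FALSE)
  ds$els
}

.valStr <- function(el) {
  v <- el$value
  while (length(v) && v[length(v)] == as.raw(0)) v <- v[-length(v)]
  sub(" +$", "", rawToChar(v))
}
.valDS <- function(el) as.numeric(strsplit(.valStr(el), "\\\\")[[1]])
.valIS <- function(el) as.integer(strsplit(.valStr(el), "\\\\")[[1]])
.valUS <- function(el)
  readBin(el$value, "integer", n = length(el$value) / 2L, size = 2L,
          signed = FALSE, endian = "little")

.need <- function(els, tag, what) {
  el <- els[[tag]]
  if (is.null(el)) stop(sprintf("DICOM object is missing %s", what),
                        call. = FALSE)
  el
}

## ---- RT Dose ----

#' Write a dose grid as a DICOM RT Dose file
#'
#' Explicit VR little endian, identity orientation, 32-bit unsigned pixels
#' scaled by a dose-grid scaling factor.
#'
#' @param dose A [DoseGrid-class].
#' @param path Output file.
#' @param scaling Gy per stored unit; default spans the dose range with
#'   about 1e6 levels.
#' @return `path`, invisibly.
#' @export
writeRTDose <- function(dose, path, scaling = NULL) {
  v <- dose@values
  d <- dim(v)
  if (is.null(scaling)) scaling <- if (max(v) > 0) max(v) / 1e6 else 1e-3
  stored <- round(as.vector(v) / scaling)
  if (any(stored > 2^31 - 1))
    stop("'scaling' too small for the dose range", call. = FALSE)
  sp <- dose@spacing; org <- dose@origin
  body <- c(
    .elStr(0x0008, 0x0016, "UI", .SOP_RTDOSE),
    .elStr(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9.7766.1.1"),
    .elStr(0x0008, 0x0060, "CS", "RTDOSE"),
    .elDS(0x0020, 0x0032, org),
    .elDS(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    .elUS(0x0028, 0x0002, 1),
    .elStr(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .elIS(0x0028, 0x0008, d[3]),
    .elUS(0x0028, 0x0010, d[2]),      # Rows = AP count
    .elUS(0x0028, 0x0011, d[1]),      # Columns = LR count
    .elDS(0x0028, 0x0030, c(sp[2], sp[1])),  # row spacing \ column spacing
    .elUS(0x0028, 0x0100, 32),
    .elUS(0x0028, 0x0101, 32),
    .elUS(0x0028, 0x0102, 31),
    .elUS(0x0028, 0x0103, 0),
    .elStr(0x3004, 0x0002, "CS", "GY"),
    .elStr(0x3004, 0x0004, "CS", "PHYSICAL"),
    .elStr(0x3004, 0x000A, "CS", "PLAN"),
    .elDS(0x3004, 0x000C, (seq_len(d[3]) - 1) * sp[3]),
    .elDS(0x3004, 0x000E, scaling),
    .dicomEl(0x7FE0, 0x0010, "OW", .rawU32(stored)))
  .dicomFile(path, .SOP_RTDOSE, "1.2.826.0.1.3680043.9.7766.1.1", body)
}

#' Read a DICOM RT Dose file
#'
#' Supports the explicit-VR little-endian dialect written by
#' [writeRTDose()] and common planning-system exports: identity image
#' orientation, uniform grid-frame offsets, dose-grid scaling, 16- or
#' 32-bit unsigned pixel data. Anything else is rejected with an explicit
#' message. The fraction count is not a DICOM RT Dose attribute and must be
#' supplied.
#'
#' @param path DICOM RT Dose file.
#' @param nFractions Fraction count to attach to the grid (default 20).
#' @return A [DoseGrid-class] with axes (LR, AP, CC) and values in Gy.
#' @export
readRTDose <- function(path, nFractions = 20L) {
  els <- .parseDicomFile(path)
  iop <- .valDS(.need(els, "00200037", "image orientation"))
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("oblique image orientations are not supported", call. = FALSE)
  scaling <- .valDS(.need(els, "3004000E", "dose-grid scaling"))
  org <- .valDS(.need(els, "00200032", "image position"))
  ps <- .valDS(.need(els, "00280030", "pixel spacing"))
  rows <- .valUS(.need(els, "00280010", "Rows"))
  cols <- .valUS(.need(els, "00280011", "Columns"))
  nframes <- .valIS(.need(els, "00280008", "NumberOfFrames"))
  bits <- .valUS(.need(els, "00280100", "BitsAllocated"))
  gfov <- .valDS(.need(els, "3004000C", "grid frame offset vector"))
  if (length(gfov) != nframes)
    stop("grid frame offset vector length disagrees with NumberOfFrames",
         call. = FALSE)
  dz <- if (nframes > 1) {
    steps <- diff(gfov)
    if (max(abs(steps - steps[1])) > 1e-6)
      stop("non-uniform grid frame offsets are not supported", call. = FALSE)
    steps[1]
  } else 1.0
  pix <- .need(els, "7FE00010", "pixel data")$value
  stored <- if (bits == 16L) {
    readBin(pix, "integer", n = length(pix) / 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else if (bits == 32L) {
    v <- readBin(pix, "integer", n = length(pix) / 4L, size = 4L,
                 endian = "little")
    ifelse(v < 0, v + 2^32, as.double(v))
  } else stop(sprintf("unsupported BitsAllocated = %d", bits), call. = FALSE)
  if (length(stored) != cols * rows * nframes)
    stop("pixel data size disagrees with Rows x Columns x NumberOfFrames",
         call. = FALSE)
  doseGrid(array(stored * scaling, c(cols, rows, nframes)),
           spacing = c(ps[2], ps[1], dz), origin = org,
           nFractions = nFractions)
}

## ---- RT Structure Set ----

#' Write contours as a DICOM RT Structure Set
#'
#' @param rois Named list; each element is one ROI given as a list of
#'   closed planar contours, each an N x 3 matrix of (LR, AP, CC) mm
#'   coordinates.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeRTStruct <- function(rois, path) {
  nums <- seq_along(rois)
  ssItems <- lapply(nums, function(i)
    .sqItem(c(.elIS(0x3006, 0x0022, i),
              .elStr(0x3006, 0x0026, "LO", names(rois)[i]))))
  rcItems <- lapply(nums, function(i) {
    cItems <- lapply(rois[[i]], function(cm) {
      cm <- as.matrix(cm)
      .sqItem(c(.elStr(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
                .elIS(0x3006, 0x0046, nrow(cm)),
                .elDS(0x3006, 0x0050, as.vector(t(cm)))))
    })
    inner <- if (length(cItems)) .elSQ(0x3006, 0x0040, cItems) else raw(0)
    .sqItem(c(inner, .elIS(0x3006, 0x0084, i)))
  })
  body <- c(
    .elStr(0x0008, 0x0016, "UI", .SOP_RTSTRUCT),
    .elStr(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9.7766.1.2"),
    .elStr(0x0008, 0x0060, "CS", "RTSTRUCT"),
    .elSQ(0x3006, 0x0020, ssItems),
    .elSQ(0x3006, 0x0039, rcItems))
  .dicomFile(path, .SOP_RTSTRUCT, "1.2.826.0.1.3680043.9.7766.1.2", body)
}

#' Read a DICOM RT Structure Set and rasterize it onto a grid
#'
#' Each ROI's closed planar contours are rasterized onto the reference dose
#' grid with the voxel-centre / even-odd rule (see [rasterizeContours()]).
#' Contours outside the grid raise an error naming the ROI; an ROI without
#' contours yields an empty mask with a warning.
#'
#' @param path DICOM RT Structure Set file.
#' @param ref Reference [DoseGrid-class].
#' @param roles Optional named character vector mapping ROI name to a role
#'   from [structureRoles()]; unmapped ROIs get role `"OTHER"`.
#' @return A [StructureSet-class].
#' @export
readRTStruct <- function(path, ref, roles = NULL) {
  els <- .parseDicomFile(path)
  ss <- .need(els, "30060020", "StructureSetROISequence")$items
  names_by_num <- list()
  for (it in ss) {
    num <- .valIS(.need(it, "30060022", "ROINumber"))
    names_by_num[[as.character(num)]] <-
      .valStr(.need(it, "30060026", "ROIName"))
  }
  rc <- .need(els, "30060039", "ROIContourSequence")$items
  masks <- list()
  for (it in rc) {
    num <- .valIS(.need(it, "30060084", "ReferencedROINumber"))
    nm <- names_by_num[[as.character(num)]] %||% sprintf("roi%d", num)
    cseq <- it[["30060040"]]
    contours <- if (is.null(cseq)) list() else lapply(cseq$items, function(ci) {
      pts <- .valDS(.need(ci, "30060050", "ContourData"))
      matrix(pts, ncol = 3L, byrow = TRUE)
    })
    role <- if (!is.null(roles) && nm %in% names(roles)) roles[[nm]] else "OTHER"
    masks[[nm]] <- rasterizeContours(contours, ref, name = nm, role = role)
  }
  structureSet(masks)
}
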