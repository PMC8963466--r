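# Minimal DICOM Part-10 codec: explicit VR little endian only, with nested
# sequences (defined or undefined length). Covers the subset of the standard
# needed for RT Plan / RT Dose objects; unknown elements survive a read/write
# round trip untouched.

.DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
.UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
# Non-clinical UID root reserved for locally generated synthetic objects.
.UID_ROOT <- "1.2.826.0.1.3680043.10.9999."

# tag dictionary: keyword -> c(group, element, VR)
.dcm_dict <- list(
  FileMetaInformationVersion = c(0x0002, 0x0001, "OB"),
  MediaStorageSOPClassUID    = c(0x0002, 0x0002, "UI"),
  MediaStorageSOPInstanceUID = c(0x0002, 0x0003, "UI"),
  TransferSyntaxUID          = c(0x0002, 0x0010, "UI"),
  ImplementationClassUID     = c(0x0002, 0x0012, "UI"),
  SOPClassUID        = c(0x0008, 0x0016, "UI"),
  SOPInstanceUID     = c(0x0008, 0x0018, "UI"),
  Modality           = c(0x0008, 0x0060, "CS"),
  Manufacturer       = c(0x0008, 0x0070, "LO"),
  SeriesDescription  = c(0x0008, 0x103E, "LO"),
  PatientName        = c(0x0010, 0x0010, "PN"),
  PatientID          = c(0x0010, 0x0020, "LO"),
  ImagePositionPatient    = c(0x0020, 0x0032, "DS"),
  ImageOrientationPatient = c(0x0020, 0x0037, "DS"),
  SamplesPerPixel      = c(0x0028, 0x0002, "US"),
  PhotometricInterpretation = c(0x0028, 0x0004, "CS"),
  NumberOfFrames       = c(0x0028, 0x0008, "IS"),
  Rows                 = c(0x0028, 0x0010, "US"),
  Columns              = c(0x0028, 0x0011, "US"),
  PixelSpacing         = c(0x0028, 0x0030, "DS"),
  BitsAllocated        = c(0x0028, 0x0100, "US"),
  BitsStored           = c(0x0028, 0x0101, "US"),
  HighBit              = c(0x0028, 0x0102, "US"),
  PixelRepresentation  = c(0x0028, 0x0103, "US"),
  FluenceMode          = c(0x3002, 0x0051, "CS"),
  FluenceModeID        = c(0x3002, 0x0052, "SH"),
  PrimaryFluenceModeSequence = c(0x3002, 0x0050, "SQ"),
  DoseUnits            = c(0x3004, 0x0002, "CS"),
  DoseType             = c(0x3004, 0x0004, "CS"),
  DoseSummationType    = c(0x3004, 0x000A, "CS"),
  GridFrameOffsetVector = c(0x3004, 0x000C, "DS"),
  DoseGridScaling      = c(0x3004, 0x000E, "DS"),
  RTPlanLabel          = c(0x300A, 0x0002, "SH"),
  RTPlanName           = c(0x300A, 0x0003, "LO"),
  DoseReferenceSequence = c(0x300A, 0x0010, "SQ"),
  DoseReferenceDescription = c(0x300A, 0x0016, "LO"),
  DoseReferencePointCoordinates = c(0x300A, 0x0018, "DS"),
  FractionGroupSequence = c(0x300A, 0x0070, "SQ"),
  NumberOfFractionsPlanned = c(0x300A, 0x0078, "IS"),
  NumberOfBeams        = c(0x300A, 0x0080, "IS"),
  BeamSequence         = c(0x300A, 0x00B0, "SQ"),
  TreatmentMachineName = c(0x300A, 0x00B2, "SH"),
  SourceAxisDistance   = c(0x300A, 0x00B4, "DS"),
  BeamLimitingDeviceSequence = c(0x300A, 0x00B6, "SQ"),
  RTBeamLimitingDeviceType = c(0x300A, 0x00B8, "CS"),
  NumberOfLeafJawPairs = c(0x300A, 0x00BC, "IS"),
  LeafPositionBoundaries = c(0x300A, 0x00BE, "DS"),
  BeamNumber           = c(0x300A, 0x00C0, "IS"),
  BeamName             = c(0x300A, 0x00C2, "LO"),
  BeamDescription      = c(0x300A, 0x00C3, "ST"),
  BeamType             = c(0x300A, 0x00C4, "CS"),
  RadiationType        = c(0x300A, 0x00C6, "CS"),
  FinalCumulativeMetersetWeight = c(0x300A, 0x010E, "DS"),
  NumberOfControlPoints = c(0x300A, 0x0110, "IS"),
  ControlPointSequence = c(0x300A, 0x0111, "SQ"),
  ControlPointIndex    = c(0x300A, 0x0112, "IS"),
  NominalBeamEnergy    = c(0x300A, 0x0114, "DS"),
  BeamLimitingDevicePositionSequence = c(0x300A, 0x011A, "SQ"),
  LeafJawPositions     = c(0x300A, 0x011C, "DS"),
  GantryAngle          = c(0x300A, 0x011E, "DS"),
  BeamLimitingDeviceAngle = c(0x300A, 0x0120, "DS"),
  IsocenterPosition    = c(0x300A, 0x012C, "DS"),
  CumulativeMetersetWeight = c(0x300A, 0x0134, "DS"),
  ReferencedBeamSequence = c(0x300C, 0x0004, "SQ"),
  BeamMeterset         = c(0x300A, 0x0086, "DS"),
  ReferencedBeamNumber = c(0x300C, 0x0006, "IS"),
  PixelData            = c(0x7FE0, 0x0010, "OW")
)

.dcm_tag_key <- function(group, element) {
  sprintf("%04X%04X", group, element)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an element: list(group, element, vr, value); SQ value = list of datasets
# a dataset: named list (by tag key) of elements
dcm_element <- function(keyword, value) {
  e <- .dcm_dict[[keyword]]
  if (is.null(e)) stop("unknown DICOM keyword: ", keyword)
  list(group = as.integer(e[1]), element = as.integer(e[2]), vr = e[3],
       keyword = keyword, value = value)
}

dcm_dataset <- function(...) {
  els <- list(...)
  ds <- list()
  for (el in els) ds[[.dcm_tag_key(el$group, el$element)]] <- el
  ds
}

dcm_get <- function(ds, keyword, default = NULL) {
  e <- .dcm_dict[[keyword]]
  if (is.null(e)) stop("unknown DICOM keyword: ", keyword)
  el <- ds[[.dcm_tag_key(as.integer(e[1]), as.integer(e[2]))]]
  if (is.null(el)) default else el$value
}

dcm_has <- function(ds, keyword) {
  e <- .dcm_dict[[keyword]]
  !is.null(ds[[.dcm_tag_key(as.integer(e[1]), as.integer(e[2]))]])
}

## ---- value serialization -------------------------------------------------

# DS values are limited to 16 bytes each by the standard
.ds_fmt <- function(x) {
  s <- formatC(x, format = "g", digits = 10, width = 1)
  s <- trimws(s)
  too_long <- nchar(s) > 16
  if (any(too_long)) {
    s[too_long] <- trimws(formatC(x[too_long], format = "g", digits = 8, width = 1))
  }
  s
}

.dcm_encode_value <- function(vr, value) {
  if (vr %in% c("DS")) {
    raw_s <- charToRaw(paste(.ds_fmt(as.numeric(value)), collapse = "\\"))
  } else if (vr %in% c("IS")) {
    raw_s <- charToRaw(paste(format(as.integer(value)), collapse = "\\"))
  } else if (vr %in% c("UI")) {
    raw_s <- charToRaw(paste(as.character(value), collapse = "\\"))
    if (length(raw_s) %% 2L == 1L) raw_s <- c(raw_s, as.raw(0L))  # UI pads with NUL
    return(raw_s)
  } else if (vr %in% c("CS", "SH", "LO", "ST", "PN", "LT", "AE", "DA", "TM")) {
    raw_s <- charToRaw(paste(as.character(value), collapse = "\\"))
  } else if (vr == "US") {
    return(writeBin(as.integer(value), raw(), size = 2L, endian = "little"))
  } else if (vr == "UL") {
    return(writeBin(as.integer(value), raw(), size = 4L, endian = "little"))
  } else if (vr == "FD") {
    return(writeBin(as.numeric(value), raw(), size = 8L, endian = "little"))
  } else if (vr == "FL") {
    return(writeBin(as.numeric(value), raw(), size = 4L, endian = "little"))
  } else if (vr %in% c("OB", "OW")) {
    if (is.raw(value)) return(value)
    # integer payload written as 32-bit words (dose pixel data convention here)
    return(writeBin(as.integer(value), raw(), size = 4L, endian = "little"))
  } else {
    stop("unsupported VR for encoding: ", vr)
  }
  if (length(raw_s) %% 2L == 1L) raw_s <- c(raw_s, charToRaw(" "))
  raw_s
}

.dcm_decode_value <- function(vr, bytes) {
  if (vr %in% c("DS", "IS")) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    parts <- strsplit(trimws(s), "\\", fixed = TRUE)[[1]]
    v <- as.numeric(trimws(parts))
    if (vr == "IS") v <- as.integer(v)
    return(v)
  }
  if (vr %in% c("UI", "CS", "SH", "LO", "ST", "PN", "LT", "AE", "DA", "TM")) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    return(trimws(strsplit(s, "\\", fixed = TRUE)[[1]]))
  }
  if (vr == "US") return(readBin(bytes, "integer", n = length(bytes) / 2L,
                                 size = 2L, signed = FALSE, endian = "little"))
  if (vr == "UL") return(readBin(bytes, "integer", n = length(bytes) / 4L,
                                 size = 4L, endian = "little"))
  if (vr == "FD") return(readBin(bytes, "double", n = length(bytes) / 8L,
                                 size = 8L, endian = "little"))
  if (vr == "FL") return(readBin(bytes, "double", n = length(bytes) / 4L,
                                 size = 4L, endian = "little"))
  bytes  # OB/OW/unknown kept raw
}

## ---- element / dataset writer -------------------------------------------

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(.u16(lo), .u16(hi))
}

.dcm_write_element <- function(el) {
  vr <- el$vr
  if (vr == "SQ") {
    body <- raw()
    for (item_ds in el$value) {
      item_body <- .dcm_write_dataset(item_ds)
      body <- c(body,
                .u16(0xFFFE), .u16(0xE000), .u32(4294967295),  # item, undefined length
                item_body,
                .u16(0xFFFE), .u16(0xE00D), .u32(0))           # item delimiter
    }
    body <- c(body, .u16(0xFFFE), .u16(0xE0DD), .u32(0))        # sequence delimiter
    return(c(.u16(el$group), .u16(el$element), charToRaw("SQ"),
             as.raw(c(0, 0)), .u32(4294967295), body))
  }
  payload <- .dcm_encode_value(vr, el$value)
  head <- c(.u16(el$group), .u16(el$element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .u32(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stop("value too long for short-form VR ", vr)
    c(head, .u16(length(payload)), payload)
  }
}

.dcm_write_dataset <- function(ds) {
  keys <- names(ds)
  ord <- order(keys)  # ascending tag order as hex keys sort lexicographically
  out <- vector("list", length(ds))
  for (i in seq_along(ord)) out[[i]] <- .dcm_write_element(ds[[ord[i]]])
  do.call(c, out) %||% raw()
}

#' @keywords internal
dcm_write_file <- function(path, dataset, sop_class_uid, sop_instance_uid) {
  meta <- dcm_dataset(
    dcm_element("FileMetaInformationVersion", as.raw(c(0, 1))),
    dcm_element("MediaStorageSOPClassUID", sop_class_uid),
    dcm_element("MediaStorageSOPInstanceUID", sop_instance_uid),
    dcm_element("TransferSyntaxUID", .DICOM_EXPLICIT_LE),
    dcm_element("ImplementationClassUID", paste0(.UID_ROOT, "1"))
  )
  meta_bytes <- .dcm_write_dataset(meta)
  # (0002,0000) group length, UL
  gl <- c(.u16(0x0002), .u16(0x0000), charToRaw("UL"), .u16(4L),
          .u32(length(meta_bytes)))
  body <- .dcm_write_dataset(dataset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(gl, meta_bytes, body), con)
  invisible(path)
}

## ---- reader ---------------------------------------------------------------

.dcm_rd_u16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
.dcm_rd_u32 <- function(buf, pos) {
  v <- readBin(buf[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 4294967296
  v
}

# parse elements from buf[pos..limit]; returns list(ds, pos). Stops early when
# an item-delimiter tag is met (used by sequence item parsing).
.dcm_parse <- function(buf, pos, limit) {
  ds <- list()
  while (pos <= limit) {
    group <- .dcm_rd_u16(buf, pos)
    element <- .dcm_rd_u16(buf, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) {
      len <- .dcm_rd_u32(buf, pos); pos <- pos + 4L
      if (element == 0xE00D || element == 0xE0DD) return(list(ds = ds, pos = pos,
                                                             delim = element))
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(buf[pos:(pos + 1L)]); pos <- pos + 2L
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      pos <- pos + 2L  # reserved
      len <- .dcm_rd_u32(buf, pos); pos <- pos + 4L
    } else {
      len <- .dcm_rd_u16(buf, pos); pos <- pos + 2L
    }
    key <- .dcm_tag_key(group, element)
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) {
        repeat {
          g <- .dcm_rd_u16(buf, pos); e <- .dcm_rd_u16(buf, pos + 2L)
          l <- .dcm_rd_u32(buf, pos + 4L); pos <- pos + 8L
          if (g == 0xFFFE && e == 0xE0DD) break
          if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence")
          if (l == 4294967295) {
            r <- .dcm_parse(buf, pos, length(buf))
            if (is.null(r$delim) || r$delim != 0xE00D) stop("missing item delimiter")
            items[[length(items) + 1L]] <- r$ds
            pos <- r$pos
          } else {
            r <- .dcm_parse(buf, pos, pos + l - 1L)
            items[[length(items) + 1L]] <- r$ds
            pos <- pos + l
          }
        }
      } else {
        end <- pos + len - 1L
        while (pos <= end) {
          g <- .dcm_rd_u16(buf, pos); e <- .dcm_rd_u16(buf, pos + 2L)
          l <- .dcm_rd_u32(buf, pos + 4L); pos <- pos + 8L
          if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence")
          if (l == 4294967295) {
            r <- .dcm_parse(buf, pos, end)
            items[[length(items) + 1L]] <- r$ds
            pos <- r$pos
          } else {
            r <- .dcm_parse(buf, pos, pos + l - 1L)
            items[[length(items) + 1L]] <- r$ds
            pos <- pos + l
          }
        }
      }
      ds[[key]] <- list(group = group, element = element, vr = "SQ",
                        value = items)
    } else {
      bytes <- if (len > 0) buf[pos:(pos + len - 1L)] else raw()
      pos <- pos + len
      ds[[key]] <- list(group = group, element = element, vr = vr,
                        value = .dcm_decode_value(vr, bytes))
    }
  }
  list(ds = ds, pos = pos, delim = NULL)
}

#' @keywords internal
dcm_read_file <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  pos <- 133L
  # file meta group (always explicit LE); read group length to skip precisely
  group <- .dcm_rd_u16(buf, pos); element <- .dcm_rd_u16(buf, pos + 2L)
  if (group != 0x0002 || element != 0x0000) stop("missing file meta group length")
  meta_len <- .dcm_rd_u32(buf, pos + 8L)
  meta <- .dcm_parse(buf, pos + 12L, pos + 11L + meta_len)$ds
  ts <- dcm_get(meta, "TransferSyntaxUID")
  if (!identical(ts, .DICOM_EXPLICIT_LE))
    stop("unsupported transfer syntax: ", ts)
  pos <- pos + 12L + meta_len
  body <- .dcm_parse(buf, pos, length(buf))$ds
  attr(body, "meta") <- meta
  body
}
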