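# Domain model for vendor-dialect-tagged RT plans and 3D dose grids.
#
# Unit conventions (used throughout the package):
#   * MLC / jaw / aperture positions: cm, at the isocenter-projection plane of
#     the owning dialect (Monaco: 143.5 cm SAD plane, Eclipse: 100 cm plane).
#     DICOM millimetres are converted at the file boundary.
#   * Patient-space coordinates, grid origins/spacings, plane lattices: mm.
#   * Dose: Gy in grids and planes; monitor units as given.

MONACO_SAD_CM <- 143.5
ECLIPSE_SAD_CM <- 100.0
MONACO_JAW_HALF_CM <- 11.0   # fixed 22 cm superior-inferior jaw extent

#' MLC aperture geometry
#'
#' Describes the leaf bank of the machine as projected to the isocenter plane:
#' leaf-pair edge positions along the stacking (superior-inferior) direction
#' and the maximum half field in the leaf-travel direction. The default is a
#' high-field MR-Linac-like bank: a fixed 22 cm stacking extent divided into
#' 31 pairs of ~7 mm projected width, with an 11 cm half field.
#'
#' @param n_leaf_pairs number of leaf pairs.
#' @param leaf_boundaries `n_leaf_pairs + 1` strictly increasing pair edge
#'   positions, cm at the isocenter plane.
#' @param max_half_field maximum half field in the leaf-travel direction, cm.
#' @return an object of class `aperture_geometry`.
#' @export
aperture_geometry <- function(n_leaf_pairs = 31L,
                              leaf_boundaries = seq(-11, 11,
                                                    length.out = n_leaf_pairs + 1L),
                              max_half_field = 11.0) {
  n_leaf_pairs <- as.integer(n_leaf_pairs)
  stopifnot(n_leaf_pairs >= 1L,
            length(leaf_boundaries) == n_leaf_pairs + 1L,
            all(diff(leaf_boundaries) > 0),
            max_half_field > 0)
  structure(list(n_leaf_pairs = n_leaf_pairs,
                 leaf_boundaries = as.numeric(leaf_boundaries),
                 max_half_field = max_half_field),
            class = "aperture_geometry")
}

#' Control point (segment) of a beam
#'
#' @param mu_weight fraction of the beam MU delivered in this segment, in
#'   `[0, 1]`; segment weights of a beam sum to 1.
#' @param bank_a,bank_b per-leaf-pair positions of the lower (A) and upper (B)
#'   banks along the leaf-travel direction, cm at the isocenter plane;
#'   `bank_a[i] <= bank_b[i]` for every open pair.
#' @param jaw_x optional `(x1, x2)` jaw pair, cm (absent in the Monaco dialect).
#' @param jaw_y `(y1, y2)` jaw pair, cm; fixed at +/-11 in the Monaco dialect.
#' @return an object of class `control_point_record`.
#' @export
control_point_record <- function(mu_weight, bank_a, bank_b,
                                 jaw_x = NULL,
                                 jaw_y = c(-MONACO_JAW_HALF_CM,
                                           MONACO_JAW_HALF_CM)) {
  stopifnot(length(bank_a) == length(bank_b),
            is.numeric(mu_weight), length(mu_weight) == 1L)
  if (!is.null(jaw_x)) stopifnot(length(jaw_x) == 2L)
  stopifnot(length(jaw_y) == 2L)
  structure(list(mu_weight = as.numeric(mu_weight),
                 bank_a = as.numeric(bank_a), bank_b = as.numeric(bank_b),
                 jaw_x = if (is.null(jaw_x)) NULL else as.numeric(jaw_x),
                 jaw_y = as.numeric(jaw_y)),
            class = "control_point_record")
}

#' Single treatment beam
#'
#' @param beam_number integer id, unique within the plan.
#' @param gantry_angle degrees, IEC 61217, in `[0, 360)`.
#' @param collimator_angle degrees; 0 in the Monaco dialect, 90 in Eclipse.
#' @param sad nominal source-to-axis distance, cm (143.5 Monaco, 100 Eclipse).
#' @param technique `"sad"` or `"extended_ssd"`.
#' @param energy_label text, e.g. `"7MV-FFF"` (Monaco) or `"6MV-FFF"` (Eclipse).
#' @param mu beam monitor units, `>= 0`.
#' @param control_points non-empty list of [control_point_record()].
#' @param isocenter 3-vector, mm, patient coordinates.
#' @param geometry the [aperture_geometry()] of the MLC, at the dialect's
#'   isocenter-projection plane.
#' @param source_distance_cm geometric source-to-isocenter distance, cm. This
#'   stays at the physical 143.5 cm through conversion so the source position
#'   in the patient frame is preserved.
#' @param name optional beam name.
#' @return an object of class `beam_record`.
#' @export
beam_record <- function(beam_number, gantry_angle, mu, control_points,
                        collimator_angle = 0,
                        sad = MONACO_SAD_CM,
                        technique = c("sad", "extended_ssd"),
                        energy_label = "7MV-FFF",
                        isocenter = c(0, 0, 0),
                        geometry = aperture_geometry(),
                        source_distance_cm = MONACO_SAD_CM,
                        name = paste0("beam", beam_number)) {
  technique <- match.arg(technique)
  stopifnot(length(control_points) >= 1L,
            all(vapply(control_points, inherits, TRUE, "control_point_record")),
            length(isocenter) == 3L)
  structure(list(beam_number = as.integer(beam_number),
                 name = name,
                 gantry_angle = as.numeric(gantry_angle),
                 collimator_angle = as.numeric(collimator_angle),
                 sad = as.numeric(sad),
                 technique = technique,
                 energy_label = energy_label,
                 mu = as.numeric(mu),
                 control_points = control_points,
                 isocenter = as.numeric(isocenter),
                 geometry = geometry,
                 source_distance_cm = as.numeric(source_distance_cm)),
            class = "beam_record")
}

#' Vendor-dialect-tagged RT plan
#'
#' @param dialect `"monaco"` or `"eclipse"`.
#' @param beams non-empty list of [beam_record()].
#' @param reference_point 3-vector, mm, patient coordinates (the default
#'   analysis-plane origin; usually the isocenter).
#' @param machine_label,fraction_label free-text identifiers.
#' @return an object of class `plan_record`.
#' @export
plan_record <- function(dialect = c("monaco", "eclipse"), beams,
                        reference_point = c(0, 0, 0),
                        machine_label = "MR-Linac",
                        fraction_label = "fx1") {
  dialect <- match.arg(dialect)
  stopifnot(length(beams) >= 1L,
            all(vapply(beams, inherits, TRUE, "beam_record")),
            length(reference_point) == 3L,
            all(is.finite(reference_point)))
  structure(list(dialect = dialect, beams = beams,
                 reference_point = as.numeric(reference_point),
                 machine_label = machine_label,
                 fraction_label = fraction_label),
            class = "plan_record")
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf("<plan_record> dialect=%s beams=%d machine=%s fraction=%s\n",
              x$dialect, length(x$beams), x$machine_label, x$fraction_label))
  for (b in x$beams) {
    cat(sprintf("  beam %d: gantry %.1f deg, collimator %.0f deg, SAD %.1f cm, %s, %s, %.1f MU, %d CP\n",
                b$beam_number, b$gantry_angle, b$collimator_angle, b$sad,
                b$technique, b$energy_label, b$mu, length(b$control_points)))
  }
  invisible(x)
}

#' 3D dose grid
#'
#' @param values 3D array `[nx, ny, nz]` of dose in Gy, on an axis-ordered
#'   lattice; x varies fastest in patient coordinates.
#' @param origin patient-space position (mm) of the center of voxel
#'   `[1, 1, 1]`.
#' @param spacing voxel spacing `(dx, dy, dz)`, mm, all `> 0`.
#' @param orientation 3x3 orthonormal matrix; column `k` is the patient-space
#'   direction of increasing index `k`.
#' @param summation `"beam"` or `"plan"`.
#' @param source_engine text tag for the producing engine.
#' @param beam_number beam this grid belongs to (`NA` for plan sums).
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing, orientation = diag(3),
                      summation = c("beam", "plan"),
                      source_engine = "unknown", beam_number = NA_integer_) {
  summation <- match.arg(summation)
  stopifnot(length(dim(values)) == 3L, all(is.finite(values)),
            all(values >= 0), length(origin) == 3L,
            length(spacing) == 3L, all(spacing > 0))
  orientation <- as.matrix(orientation)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("dose_grid orientation must be orthonormal")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), orientation = orientation,
                 summation = summation, source_engine = source_engine,
                 beam_number = as.integer(beam_number)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %dx%dx%d voxels, spacing %.2f/%.2f/%.2f mm, max %.4g Gy, %s (%s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              max(x$values), x$summation, x$source_engine))
  invisible(x)
}

## ---- energy label <-> DICOM ------------------------------------------------

.energy_from_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9.]+)MV(-FFF)?$", label))[[1]]
  if (length(m) == 0) stop("cannot parse energy label: ", label)
  list(energy = as.numeric(m[2]), fff = nzchar(m[3]))
}

.label_from_energy <- function(energy, fff) {
  paste0(format(energy), "MV", if (fff) "-FFF" else "")
}

## ---- RT Plan writer --------------------------------------------------------

.round_cm <- function(x) round(x, 2)   # positions written at 0.01 cm precision

.cp_bld_items <- function(cp, dialect) {
  items <- list()
  if (dialect == "eclipse") {
    items <- c(items, list(
      dcm_dataset(dcm_element("RTBeamLimitingDeviceType", "ASYMX"),
                  dcm_element("LeafJawPositions", .round_cm(cp$jaw_x) * 10)),
      dcm_dataset(dcm_element("RTBeamLimitingDeviceType", "ASYMY"),
                  dcm_element("LeafJawPositions", .round_cm(cp$jaw_y) * 10))))
  }
  mlc_tag <- if (dialect == "monaco") "MLCY" else "MLCX"
  items <- c(items, list(
    dcm_dataset(dcm_element("RTBeamLimitingDeviceType", mlc_tag),
                dcm_element("LeafJawPositions",
                            .round_cm(c(cp$bank_a, cp$bank_b)) * 10))))
  items
}

.beam_to_dcm <- function(beam, dialect, machine_label) {
  en <- .energy_from_label(beam$energy_label)
  geom <- beam$geometry
  bld <- list()
  if (dialect == "eclipse") {
    bld <- c(bld, list(
      dcm_dataset(dcm_element("RTBeamLimitingDeviceType", "ASYMX"),
                  dcm_element("NumberOfLeafJawPairs", 1L)),
      dcm_dataset(dcm_element("RTBeamLimitingDeviceType", "ASYMY"),
                  dcm_element("NumberOfLeafJawPairs", 1L))))
  }
  mlc_tag <- if (dialect == "monaco") "MLCY" else "MLCX"
  bld <- c(bld, list(
    dcm_dataset(dcm_element("RTBeamLimitingDeviceType", mlc_tag),
                dcm_element("NumberOfLeafJawPairs", geom$n_leaf_pairs),
                dcm_element("LeafPositionBoundaries",
                            geom$leaf_boundaries * 10))))
  cum <- cumsum(vapply(beam$control_points, `[[`, 0, "mu_weight"))
  cps <- vector("list", length(beam$control_points))
  for (i in seq_along(beam$control_points)) {
    cp <- beam$control_points[[i]]
    cp_el <- dcm_dataset(
      dcm_element("ControlPointIndex", i - 1L),
      dcm_element("CumulativeMetersetWeight", cum[i]),
      dcm_element("BeamLimitingDevicePositionSequence",
                  .cp_bld_items(cp, dialect)))
    if (i == 1L) {
      cp_el <- c(cp_el, dcm_dataset(
        dcm_element("NominalBeamEnergy", en$energy),
        dcm_element("GantryAngle", beam$gantry_angle),
        dcm_element("BeamLimitingDeviceAngle", beam$collimator_angle),
        dcm_element("IsocenterPosition", beam$isocenter)))
    }
    cps[[i]] <- cp_el
  }
  beam_ds <- dcm_dataset(
    dcm_element("BeamNumber", beam$beam_number),
    dcm_element("BeamName", beam$name),
    dcm_element("BeamDescription",
                sprintf("TECHNIQUE=%s;SOURCE_DISTANCE_CM=%.4f",
                        toupper(beam$technique), beam$source_distance_cm)),
    dcm_element("BeamType", "STATIC"),
    dcm_element("RadiationType", "PHOTON"),
    dcm_element("TreatmentMachineName", machine_label),
    dcm_element("SourceAxisDistance", beam$sad * 10),
    dcm_element("BeamLimitingDeviceSequence", bld),
    dcm_element("NumberOfControlPoints", length(beam$control_points)),
    dcm_element("FinalCumulativeMetersetWeight", 1),
    dcm_element("ControlPointSequence", cps))
  if (en$fff) {
    beam_ds <- c(beam_ds, dcm_dataset(
      dcm_element("PrimaryFluenceModeSequence", list(
        dcm_dataset(dcm_element("FluenceMode", "NON_STANDARD"),
                    dcm_element("FluenceModeID", "FFF"))))))
  }
  beam_ds
}

# deterministic content-derived SOP instance UID (no timestamps, so identical
# inputs produce byte-identical files)
.content_uid <- function(x) {
  b <- serialize(x, NULL, version = 2)
  v <- as.integer(b)
  h1 <- sum(v * (seq_along(v) %% 97 + 1)) %% 999999937
  h2 <- sum(v * (seq_along(v) %% 31 + 1)) %% 999999893
  paste0(.UID_ROOT, "2.", h1, ".", h2)
}

#' Write an RT Plan file
#'
#' Emits dialect-correct DICOM tags: a Monaco-dialect plan carries MLC
#' positions under MLCY with no X jaw sequence; an Eclipse-dialect plan
#' carries MLCX plus ASYMX/ASYMY jaw sequences. Positions are written in mm at
#' 0.1 mm precision. Refuses to write a plan whose beams are inconsistent with
#' its dialect tag.
#'
#' @param plan a [plan_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(plan, path) {
  stopifnot(inherits(plan, "plan_record"))
  v <- validate_plan(plan)
  bad <- v[v$field %in% c("dialect", "collimator_angle", "sad", "energy_label",
                          "jaw_y", "jaw_x"), , drop = FALSE]
  if (nrow(bad) > 0)
    stop("refusing to write dialect-inconsistent plan: ",
         paste(unique(bad$message), collapse = "; "))
  beams <- lapply(plan$beams, .beam_to_dcm, dialect = plan$dialect,
                  machine_label = plan$machine_label)
  refs <- lapply(plan$beams, function(b) dcm_dataset(
    dcm_element("ReferencedBeamNumber", b$beam_number),
    dcm_element("BeamMeterset", b$mu)))
  ds <- dcm_dataset(
    dcm_element("SOPClassUID", .UID_RTPLAN),
    dcm_element("SOPInstanceUID", .content_uid(plan)),
    dcm_element("Modality", "RTPLAN"),
    dcm_element("Manufacturer", if (plan$dialect == "monaco") "MonacoDialect"
                                else "EclipseDialect"),
    dcm_element("PatientName", "QA^Synthetic"),
    dcm_element("PatientID", "IMUQA"),
    dcm_element("RTPlanLabel", plan$fraction_label),
    dcm_element("DoseReferenceSequence", list(
      dcm_dataset(dcm_element("DoseReferenceDescription", "reference point"),
                  dcm_element("DoseReferencePointCoordinates",
                              plan$reference_point)))),
    dcm_element("FractionGroupSequence", list(
      dcm_dataset(dcm_element("NumberOfFractionsPlanned", 1L),
                  dcm_element("NumberOfBeams", length(plan$beams)),
                  dcm_element("ReferencedBeamSequence", refs)))),
    dcm_element("BeamSequence", beams))
  dcm_write_file(path, ds, .UID_RTPLAN, .content_uid(plan))
  invisible(path)
}

## ---- RT Plan reader --------------------------------------------------------

.bld_position <- function(cp_ds, type) {
  seq_ <- dcm_get(cp_ds, "BeamLimitingDevicePositionSequence")
  if (is.null(seq_)) return(NULL)
  for (item in seq_) {
    if (identical(dcm_get(item, "RTBeamLimitingDeviceType"), type))
      return(dcm_get(item, "LeafJawPositions"))
  }
  NULL
}

.beam_from_dcm <- function(beam_ds, beam_index, mu_by_number) {
  bn <- dcm_get(beam_ds, "BeamNumber", beam_index)
  bld <- dcm_get(beam_ds, "BeamLimitingDeviceSequence")
  if (is.null(bld)) stop("beam ", bn, ": missing beam limiting device sequence")
  types <- vapply(bld, function(x) dcm_get(x, "RTBeamLimitingDeviceType", ""), "")
  mlc_tag <- if ("MLCY" %in% types) "MLCY" else if ("MLCX" %in% types) "MLCX" else
    stop("beam ", bn, ": missing MLC sequence (no MLCX/MLCY item)")
  dialect_tag <- if (mlc_tag == "MLCY") "monaco" else "eclipse"
  sad_cm <- dcm_get(beam_ds, "SourceAxisDistance", NA_real_) / 10
  sad_dialect <- if (is.na(sad_cm)) NA_character_
    else if (abs(sad_cm - MONACO_SAD_CM) < 0.1) "monaco"
    else if (abs(sad_cm - ECLIPSE_SAD_CM) < 0.1) "eclipse"
    else NA_character_
  if (is.na(sad_dialect))
    stop("beam ", bn, ": unknown dialect; SAD ", sad_cm,
         " cm matches neither 143.5 (Monaco) nor 100 (Eclipse)")
  if (!identical(sad_dialect, dialect_tag))
    stop("beam ", bn, ": dialect detection conflict; MLC tag ", mlc_tag,
         " implies ", dialect_tag, " but SAD ", sad_cm, " cm implies ",
         sad_dialect)
  mlc_item <- bld[[which(types == mlc_tag)[1]]]
  boundaries <- dcm_get(mlc_item, "LeafPositionBoundaries")
  n_pairs <- dcm_get(mlc_item, "NumberOfLeafJawPairs",
                     length(boundaries) - 1L)
  geom <- aperture_geometry(n_pairs, boundaries / 10,
                            max_half_field = if (dialect_tag == "monaco")
                              MONACO_JAW_HALF_CM else
                              MONACO_JAW_HALF_CM * ECLIPSE_SAD_CM / MONACO_SAD_CM)
  cps_ds <- dcm_get(beam_ds, "ControlPointSequence")
  if (is.null(cps_ds) || length(cps_ds) == 0)
    stop("beam ", bn, ": empty control point sequence")
  cum <- vapply(cps_ds, function(x)
    dcm_get(x, "CumulativeMetersetWeight", NA_real_), 0)
  final <- dcm_get(beam_ds, "FinalCumulativeMetersetWeight", 1)
  dynamic_pairs <- length(cps_ds) > 1L && isTRUE(abs(cum[1]) < 1e-9)
  if (dynamic_pairs) {
    # dynamic-pair export: N+1 control points with cumulative weights 0..final;
    # segment i uses the leading aperture of the pair
    seg_idx <- seq_len(length(cps_ds) - 1L)
    weights <- diff(cum) / final
  } else {
    # static-segment export: one control point per segment, weights ending at 1
    seg_idx <- seq_along(cps_ds)
    weights <- diff(c(0, cum)) / final
  }
  cps <- vector("list", length(seg_idx))
  for (k in seq_along(seg_idx)) {
    cp_ds <- cps_ds[[seg_idx[k]]]
    mlc <- .bld_position(cp_ds, mlc_tag)
    if (is.null(mlc))
      stop("beam ", bn, ", control point ", seg_idx[k] - 1L,
           ": missing MLC positions (", mlc_tag, ")")
    np <- length(mlc) / 2L
    jx <- .bld_position(cp_ds, "ASYMX") %||% .bld_position(cp_ds, "X")
    jy <- .bld_position(cp_ds, "ASYMY") %||% .bld_position(cp_ds, "Y")
    cps[[k]] <- control_point_record(
      mu_weight = weights[k],
      bank_a = mlc[seq_len(np)] / 10, bank_b = mlc[np + seq_len(np)] / 10,
      jaw_x = if (is.null(jx)) NULL else jx / 10,
      jaw_y = if (is.null(jy)) {
        if (dialect_tag == "monaco")
          c(-MONACO_JAW_HALF_CM, MONACO_JAW_HALF_CM)
        else stop("beam ", bn, ": eclipse dialect requires Y jaw positions")
      } else jy / 10)
  }
  first_cp <- cps_ds[[1]]
  en <- dcm_get(first_cp, "NominalBeamEnergy", 7)
  fff <- FALSE
  fm <- dcm_get(beam_ds, "PrimaryFluenceModeSequence")
  if (!is.null(fm) && length(fm) > 0)
    fff <- identical(dcm_get(fm[[1]], "FluenceModeID"), "FFF")
  desc <- dcm_get(beam_ds, "BeamDescription", "")
  technique <- if (grepl("TECHNIQUE=EXTENDED_SSD", desc)) "extended_ssd" else "sad"
  sdist <- sad_cm
  m <- regmatches(desc, regexec("SOURCE_DISTANCE_CM=([0-9.]+)", desc))[[1]]
  if (length(m) == 2) sdist <- as.numeric(m[2])
  beam_record(
    beam_number = as.integer(bn),
    name = dcm_get(beam_ds, "BeamName", paste0("beam", bn)),
    gantry_angle = dcm_get(first_cp, "GantryAngle", 0),
    collimator_angle = dcm_get(first_cp, "BeamLimitingDeviceAngle", 0),
    sad = sad_cm, technique = technique,
    energy_label = .label_from_energy(en, fff),
    mu = mu_by_number[[as.character(bn)]] %||% 0,
    control_points = cps,
    isocenter = dcm_get(first_cp, "IsocenterPosition", c(0, 0, 0)),
    geometry = geom, source_distance_cm = sdist)
}

#' Read an RT Plan file
#'
#' The vendor dialect is auto-detected per beam: MLC positions under tag MLCY
#' with SAD 143.5 cm mark the Monaco dialect, MLCX with SAD 100 cm the Eclipse
#' dialect. The MLC tag name takes precedence and the SAD must confirm it;
#' disagreement, or any other combination, is an error rather than a guess.
#'
#' @param path a DICOM RT Plan file.
#' @return a [plan_record()].
#' @export
read_rtplan <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_get(ds, "Modality"), "RTPLAN"))
    stop("not an RT Plan file (Modality=", dcm_get(ds, "Modality"), "): ", path)
  beams_ds <- dcm_get(ds, "BeamSequence")
  if (is.null(beams_ds) || length(beams_ds) == 0)
    stop("RT Plan has no beams: ", path)
  mu_by_number <- list()
  fg <- dcm_get(ds, "FractionGroupSequence")
  if (!is.null(fg) && length(fg) > 0) {
    for (rb in dcm_get(fg[[1]], "ReferencedBeamSequence") %||% list()) {
      mu_by_number[[as.character(dcm_get(rb, "ReferencedBeamNumber"))]] <-
        dcm_get(rb, "BeamMeterset", 0)
    }
  }
  beams <- lapply(seq_along(beams_ds), function(i)
    .beam_from_dcm(beams_ds[[i]], i, mu_by_number))
  dialects <- unique(vapply(beams, function(b)
    if (abs(b$sad - MONACO_SAD_CM) < 0.1) "monaco" else "eclipse", ""))
  if (length(dialects) != 1)
    stop("beams mix dialects within one plan: ", path)
  ref <- c(0, 0, 0)
  dr <- dcm_get(ds, "DoseReferenceSequence")
  if (!is.null(dr) && length(dr) > 0) {
    p <- dcm_get(dr[[1]], "DoseReferencePointCoordinates")
    if (!is.null(p)) ref <- p
  }
  plan_record(dialect = dialects,
              beams = beams,
              reference_point = ref,
              machine_label = dcm_get(beams_ds[[1]], "TreatmentMachineName",
                                      "MR-Linac"),
              fraction_label = dcm_get(ds, "RTPlanLabel", "fx"))
}

## ---- RT Dose I/O -----------------------------------------------------------

#' Write an RT Dose file
#'
#' Dose is stored as 32-bit unsigned integers with a `DoseGridScaling` factor
#' chosen so the grid maximum maps to the top of the integer range; the
#' quantization error is below `max(dose) * 5e-10` Gy.
#'
#' @param grid a [dose_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  mx <- max(grid$values)
  scaling <- if (mx > 0) mx / (2^31 - 1) else 1
  stored <- as.integer(round(grid$values / scaling))
  ds <- dcm_dataset(
    dcm_element("SOPClassUID", .UID_RTDOSE),
    dcm_element("SOPInstanceUID", .content_uid(grid)),
    dcm_element("Modality", "RTDOSE"),
    dcm_element("PatientName", "QA^Synthetic"),
    dcm_element("PatientID", "IMUQA"),
    dcm_element("SamplesPerPixel", 1L),
    dcm_element("PhotometricInterpretation", "MONOCHROME2"),
    dcm_element("NumberOfFrames", d[3]),
    dcm_element("Rows", d[2]),
    dcm_element("Columns", d[1]),
    dcm_element("PixelSpacing", c(grid$spacing[2], grid$spacing[1])),
    dcm_element("ImagePositionPatient", grid$origin),
    dcm_element("ImageOrientationPatient",
                c(grid$orientation[, 1], grid$orientation[, 2])),
    dcm_element("BitsAllocated", 32L),
    dcm_element("BitsStored", 32L),
    dcm_element("HighBit", 31L),
    dcm_element("PixelRepresentation", 0L),
    dcm_element("DoseUnits", "GY"),
    dcm_element("DoseType", "PHYSICAL"),
    dcm_element("DoseSummationType", toupper(grid$summation)),
    dcm_element("GridFrameOffsetVector", (seq_len(d[3]) - 1) * grid$spacing[3]),
    dcm_element("DoseGridScaling", scaling),
    dcm_element("SeriesDescription", grid$source_engine),
    dcm_element("PixelData", stored))
  if (!is.na(grid$beam_number))
    ds <- c(ds, dcm_dataset(dcm_element("ReferencedBeamNumber",
                                        grid$beam_number)))
  dcm_write_file(path, ds, .UID_RTDOSE, .content_uid(grid))
  invisible(path)
}

#' Read an RT Dose file
#'
#' Applies the stored `DoseGridScaling` so values come back in Gy. Requires a
#' uniformly spaced `GridFrameOffsetVector`; non-uniform slice spacing or a
#' missing scaling factor is an error.
#'
#' @param path a DICOM RT Dose file.
#' @return a [dose_grid()].
#' @export
read_rtdose <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_get(ds, "Modality"), "RTDOSE"))
    stop("not an RT Dose file: ", path)
  scaling <- dcm_get(ds, "DoseGridScaling")
  if (is.null(scaling)) stop("RT Dose missing DoseGridScaling: ", path)
  nx <- dcm_get(ds, "Columns"); ny <- dcm_get(ds, "Rows")
  nz <- dcm_get(ds, "NumberOfFrames")
  if (is.null(nx) || is.null(ny) || is.null(nz) || nx * ny * nz == 0)
    stop("RT Dose has an empty grid: ", path)
  gfov <- dcm_get(ds, "GridFrameOffsetVector")
  if (length(gfov) != nz) stop("GridFrameOffsetVector length mismatch: ", path)
  dz <- if (nz > 1) diff(gfov) else 1
  if (nz > 1 && (max(dz) - min(dz) > 1e-6 || any(dz <= 0)))
    stop("non-uniform or non-increasing slice spacing: ", path)
  dz <- dz[1]
  ps <- dcm_get(ds, "PixelSpacing")   # (row, col) = (dy, dx)
  pix <- dcm_get(ds, "PixelData")
  stored <- readBin(pix, "integer", n = nx * ny * nz, size = 4L,
                    endian = "little")
  values <- array(stored * scaling, dim = c(nx, ny, nz))
  iop <- dcm_get(ds, "ImageOrientationPatient", c(1, 0, 0, 0, 1, 0))
  xdir <- iop[1:3]; ydir <- iop[4:6]
  zdir <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
            xdir[3] * ydir[1] - xdir[1] * ydir[3],
            xdir[1] * ydir[2] - xdir[2] * ydir[1])
  dose_grid(values = values,
            origin = dcm_get(ds, "ImagePositionPatient", c(0, 0, 0)),
            spacing = c(ps[2], ps[1], dz),
            orientation = cbind(xdir, ydir, zdir),
            summation = tolower(dcm_get(ds, "DoseSummationType", "beam")),
            source_engine = dcm_get(ds, "SeriesDescription", "unknown"),
            beam_number = dcm_get(ds, "ReferencedBeamNumber", NA_integer_))
}

## ---- validation ------------------------------------------------------------

#' Validate a plan's internal consistency
#'
#' A reporting operation: never raises. Returns a data frame of invariant
#' violations, one row each, naming the beam and control point involved; an
#' empty frame means the plan is internally consistent (including the
#' dialect-consistent (SAD, collimator angle, energy label) triple and the
#' fixed 22 cm Monaco jaw extent).
#'
#' @param plan a [plan_record()].
#' @return a `data.frame` with columns `beam`, `control_point`, `field`,
#'   `message`, of class `imu_validation`.
#' @export
validate_plan <- function(plan) {
  rows <- list()
  add <- function(beam, cp, field, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      beam = beam, control_point = cp, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  if (!all(is.finite(plan$reference_point)))
    add(NA_integer_, NA_integer_, "reference_point",
        "reference point is not finite")
  for (b in plan$beams) {
    bn <- b$beam_number
    if (b$gantry_angle < 0 || b$gantry_angle >= 360)
      add(bn, NA_integer_, "gantry_angle",
          sprintf("beam %d: gantry angle %.2f outside [0, 360)", bn,
                  b$gantry_angle))
    if (b$mu < 0)
      add(bn, NA_integer_, "mu", sprintf("beam %d: negative MU", bn))
    want <- if (plan$dialect == "monaco")
      list(sad = MONACO_SAD_CM, coll = 0, energy = "7MV")
    else list(sad = ECLIPSE_SAD_CM, coll = 90, energy = "6MV")
    if (abs(b$sad - want$sad) > 0.1)
      add(bn, NA_integer_, "sad",
          sprintf("beam %d: SAD %.1f cm inconsistent with %s dialect", bn,
                  b$sad, plan$dialect))
    if (abs(b$collimator_angle - want$coll) > 1e-6)
      add(bn, NA_integer_, "collimator_angle",
          sprintf("beam %d: collimator %.1f deg inconsistent with %s dialect",
                  bn, b$collimator_angle, plan$dialect))
    if (!startsWith(b$energy_label, want$energy))
      add(bn, NA_integer_, "energy_label",
          sprintf("beam %d: energy label %s inconsistent with %s dialect", bn,
                  b$energy_label, plan$dialect))
    cum <- 0
    for (i in seq_along(b$control_points)) {
      cp <- b$control_points[[i]]
      bad_pairs <- which(cp$bank_a > cp$bank_b + 1e-9)
      for (p in bad_pairs)
        add(bn, i, "leaf_banks",
            sprintf("beam %d, control point %d, leaf pair %d: bank A (%.3f) above bank B (%.3f)",
                    bn, i, p, cp$bank_a[p], cp$bank_b[p]))
      if (cp$mu_weight < -1e-9)
        add(bn, i, "mu_weight",
            sprintf("beam %d, control point %d: negative segment weight", bn, i))
      cum <- cum + cp$mu_weight
      if (plan$dialect == "monaco" &&
          abs(diff(cp$jaw_y) - 2 * MONACO_JAW_HALF_CM) > 1e-6)
        add(bn, i, "jaw_y",
            sprintf("beam %d, control point %d: jaw Y extent %.2f cm, expected fixed 22 cm",
                    bn, i, diff(cp$jaw_y)))
      if (plan$dialect == "eclipse" && is.null(cp$jaw_x))
        add(bn, i, "jaw_x",
            sprintf("beam %d, control point %d: eclipse dialect requires X jaws",
                    bn, i))
    }
    if (abs(cum - 1) > 1e-6)
      add(bn, NA_integer_, "mu_weight",
          sprintf("beam %d: segment weights sum to %.6f, expected 1", bn, cum))
  }
  out <- if (length(rows) == 0)
    data.frame(beam = integer(), control_point = integer(),
               field = character(), message = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  class(out) <- c("imu_validation", class(out))
  out
}

#' @export
print.imu_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("plan is internally consistent\n")
  else {
    cat(nrow(x), "invariant violation(s):\n")
    for (m in x$message) cat("  -", m, "\n")
  }
  invisible(x)
}
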