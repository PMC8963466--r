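# Monaco -> Eclipse plan transformation. Three rules:
#   1. rescale collimation from the 143.5 cm SAD plane to the 100 cm plane
#      (factor 100/143.5, i.e. dividing by 1.435) and switch the beam to
#      extended-SSD technique so the physical source distance is retained;
#   2. relabel the nominal energy (7MV-FFF -> 6MV-FFF);
#   3. swap the in-plane axes: MLCY -> MLCX, collimator 0 -> 90 deg, and
#      derive X jaws from the leaf envelope (or use the fixed +/-7.67 cm).
# MU are never touched: the second calculation runs with fixed MU.

# leaf pairs with a tip gap at or below this (cm, at the 100 cm plane) are
# treated as closed; shared with the CIAO construction
LEAF_CLOSED_TOL_CM <- 0.05

#' Conversion configuration
#'
#' @param target_sad target source-to-axis distance, cm (100 for a
#'   conventional TPS).
#' @param jaw_margin margin added around the open-leaf envelope when deriving
#'   X jaws, cm at the target SAD plane (the rule is applied after rescaling).
#' @param jaw_mode `"from_leaves"` (envelope + margin, clipped to
#'   `fixed_jaw_half`) or `"fixed"` (always `+/-fixed_jaw_half`).
#' @param fixed_jaw_half fixed X jaw half width, cm; 7.67 is the +/-11 cm
#'   physical limit projected to the 100 cm plane.
#' @param energy_relabel named character vector mapping source to target
#'   energy labels.
#' @return an object of class `conversion_config`.
#' @export
conversion_config <- function(target_sad = ECLIPSE_SAD_CM,
                              jaw_margin = 0.5,
                              jaw_mode = c("from_leaves", "fixed"),
                              fixed_jaw_half = 7.67,
                              energy_relabel = c("7MV-FFF" = "6MV-FFF")) {
  jaw_mode <- match.arg(jaw_mode)
  stopifnot(target_sad > 0, jaw_margin >= 0, fixed_jaw_half > 0)
  structure(list(target_sad = target_sad, jaw_margin = jaw_margin,
                 jaw_mode = jaw_mode, fixed_jaw_half = fixed_jaw_half,
                 energy_relabel = energy_relabel),
            class = "conversion_config")
}

#' Rescale projected positions between SAD planes
#'
#' Similar-triangle rescaling of positions defined at the `sad_from` plane to
#' the `sad_to` plane: each position is multiplied by `sad_to / sad_from`, so
#' the projected aperture in the original beam's-eye-view is unchanged.
#' Rescaling 143.5 cm positions to 100 cm divides by 1.435.
#'
#' @param positions numeric positions, cm at the `sad_from` plane.
#' @param sad_from,sad_to source-to-axis distances, cm, both `> 0`.
#' @return positions, cm at the `sad_to` plane.
#' @export
rescale_positions <- function(positions, sad_from, sad_to) {
  if (sad_from <= 0 || sad_to <= 0)
    stop("SAD values must be positive")
  positions * (sad_to / sad_from)
}

#' Swap the in-plane axes of a Monaco-dialect beam
#'
#' Relabels the MLC sequence MLCY -> MLCX and sets the collimator angle to 90
#' degrees from 0. The swap is a pure relabeling: the aperture shape in the
#' patient frame is identical before and after (the 90 degree collimator
#' rotation exactly undoes the axis interchange).
#'
#' @param beam a [beam_record()] with collimator angle 0 (any other input
#'   collimator angle is unsupported and raises).
#' @return the beam with eclipse axis conventions (collimator 90).
#' @export
swap_axes <- function(beam) {
  stopifnot(inherits(beam, "beam_record"))
  if (abs(beam$collimator_angle - 0) > 1e-9)
    stop("swap_axes requires collimator angle 0 (got ",
         beam$collimator_angle, " deg); beam is not in the monaco dialect")
  beam$collimator_angle <- 90
  beam
}

#' Derive X jaw positions for a control point
#'
#' In `from_leaves` mode the jaws are the open-leaf envelope (minimum and
#' maximum leaf positions over pairs with tip gap above the closure tolerance)
#' plus a margin, clipped to `+/-fixed_jaw_half` (the physical +/-11 cm limit
#' projected to the target plane). In `fixed` mode they are always
#' `+/-fixed_jaw_half`. Closed parked pairs are ignored; a fully closed
#' control point degenerates to the closed-leaf position +/- margin, with a
#' warning.
#'
#' @param cp a [control_point_record()] with positions already rescaled to the
#'   target SAD plane.
#' @param cfg a [conversion_config()].
#' @return `(x1, x2)` jaw pair, cm.
#' @export
derive_x_jaws <- function(cp, cfg = conversion_config()) {
  if (cfg$jaw_mode == "fixed")
    return(c(-cfg$fixed_jaw_half, cfg$fixed_jaw_half))
  open_ <- (cp$bank_b - cp$bank_a) > LEAF_CLOSED_TOL_CM
  if (!any(open_)) {
    warning("fully closed control point: jaws collapse to the closed-leaf position")
    pos <- mean(c(cp$bank_a, cp$bank_b))
    return(c(pos - cfg$jaw_margin, pos + cfg$jaw_margin))
  }
  lo <- min(cp$bank_a[open_]) - cfg$jaw_margin
  hi <- max(cp$bank_b[open_]) + cfg$jaw_margin
  c(max(lo, -cfg$fixed_jaw_half), min(hi, cfg$fixed_jaw_half))
}

#' Switch a beam from SAD to extended-SSD technique
#'
#' Sets the nominal SAD to the target (100 cm) while keeping the geometric
#' source-to-isocenter distance at its physical value, so the source position
#' in the patient frame is unchanged.
#'
#' @param beam a [beam_record()] in `"sad"` technique.
#' @param target_sad nominal SAD after the switch, cm.
#' @return the beam in `"extended_ssd"` technique.
#' @export
to_extended_ssd <- function(beam, target_sad = ECLIPSE_SAD_CM) {
  stopifnot(inherits(beam, "beam_record"))
  if (beam$technique == "extended_ssd")
    stop("beam ", beam$beam_number, " is already in extended-SSD technique")
  beam$technique <- "extended_ssd"
  # source_distance_cm keeps the physical distance; only the nominal SAD moves
  beam$sad <- target_sad
  beam
}

#' Invert the extended-SSD switch
#'
#' Restores `"sad"` technique with the nominal SAD equal to the stored
#' physical source distance. Inverse of [to_extended_ssd()].
#'
#' @param beam a [beam_record()] in `"extended_ssd"` technique.
#' @return the beam in `"sad"` technique.
#' @export
from_extended_ssd <- function(beam) {
  stopifnot(inherits(beam, "beam_record"))
  if (beam$technique == "sad")
    stop("beam ", beam$beam_number, " is already in SAD technique")
  beam$technique <- "sad"
  beam$sad <- beam$source_distance_cm
  beam
}

#' Convert a Monaco-dialect plan to the Eclipse dialect
#'
#' Applies, per beam: position rescaling to the target SAD plane, energy
#' relabeling, the in-plane axis swap (MLCY -> MLCX, collimator 0 -> 90),
#' X jaw derivation (one static pair per beam, the envelope over all control
#' points), and the extended-SSD technique switch. Beam MU are unchanged.
#' Converting a plan already in the Eclipse dialect raises, so positions can
#' never be scaled twice.
#'
#' @param plan a [plan_record()] in the Monaco dialect that validates cleanly.
#' @param cfg a [conversion_config()].
#' @return a [plan_record()] in the Eclipse dialect.
#' @export
convert_plan <- function(plan, cfg = conversion_config()) {
  stopifnot(inherits(plan, "plan_record"))
  if (plan$dialect != "monaco")
    stop("convert_plan expects a monaco-dialect plan (got ", plan$dialect,
         "); refusing to scale twice")
  v <- validate_plan(plan)
  if (nrow(v) > 0)
    stop("plan does not validate; first violation: ", v$message[1])
  out_beams <- vector("list", length(plan$beams))
  for (bi in seq_along(plan$beams)) {
    beam <- plan$beams[[bi]]
    res <- tryCatch({
      s <- cfg$target_sad / beam$sad
      # rule 1: rescale collimation to the target SAD plane
      beam$geometry <- aperture_geometry(
        beam$geometry$n_leaf_pairs,
        beam$geometry$leaf_boundaries * s,
        max_half_field = beam$geometry$max_half_field * s)
      beam$control_points <- lapply(beam$control_points, function(cp) {
        cp$bank_a <- rescale_positions(cp$bank_a, beam$sad, cfg$target_sad)
        cp$bank_b <- rescale_positions(cp$bank_b, beam$sad, cfg$target_sad)
        cp$jaw_y <- rescale_positions(cp$jaw_y, beam$sad, cfg$target_sad)
        cp
      })
      # rule 2: nominal energy relabel
      relabel <- cfg$energy_relabel[beam$energy_label]
      if (!is.na(relabel)) beam$energy_label <- unname(relabel)
      # rule 3: axis swap and derived static X jaws (envelope over segments)
      beam <- swap_axes(beam)
      jaws <- vapply(beam$control_points, derive_x_jaws, numeric(2), cfg = cfg)
      jaw <- c(min(jaws[1, ]), max(jaws[2, ]))
      beam$control_points <- lapply(beam$control_points, function(cp) {
        cp$jaw_x <- jaw
        cp
      })
      # rule 1 (technique): extended SSD, nominal SAD 100
      to_extended_ssd(beam, cfg$target_sad)
    }, error = function(e)
      stop("conversion failed for beam index ", bi, " (beam number ",
           beam$beam_number, "): ", conditionMessage(e), call. = FALSE))
    out_beams[[bi]] <- res
  }
  plan_record(dialect = "eclipse", beams = out_beams,
              reference_point = plan$reference_point,
              machine_label = plan$machine_label,
              fraction_label = plan$fraction_label)
}
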