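# Synthetic end-to-end fixtures: a deterministic toy divergent-beam dose
# engine standing in for the two commercial calculations, plus generators
# for matched and deliberately mismatched QA cases.
#
# The engine is deliberately simple and is shared by the "reference"
# (Monaco-like: B-field deflection emulated, posterior coil present) and
# "evaluated" (conventional-TPS-like: no B-field, coil ignored) sides, so a
# matched case passes gamma near 100% by construction and the pipeline's
# shift/attenuation corrections are the only discriminators.

#' Uniform box phantom with optional couch and posterior-coil slabs
#'
#' @param size_mm box edge lengths `(x, y, z)`, mm.
#' @param center_mm box center, mm patient coordinates.
#' @param density uniform relative electron density (scales the effective
#'   attenuation coefficient).
#' @param couch optional slab `list(y0, y1, transmission)`: a couch top at
#'   patient-posterior `y in [y0, y1]` mm crossed by posterior beams.
#' @param coil optional posterior RF-coil slab, same form.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size_mm = c(240, 240, 240), center_mm = c(0, 0, 0),
                         density = 1.0, couch = NULL, coil = NULL) {
  stopifnot(all(size_mm > 0), density > 0)
  for (slab in list(couch, coil)) {
    if (!is.null(slab))
      stopifnot(slab$y1 > slab$y0, slab$transmission > 0,
                slab$transmission <= 1)
  }
  structure(list(size_mm = as.numeric(size_mm),
                 center_mm = as.numeric(center_mm),
                 density = density, couch = couch, coil = coil),
            class = "phantom_spec")
}

#' Toy engine configuration
#'
#' @param mu_calibration cGy/MU at the calibration point (depth 5.0 cm at
#'   SSD 138.5 cm, i.e. the isocenter of a phantom whose surface sits 5 cm
#'   upstream).
#' @param atten_per_cm effective linear attenuation coefficient, 1/cm.
#' @param penumbra_sigma_mm Gaussian penumbra sigma at the isocenter plane.
#' @param fff_slope_per_cm linear off-axis falloff of the
#'   flattening-filter-free profile, fraction per cm of off-axis distance.
#' @param bfield_shift_mm emulated magnetic-field deflection: the fluence
#'   pattern is displaced by this amount towards `+v` (the Lorentz
#'   direction); 0 disables the emulation.
#' @param noise_sd_pct multiplicative Gaussian noise, percent of local dose;
#'   0 (off) by default.
#' @param grid_spacing_mm dose grid spacing.
#' @param seed optional integer; when set, per-beam noise streams derive
#'   from `seed + beam_number` so outputs are reproducible beam by beam.
#' @return an object of class `toy_engine_config`.
#' @export
toy_engine_config <- function(mu_calibration = 1.0, atten_per_cm = 0.05,
                              penumbra_sigma_mm = 3, fff_slope_per_cm = 0.015,
                              bfield_shift_mm = 0, noise_sd_pct = 0,
                              grid_spacing_mm = 4, seed = NULL) {
  stopifnot(mu_calibration > 0, atten_per_cm >= 0, penumbra_sigma_mm >= 0,
            fff_slope_per_cm >= 0, noise_sd_pct >= 0, grid_spacing_mm > 0)
  structure(list(mu_calibration = mu_calibration, atten_per_cm = atten_per_cm,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 fff_slope_per_cm = fff_slope_per_cm,
                 bfield_shift_mm = bfield_shift_mm,
                 noise_sd_pct = noise_sd_pct,
                 grid_spacing_mm = grid_spacing_mm, seed = seed),
            class = "toy_engine_config")
}

# fluence of one control point at projected BEV coordinates (cm, isocenter
# plane): per-leaf-pair soft-edged gate along v, hard leaf boundaries along u
.cp_fluence <- function(cp, geometry, pu, pv, sigma_cm) {
  pair <- findInterval(pu, geometry$leaf_boundaries,
                       rightmost.closed = TRUE)
  ok <- pair >= 1L & pair <= geometry$n_leaf_pairs
  f <- numeric(length(pu))
  if (!any(ok)) return(f)
  a <- cp$bank_a[pair[ok]]; b <- cp$bank_b[pair[ok]]
  open_ <- (b - a) > LEAF_CLOSED_TOL_CM
  pvok <- pv[ok]
  g <- numeric(sum(ok))
  if (sigma_cm > 0) {
    g[open_] <- stats::pnorm((pvok[open_] - a[open_]) / sigma_cm) -
                stats::pnorm((pvok[open_] - b[open_]) / sigma_cm)
  } else {
    g[open_] <- as.numeric(pvok[open_] >= a[open_] & pvok[open_] <= b[open_])
  }
  # stacking-direction jaws (fixed 22 cm in the monaco dialect)
  jy <- sort(cp$jaw_y)
  g[pu[ok] < jy[1] | pu[ok] > jy[2]] <- 0
  if (!is.null(cp$jaw_x)) {
    jx <- sort(cp$jaw_x)
    if (sigma_cm > 0) {
      g <- g * (stats::pnorm((pvok - jx[1]) / sigma_cm) -
                stats::pnorm((pvok - jx[2]) / sigma_cm))
    } else {
      g <- g * as.numeric(pvok >= jx[1] & pvok <= jx[2])
    }
  }
  f[ok] <- g
  f
}

# does the segment source -> p fully cross a posterior y-slab?
.crosses_slab <- function(src_y, p_y, slab) {
  (src_y >= slab$y1 & p_y <= slab$y0) | (src_y <= slab$y0 & p_y >= slab$y1)
}

#' Toy engine dose at arbitrary points
#'
#' The noise-free engine evaluated at patient-space points: the dose is
#' `MU x calibration x inverse-square x exp(-mu * depth) x fluence x
#' off-axis`, further multiplied by the transmission of any couch/coil slab
#' the ray crosses. The fluence is the control-point-weighted sum of
#' aperture gates convolved with a Gaussian penumbra, displaced towards `+v`
#' by `bfield_shift_mm` when the B-field emulation is on. The calibration
#' fixes 1 cGy/MU (by default) on the central axis at 5 cm depth and
#' 138.5 cm SSD.
#'
#' @param beam a [beam_record()].
#' @param phantom a [phantom_spec()].
#' @param cfg a [toy_engine_config()].
#' @param pts `n x 3` matrix of patient coordinates, mm.
#' @return numeric vector of dose, Gy.
#' @export
toy_dose_at_points <- function(beam, phantom, cfg, pts) {
  half <- phantom$size_mm / 2
  mu_eff <- cfg$atten_per_cm * phantom$density
  sigma_cm <- cfg$penumbra_sigma_mm / 10
  shift_cm <- cfg$bfield_shift_mm / 10
  f <- beam_unit_vectors(beam$gantry_angle)
  src <- beam_source_position(beam)
  d_iso <- beam$source_distance_cm * 10
  # field coverage check: the widest open aperture, projected to the
  # isocenter plane, must fit inside the phantom's lateral extent (box
  # support function along the in-plane axes)
  tip_v <- 0.1; tip_u <- 0.1
  for (cp in beam$control_points) {
    open_ <- (cp$bank_b - cp$bank_a) > LEAF_CLOSED_TOL_CM
    if (any(open_)) {
      tip_v <- max(tip_v, abs(cp$bank_a[open_]), abs(cp$bank_b[open_]))
      ob <- range(beam$geometry$leaf_boundaries[c(which(open_),
                                                  which(open_) + 1L)])
      tip_u <- max(tip_u, abs(ob))
    }
  }
  proj <- beam$source_distance_cm / beam$sad   # definition plane -> iso
  vb <- sum(abs(f$v) * half); ub <- sum(abs(f$u) * half)
  if (tip_v * 10 * proj > 0.95 * vb || tip_u * 10 * proj > 0.95 * ub)
    stop("phantom does not cover the field of beam ", beam$beam_number)
  rx <- pts[, 1] - src[1]; ry <- pts[, 2] - src[2]; rz <- pts[, 3] - src[3]
  w <- rx * f$dir[1] + ry * f$dir[2] + rz * f$dir[3]
  if (any(w <= 0)) stop("phantom extends behind the source")
  dist <- sqrt(rx^2 + ry^2 + rz^2)
  # projected BEV coordinates at the beam's definition plane (cm)
  pu <- (rx * f$u[1] + ry * f$u[2] + rz * f$u[3]) / w * beam$sad
  pv <- (rx * f$v[1] + ry * f$v[2] + rz * f$v[3]) / w * beam$sad
  # depth from the phantom entry surface along each ray (slab method)
  t_entry <- rep(-Inf, length(w))
  for (a in 1:3) {
    da <- (list(rx, ry, rz))[[a]] / dist
    da[abs(da) < 1e-12] <- 1e-12
    lo <- (phantom$center_mm[a] - half[a] - src[a]) / da
    hi <- (phantom$center_mm[a] + half[a] - src[a]) / da
    t_entry <- pmax(t_entry, pmin(lo, hi))
  }
  depth_cm <- pmax(0, dist - t_entry) / 10
  pv_eff <- pv - shift_cm   # B-field displaces the pattern towards +v
  fl <- numeric(length(pu))
  for (cp in beam$control_points) {
    fl <- fl + cp$mu_weight *
      .cp_fluence(cp, beam$geometry, pu, pv_eff, sigma_cm)
  }
  oar <- pmax(0, 1 - cfg$fff_slope_per_cm * sqrt(pu^2 + pv^2))
  dose_cgy <- beam$mu * cfg$mu_calibration * exp(mu_eff * 5) *
    (d_iso / dist)^2 * exp(-mu_eff * depth_cm) * fl * oar
  for (slab in list(phantom$couch, phantom$coil)) {
    if (!is.null(slab)) {
      crossed <- .crosses_slab(src[2], pts[, 2], slab)
      dose_cgy[crossed] <- dose_cgy[crossed] * slab$transmission
    }
  }
  dose_cgy / 100
}

#' Toy divergent-beam dose engine
#'
#' Evaluates [toy_dose_at_points()] on a regular grid covering the phantom
#' and adds optional multiplicative Gaussian noise.
#'
#' @param plan a [plan_record()] (either dialect; geometry is interpreted at
#'   the beam's own projection plane).
#' @param phantom a [phantom_spec()].
#' @param cfg a [toy_engine_config()].
#' @return list of per-beam [dose_grid()] objects.
#' @export
toy_dose_engine <- function(plan, phantom, cfg = toy_engine_config()) {
  stopifnot(inherits(plan, "plan_record"), inherits(phantom, "phantom_spec"),
            inherits(cfg, "toy_engine_config"))
  sp <- cfg$grid_spacing_mm
  ax <- lapply(1:3, function(a) {
    n <- max(2L, floor(phantom$size_mm[a] / sp))
    phantom$center_mm[a] + (seq_len(n) - (n + 1) / 2) * sp
  })
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  pts <- cbind(rep(ax[[1]], times = ny * nz),
               rep(rep(ax[[2]], each = nx), times = nz),
               rep(ax[[3]], each = nx * ny))
  origin <- c(ax[[1]][1], ax[[2]][1], ax[[3]][1])
  lapply(plan$beams, function(beam) {
    dose_gy <- toy_dose_at_points(beam, phantom, cfg, pts)
    if (cfg$noise_sd_pct > 0) {
      if (!is.null(cfg$seed))
        set.seed((cfg$seed + beam$beam_number) %% .Machine$integer.max)
      dose_gy <- pmax(0, dose_gy *
                        (1 + stats::rnorm(length(dose_gy),
                                          0, cfg$noise_sd_pct / 100)))
    }
    dose_grid(array(dose_gy, dim = c(nx, ny, nz)),
              origin = origin, spacing = rep(sp, 3),
              summation = "beam", source_engine = "toy",
              beam_number = beam$beam_number)
  })
}

#' Evaluate the toy engine directly on an analysis-plane lattice
#'
#' Bypasses the 3D grid (no resampling error); used for plane-level
#' self-consistency checks.
#'
#' @param beam a [beam_record()].
#' @param phantom a [phantom_spec()].
#' @param cfg a [toy_engine_config()].
#' @param spec a [plane_spec()].
#' @param role passed to [dose_plane()].
#' @return a [dose_plane()].
#' @export
toy_dose_on_plane <- function(beam, phantom, cfg, spec, role = "reference") {
  off <- .plane_offsets(spec)
  nu <- spec$extent[1]; nv <- spec$extent[2]
  ou <- rep(off$u, times = nv); ov <- rep(off$v, each = nu)
  pts <- cbind(spec$origin[1] + ou * spec$axis_u[1] + ov * spec$axis_v[1],
               spec$origin[2] + ou * spec$axis_u[2] + ov * spec$axis_v[2],
               spec$origin[3] + ou * spec$axis_u[3] + ov * spec$axis_v[3])
  vals <- toy_dose_at_points(beam, phantom, cfg, pts)
  dose_plane(matrix(vals, nu, nv), matrix(TRUE, nu, nv), spec, role = role)
}

#' Random synthetic Monaco-dialect plan
#'
#' Beams at evenly spread gantry angles, each with 2-3 segments of jittered
#' roughly rectangular apertures (3-7 cm fields) and 80-160 MU: the scale of
#' a typical online-adaptive IMRT fraction.
#'
#' @param n_beams number of beams.
#' @param seed RNG seed (all randomness in the plan derives from it).
#' @param field_half_cm range of field half widths, cm.
#' @return a [plan_record()] in the Monaco dialect.
#' @export
make_synthetic_plan <- function(n_beams = 15L, seed = 1L,
                                field_half_cm = c(1.5, 3.5)) {
  set.seed(seed)
  geom <- aperture_geometry()
  mid <- (geom$leaf_boundaries[-1] +
          geom$leaf_boundaries[-(geom$n_leaf_pairs + 1L)]) / 2
  beams <- lapply(seq_len(n_beams), function(bi) {
    gantry <- round(((bi - 1) * 360 / n_beams +
                       stats::runif(1, 0, 360 / n_beams / 2)) %% 360, 1)
    wu <- stats::runif(1, field_half_cm[1], field_half_cm[2])
    wv <- stats::runif(1, field_half_cm[1], field_half_cm[2])
    n_cp <- sample(2:3, 1)
    wts <- stats::runif(n_cp, 0.5, 1.5); wts <- wts / sum(wts)
    # weights at 0.01-cm-compatible precision so files round-trip exactly
    wts <- round(wts, 4); wts[n_cp] <- 1 - sum(wts[-n_cp])
    cps <- lapply(seq_len(n_cp), function(ci) {
      a <- rep(0.02, geom$n_leaf_pairs); b <- rep(0.02, geom$n_leaf_pairs)
      open_ <- abs(mid) <= wu
      a[open_] <- round(-wv + stats::runif(sum(open_), -0.3, 0.3), 2)
      b[open_] <- round(wv + stats::runif(sum(open_), -0.3, 0.3), 2)
      control_point_record(wts[ci], a, b)
    })
    beam_record(beam_number = bi, gantry_angle = gantry,
                mu = round(stats::runif(1, 80, 160), 1),
                control_points = cps)
  })
  plan_record("monaco", beams, reference_point = c(0, 0, 0),
              machine_label = "SyntheticMRL", fraction_label = "synth")
}

#' Default phantom for synthetic cases
#'
#' A 24 cm water-equivalent cube centered at the isocenter, with a couch top
#' (modeled in both calculations) and a posterior RF-coil slab (modeled only
#' in the reference calculation) behind its posterior face.
#'
#' @param coil logical: include the posterior coil slab (transmission
#'   0.978, the 2.2% attenuation)?
#' @return a [phantom_spec()].
#' @export
default_phantom <- function(coil = TRUE) {
  phantom_spec(size_mm = c(240, 240, 240),
               couch = list(y0 = 135, y1 = 150, transmission = 0.97),
               coil = if (coil) list(y0 = 122, y1 = 132, transmission = 0.978)
                      else NULL)
}

#' Generate a synthetic QA case
#'
#' Builds a Monaco-dialect plan and two per-beam dose sets from the toy
#' engine: the "reference" side with the B-field emulation on (2 mm Lorentz
#' displacement) and the posterior coil present, the "evaluated" side with
#' neither -- mimicking a B-field-aware primary calculation paired with a
#' conventional second calculation that ignores the coil. With a `dir`, the
#' plan, dose files and a manifest are written to disk (deterministically:
#' the same seed yields byte-identical files).
#'
#' @param name case label.
#' @param n_beams number of beams.
#' @param seed RNG seed driving the plan and any engine noise.
#' @param dir optional output directory (created); `NULL` keeps the case in
#'   memory only.
#' @param noise_sd_pct engine noise, percent (applied to both sides with
#'   independent streams); 0 by default.
#' @param bfield_shift_mm emulated deflection on the reference side, mm.
#' @param grid_spacing_mm engine grid spacing, mm.
#' @return an object of class `imu_case`: the plan, per-beam `ref_grids` and
#'   `eval_grids`, the manifest data frame, and file paths when written.
#' @export
make_synthetic_case <- function(name = "case", n_beams = 15L, seed = 1L,
                                dir = NULL, noise_sd_pct = 0,
                                bfield_shift_mm = 2,
                                grid_spacing_mm = 4) {
  plan <- make_synthetic_plan(n_beams, seed)
  cfg_ref <- toy_engine_config(bfield_shift_mm = bfield_shift_mm,
                               noise_sd_pct = noise_sd_pct,
                               grid_spacing_mm = grid_spacing_mm,
                               seed = seed * 1000L)
  cfg_eval <- toy_engine_config(bfield_shift_mm = 0,
                                noise_sd_pct = noise_sd_pct,
                                grid_spacing_mm = grid_spacing_mm,
                                seed = seed * 1000L + 500L)
  ref_grids <- toy_dose_engine(plan, default_phantom(coil = TRUE), cfg_ref)
  eval_grids <- toy_dose_engine(plan, default_phantom(coil = FALSE), cfg_eval)
  manifest <- data.frame(
    beam = vapply(plan$beams, `[[`, 0L, "beam_number"),
    kind = "matched", magnitude = 0, expected_match = TRUE,
    stringsAsFactors = FALSE)
  case <- structure(list(name = name, seed = seed, plan = plan,
                         ref_grids = ref_grids, eval_grids = eval_grids,
                         manifest = manifest,
                         cfg_ref = cfg_ref, cfg_eval = cfg_eval,
                         plan_path = NULL, ref_dir = NULL, eval_dir = NULL),
                    class = "imu_case")
  if (!is.null(dir)) case <- write_case(case, dir)
  case
}

#' Write a case's plan, dose files and manifest to a directory
#'
#' @param case an `imu_case`.
#' @param dir output directory.
#' @return the case with `plan_path`, `ref_dir`, `eval_dir` filled in.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "imu_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_dir <- file.path(dir, "reference"); eval_dir <- file.path(dir, "evaluated")
  dir.create(ref_dir, showWarnings = FALSE)
  dir.create(eval_dir, showWarnings = FALSE)
  plan_path <- file.path(dir, "rtplan.dcm")
  write_rtplan(case$plan, plan_path)
  for (g in case$ref_grids)
    write_rtdose(g, file.path(ref_dir, sprintf("beam_%03d.dcm", g$beam_number)))
  for (g in case$eval_grids)
    write_rtdose(g, file.path(eval_dir, sprintf("beam_%03d.dcm", g$beam_number)))
  yaml::write_yaml(list(name = case$name, seed = case$seed,
                        manifest = lapply(seq_len(nrow(case$manifest)),
                                          function(i) as.list(case$manifest[i, ]))),
                   file.path(dir, "manifest.yaml"))
  case$plan_path <- plan_path; case$ref_dir <- ref_dir; case$eval_dir <- eval_dir
  case
}

#' Inject a deliberate mismatch into one beam of a case
#'
#' Perturbs the evaluated side only (the reference stays the ground truth)
#' and records the perturbation in the manifest:
#' * `mu_error`: evaluated dose scaled by `1 + magnitude/100` (the engine is
#'   linear in MU, so this is exactly a wrong-MU recalculation);
#' * `leaf_shift`: evaluated dose recomputed with both leaf banks displaced
#'   by `magnitude` mm along the leaf-travel direction;
#' * `wrong_shift_sign`: evaluated dose recomputed with the B-field
#'   emulation at the opposite sign of the reference side;
#' * `missing_coil_correction`: evaluated dose recomputed with the posterior
#'   coil slab present (so the pipeline's posterior correction
#'   double-counts; anterior beams are unaffected).
#'
#' @param case an `imu_case`.
#' @param kind one of the four mismatch kinds.
#' @param magnitude percent for `mu_error`, mm for `leaf_shift`; ignored for
#'   the other kinds. Must be `> 0` where used.
#' @param beam beam number to perturb.
#' @return the perturbed case (files are NOT rewritten; call [write_case()]).
#' @export
inject_mismatch <- function(case, kind = c("mu_error", "leaf_shift",
                                           "wrong_shift_sign",
                                           "missing_coil_correction"),
                            magnitude = 0, beam = 1L) {
  stopifnot(inherits(case, "imu_case"))
  kind <- match.arg(kind)
  bi <- which(vapply(case$plan$beams, `[[`, 0L, "beam_number") == beam)
  if (length(bi) != 1) stop("no beam numbered ", beam, " in the case")
  if (kind %in% c("mu_error", "leaf_shift") && magnitude < 0)
    stop("magnitude must be >= 0")
  if (kind == "mu_error") {
    g <- case$eval_grids[[bi]]
    g$values <- g$values * (1 + magnitude / 100)
    case$eval_grids[[bi]] <- g
  } else if (kind == "leaf_shift") {
    if (magnitude > 0) {
      plan2 <- case$plan
      plan2$beams[[bi]]$control_points <-
        lapply(plan2$beams[[bi]]$control_points, function(cp) {
          cp$bank_a <- cp$bank_a + magnitude / 10
          cp$bank_b <- cp$bank_b + magnitude / 10
          cp
        })
      case$eval_grids[[bi]] <- toy_dose_engine(
        plan_record("monaco", plan2$beams[bi],
                    reference_point = case$plan$reference_point),
        default_phantom(coil = FALSE), case$cfg_eval)[[1]]
    }
  } else if (kind == "wrong_shift_sign") {
    cfg <- case$cfg_eval
    cfg$bfield_shift_mm <- -case$cfg_ref$bfield_shift_mm
    case$eval_grids[[bi]] <- toy_dose_engine(
      plan_record("monaco", case$plan$beams[bi],
                  reference_point = case$plan$reference_point),
      default_phantom(coil = FALSE), cfg)[[1]]
  } else if (kind == "missing_coil_correction") {
    case$eval_grids[[bi]] <- toy_dose_engine(
      plan_record("monaco", case$plan$beams[bi],
                  reference_point = case$plan$reference_point),
      default_phantom(coil = TRUE), case$cfg_eval)[[1]]
  }
  row <- case$manifest$beam == beam
  case$manifest$kind[row] <- kind
  case$manifest$magnitude[row] <- magnitude
  case$manifest$expected_match[row] <-
    kind == "leaf_shift" && magnitude == 0
  case
}
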