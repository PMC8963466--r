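# BEV-parallel plane extraction from 3D dose grids, the magnetic-field
# lateral-shift approximation, and coil attenuation corrections.
#
# Fixed frame conventions (DICOM patient coordinates, head-first supine):
#   +x patient left, +y posterior, +z superior. The main magnetic field of the
#   MR-Linac is along +z (superior-inferior). The gantry rotates about z:
#   beam direction d(theta) = (-sin theta, cos theta, 0), so gantry 0 points
#   anterior -> posterior and the beam axis is never parallel to the B axis
#   for physically realizable (coplanar) beams.

B_AXIS <- c(0, 0, 1)

#' Unit vectors of a beam's BEV frame
#'
#' @param gantry_angle gantry angle, degrees IEC 61217.
#' @return list with `dir` (beam direction, source towards isocenter), `u`
#'   (in-plane leaf-stacking axis, parallel to superior-inferior for coplanar
#'   beams) and `v` (in-plane leaf-travel axis, always perpendicular to both
#'   the B-field axis and the beam axis; the lateral-shift direction).
#' @export
beam_unit_vectors <- function(gantry_angle) {
  th <- gantry_angle * pi / 180
  dir <- c(-sin(th), cos(th), 0)
  vraw <- c(dir[2] * B_AXIS[3] - dir[3] * B_AXIS[2],
            dir[3] * B_AXIS[1] - dir[1] * B_AXIS[3],
            dir[1] * B_AXIS[2] - dir[2] * B_AXIS[1])   # dir x B
  nv <- sqrt(sum(vraw^2))
  if (nv < 1e-9)
    stop("beam axis is parallel to the B-field axis; no BEV-Y direction exists")
  v <- vraw / nv
  u <- c(v[2] * dir[3] - v[3] * dir[2],
         v[3] * dir[1] - v[1] * dir[3],
         v[1] * dir[2] - v[2] * dir[1])                # v x dir
  list(dir = dir, u = u, v = v)
}

#' Source position of a beam in patient coordinates (mm)
#' @param beam a [beam_record()].
#' @return 3-vector, mm.
#' @export
beam_source_position <- function(beam) {
  f <- beam_unit_vectors(beam$gantry_angle)
  beam$isocenter - beam$source_distance_cm * 10 * f$dir
}

#' Specification of a BEV-parallel analysis plane
#'
#' @param origin plane origin (on the plane), mm, patient coordinates.
#' @param axis_u,axis_v,normal orthonormal right-handed frame with
#'   `normal = axis_u x axis_v`; `axis_v` is the lateral-shift (BEV-Y) axis.
#' @param spacing lattice spacing, mm.
#' @param extent `(nu, nv)` samples along `axis_u` and `axis_v`.
#' @return an object of class `plane_spec`.
#' @export
plane_spec <- function(origin, axis_u, axis_v, normal, spacing, extent) {
  axis_u <- as.numeric(axis_u); axis_v <- as.numeric(axis_v)
  normal <- as.numeric(normal)
  M <- cbind(axis_u, axis_v, normal)
  if (max(abs(crossprod(M) - diag(3))) > 1e-9)
    stop("plane axes must be orthonormal")
  cx <- c(axis_u[2] * axis_v[3] - axis_u[3] * axis_v[2],
          axis_u[3] * axis_v[1] - axis_u[1] * axis_v[3],
          axis_u[1] * axis_v[2] - axis_u[2] * axis_v[1])
  if (max(abs(cx - normal)) > 1e-9)
    stop("plane frame must be right-handed (normal = u x v)")
  stopifnot(spacing > 0, length(extent) == 2L, all(extent >= 2))
  structure(list(origin = as.numeric(origin), axis_u = axis_u,
                 axis_v = axis_v, normal = normal,
                 spacing = as.numeric(spacing),
                 extent = as.integer(extent)),
            class = "plane_spec")
}

#' BEV-parallel plane through the reference point for a beam
#'
#' The plane is perpendicular to the beam central axis and passes through the
#' plan reference point. Its `axis_v` is perpendicular to both the B-field
#' axis (patient superior-inferior) and the beam axis -- the direction along
#' which the magnetic-field lateral shift acts -- and `axis_u` completes the
#' right-handed frame.
#'
#' @param beam a [beam_record()].
#' @param reference_point 3-vector, mm (plane origin).
#' @param spacing lattice spacing, mm.
#' @param extent `(nu, nv)` samples.
#' @return a [plane_spec()].
#' @export
bev_plane_for_beam <- function(beam, reference_point, spacing = 1,
                               extent = c(121L, 121L)) {
  f <- beam_unit_vectors(beam$gantry_angle)
  plane_spec(origin = reference_point, axis_u = f$u, axis_v = f$v,
             normal = f$dir, spacing = spacing, extent = extent)
}

# lattice offsets from the plane origin, mm; sample (iu, iv) sits at
# origin + off_u[iu]*axis_u + off_v[iv]*axis_v
.plane_offsets <- function(spec) {
  list(u = (seq_len(spec$extent[1]) - (spec$extent[1] + 1) / 2) * spec$spacing,
       v = (seq_len(spec$extent[2]) - (spec$extent[2] + 1) / 2) * spec$spacing)
}

#' 2D dose image on an analysis plane
#'
#' @param values `nu x nv` matrix of dose, Gy; `NA` where invalid.
#' @param valid logical matrix marking samples inside the source grid.
#' @param spec the [plane_spec()] the image lies on.
#' @param role `"reference"` or `"evaluated"`.
#' @param shift_applied_mm net lateral shift applied along `axis_v`, mm.
#' @return an object of class `dose_plane`.
#' @export
dose_plane <- function(values, valid, spec, role = c("reference", "evaluated"),
                       shift_applied_mm = 0) {
  role <- match.arg(role)
  stopifnot(inherits(spec, "plane_spec"),
            all(dim(values) == spec$extent),
            all(dim(valid) == spec$extent))
  if (any(values[valid] < 0, na.rm = TRUE))
    stop("dose values must be non-negative")
  structure(list(values = values, valid = valid, spec = spec, role = role,
                 shift_applied_mm = as.numeric(shift_applied_mm)),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<dose_plane> %dx%d @ %.2f mm, role=%s, shift=%+.2f mm, max %.4g Gy, %.1f%% valid\n",
              x$spec$extent[1], x$spec$extent[2], x$spec$spacing, x$role,
              x$shift_applied_mm, suppressWarnings(max(x$values, na.rm = TRUE)),
              100 * mean(x$valid)))
  invisible(x)
}

#' Resample a 3D dose grid on an analysis plane
#'
#' Trilinear interpolation of the grid at every plane lattice sample. Samples
#' outside the grid volume are marked invalid (`NA`), never zero-filled, so
#' they can be excluded from any region of interest downstream. Raises if the
#' plane lies wholly outside the grid.
#'
#' @param grid a [dose_grid()].
#' @param spec a [plane_spec()].
#' @param role passed through to the [dose_plane()].
#' @return a [dose_plane()].
#' @export
sample_plane <- function(grid, spec, role = "reference") {
  off <- .plane_offsets(spec)
  nu <- spec$extent[1]; nv <- spec$extent[2]
  # world coordinates of all samples (n x 3)
  ou <- rep(off$u, times = nv); ov <- rep(off$v, each = nu)
  pts <- cbind(spec$origin[1] + ou * spec$axis_u[1] + ov * spec$axis_v[1],
               spec$origin[2] + ou * spec$axis_u[2] + ov * spec$axis_v[2],
               spec$origin[3] + ou * spec$axis_u[3] + ov * spec$axis_v[3])
  vals <- interp_grid(grid, pts)
  valid <- !is.na(vals)
  if (!any(valid)) stop("analysis plane lies wholly outside the dose grid")
  dose_plane(matrix(vals, nu, nv), matrix(valid, nu, nv), spec, role = role)
}

#' Trilinear interpolation of a dose grid at arbitrary points
#'
#' @param grid a [dose_grid()].
#' @param pts `n x 3` matrix of patient coordinates, mm.
#' @return numeric vector; `NA` outside the grid.
#' @export
interp_grid <- function(grid, pts) {
  d <- dim(grid$values)
  rel <- sweep(pts, 2, grid$origin)           # n x 3
  q <- rel %*% grid$orientation               # continuous index - 1 (in mm)
  q <- sweep(q, 2, grid$spacing, "/") + 1     # 1-based fractional voxel index
  eps <- 1e-9
  inside <- q[, 1] >= 1 - eps & q[, 1] <= d[1] + eps &
            q[, 2] >= 1 - eps & q[, 2] <= d[2] + eps &
            q[, 3] >= 1 - eps & q[, 3] <= d[3] + eps
  out <- rep(NA_real_, nrow(pts))
  if (!any(inside)) return(out)
  # clamp base voxels so points exactly on the upper faces interpolate cleanly
  i0 <- pmin(pmax(floor(q[inside, 1]), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(q[inside, 2]), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(q[inside, 3]), 1), d[3] - 1)
  fx <- pmin(pmax(q[inside, 1] - i0, 0), 1)
  fy <- pmin(pmax(q[inside, 2] - j0, 0), 1)
  fz <- pmin(pmax(q[inside, 3] - k0, 0), 1)
  V <- grid$values
  idx <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  c000 <- V[idx(i0,     j0,     k0)];     c100 <- V[idx(i0 + 1, j0,     k0)]
  c010 <- V[idx(i0,     j0 + 1, k0)];     c110 <- V[idx(i0 + 1, j0 + 1, k0)]
  c001 <- V[idx(i0,     j0,     k0 + 1)]; c101 <- V[idx(i0 + 1, j0,     k0 + 1)]
  c011 <- V[idx(i0,     j0 + 1, k0 + 1)]; c111 <- V[idx(i0 + 1, j0 + 1, k0 + 1)]
  w <- (c000 * (1 - fx) + c100 * fx) * (1 - fy) +
       (c010 * (1 - fx) + c110 * fx) * fy
  w2 <- (c001 * (1 - fx) + c101 * fx) * (1 - fy) +
        (c011 * (1 - fx) + c111 * fx) * fy
  out[inside] <- w * (1 - fz) + w2 * fz
  out
}

#' Translate a dose plane along its BEV-Y axis
#'
#' Shifts the image by `shift_mm` along `axis_v` (linear interpolation
#' between lattice columns); the trailing edge that has no source data
#' becomes invalid. The shift never touches the stored 3D dose -- it exists
#' only for the comparison step.
#'
#' @param plane a [dose_plane()].
#' @param shift_mm signed shift, mm; positive moves the image towards +v.
#' @return the shifted [dose_plane()] with `shift_applied_mm` updated.
#' @export
shift_plane <- function(plane, shift_mm) {
  stopifnot(inherits(plane, "dose_plane"))
  nv <- plane$spec$extent[2]
  ext_mm <- (nv - 1) * plane$spec$spacing
  if (abs(shift_mm) >= ext_mm)
    stop("shift (", shift_mm, " mm) exceeds the plane extent (", ext_mm, " mm)")
  if (shift_mm == 0) return(plane)
  src <- seq_len(nv) - shift_mm / plane$spec$spacing
  j0 <- floor(src); f <- src - j0
  # snap exact-integer sources so an integer-lattice shift is a pure roll
  exact <- abs(f) < 1e-9 | abs(f - 1) < 1e-9
  j0[abs(f - 1) < 1e-9] <- j0[abs(f - 1) < 1e-9] + 1L
  f[exact] <- 0
  ok0 <- j0 >= 1 & j0 <= nv
  ok1 <- (j0 + 1) >= 1 & (j0 + 1) <= nv
  vals <- plane$values; vv <- plane$valid
  newv <- matrix(NA_real_, nrow(vals), nv)
  newok <- matrix(FALSE, nrow(vals), nv)
  for (j in seq_len(nv)) {
    if (!ok0[j]) next
    a <- vals[, j0[j]]; va <- vv[, j0[j]]
    if (f[j] == 0) {
      newv[, j] <- a; newok[, j] <- va
    } else {
      if (!ok1[j]) next
      b <- vals[, j0[j] + 1]; vb <- vv[, j0[j] + 1]
      w <- (1 - f[j]) * a + f[j] * b
      ok <- va & vb
      newv[ok, j] <- w[ok]; newok[, j] <- ok
    }
  }
  newv[!newok] <- NA_real_
  dose_plane(newv, newok, plane$spec, role = plane$role,
             shift_applied_mm = plane$shift_applied_mm + shift_mm)
}

#' Correction configuration for the comparison step
#'
#' @param bfield_shift_mm magnitude of the magnetic-field lateral-shift
#'   approximation, mm (2 mm from profile commissioning).
#' @param shift_sign `+1` or `-1`: the corrective shift applied to the
#'   reference plane is `shift_sign * bfield_shift_mm` along `axis_v`. The
#'   default `-1` moves the reference pattern opposite the emulated Lorentz
#'   deflection (which is along `+v`), overlaying it on a no-B-field
#'   calculation.
#' @param posterior_coil_factor multiplicative correction applied to the
#'   evaluated dose of posterior beams (0.978 = 2.2% posterior RF-coil
#'   attenuation the second calculation does not model).
#' @param anterior_coil_factor same for anterior beams; 1.0 (the 0.4%
#'   anterior coil attenuation is ignored).
#' @param posterior_gantry_range closed gantry interval (degrees, interval
#'   arithmetic modulo 360) classified as posterior.
#' @return an object of class `correction_config`.
#' @export
correction_config <- function(bfield_shift_mm = 2.0,
                              shift_sign = -1,
                              posterior_coil_factor = 0.978,
                              anterior_coil_factor = 1.0,
                              posterior_gantry_range = c(100, 260)) {
  stopifnot(is.finite(bfield_shift_mm), shift_sign %in% c(-1, 1),
            posterior_coil_factor > 0, posterior_coil_factor <= 1,
            anterior_coil_factor > 0, anterior_coil_factor <= 1,
            length(posterior_gantry_range) == 2L)
  structure(list(bfield_shift_mm = bfield_shift_mm, shift_sign = shift_sign,
                 posterior_coil_factor = posterior_coil_factor,
                 anterior_coil_factor = anterior_coil_factor,
                 posterior_gantry_range = as.numeric(posterior_gantry_range)),
            class = "correction_config")
}

#' Is a beam posterior?
#'
#' True iff the gantry angle lies in the configured closed interval
#' (modulo 360), i.e. the beam traverses the couch / posterior RF coil.
#'
#' @param beam a [beam_record()] (or a bare gantry angle).
#' @param cfg a [correction_config()].
#' @return logical.
#' @export
classify_posterior <- function(beam, cfg = correction_config()) {
  g <- if (inherits(beam, "beam_record")) beam$gantry_angle else as.numeric(beam)
  g <- g %% 360
  r <- cfg$posterior_gantry_range %% 360
  if (r[1] <= r[2]) g >= r[1] & g <= r[2] else g >= r[1] | g <= r[2]
}

#' Apply a multiplicative attenuation correction
#'
#' Multiplies every dose value by `factor` and records the applied factor in
#' the object's `attenuation_applied` field (a product over repeated
#' applications). Works on [dose_plane()] and [dose_grid()] objects.
#'
#' @param x a [dose_plane()] or [dose_grid()].
#' @param factor positive multiplicative factor (0.978 for the posterior
#'   coil).
#' @return corrected copy of `x`.
#' @export
apply_attenuation <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("attenuation factor must be a single positive number")
  x$values <- x$values * factor
  x$attenuation_applied <- (x$attenuation_applied %||% 1) * factor
  x
}
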