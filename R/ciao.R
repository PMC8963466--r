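# Complete irradiated area outline (CIAO): the union over control points of
# the open MLC aperture intersected with the jaws, projected onto the
# analysis plane and rasterized as the gamma region of interest.

#' Rectilinear aperture polygon of a control point
#'
#' The open aperture at the isocenter-projection plane: the union over leaf
#' pairs of `[bank_a_i, bank_b_i]` (leaf-travel direction, v) by the pair's
#' edge interval (stacking direction, u), intersected with the jaw rectangle.
#' Pairs whose tip gap is at or below the closure tolerance (0.05 cm,
#' shared with the jaw-derivation rule) contribute nothing; an empty polygon
#' is allowed.
#'
#' @param cp a [control_point_record()].
#' @param geometry an [aperture_geometry()].
#' @return an object of class `aperture_polygon`: a data frame of per-pair
#'   open rectangles with columns `u0`, `u1` (stacking interval, cm) and
#'   `v0`, `v1` (travel interval, cm), with the total open `area` (cm^2) as
#'   an attribute.
#' @export
aperture_polygon <- function(cp, geometry) {
  stopifnot(inherits(cp, "control_point_record"),
            inherits(geometry, "aperture_geometry"),
            length(cp$bank_a) == geometry$n_leaf_pairs)
  jaw_u <- sort(cp$jaw_y)   # stacking direction jaws (fixed 22 cm in monaco)
  jaw_v <- if (is.null(cp$jaw_x))
    c(-geometry$max_half_field, geometry$max_half_field) else sort(cp$jaw_x)
  lo_u <- geometry$leaf_boundaries[-(geometry$n_leaf_pairs + 1L)]
  hi_u <- geometry$leaf_boundaries[-1L]
  v0 <- pmax(cp$bank_a, jaw_v[1]); v1 <- pmin(cp$bank_b, jaw_v[2])
  u0 <- pmax(lo_u, jaw_u[1]); u1 <- pmin(hi_u, jaw_u[2])
  open_ <- (cp$bank_b - cp$bank_a) > LEAF_CLOSED_TOL_CM &
    (v1 - v0) > 0 & (u1 - u0) > 0
  rect <- data.frame(u0 = u0[open_], u1 = u1[open_],
                     v0 = v0[open_], v1 = v1[open_])
  structure(rect, class = c("aperture_polygon", "data.frame"),
            area = sum((rect$u1 - rect$u0) * (rect$v1 - rect$v0)))
}

#' Open area of an aperture polygon, cm^2
#' @param polygon an [aperture_polygon()].
#' @return numeric scalar.
#' @export
aperture_area <- function(polygon) attr(polygon, "area")

# membership test of BEV points (cm, isocenter plane) against an aperture
# polygon; points exactly on an edge count inside (deterministic tie rule)
.in_aperture <- function(polygon, u, v) {
  inside <- rep(FALSE, length(u))
  for (r in seq_len(nrow(polygon))) {
    inside <- inside |
      (u >= polygon$u0[r] & u <= polygon$u1[r] &
       v >= polygon$v0[r] & v <= polygon$v1[r])
  }
  inside
}

#' Binary region-of-interest mask on an analysis plane
#'
#' @param mask logical `nu x nv` matrix on the plane lattice.
#' @param source beam identifier.
#' @param exclusions_applied names of subtracted ROIs.
#' @return an object of class `ciao_mask`.
#' @export
ciao_mask_record <- function(mask, source = NA_integer_,
                             exclusions_applied = character()) {
  structure(list(mask = mask, source = source,
                 exclusions_applied = exclusions_applied),
            class = "ciao_mask")
}

#' @export
print.ciao_mask <- function(x, ...) {
  cat(sprintf("<ciao_mask> beam %s: %d ROI pixels (%.1f%% of plane)%s\n",
              as.character(x$source), sum(x$mask), 100 * mean(x$mask),
              if (length(x$exclusions_applied))
                paste0(", exclusions: ",
                       paste(x$exclusions_applied, collapse = ", ")) else ""))
  invisible(x)
}

#' CIAO mask of a beam on an analysis plane
#'
#' Union over control points of the open aperture polygons, projected from
#' the isocenter plane to the analysis plane by the divergence factor
#' (source-to-plane distance over source-to-isocenter distance), and
#' rasterized on the plane lattice with a pixel-center containment test
#' (centers exactly on an edge count inside).
#'
#' @param beam a [beam_record()].
#' @param spec the beam's analysis-plane [plane_spec()].
#' @param geometry an [aperture_geometry()]; defaults to the beam's own.
#' @return a [ciao_mask_record()]. Raises if the union is empty (no region
#'   of interest to analyze).
#' @export
ciao_mask <- function(beam, spec, geometry = beam$geometry) {
  stopifnot(inherits(beam, "beam_record"), inherits(spec, "plane_spec"))
  src <- beam_source_position(beam)
  # divergence factor: source-to-plane over source-to-isocenter distance
  d_plane <- sum((spec$origin - src) * spec$normal)
  d_iso <- beam$source_distance_cm * 10
  if (d_plane <= 0) stop("analysis plane is on the source side of the beam")
  proj <- d_plane / d_iso
  off <- .plane_offsets(spec)
  nu <- spec$extent[1]; nv <- spec$extent[2]
  # plane offsets are measured from the plane origin; project pixel centers
  # back to the isocenter plane (cm)
  u_cm <- off$u / proj / 10
  v_cm <- off$v / proj / 10
  uu <- rep(u_cm, times = nv); vv <- rep(v_cm, each = nu)
  inside <- rep(FALSE, nu * nv)
  for (cp in beam$control_points) {
    poly <- aperture_polygon(cp, geometry)
    if (nrow(poly) > 0) inside <- inside | .in_aperture(poly, uu, vv)
  }
  if (!any(inside))
    stop("beam ", beam$beam_number,
         ": empty CIAO (all control points closed); no ROI to analyze")
  ciao_mask_record(matrix(inside, nu, nv), source = beam$beam_number)
}

# even-odd ray-casting point-in-polygon; vertices (n x 2), points as vectors
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Subtract an exclusion contour from a CIAO mask
#'
#' Removes pixels whose centers fall inside the contour (even-odd rule) --
#' used to exclude, e.g., an air cavity that would otherwise dominate the
#' gamma failure count. Idempotent; an empty contour leaves the mask
#' unchanged. Raises if the exclusion would empty the ROI.
#'
#' @param mask a [ciao_mask_record()].
#' @param contour `k x 2` matrix of polygon vertices in plane coordinates
#'   (mm, offsets from the plane origin along `axis_u`, `axis_v`), or a list
#'   with elements `name` and `vertices`.
#' @param spec the [plane_spec()] the mask lies on.
#' @param name label recorded in `exclusions_applied`.
#' @return the reduced [ciao_mask_record()].
#' @export
subtract_roi <- function(mask, contour, spec, name = "exclusion") {
  stopifnot(inherits(mask, "ciao_mask"), inherits(spec, "plane_spec"))
  if (is.list(contour) && !is.matrix(contour)) {
    name <- contour$name %||% name
    contour <- contour$vertices
  }
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) {
    mask$exclusions_applied <- unique(c(mask$exclusions_applied, name))
    return(mask)
  }
  off <- .plane_offsets(spec)
  nu <- spec$extent[1]; nv <- spec$extent[2]
  uu <- rep(off$u, times = nv); vv <- rep(off$v, each = nu)
  inside <- .point_in_polygon(uu, vv, contour[, 1], contour[, 2])
  new_mask <- mask$mask & !matrix(inside, nu, nv)
  if (!any(new_mask))
    stop("exclusion contour covers the whole CIAO; empty ROI")
  mask$mask <- new_mask
  mask$exclusions_applied <- unique(c(mask$exclusions_applied, name))
  mask
}
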