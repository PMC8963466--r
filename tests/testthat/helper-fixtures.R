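# builders shared across the suite; everything is generated in code

# beam with a single rectangular open aperture (half widths in cm)
open_beam <- function(beam_number = 1L, gantry = 0, half_u = 5, half_v = 5,
                      mu = 100, n_cp = 1L) {
  geom <- aperture_geometry()
  mid <- (geom$leaf_boundaries[-1] +
          geom$leaf_boundaries[-(geom$n_leaf_pairs + 1L)]) / 2
  a <- rep(0.02, geom$n_leaf_pairs); b <- rep(0.02, geom$n_leaf_pairs)
  open_ <- abs(mid) <= half_u
  a[open_] <- -half_v; b[open_] <- half_v
  cps <- lapply(seq_len(n_cp), function(i)
    control_point_record(1 / n_cp, a, b))
  beam_record(beam_number, gantry_angle = gantry, mu = mu,
              control_points = cps)
}

open_plan <- function(...) plan_record("monaco", list(open_beam(...)))

# flat dose plane of a given value on a gantry-0 BEV frame
flat_plane <- function(value, n = 21L, spacing = 1, role = "reference") {
  sp <- plane_spec(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                   spacing, c(n, n))
  dose_plane(matrix(value, n, n), matrix(TRUE, n, n), sp, role = role)
}

# smooth strictly positive random field (sum of Gaussian bumps)
smooth_field <- function(n, seed, spacing = 1) {
  set.seed(seed)
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  f <- matrix(0.5, n, n)
  for (k in 1:4) {
    cx <- stats::runif(1, min(x), max(x)); cy <- stats::runif(1, min(x), max(x))
    s <- stats::runif(1, 0.25, 0.6) * n * spacing
    amp <- stats::runif(1, 0.5, 2)
    f <- f + amp * outer(exp(-(x - cx)^2 / (2 * s^2)),
                         exp(-(x - cy)^2 / (2 * s^2)))
  }
  f
}

as_plane <- function(values, spacing = 1, role = "reference") {
  n1 <- nrow(values); n2 <- ncol(values)
  sp <- plane_spec(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                   spacing, c(n1, n2))
  dose_plane(values, matrix(TRUE, n1, n2), sp, role = role)
}

full_roi <- function(n1, n2 = n1) ciao_mask_record(matrix(TRUE, n1, n2))

# mildly perturbed evaluated/reference pair of smooth planes
smooth_plane_pair <- function(seed, n = 32L, spacing = 1) {
  ref <- smooth_field(n, seed, spacing)
  set.seed(seed + 5000)
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  pert <- 1 + 0.02 * outer(sin(x / 7 + stats::runif(1)),
                           cos(x / 9 + stats::runif(1)))
  list(ref = as_plane(ref, spacing),
       eval = as_plane(ref * pert, spacing, role = "evaluated"))
}

# uniform synthetic dose grid
uniform_grid <- function(value = 2, n = c(12L, 12L, 12L), spacing = c(5, 5, 5),
                         origin = -spacing * (n - 1) / 2) {
  dose_grid(array(value, dim = n), origin = origin, spacing = spacing)
}
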