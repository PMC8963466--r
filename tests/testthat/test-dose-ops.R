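# plane geometry, grid resampling, shifting, posterior classification and
# attenuation corrections

test_that("BEV frames are orthonormal, right-handed, with v perpendicular to the B axis", {
  for (g in c(0, 37.5, 90, 123, 180, 222, 270, 318.2, 359.9)) {
    f <- beam_unit_vectors(g)
    M <- cbind(f$u, f$v, f$dir)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-12)
    # v is perpendicular to both the B axis (z) and the beam axis
    expect_lt(abs(f$v[3]), 1e-12)
    expect_lt(abs(sum(f$v * f$dir)), 1e-12)
    # right-handed: normal = u x v
    cx <- c(f$u[2] * f$v[3] - f$u[3] * f$v[2],
            f$u[3] * f$v[1] - f$u[1] * f$v[3],
            f$u[1] * f$v[2] - f$u[2] * f$v[1])
    expect_lt(max(abs(cx - f$dir)), 1e-12)
  }
  # gantry 0: beam along anterior-posterior (+y), u along superior-inferior
  f0 <- beam_unit_vectors(0)
  expect_equal(f0$dir, c(0, 1, 0))
  expect_equal(abs(f0$u), c(0, 0, 1))
})

test_that("the analysis plane passes through the reference point", {
  ref <- c(12.5, -3, 41)
  spec <- bev_plane_for_beam(open_beam(gantry = 77), ref, spacing = 2,
                             extent = c(21L, 21L))
  expect_equal(spec$origin, ref)
  expect_lt(abs(sum((spec$origin - ref) * spec$normal)), 1e-12)
})

test_that("plane sampling is exact on constant and linear fields", {
  g <- uniform_grid(2)
  spec <- bev_plane_for_beam(open_beam(gantry = 33), c(0, 0, 0),
                             spacing = 1.5, extent = c(15L, 15L))
  p <- sample_plane(g, spec)
  expect_true(all(p$valid))
  expect_equal(max(abs(p$values - 2)), 0)
  # linear ramp D = a + b*z is reproduced exactly by trilinear interpolation
  n <- c(14L, 14L, 14L); sp <- c(4, 4, 4)
  z <- (seq_len(n[3]) - (n[3] + 1) / 2) * sp[3]
  vals <- array(rep(5 + 0.01 * z, each = n[1] * n[2]), dim = n)
  gr <- dose_grid(vals, origin = -sp * (n - 1) / 2, spacing = sp)
  spec2 <- bev_plane_for_beam(open_beam(gantry = 61), c(0, 0, 0),
                              spacing = 1, extent = c(19L, 19L))
  p2 <- sample_plane(gr, spec2)
  off <- imucheck:::.plane_offsets(spec2)
  zs <- outer(off$u * spec2$axis_u[3], off$v * spec2$axis_v[3], "+")
  expect_lt(max(abs(p2$values - (5 + 0.01 * zs))), 1e-12)
})

test_that("plane sampling is linear in the grid values and matches a brute-force resampler", {
  set.seed(12)
  n <- c(13L, 12L, 11L); sp <- c(5, 5, 5)
  v1 <- array(stats::runif(prod(n), 1, 3), dim = n)
  v2 <- array(stats::runif(prod(n), 0, 2), dim = n)
  org <- -sp * (n - 1) / 2
  g1 <- dose_grid(v1, org, sp); g2 <- dose_grid(v2, org, sp)
  g12 <- dose_grid(0.3 * v1 + 0.7 * v2, org, sp)
  spec <- bev_plane_for_beam(open_beam(gantry = 142), c(1, 2, -3),
                             spacing = 2, extent = c(13L, 13L))
  pa <- sample_plane(g1, spec); pb <- sample_plane(g2, spec)
  pc <- sample_plane(g12, spec)
  expect_equal(pc$values, 0.3 * pa$values + 0.7 * pb$values, tolerance = 1e-12)

  # independent scalar resampler (straightforward per-point trilinear loop)
  off <- imucheck:::.plane_offsets(spec)
  brute <- matrix(NA_real_, spec$extent[1], spec$extent[2])
  for (i in seq_len(spec$extent[1])) {
    for (j in seq_len(spec$extent[2])) {
      p <- spec$origin + off$u[i] * spec$axis_u + off$v[j] * spec$axis_v
      q <- (p - org) / sp + 1
      i0 <- floor(q)
      if (any(i0 < 1) || any(i0 > n - 1)) next
      fr <- q - i0
      acc <- 0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
        acc <- acc + w * v1[i0[1] + dx, i0[2] + dy, i0[3] + dz]
      }
      brute[i, j] <- acc
    }
  }
  ok <- !is.na(brute)
  expect_lt(max(abs(pa$values[ok] - brute[ok])), 1e-9)
  expect_error(sample_plane(g1, bev_plane_for_beam(open_beam(), c(0, 0, 1e5),
                                                   extent = c(5L, 5L))),
               "outside")
})

test_that("plane shifting rolls, inverts, invalidates the trailing edge and bounds the shift", {
  pp <- smooth_plane_pair(3, n = 41)
  p <- pp$ref
  expect_identical(shift_plane(p, 0), p)
  # integer-lattice shift is a pure roll with one invalid trailing column
  s1 <- shift_plane(p, p$spec$spacing)
  expect_equal(s1$values[, 2:41], p$values[, 1:40])
  expect_false(any(s1$valid[, 1]))
  expect_equal(s1$shift_applied_mm, 1)
  # round trip on the interior of a smooth field
  rt <- shift_plane(shift_plane(p, 2), -2)
  ok <- rt$valid
  expect_lt(max(abs(rt$values[ok] - p$values[ok])) / max(p$values), 2e-3)
  expect_error(shift_plane(p, 1000), "exceeds")
})

test_that("posterior classification uses a closed gantry interval modulo 360", {
  cfg <- correction_config()
  expect_true(classify_posterior(180, cfg))
  expect_false(classify_posterior(0, cfg))
  expect_true(classify_posterior(100, cfg))   # closed boundary
  expect_true(classify_posterior(260, cfg))
  expect_false(classify_posterior(99.9, cfg))
  expect_false(classify_posterior(260.1, cfg))
  # wrapped interval
  wrap <- correction_config(posterior_gantry_range = c(300, 60))
  expect_true(classify_posterior(0, wrap))
  expect_true(classify_posterior(300, wrap))
  expect_false(classify_posterior(180, wrap))
  expect_true(classify_posterior(open_beam(gantry = 180), cfg))
})

test_that("attenuation correction scales dose, composes and commutes with extraction and shift", {
  p <- flat_plane(1.0)   # 100 cGy
  corrected <- apply_attenuation(p, 0.978)
  expect_equal(max(corrected$values), 0.978)   # 97.8 cGy exactly
  expect_equal(corrected$attenuation_applied, 0.978)
  expect_identical(apply_attenuation(p, 1.0)$values, p$values)
  rt <- apply_attenuation(apply_attenuation(p, 0.9), 1 / 0.9)
  expect_equal(rt$values, p$values, tolerance = 1e-12)
  expect_error(apply_attenuation(p, 0), "positive")
  expect_error(apply_attenuation(p, -1), "positive")

  # commutes with plane extraction
  g <- uniform_grid(3)
  spec <- bev_plane_for_beam(open_beam(gantry = 205), c(0, 0, 0),
                             spacing = 2, extent = c(11L, 11L))
  a <- apply_attenuation(sample_plane(g, spec), 0.978)
  b <- sample_plane(apply_attenuation(g, 0.978), spec)
  expect_equal(a$values, b$values, tolerance = 1e-12)
  # commutes with shifting
  pp <- smooth_plane_pair(8, n = 31)$ref
  x <- shift_plane(apply_attenuation(pp, 0.978), 2)
  y <- apply_attenuation(shift_plane(pp, 2), 0.978)
  expect_equal(x$values, y$values, tolerance = 1e-12)
})
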