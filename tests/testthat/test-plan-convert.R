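# Monaco -> Eclipse conversion rules

test_that("SAD rescaling follows similar triangles", {
  expect_equal(rescale_positions(14.35, 143.5, 100), 10)
  expect_equal(rescale_positions(0, 143.5, 100), 0)
  expect_equal(rescale_positions(0, 97, 123), 0)
  # the physical +/-11 cm limit projects to the printed +/-7.67 cm
  expect_equal(round(rescale_positions(11, 143.5, 100), 2), 7.67)
  # double application via the inverse is the identity
  x <- c(-7.3, 0.01, 4.999)
  expect_equal(rescale_positions(rescale_positions(x, 143.5, 100), 100, 143.5),
               x, tolerance = 1e-12)
  expect_error(rescale_positions(1, -143.5, 100), "positive")
})

test_that("axis swap flips the collimator 0 -> 90 and refuses anything else", {
  b <- open_beam()
  sw <- swap_axes(b)
  expect_equal(sw$collimator_angle, 90)
  expect_error(swap_axes(sw), "collimator angle 0")
  b2 <- open_beam(); b2$collimator_angle <- 15
  expect_error(swap_axes(b2), "collimator angle 0")
})

test_that("X jaws derive from the open-leaf envelope with margin, clip and fixed mode", {
  geom <- aperture_geometry()
  a <- rep(0.02, geom$n_leaf_pairs); b <- rep(0.02, geom$n_leaf_pairs)
  a[10:20] <- -3.0; b[10:20] <- 4.2
  cp <- control_point_record(1, a, b)
  cfg <- conversion_config()
  expect_equal(derive_x_jaws(cp, cfg), c(-3.5, 4.7))
  expect_equal(derive_x_jaws(cp, conversion_config(jaw_mode = "fixed")),
               c(-7.67, 7.67))
  # wide leaves clip to the physical projection of +/-11 cm
  a2 <- a; b2 <- b; a2[10:20] <- -7.5; b2[10:20] <- 7.5
  expect_equal(derive_x_jaws(control_point_record(1, a2, b2), cfg),
               c(-7.67, 7.67))
  # closed parked pairs are ignored by the envelope
  a3 <- a; b3 <- b; a3[25] <- 6.9; b3[25] <- 6.92   # gap below tolerance
  expect_equal(derive_x_jaws(control_point_record(1, a3, b3), cfg),
               c(-3.5, 4.7))
  # fully closed aperture degenerates with a warning
  expect_warning(j <- derive_x_jaws(control_point_record(1, rep(0, 31),
                                                         rep(0, 31)), cfg),
                 "closed")
  expect_equal(j, c(-0.5, 0.5))
})

test_that("extended-SSD switch preserves the source position and inverts", {
  b <- open_beam(gantry = 237)
  src_before <- beam_source_position(b)
  e <- to_extended_ssd(b)
  expect_identical(e$technique, "extended_ssd")
  expect_equal(e$sad, 100)
  expect_equal(beam_source_position(e), src_before)
  expect_error(to_extended_ssd(e), "already")
  back <- from_extended_ssd(e)
  expect_equal(back$sad, 143.5)
  expect_identical(back$technique, "sad")
  expect_error(from_extended_ssd(back), "already")
})

test_that("full conversion relabels energy, keeps MU, validates, and refuses twice", {
  plan <- make_synthetic_plan(4, seed = 6)
  conv <- convert_plan(plan)
  expect_identical(conv$dialect, "eclipse")
  expect_identical(nrow(validate_plan(conv)), 0L)
  expect_true(all(vapply(conv$beams, `[[`, "", "energy_label") == "6MV-FFF"))
  expect_equal(vapply(conv$beams, `[[`, 0, "mu"),
               vapply(plan$beams, `[[`, 0, "mu"))
  expect_error(convert_plan(conv), "monaco-dialect")
  # derived jaws contain every open leaf tip of every segment
  for (bi in seq_along(conv$beams)) {
    for (cp in conv$beams[[bi]]$control_points) {
      open_ <- (cp$bank_b - cp$bank_a) > imucheck:::LEAF_CLOSED_TOL_CM
      expect_true(all(cp$jaw_x[1] <= cp$bank_a[open_] + 1e-9))
      expect_true(all(cp$jaw_x[2] >= cp$bank_b[open_] - 1e-9))
    }
  }
})

test_that("conversion preserves the projected aperture at the original plane", {
  set.seed(17)
  for (rep_i in 1:20) {
    plan <- make_synthetic_plan(1, seed = 100 + rep_i)
    conv <- convert_plan(plan)
    s <- 143.5 / 100
    for (ci in seq_along(plan$beams[[1]]$control_points)) {
      p0 <- aperture_polygon(plan$beams[[1]]$control_points[[ci]],
                             plan$beams[[1]]$geometry)
      p1 <- aperture_polygon(conv$beams[[1]]$control_points[[ci]],
                             conv$beams[[1]]$geometry)
      expect_identical(nrow(p0), nrow(p1))
      for (col in c("u0", "u1", "v0", "v1"))
        expect_lt(max(abs(p0[[col]] - p1[[col]] * s)), 1e-9)
    }
  }
})

test_that("from_leaves and fixed jaw modes agree inside the CIAO", {
  plan <- make_synthetic_plan(2, seed = 31)
  conv_l <- convert_plan(plan, conversion_config(jaw_mode = "from_leaves"))
  conv_f <- convert_plan(plan, conversion_config(jaw_mode = "fixed"))
  ph <- default_phantom(coil = FALSE)
  cfg <- toy_engine_config()
  for (bi in 1:2) {
    bl <- conv_l$beams[[bi]]; bf <- conv_f$beams[[bi]]
    spec <- bev_plane_for_beam(bl, c(0, 0, 0), spacing = 1,
                               extent = c(101L, 101L))
    pl <- toy_dose_on_plane(bl, ph, cfg, spec, role = "reference")
    pf <- toy_dose_on_plane(bf, ph, cfg, spec, role = "evaluated")
    roi <- ciao_mask(bl, spec)
    g <- gamma_map(pl, pf, roi, gamma_criteria(3, 3))
    expect_gte(g$pass_rate, 99.5)
  }
})
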