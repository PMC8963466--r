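# gamma engine: identities, analytic cases, oracle equivalence, monotonicity

test_that("identical planes give gamma == 0 and a 100% pass rate", {
  pp <- smooth_plane_pair(1)
  ev <- pp$ref; ev$role <- "evaluated"
  g <- gamma_map(pp$ref, ev, full_roi(32), gamma_criteria(3, 3))
  expect_equal(max(g$gamma, na.rm = TRUE), 0)
  expect_equal(g$pass_rate, 100)
  expect_identical(g$roi_pixel_count, 1024L)
})

test_that("a uniform 3% scaling passes everywhere under global normalization", {
  pp <- smooth_plane_pair(2)
  ev <- pp$ref; ev$role <- "evaluated"
  ev$values <- ev$values * 1.03
  g <- gamma_map(pp$ref, ev, full_roi(32), gamma_criteria(3, 3))
  expect_equal(g$pass_rate, 100)
})

test_that("a smooth edge translated by exactly the DTA scores gamma <= 1 and passes", {
  n <- 41L; spacing <- 1
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  edge <- function(shift) {
    v <- stats::pnorm((x - shift) / 2)   # sigmoid edge along v, sigma 2 mm
    as_plane(matrix(rep(v, each = n), n, n) + 0.1, spacing)
  }
  ref <- edge(0)
  ev <- edge(3); ev$role <- "evaluated"      # translated by dta = 3 mm
  g <- gamma_map(ref, ev, full_roi(n), gamma_criteria(3, 3))
  expect_lte(max(g$gamma, na.rm = TRUE), 1 + 1e-9)
  expect_equal(g$pass_rate, 100)
  # the edge region genuinely needs the full DTA
  mid <- g$gamma[, 19:23]
  expect_gt(max(mid, na.rm = TRUE), 0.9)
  # agrees with the brute-force oracle
  gb <- gamma_brute_force(ref, ev, full_roi(n), gamma_criteria(3, 3))
  expect_lt(max(abs(g$gamma - gb$gamma), na.rm = TRUE), 1e-6)
})

test_that("the optimized search equals the exhaustive oracle on random smooth pairs", {
  for (seed in c(11, 23, 35)) {
    pp <- smooth_plane_pair(seed)
    cr <- gamma_criteria(3, 3)
    g1 <- gamma_map(pp$ref, pp$eval, full_roi(32), cr)
    g2 <- gamma_brute_force(pp$ref, pp$eval, full_roi(32), cr)
    expect_lt(max(abs(g1$gamma - g2$gamma), na.rm = TRUE), 1e-6)
    expect_equal(g1$pass_rate, g2$pass_rate)
  }
  # refining the oracle's sub-lattice changes gamma only at the
  # discretization scale, and never increases it
  pp <- smooth_plane_pair(47)
  g1 <- gamma_brute_force(pp$ref, pp$eval, full_roi(32), gamma_criteria(3, 3))
  g2 <- gamma_brute_force(pp$ref, pp$eval, full_roi(32), gamma_criteria(3, 3),
                          refine = 2L)
  expect_true(all(g2$gamma <= g1$gamma + 1e-12, na.rm = TRUE))
  # where the dose term dominates, gamma varies along the lattice at the
  # dose-gradient scale (~0.7 per mm here), so halving the 0.33 mm step can
  # move the discrete minimum by up to ~0.12
  expect_lt(max(g1$gamma - g2$gamma, na.rm = TRUE), 0.15)
})

test_that("gamma is pointwise monotone in the criteria", {
  pp <- smooth_plane_pair(5)
  pp$eval$values <- pp$eval$values * 1.04
  # same candidate lattice so the comparison is exact
  c33 <- gamma_criteria(3, 3, interp_step_mm = 0.25, search_radius_mm = 9)
  c32 <- gamma_criteria(3, 2, interp_step_mm = 0.25, search_radius_mm = 9)
  c53 <- gamma_criteria(5, 3, interp_step_mm = 0.25, search_radius_mm = 9)
  g33 <- gamma_map(pp$ref, pp$eval, full_roi(32), c33)
  g32 <- gamma_map(pp$ref, pp$eval, full_roi(32), c32)
  g53 <- gamma_map(pp$ref, pp$eval, full_roi(32), c53)
  expect_true(all(g33$gamma <= g32$gamma + 1e-12, na.rm = TRUE))
  expect_true(all(g53$gamma <= g33$gamma + 1e-12, na.rm = TRUE))
  expect_gte(g33$pass_rate, g32$pass_rate)
})

test_that("gamma is invariant under a common dose rescaling", {
  pp <- smooth_plane_pair(6)
  pp$eval$values <- pp$eval$values * 1.02
  g1 <- gamma_map(pp$ref, pp$eval, full_roi(32), gamma_criteria(3, 3))
  ref2 <- pp$ref; ref2$values <- ref2$values * 7.3
  ev2 <- pp$eval; ev2$values <- ev2$values * 7.3
  g2 <- gamma_map(ref2, ev2, full_roi(32), gamma_criteria(3, 3))
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-9)
  expect_equal(g2$normalization_dose, g1$normalization_dose * 7.3)
})

test_that("gamma values are capped at the search-radius bound", {
  ref <- flat_plane(1, n = 21L)
  ev <- flat_plane(10, n = 21L, role = "evaluated")   # hopeless dose mismatch
  g <- gamma_map(ref, ev, full_roi(21), gamma_criteria(3, 3))
  expect_equal(max(g$gamma, na.rm = TRUE), 3)   # search_radius / dta
  expect_equal(g$pass_rate, 0)
})

test_that("zero normalization dose and mismatched lattices are errors", {
  z <- flat_plane(0)
  expect_error(gamma_map(z, z, full_roi(21), gamma_criteria()),
               "zero normalization|non-negative")
  pp <- smooth_plane_pair(9)
  small <- smooth_plane_pair(9, n = 16)
  expect_error(gamma_map(pp$ref, small$eval, full_roi(32), gamma_criteria()),
               "lattice")
  big <- smooth_plane_pair(10, n = 80)
  expect_error(gamma_brute_force(big$ref, big$eval, full_roi(80),
                                 gamma_criteria()), "64")
})

test_that("pass-rate summaries aggregate order-invariantly", {
  pp <- smooth_plane_pair(13)
  mk <- function(scale) {
    ev <- pp$ref; ev$role <- "evaluated"; ev$values <- ev$values * scale
    gamma_map(pp$ref, ev, full_roi(32), gamma_criteria(3, 3))
  }
  r100 <- mk(1)          # pass rate 100
  r_bad <- mk(1.5)       # heavy failure
  s <- pass_rate_summary(list(r100, r_bad), threshold = 95)
  expect_identical(s$per_beam$verdict, c("pass", "fail"))
  expect_equal(s$mean, mean(c(r100$pass_rate, r_bad$pass_rate)))
  s_perm <- pass_rate_summary(list(r_bad, r100), threshold = 95)
  expect_equal(sort(s_perm$per_beam$pass_rate), sort(s$per_beam$pass_rate))
  expect_equal(s_perm$mean, s$mean)
  expect_equal(s_perm$sd, s$sd)
  s1 <- pass_rate_summary(list(r100))
  expect_equal(s1$mean, s1$min)
  expect_equal(s1$mean, s1$max)
})
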