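test_that("effective attenuation coefficient follows sqrt(3 mu_a mu_s')", {
  expect_equal(effective_attenuation(optical_properties(0, 1.0)), 0)
  expect_equal(effective_attenuation(optical_properties(1 / 3, 1.0)), 1)
  expect_equal(effective_attenuation(optical_properties(0.01, 1.41)),
               sqrt(3 * 0.01 * 1.41))
  expect_equal(effective_attenuation(optical_properties(0.01, 1.41)),
               0.2057, tolerance = 1e-3)
})

test_that("optical property invariants are enforced", {
  expect_error(optical_properties(-0.01, 1), "mu_a")
  expect_error(optical_properties(0.01, 0), "mu_s_prime")
  expect_error(optical_properties(0.01, 1, g = 1), "g must")
  expect_error(optical_properties(0.01, 1, boundary_A = 0), "boundary_A")
  op <- optical_properties(0.02, 1.2)
  expect_equal(op$D, 1 / (3 * 1.22))
  expect_equal(op$z0, 1 / 1.2)
})

test_that("transport mean free path reproduces the printed skin values", {
  expect_equal(round(transport_mfp(skin_optics(730)), 3), 0.704)
  expect_equal(round(transport_mfp(skin_optics(810)), 3), 0.806)
  expect_equal(round(transport_mfp(skin_optics(855)), 3), 0.877)
  expect_equal(transport_mfp(optical_properties(0.4, 0.6)), 1)
})

test_that("near-detector distance expressed in transport mean free paths", {
  expect_equal(distance_in_mfp(4.2, skin_optics(730), digits = 1), 6.0)
  expect_equal(distance_in_mfp(4.2, skin_optics(810), digits = 1), 5.2)
  # the shortest-MTF wavelength is conventionally quoted truncated
  expect_equal(distance_in_mfp(4.2, skin_optics(855), digits = 2,
                               mode = "truncate"), 4.78)
  op <- skin_optics(730)
  expect_equal(distance_in_mfp(transport_mfp(op), op), 1)
  expect_error(distance_in_mfp(0, op), "distance")
})

test_that("monotonicity of derived coefficients", {
  mu_a <- seq(0.005, 0.05, length.out = 9)
  eff <- vapply(mu_a, function(a) {
    effective_attenuation(optical_properties(a, 1.2))
  }, numeric(1))
  expect_true(all(diff(eff) > 0))
  mfp <- vapply(mu_a, function(a) {
    transport_mfp(optical_properties(a, 1.2))
  }, numeric(1))
  expect_true(all(diff(mfp) < 0))
})

test_that("reflectance ratios follow the inverse-square and exponential laws", {
  op <- skin_optics(730)
  g <- probe_geometry_preset("asbuilt")
  expect_equal(reflectance(op, 7) / reflectance(op, 7), 1)
  # vanishing absorption: pure inverse-square ratio
  op0 <- optical_properties(1e-12, 1.41)
  expect_equal(reflectance(op0, g$r1) / reflectance(op0, g$r2),
               g$r2^2 / g$r1^2, tolerance = 1e-4)
  # hand-evaluated ratio (r2^2/r1^2) exp(mu_eff (r2 - r1)) at skin optics
  ratio <- reflectance(op, g$r1) / reflectance(op, g$r2)
  expect_equal(ratio, (g$r2^2 / g$r1^2) * exp(op$mu_eff * (g$r2 - g$r1)))
  expect_equal(ratio, 602.7, tolerance = 2e-4)
  expect_error(reflectance(op, 0), "invalid geometry")
})

test_that("two-distance inversion round-trips the forward model exactly", {
  for (geom in list(probe_geometry_preset("asbuilt"),
                    probe_geometry_preset("nominal"))) {
    for (mu in seq(0.05, 0.5, by = 0.05)) {
      op <- optical_properties(mu^2 / (3 * 1.27), 1.27)
      est <- invert_mu_eff(reflectance(op, geom$r1),
                           reflectance(op, geom$r2), geom)
      expect_equal(as.numeric(est), mu, tolerance = 1e-12)
    }
  }
  # published-scale value with the nominal 4/20 mm geometry
  geom <- probe_geometry_preset("nominal")
  op <- optical_properties(0.142^2 / (3 * 1.3), 1.3)
  est <- invert_mu_eff(reflectance(op, 4), reflectance(op, 20), geom)
  expect_equal(as.numeric(est), 0.142, tolerance = 1e-12)
})

test_that("inversion is invariant to common detector gain scaling", {
  op <- skin_optics(730)
  geom <- probe_geometry_preset("asbuilt")
  R1 <- reflectance(op, geom$r1)
  R2 <- reflectance(op, geom$r2)
  base <- as.numeric(invert_mu_eff(R1, R2, geom))
  for (k in c(1e-6, 0.1, 3, 1e8)) {
    expect_equal(as.numeric(invert_mu_eff(k * R1, k * R2, geom)), base)
  }
})

test_that("negative inversions are flagged, not raised; bad flux is raised", {
  geom <- probe_geometry_preset("asbuilt")
  # R1 r1^2 < R2 r2^2: physically inadmissible, flagged
  expect_warning(est <- invert_mu_eff(1, 1, geom), "negative")
  expect_true(attr(est, "flagged"))
  expect_lt(as.numeric(est), 0)
  expect_error(invert_mu_eff(0, 1, geom), "sensor fault")
  expect_error(invert_mu_eff(1, -2, geom), "sensor fault")
})

test_that("repeat summaries reproduce reported means and RSDs", {
  for (tr in repeat_triples) {
    s <- summarize_repeats(tr$values)
    expect_equal(s$mean_reported, tr$mean)
    expect_equal(s$mean, mean(tr$values))
  }
  s <- summarize_repeats(c(0.2, 0.2, 0.2))
  expect_equal(s$mean, 0.2)
  expect_equal(s$rsd, 0)
  expect_error(summarize_repeats(0.2), "insufficient repeats")
})
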