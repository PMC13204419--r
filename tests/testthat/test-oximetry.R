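test_that("optical density is -log10 of the relative flux", {
  expect_equal(optical_density(1), 0)
  expect_equal(optical_density(0.01), 2)
  expect_equal(optical_density(10^-0.5), 0.5)
  expect_error(optical_density(0), "invalid flux")
  expect_error(optical_density(-1), "invalid flux")
})

test_that("absorption ratio recovers mu_a ratios from constructed OD slopes", {
  geom <- probe_geometry_preset("asbuilt")
  r_ref <- r_reference(geom)
  dr <- geom$r2 - geom$r1
  musp <- 1.3
  # build OD differences from the analytic OD slope at the reference radius
  d_od <- function(mu_a) {
    (dr / log(10)) * (sqrt(3 * mu_a * musp) + 2 / r_ref)
  }
  kap <- absorption_ratio(d_od(0.02), d_od(0.01), geom)
  expect_equal(as.numeric(kap), 2.0, tolerance = 1e-12)
  expect_false(attr(kap, "flagged"))
  expect_equal(as.numeric(absorption_ratio(d_od(0.015), d_od(0.015), geom)),
               1.0)
  # degenerate: corrected denominator exactly zero
  corr <- 2 * dr / (r_ref * log(10))
  expect_error(absorption_ratio(0.5, corr, geom), "degenerate")
  # opposite-sign corrected terms are flagged with a warning
  expect_warning(out <- absorption_ratio(corr + 0.1, corr - 0.1, geom),
                 "opposite-sign")
  expect_true(attr(out, "flagged"))
})

test_that("reference-radius conventions bracket the logarithmic mean", {
  geom <- probe_geometry_preset("asbuilt")
  lm_ <- r_reference(geom, "logmean")
  expect_equal(lm_, (geom$r2 - geom$r1) / log(geom$r2 / geom$r1))
  expect_lt(r_reference(geom, "geomean"), lm_)
  expect_lt(lm_, r_reference(geom, "midpoint"))
  expect_equal(r_reference(geom, "r1"), geom$r1)
})

test_that("saturation estimator hits the algebraic limits exactly", {
  sp <- default_spectra()
  e730 <- sp[sp$wavelength_nm == 730, ]
  e855 <- sp[sp$wavelength_nm == 855, ]
  expect_equal(rso2_from_ratio(e730$eps_hbo2 / e855$eps_hbo2, sp), 1.0)
  expect_equal(rso2_from_ratio(e730$eps_hb / e855$eps_hb, sp), 0.0)
})

test_that("saturation round-trips through the mixture model", {
  sp <- default_spectra()
  for (S in seq(0.1, 0.9, by = 0.1)) {
    kap <- mixture_absorption(sp, 730, S) / mixture_absorption(sp, 855, S)
    expect_equal(rso2_from_ratio(kap, sp), S, tolerance = 1e-9)
  }
})

test_that("saturation is monotone in kappa on the admissible interval", {
  sp <- default_spectra()
  e730 <- sp[sp$wavelength_nm == 730, ]
  e855 <- sp[sp$wavelength_nm == 855, ]
  k_hb <- e730$eps_hb / e855$eps_hb        # maps to 0
  k_hbo2 <- e730$eps_hbo2 / e855$eps_hbo2  # maps to 1
  ks <- seq(min(k_hb, k_hbo2) + 1e-6, max(k_hb, k_hbo2) - 1e-6,
            length.out = 50)
  s <- rso2_from_ratio(ks, sp)
  expect_true(all(diff(s) < 0) || all(diff(s) > 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("noise-free telemetry streams recover the saturation exactly", {
  geom <- probe_geometry_preset("asbuilt")
  sp <- default_spectra()
  for (S in seq(0.1, 0.9, by = 0.2)) {
    ph <- occlusion_phantom(saturation = S)
    stream <- occlusion_series(ph, drop_to = S, duration = 3, dt = 1)
    series <- rso2_series(stream, geom, sp)
    expect_equal(series$rso2, rep(S, nrow(series)), tolerance = 1e-9)
    expect_false(any(series$clipped))
  }
})

test_that("occlusion episodes are recovered pointwise from clean streams", {
  geom <- probe_geometry_preset("asbuilt")
  sp <- default_spectra()
  ph <- occlusion_phantom(saturation = 0.7)
  stream <- occlusion_series(ph, drop_to = 0.45)
  truth <- attr(stream, "truth")
  series <- rso2_series(stream, geom, sp)
  expect_equal(nrow(series), nrow(truth))
  expect_equal(series$rso2, truth$saturation, tolerance = 1e-6)
  smry <- rso2_summary(series)
  expect_gte(smry$t_minimum_s, 8)
  expect_lte(smry$t_minimum_s, 12)
  expect_lt(abs(smry$final - smry$baseline) / smry$baseline, 0.02)
})

test_that("incomplete frames are skipped and counted", {
  geom <- probe_geometry_preset("asbuilt")
  sp <- default_spectra()
  ph <- occlusion_phantom()
  stream <- occlusion_series(ph, drop_to = 0.5, duration = 5, dt = 1)
  # single-wavelength stream: every frame incomplete
  one_wl <- stream[stream$wavelength_nm == 730, ]
  expect_message(series <- rso2_series(one_wl, geom, sp), "skipped 6")
  expect_equal(nrow(series), 0)
  expect_equal(attr(series, "n_skipped"), 6L)
  # drop a single detector sample: only that frame is skipped
  broken <- stream[-5, ]
  expect_message(series2 <- rso2_series(broken, geom, sp), "skipped 1")
  expect_equal(nrow(series2), 5)
})

test_that("rSO2 is invariant to common gain but sensitive to per-detector gain", {
  geom <- probe_geometry_preset("asbuilt")
  sp <- default_spectra()
  ph <- occlusion_phantom()
  stream <- occlusion_series(ph, drop_to = 0.5, duration = 5, dt = 1)
  base <- rso2_series(stream, geom, sp)
  # scaling every flux by one constant cancels in each OD difference
  scaled <- stream
  scaled$flux <- scaled$flux * 7.3
  expect_equal(rso2_series(scaled, geom, sp)$rso2, base$rso2,
               tolerance = 1e-12)
  # a gain change on a single detector at a single wavelength breaks the
  # OD differences and must propagate to the estimate - each wavelength's
  # OD difference has to come from one consistent gain state
  uneven <- stream
  sel <- uneven$detector_id == "near" & uneven$wavelength_nm == 730
  uneven$flux[sel] <- uneven$flux[sel] * 2
  expect_false(isTRUE(all.equal(rso2_series(uneven, geom, sp)$rso2,
                                base$rso2)))
})

test_that("out-of-range saturations are clipped and flagged", {
  geom <- probe_geometry_preset("asbuilt")
  sp <- default_spectra()
  # kappa beyond the pure-oxyhemoglobin limit implies S > 1
  e730 <- sp[sp$wavelength_nm == 730, ]
  e855 <- sp[sp$wavelength_nm == 855, ]
  k_over <- (e730$eps_hbo2 / e855$eps_hbo2) * 0.9
  expect_gt(rso2_from_ratio(k_over, sp), 1)
  # series-level clipping: synthesize one frame whose ODs give that kappa
  dr <- geom$r2 - geom$r1
  corr <- 2 * dr / (r_reference(geom) * log(10))
  d_od2 <- 0.3
  d_od1 <- corr + sqrt(k_over) * (d_od2 - corr)
  frame <- data.frame(
    timestamp_s = 0, wavelength_nm = rep(c(730, 855), each = 2),
    detector_id = rep(c("near", "far"), 2), distance_mm = rep(c(geom$r1, geom$r2), 2),
    flux = c(1, 10^-d_od1, 1, 10^-d_od2), gain = 1L,
    integration_ms = 100, temp_c = NA_real_)
  series <- rso2_series(frame, geom, sp)
  expect_true(series$clipped)
  expect_equal(series$rso2, 1)
})
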