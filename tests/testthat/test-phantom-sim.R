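test_that("noise-free detector readings invert to the phantom truth exactly", {
  geom <- probe_geometry_preset("asbuilt")
  ph <- phantom_with_mueff(0.21, noise_rsd = 0, seed = 3)
  tel <- generate_detector_readings(ph, geom, 730, n = 4)
  near <- tel$flux[tel$detector_id == "near"]
  far <- tel$flux[tel$detector_id == "far"]
  expect_equal(as.numeric(invert_mu_eff(near, far, geom)),
               rep(0.21, 4), tolerance = 1e-12)
})

test_that("generators are bitwise-reproducible functions of the seed", {
  geom <- probe_geometry_preset("asbuilt")
  ph <- phantom_spec(seed = 9)
  expect_identical(generate_detector_readings(ph, geom, 730, n = 5),
                   generate_detector_readings(ph, geom, 730, n = 5))
  expect_identical(led_stability_series(seed = 2),
                   led_stability_series(seed = 2))
  expect_identical(occlusion_series(occlusion_phantom(seed = 4), 0.5),
                   occlusion_series(occlusion_phantom(seed = 4), 0.5))
  expect_identical(temperature_rise_series(5, seed = 8),
                   temperature_rise_series(5, seed = 8))
  expect_false(identical(led_stability_series(seed = 2),
                         led_stability_series(seed = 3)))
})

test_that("detector noise matches the target RSD distributionally", {
  geom <- probe_geometry_preset("asbuilt")
  ph <- phantom_spec(noise_rsd = 0.3, seed = 17)
  tel <- generate_detector_readings(ph, geom, 730, n = 20)
  n <- 20
  ci <- 0.3 * sqrt(qchisq(c(0.025, 0.975), n - 1) / (n - 1))
  for (det in c("near", "far")) {
    x <- tel$flux[tel$detector_id == det]
    rsd <- 100 * sd(x) / mean(x)
    expect_gt(rsd, ci[1])
    expect_lt(rsd, ci[2])
  }
})

test_that("LED stability series has the target RSD and no drift", {
  flat <- led_stability_series(rsd = 0, seed = 1)
  expect_equal(length(unique(flat$flux)), 1)
  s <- led_stability_series(n = 20, rsd = 0.23, seed = 21)
  rsd <- summarize_repeats(s$flux)$rsd
  ci <- 0.23 * sqrt(qchisq(c(0.025, 0.975), 19) / 19)
  expect_gt(rsd, ci[1])
  expect_lt(rsd, ci[2])
  # no trend drift: regression slope consistent with zero at alpha = 0.01
  fit <- summary(lm(flux ~ timestamp_s, data = s))
  expect_gt(fit$coefficients["timestamp_s", "Pr(>|t|)"], 0.01)
})

test_that("occlusion stream kinetics have the prescribed shape", {
  ph <- occlusion_phantom(saturation = 0.7)
  flat <- occlusion_series(ph, drop_to = 0.7, duration = 5, dt = 1)
  expect_equal(length(unique(attr(flat, "truth")$saturation)), 1)
  stream <- occlusion_series(ph, drop_to = 0.45)
  truth <- attr(stream, "truth")
  i_min <- which.min(truth$saturation)
  expect_gte(truth$timestamp_s[i_min], 0)
  expect_lte(truth$timestamp_s[i_min], 12)
  expect_lt(abs(truth$saturation[nrow(truth)] - 0.7) / 0.7, 0.02)
})

test_that("temperature-rise replicates start at zero and scale with power", {
  tab <- temperature_rise_series(12.08, seed = 6)
  expect_true(all(tab$dT_c[tab$t_s == 0] == 0))
  means <- tapply(tab$dT_c, tab$t_s, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
  # power proportionality is exact for the noise-free mean component
  lo <- temperature_rise_series(2, noise_scale = 0, reps = 1, seed = 1)
  hi <- temperature_rise_series(4, noise_scale = 0, reps = 1, seed = 1)
  expect_equal(hi$dT_c[hi$t_s > 0], 2 * lo$dT_c[lo$t_s > 0])
})

test_that("periodic surface drive oscillates between base and heated levels", {
  ts <- periodic_temperature_series(noise_sd = 0, seed = 1)
  expect_equal(nrow(ts), 3 * 240 / 5 + 1)
  expect_gte(min(ts$temp_c), 33.5)
  expect_lte(max(ts$temp_c), 35.0)
  expect_gt(max(ts$temp_c) - min(ts$temp_c), 1)  # visible swing
})

test_that("Monte Carlo weight accounting closes exactly", {
  op <- optical_properties(0.01, 1.41, g = 0.9)
  mc <- mc_oracle(op, 2e4, seed = 1)
  expect_lt(mc_weight_closure(mc), 1e-9)
  # no absorption: all launched weight escapes or is truncated
  op0 <- optical_properties(0, 1.41, g = 0.9)
  mc0 <- mc_oracle(op0, 5e3, seed = 2)
  expect_lt(mc_weight_closure(mc0), 1e-9)
  expect_equal(mc0$tallies$absorbed, 0)
  expect_equal(mc0$tallies$roulette_killed, 0)
  expect_equal(mc0$tallies$escaped + mc0$tallies$truncated, 5e3)
})

test_that("Monte Carlo runs are reproducible under a fixed seed", {
  op <- optical_properties(0.02, 1.2, g = 0.85)
  a <- mc_oracle(op, 5e3, seed = 33)
  b <- mc_oracle(op, 5e3, seed = 33)
  expect_identical(a$reflectance_per_area, b$reflectance_per_area)
  expect_identical(a$fluence, b$fluence)
  c_ <- mc_oracle(op, 5e3, seed = 34)
  expect_false(identical(a$reflectance_per_area, c_$reflectance_per_area))
})

test_that("Monte Carlo reflectance decays with distance as expected", {
  op <- optical_properties(0.01, 1.41, g = 0.9)
  mc <- mc_oracle(op, 5e4, seed = 12)
  keep <- mc$r_centers <= 12
  R <- mc$reflectance_per_area[keep]
  expect_true(all(R > 0))
  # smoothed monotone decay beyond the first transport mean free path
  far <- mc$r_centers[keep] > 1
  expect_true(all(diff(log(R[far])) < 0))
})

test_that("noisy two-distance pipeline recovers phantom attenuation within 2%", {
  geom <- probe_geometry_preset("asbuilt")
  for (mu in c(0.14, 0.21, 0.27)) {
    ph <- phantom_with_mueff(mu, noise_rsd = 0.3, seed = round(1000 * mu))
    tel <- generate_detector_readings(ph, geom, 730, n = 3)
    est <- invert_mu_eff(tel$flux[tel$detector_id == "near"],
                         tel$flux[tel$detector_id == "far"], geom)
    s <- summarize_repeats(as.numeric(est))
    expect_lt(abs(s$mean - mu) / mu, 0.02)
  }
})
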