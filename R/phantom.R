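#' Tissue phantom specification for the telemetry simulator
#'
#' Describes the synthetic homogeneous tissue phantom from which the
#' simulator generates detector readings: per-wavelength reduced scattering
#' coefficients, a hemoglobin-mixture absorption model (total concentration
#' and baseline saturation), thermal parameters, multiplicative detector
#' noise level and the RNG seed. Per-wavelength [optical_properties()] can
#' be supplied directly through `optics`, which then takes precedence over
#' the mixture model.
#'
#' Defaults emulate forearm skin at the probe's wavelengths: reduced
#' scattering 1.41 / 1.23 / 1.13 mm^-1 at 730 / 810 / 855 nm, baseline
#' saturation 0.7, total hemoglobin 60 umol/L, detector noise RSD 0.3%.
#'
#' @param mu_s_prime Named vector of reduced scattering coefficients,
#'   mm^-1, keyed by wavelength in nm.
#' @param saturation Baseline oxygen saturation fraction in \[0, 1\].
#' @param c_hbt_M Total hemoglobin concentration, mol/L.
#' @param spectra A [hemoglobin_extinction()] table.
#' @param optics Optional named list of [optical_properties()] keyed by
#'   wavelength (as character), overriding the mixture model.
#' @param thermal A [thermal_properties()] object.
#' @param noise_rsd Multiplicative detector noise relative SD, percent
#'   (>= 0).
#' @param g Anisotropy used when building optics from the mixture model.
#' @param boundary_A Boundary factor for the same.
#' @param seed Integer RNG seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(mu_s_prime = c(`730` = 1.41, `810` = 1.23,
                                        `855` = 1.13),
                         saturation = 0.7,
                         c_hbt_M = 6e-5,
                         spectra = hemoglobin_extinction(),
                         optics = NULL,
                         thermal = thermal_properties(),
                         noise_rsd = 0.3,
                         g = 0.9,
                         boundary_A = 1,
                         seed = 1L) {
  if (noise_rsd < 0) stop("noise_rsd must be >= 0")
  if (saturation < 0 || saturation > 1) stop("saturation must lie in [0, 1]")
  structure(
    list(mu_s_prime = mu_s_prime, saturation = saturation,
         c_hbt_M = c_hbt_M, spectra = spectra, optics = optics,
         thermal = thermal, noise_rsd = noise_rsd, g = g,
         boundary_A = boundary_A, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Tissue phantom:\n")
  if (is.null(x$optics)) {
    cat(sprintf("  mu_s' [%s nm] = %s mm^-1 (hemoglobin-mixture absorption)\n",
                paste(names(x$mu_s_prime), collapse = "/"),
                paste(format(unname(x$mu_s_prime)), collapse = "/")))
    cat(sprintf("  saturation = %.2f, HbT = %.3g mol/L\n",
                x$saturation, x$c_hbt_M))
  } else {
    cat(sprintf("  direct optics at %s nm\n",
                paste(names(x$optics), collapse = "/")))
  }
  cat(sprintf("  noise RSD = %.3g%%, seed = %d\n", x$noise_rsd, x$seed))
  invisible(x)
}

#' Optical properties of a phantom at one wavelength
#'
#' Returns the phantom's [optical_properties()] at `wavelength`, either the
#' directly supplied override or built from the hemoglobin mixture model at
#' the given saturation.
#'
#' @param phantom A [phantom_spec()].
#' @param wavelength Wavelength, nm.
#' @param saturation Optional saturation overriding the phantom baseline
#'   (used for dynamic episodes).
#' @return An [optical_properties()] object.
#' @export
phantom_optics <- function(phantom, wavelength, saturation = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"))
  key <- as.character(wavelength)
  if (!is.null(phantom$optics)) {
    if (!key %in% names(phantom$optics)) {
      stop("missing phantom optics at wavelength ", wavelength, " nm")
    }
    return(phantom$optics[[key]])
  }
  if (!key %in% names(phantom$mu_s_prime)) {
    stop("missing phantom optics at wavelength ", wavelength, " nm")
  }
  s <- if (is.null(saturation)) phantom$saturation else saturation
  mu_a <- mixture_absorption(phantom$spectra, wavelength, s,
                             phantom$c_hbt_M)
  optical_properties(mu_a, unname(phantom$mu_s_prime[key]),
                     g = phantom$g, boundary_A = phantom$boundary_A)
}

#' Phantom with a prescribed effective attenuation coefficient
#'
#' Convenience constructor for inversion studies: builds a single-wavelength
#' phantom whose optics give exactly the requested `mu_eff` at the given
#' reduced scattering coefficient (`mu_a = mu_eff^2 / (3 mu_s_prime)`).
#'
#' @param mu_eff Target effective attenuation coefficient, mm^-1.
#' @param wavelength Wavelength label, nm. Default 730.
#' @param mu_s_prime Reduced scattering coefficient, mm^-1. Default 1.27.
#' @param ... Passed to [phantom_spec()] (e.g. `noise_rsd`, `seed`).
#' @return A [phantom_spec()] with direct optics at `wavelength`.
#' @export
phantom_with_mueff <- function(mu_eff, wavelength = 730, mu_s_prime = 1.27,
                               ...) {
  op <- optical_properties(mu_eff^2 / (3 * mu_s_prime), mu_s_prime)
  optics <- stats::setNames(list(op), as.character(wavelength))
  phantom_spec(optics = optics, ...)
}

# one multiplicative-noise draw per record; rsd in percent
noisy <- function(x, rsd_percent) {
  x * (1 + rnorm(length(x), sd = rsd_percent / 100))
}

#' Simulate paired two-distance detector readings
#'
#' Generates `n` time points of near/far telemetry records at one
#' wavelength: each flux is the forward diffuse reflectance at the detector
#' distance times independent multiplicative Gaussian noise at the
#' phantom's RSD. Output follows the telemetry schema (see
#' [read_telemetry()]).
#'
#' @param phantom A [phantom_spec()].
#' @param geom A [probe_geometry()].
#' @param wavelength Wavelength, nm (must be defined in the phantom).
#' @param n Number of time points.
#' @param dt Sampling interval, s. Default 10.
#' @param t0 First timestamp, s.
#' @param gain Detector gain code recorded in the stream.
#' @param integration_ms Exposure recorded in the stream.
#' @param seed Seed; defaults to the phantom's.
#' @return Telemetry `data.frame` with `2 n` rows.
#' @export
generate_detector_readings <- function(phantom, geom, wavelength, n,
                                       dt = 10, t0 = 0, gain = 1L,
                                       integration_ms = 100,
                                       seed = phantom$seed) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(geom, "probe_geometry"), n >= 1)
  op <- phantom_optics(phantom, wavelength)
  base <- c(near = reflectance(op, geom$r1), far = reflectance(op, geom$r2))
  with_seed(seed, {
    t <- t0 + dt * (seq_len(n) - 1)
    near <- noisy(rep(base["near"], n), phantom$noise_rsd)
    far <- noisy(rep(base["far"], n), phantom$noise_rsd)
    data.frame(
      timestamp_s = rep(t, each = 2),
      wavelength_nm = wavelength,
      detector_id = rep(c("near", "far"), n),
      distance_mm = rep(c(geom$r1, geom$r2), n),
      flux = as.numeric(rbind(near, far)),
      gain = gain,
      integration_ms = integration_ms,
      temp_c = NA_real_
    )
  })
}

#' Simulated LED output stability series
#'
#' Constant mean flux with multiplicative Gaussian noise at the target
#' relative standard deviation and no trend component, emulating the
#' bench stability protocol (readings every 10 s, 20 samples).
#'
#' @param n Number of readings (>= 2). Default 20.
#' @param interval Sampling interval, s. Default 10.
#' @param rsd Target relative standard deviation, percent.
#' @param mean_flux Mean detector reading, arbitrary units.
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `timestamp_s` and `flux`.
#' @export
led_stability_series <- function(n = 20, interval = 10, rsd = 0.23,
                                 mean_flux = 100, seed = 1L) {
  if (n < 2) stop("need at least 2 readings")
  with_seed(seed, data.frame(
    timestamp_s = interval * (seq_len(n) - 1),
    flux = noisy(rep(mean_flux, n), rsd)
  ))
}

#' Saturation trajectory of a muscle-occlusion episode
#'
#' First-order kinetics: baseline before contraction, exponential decay
#' toward `drop_to` during contraction, exponential recovery to baseline
#' after release. The time constants (fall 4 s, rise 3 s) are modeling
#' choices that reproduce the qualitative dip-and-recover shape of a
#' forearm occlusion episode; only that shape is ever asserted.
#'
#' @param t Time(s), s. Vectorized.
#' @param baseline Baseline saturation fraction.
#' @param drop_to Saturation floor approached during contraction
#'   (< baseline).
#' @param t_contract Contraction onset, s. Default 0.
#' @param t_release Release time, s. Default 11.
#' @param tau_fall,tau_rise Time constants, s.
#' @return Saturation fraction(s).
#' @export
occlusion_trajectory <- function(t, baseline, drop_to, t_contract = 0,
                                 t_release = 11, tau_fall = 4,
                                 tau_rise = 3) {
  if (drop_to > baseline) stop("drop_to must not exceed baseline saturation")
  s_release <- drop_to + (baseline - drop_to) *
    exp(-(t_release - t_contract) / tau_fall)
  ifelse(t < t_contract, baseline,
         ifelse(t < t_release,
                drop_to + (baseline - drop_to) *
                  exp(-(t - t_contract) / tau_fall),
                baseline + (s_release - baseline) *
                  exp(-(t - t_release) / tau_rise)))
}

#' Simulated muscle-occlusion telemetry stream
#'
#' Per time point, the saturation trajectory sets the hemoglobin-mixture
#' absorption coefficient at each wavelength; near/far fluxes then follow
#' the forward reflectance model (with the phantom's multiplicative noise),
#' producing a paired two-wavelength stream that [rso2_series()] can
#' invert. Exact pointwise recovery requires the phantom's reduced
#' scattering coefficients to be equal at the two wavelengths (the
#' estimator's own assumption); see [occlusion_phantom()].
#'
#' @param phantom A [phantom_spec()].
#' @param drop_to Saturation floor (< phantom baseline).
#' @param t_contract,t_release Episode times, s. Defaults 0 and 11.
#' @param duration Total duration, s. Default 30.
#' @param dt Sampling interval, s. Default 0.5.
#' @param wavelengths The two wavelengths, nm. Default c(730, 855).
#' @param geom A [probe_geometry()].
#' @param tau_fall,tau_rise Trajectory time constants, s.
#' @param seed Seed; defaults to the phantom's.
#' @return Telemetry `data.frame` (4 rows per time point), with the true
#'   trajectory attached as attribute `"truth"` (`data.frame` of
#'   `timestamp_s`, `saturation`).
#' @export
occlusion_series <- function(phantom, drop_to, t_contract = 0,
                             t_release = 11, duration = 30, dt = 0.5,
                             wavelengths = c(730, 855),
                             geom = probe_geometry_preset("asbuilt"),
                             tau_fall = 4, tau_rise = 3,
                             seed = phantom$seed) {
  stopifnot(inherits(phantom, "phantom_spec"), length(wavelengths) == 2)
  t <- seq(0, duration, by = dt)
  s_t <- occlusion_trajectory(t, phantom$saturation, drop_to, t_contract,
                              t_release, tau_fall, tau_rise)
  with_seed(seed, {
    rows <- lapply(seq_along(t), function(i) {
      per_wl <- lapply(wavelengths, function(wl) {
        op <- phantom_optics(phantom, wl, saturation = s_t[i])
        flux <- noisy(c(reflectance(op, geom$r1), reflectance(op, geom$r2)),
                      phantom$noise_rsd)
        data.frame(timestamp_s = t[i], wavelength_nm = wl,
                   detector_id = c("near", "far"),
                   distance_mm = c(geom$r1, geom$r2),
                   flux = flux, gain = 1L, integration_ms = 100,
                   temp_c = NA_real_)
      })
      do.call(rbind, per_wl)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- data.frame(timestamp_s = t, saturation = s_t)
    out
  })
}

#' Phantom suited to occlusion round-trip studies
#'
#' An equal-scattering two-wavelength phantom (the saturation estimator
#' assumes equal reduced scattering at the two wavelengths), noise-free by
#' default.
#'
#' @param mu_s_prime Common reduced scattering coefficient, mm^-1.
#' @param ... Passed to [phantom_spec()].
#' @export
occlusion_phantom <- function(mu_s_prime = 1.27, ...) {
  args <- list(...)
  if (is.null(args$noise_rsd)) args$noise_rsd <- 0
  do.call(phantom_spec, c(
    list(mu_s_prime = c(`730` = mu_s_prime, `855` = mu_s_prime)), args))
}

#' Simulated surface temperature-rise replicates under irradiation
#'
#' Emulates repeated irradiation runs: the mean rise follows a saturating
#' exponential `dT(t) = dT_max * (1 - exp(-t / tau))` with `dT_max`
#' proportional to the optical power, plus additive Gaussian sensor noise.
#' The noise SD defaults to the thermal sensor's 0.5 degC accuracy scaled
#' by `noise_scale`; repeat-to-repeat scatter reflects the sensor's
#' repeatability, which is far better than its absolute accuracy.
#'
#' @param power_mw Optical power, mW (> 0).
#' @param duration Irradiation time, s. Default 60.
#' @param dt Sampling interval, s. Default 5.
#' @param reps Number of replicate runs. Default 10.
#' @param tau Thermal time constant, s. Default 60 (visible curvature over
#'   a 60 s window without saturating).
#' @param dT_per_mw Steady-state rise per mW, degC/mW. Default 0.15.
#' @param noise_scale Factor applied to the 0.5 degC sensor accuracy to get
#'   the additive noise SD. Default 0.1.
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `replicate`, `t_s`, `dT_c` (rise is 0
#'   at t = 0 by construction).
#' @export
temperature_rise_series <- function(power_mw, duration = 60, dt = 5,
                                    reps = 10, tau = 60, dT_per_mw = 0.15,
                                    noise_scale = 0.1, seed = 1L) {
  if (power_mw <= 0) stop("power must be > 0")
  t <- seq(0, duration, by = dt)
  mean_rise <- dT_per_mw * power_mw * (1 - exp(-t / tau))
  sd_noise <- 0.5 * noise_scale
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(reps), function(rep) {
      noise <- c(0, rnorm(length(t) - 1, sd = sd_noise))  # rise 0 at t = 0
      data.frame(replicate = rep, t_s = t, dT_c = mean_rise + noise)
    }))
  })
}

#' Simulated surface temperature under periodic illumination
#'
#' Surface-temperature record for an on/off LED duty cycle: saturating
#' exponential rise toward `T_base + dT_max` while on, exponential
#' relaxation toward `T_base` while off, plus additive sensor noise. Used
#' to drive [depth_series()] the way the wearable drives it from measured
#' skin temperature.
#'
#' @param t_on,t_off On and off durations per cycle, s. Defaults 120 / 120.
#' @param cycles Number of full cycles. Default 3.
#' @param dt Sampling interval, s. Default 5.
#' @param T_base Unirradiated skin surface temperature, degC. Default 33.5.
#' @param dT_max Steady-state rise while on, degC. Default 1.5.
#' @param tau Thermal time constant, s. Default 60.
#' @param noise_sd Additive sensor noise SD, degC. Default 0.05.
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `timestamp_s` and `temp_c`.
#' @export
periodic_temperature_series <- function(t_on = 120, t_off = 120, cycles = 3,
                                        dt = 5, T_base = 33.5, dT_max = 1.5,
                                        tau = 60, noise_sd = 0.05,
                                        seed = 1L) {
  total <- cycles * (t_on + t_off)
  t <- seq(0, total, by = dt)
  temp <- numeric(length(t))
  cur <- T_base
  for (i in seq_along(t)) {
    phase <- (t[i] %% (t_on + t_off))
    on <- phase < t_on
    target <- if (on) T_base + dT_max else T_base
    if (i == 1) {
      cur <- T_base
    } else {
      cur <- target + (cur - target) * exp(-dt / tau)
    }
    temp[i] <- cur
  }
  with_seed(seed, data.frame(
    timestamp_s = t,
    temp_c = temp + rnorm(length(t), sd = noise_sd)
  ))
}
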