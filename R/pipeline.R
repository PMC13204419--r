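#' Session configuration for the end-to-end pipeline
#'
#' Collects everything [run_pipeline()] needs: phantom, geometry preset,
#' wavelength plan, extinction table, thermal constants, fluence grid,
#' simulation settings and the safety threshold. All arguments have working
#' defaults so `run_pipeline(session_config())` exercises the whole chain
#' on the bundled phantom.
#'
#' @param phantom A [phantom_spec()] used by the simulation stages.
#' @param geometry Geometry preset name (see [probe_geometry_preset()]) or
#'   a [probe_geometry()] object.
#' @param wavelengths Wavelengths (nm) at which to invert the attenuation
#'   coefficient.
#' @param oximetry_wavelengths The two oximetry wavelengths, nm.
#' @param extinction_path Path to the extinction table CSV; `NULL` for the
#'   bundled table.
#' @param n_repeats Repeat measurements averaged per wavelength. Default 3.
#' @param thermal_m,thermal_T0 Simplified bioheat constants.
#' @param depths Depths (mm) for the bioheat stage.
#' @param grid_step Fluence map step, mm.
#' @param r_range,z_range Fluence map extents, mm.
#' @param occlusion_drop_to Saturation floor for the simulated occlusion
#'   episode.
#' @param safety_threshold Shutoff threshold, degC.
#' @param seed Master seed for all simulation stages.
#' @return Object of class `session_config` (a list).
#' @export
session_config <- function(phantom = phantom_spec(),
                           geometry = "asbuilt",
                           wavelengths = c(730, 810, 855),
                           oximetry_wavelengths = c(730, 855),
                           extinction_path = NULL,
                           n_repeats = 3,
                           thermal_m = 0.0876,
                           thermal_T0 = 36.5,
                           depths = c(0, 3, 5, 10),
                           grid_step = 0.1,
                           r_range = c(-10, 10),
                           z_range = c(0, 10),
                           occlusion_drop_to = 0.45,
                           safety_threshold = 43,
                           seed = 1L) {
  geom <- if (inherits(geometry, "probe_geometry")) {
    geometry
  } else {
    probe_geometry_preset(geometry)
  }
  structure(
    list(phantom = phantom, geom = geom, wavelengths = wavelengths,
         oximetry_wavelengths = oximetry_wavelengths,
         extinction_path = extinction_path, n_repeats = n_repeats,
         thermal_m = thermal_m, thermal_T0 = thermal_T0, depths = depths,
         grid_step = grid_step, r_range = r_range, z_range = z_range,
         occlusion_drop_to = occlusion_drop_to,
         safety_threshold = safety_threshold, seed = as.integer(seed)),
    class = "session_config"
  )
}

run_stage <- function(report, name, depends_on = NULL, expr) {
  for (dep in depends_on) {
    if (!identical(report$stages[[dep]]$status, "ok")) {
      report$stages[[name]] <- list(status = "skipped",
                                    reason = paste0("requires stage '", dep,
                                                    "'"))
      return(report)
    }
  }
  res <- tryCatch(
    list(status = "ok", result = expr),
    error = function(e) list(status = "error", message = conditionMessage(e))
  )
  report$stages[[name]] <- res
  report
}

#' Run the full measurement-to-monitoring pipeline
#'
#' Executes, in order: telemetry simulation on the configured phantom,
#' per-wavelength inversion of the effective attenuation coefficient with
#' repeat averaging, relative fluence-map reconstruction from the inverted
#' coefficients, occlusion-episode saturation monitoring, bioheat
#' depth-temperature prediction from a simulated periodic surface drive,
#' and the over-temperature safety monitor. Each stage is recorded in the
#' report with its status; a failed stage is logged and stages that depend
#' on it are skipped while independent stages still run.
#'
#' @param config A [session_config()].
#' @return Object of class `dosimetry_report`: list with `config` (echo of
#'   key settings) and `stages`.
#' @export
run_pipeline <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  report <- list(
    config = list(
      geometry = list(r1_mm = config$geom$r1, r2_mm = config$geom$r2),
      wavelengths_nm = config$wavelengths,
      n_repeats = config$n_repeats,
      seed = config$seed
    ),
    stages = list()
  )

  report <- run_stage(report, "simulate", NULL, {
    streams <- lapply(seq_along(config$wavelengths), function(i) {
      generate_detector_readings(
        config$phantom, config$geom, config$wavelengths[i],
        n = config$n_repeats, seed = config$seed + i)
    })
    names(streams) <- as.character(config$wavelengths)
    streams
  })

  report <- run_stage(report, "invert_mueff", "simulate", {
    streams <- report$stages$simulate$result
    lapply(config$wavelengths, function(wl) {
      tel <- streams[[as.character(wl)]]
      near <- tel$flux[tel$detector_id == "near"]
      far <- tel$flux[tel$detector_id == "far"]
      est <- invert_mu_eff(near, far, config$geom)
      summ <- summarize_repeats(as.numeric(est))
      list(wavelength_nm = wl,
           mu_eff_mm_inv = summ$mean,
           n_repeats = summ$n,
           mean = summ$mean_reported,
           rsd_percent = summ$rsd,
           flags = sum(attr(est, "flagged")))
    })
  })

  report <- run_stage(report, "fluence_map", "invert_mueff", {
    inv <- report$stages$invert_mueff$result
    lapply(inv, function(x) {
      fld <- fluence_map(x$mu_eff_mm_inv, r_range = config$r_range,
                         z_range = config$z_range, step = config$grid_step)
      list(wavelength_nm = x$wavelength_nm,
           mu_eff = fld$mu_eff,
           grid = dim(fld$values),
           value_at_r0_z5 = relative_fluence(fld$mu_eff, 0, 5,
                                             ref = fld$reference))
    })
  })

  report <- run_stage(report, "rso2", "simulate", {
    spectra <- hemoglobin_extinction(config$extinction_path)
    occ_phantom <- occlusion_phantom(
      saturation = config$phantom$saturation,
      c_hbt_M = config$phantom$c_hbt_M,
      noise_rsd = config$phantom$noise_rsd,
      seed = config$seed)
    stream <- occlusion_series(occ_phantom, drop_to = config$occlusion_drop_to,
                               geom = config$geom,
                               wavelengths = config$oximetry_wavelengths)
    series <- rso2_series(stream, config$geom, spectra,
                          l1 = config$oximetry_wavelengths[1],
                          l2 = config$oximetry_wavelengths[2])
    c(rso2_summary(series), list(n_samples = nrow(series)))
  })

  report <- run_stage(report, "bioheat", NULL, {
    ts <- periodic_temperature_series(seed = config$seed)
    ds <- depth_series(ts, depths = config$depths,
                       T0 = config$thermal_T0, m = config$thermal_m)
    amp <- vapply(config$depths, function(z) {
      col <- ds[[sprintf("z%g_mm", z)]]
      max(col) - min(col)
    }, numeric(1))
    list(depths_mm = config$depths, oscillation_amplitude_c = amp,
         n_samples = nrow(ds))
  })

  report <- run_stage(report, "safety", NULL, {
    ts <- periodic_temperature_series(seed = config$seed)
    mon <- safety_monitor(ts, threshold = config$safety_threshold)
    list(threshold_c = config$safety_threshold,
         n_events = nrow(mon$events))
  })

  # drop bulky raw telemetry from the report; summaries remain
  report$stages$simulate$result <-
    lapply(report$stages$simulate$result, function(s) {
      list(n_records = nrow(s))
    })
  class(report) <- "dosimetry_report"
  report
}

#' @export
print.dosimetry_report <- function(x, ...) {
  cat("Dosimetry pipeline report\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]$status))
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
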