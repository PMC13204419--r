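#' Hemoglobin molar extinction coefficients
#'
#' Loads the bundled two-chromophore extinction table (oxygenated and
#' reduced hemoglobin, cm^-1/M) at the probe's LED wavelengths 730, 810 and
#' 855 nm. The shipped values are compiled literature values and are
#' editable: every estimator in this package uses only ratios constructed
#' from the same table, so results are insensitive to its absolute scale.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `wavelength_nm`, `eps_hbo2`, `eps_hb`.
#' @return Object of class `chromophore_spectra` (a validated data.frame).
#' @export
hemoglobin_extinction <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hemoglobin_extinction.csv",
                        package = "photodose")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("extinction table not found: ", path)
  }
  tab <- read.csv(path)
  required <- c("wavelength_nm", "eps_hbo2", "eps_hb")
  if (!all(required %in% names(tab))) {
    stop("extinction table must have columns: ",
         paste(required, collapse = ", "))
  }
  if (any(tab$eps_hbo2 <= 0) || any(tab$eps_hb <= 0)) {
    stop("extinction coefficients must be positive")
  }
  if (is.unsorted(tab$wavelength_nm, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  class(tab) <- c("chromophore_spectra", "data.frame")
  tab
}

# exact-match lookup; the table is tiny and tied to the LED wavelengths
extinction_at <- function(spectra, wavelength) {
  i <- match(wavelength, spectra$wavelength_nm)
  if (is.na(i)) {
    stop("extinction table has no entry at ", wavelength, " nm")
  }
  list(hbo2 = spectra$eps_hbo2[i], hb = spectra$eps_hb[i])
}

#' Absorption coefficient of a hemoglobin mixture
#'
#' Forward two-chromophore model used by the phantom simulator:
#' `mu_a = ln(10) * (eps_HbO2 * S + eps_Hb * (1 - S)) * C / 10` in mm^-1,
#' with extinction coefficients in cm^-1/M and total hemoglobin
#' concentration `c_hbt_M` in mol/L.
#'
#' @param spectra A [hemoglobin_extinction()] table.
#' @param wavelength Wavelength, nm (must be present in the table).
#' @param saturation Oxygen saturation fraction S in \[0, 1\].
#' @param c_hbt_M Total hemoglobin concentration, mol/L.
#' @return Absorption coefficient, mm^-1.
#' @export
mixture_absorption <- function(spectra, wavelength, saturation,
                               c_hbt_M = 6e-5) {
  if (any(saturation < 0 | saturation > 1)) {
    stop("saturation must lie in [0, 1]")
  }
  eps <- extinction_at(spectra, wavelength)
  log(10) * (eps$hbo2 * saturation + eps$hb * (1 - saturation)) *
    c_hbt_M / 10
}

#' Optical density of a relative flux
#'
#' `OD = -log10(R)`.
#'
#' @param R Relative flux (> 0). Vectorized.
#' @return Optical density, dimensionless.
#' @export
optical_density <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("invalid flux: optical density requires R > 0")
  }
  -log10(R)
}

#' Effective radial reference distance for the finite-difference OD slope
#'
#' The radial derivative of the optical density contains a geometric `2/r`
#' term. Replacing the derivative by a finite difference between the two
#' detector distances leaves the `r` in that term unspecified. The
#' logarithmic mean `(r2 - r1)/ln(r2/r1)` is the default because it makes
#' the difference form of the geometric term exact:
#' `OD(r2) - OD(r1)` of the `1/r^2` prefactor is exactly
#' `2 ln(r2/r1)/ln 10 = (2 dr / r_logmean)/ln 10`. The geometric mean,
#' near distance and midpoint are provided as alternatives.
#'
#' @param geom A [probe_geometry()].
#' @param method `"logmean"` (default), `"geomean"`, `"r1"` or `"midpoint"`.
#' @return Reference distance, mm.
#' @export
r_reference <- function(geom,
                        method = c("logmean", "geomean", "r1", "midpoint")) {
  stopifnot(inherits(geom, "probe_geometry"))
  method <- match.arg(method)
  switch(method,
         logmean = (geom$r2 - geom$r1) / log(geom$r2 / geom$r1),
         geomean = sqrt(geom$r1 * geom$r2),
         r1 = geom$r1,
         midpoint = (geom$r1 + geom$r2) / 2)
}

#' Two-wavelength absorption-coefficient ratio from OD differences
#'
#' From the OD slope relation
#' `dOD/dr = (1/ln 10) (sqrt(3 mu_a mu_s') + 2/r)`, subtracting the
#' geometric `2/r` term from each wavelength's measured OD difference and
#' squaring the ratio gives the absorption-coefficient ratio
#' `kappa = mu_a(l1) / mu_a(l2)` under the assumption that the reduced
#' scattering coefficient is equal at the two wavelengths:
#' \deqn{\kappa = \left[\frac{\Delta OD_{\lambda_1} - 2\Delta r/(r\ln 10)}
#'   {\Delta OD_{\lambda_2} - 2\Delta r/(r\ln 10)}\right]^2.}
#'
#' @param delta_od_l1,delta_od_l2 OD differences `OD(r2) - OD(r1)` at the
#'   two wavelengths. Vectorized.
#' @param geom A [probe_geometry()].
#' @param r_ref Radial reference for the `2/r` term; defaults to
#'   [r_reference()] with the logarithmic-mean method.
#' @return Dimensionless ratio(s) `kappa`, with a logical `"flagged"`
#'   attribute marking samples whose corrected numerator and denominator
#'   had opposite signs (physically inadmissible; typically noise).
#' @export
absorption_ratio <- function(delta_od_l1, delta_od_l2, geom,
                             r_ref = r_reference(geom)) {
  stopifnot(inherits(geom, "probe_geometry"))
  dr <- geom$r2 - geom$r1
  corr <- 2 * dr / (r_ref * log(10))
  num <- delta_od_l1 - corr
  den <- delta_od_l2 - corr
  if (any(abs(den) < 1e-14)) {
    stop("degenerate measurement: corrected OD difference at wavelength 2 is ~0")
  }
  bad <- sign(num) != sign(den)
  if (any(bad)) {
    warning(sprintf(
      "%d sample(s) with opposite-sign corrected OD differences flagged",
      sum(bad)))
  }
  out <- (num / den)^2
  attr(out, "flagged") <- bad
  out
}

#' Regional oxygen saturation from an absorption ratio
#'
#' Solves the two-chromophore mixture equation
#' `eps_HbO2(l1) S + eps_Hb(l1) (1-S) = kappa * (eps_HbO2(l2) S + eps_Hb(l2) (1-S))`
#' for the saturation fraction S:
#' \deqn{S = \frac{\varepsilon_{Hb}(\lambda_1) - \varepsilon_{Hb}(\lambda_2)\kappa}
#'  {\kappa\,[\varepsilon_{HbO_2}(\lambda_2) - \varepsilon_{Hb}(\lambda_2)]
#'   - [\varepsilon_{HbO_2}(\lambda_1) - \varepsilon_{Hb}(\lambda_1)]}.}
#' The pure-oxyhemoglobin ratio `eps_HbO2(l1)/eps_HbO2(l2)` maps to exactly
#' 1 and the pure-deoxyhemoglobin ratio to exactly 0. Values outside
#' \[0, 1\] are returned as-is (clipping is the series pipeline's job).
#'
#' @param kappa Absorption-coefficient ratio(s) `mu_a(l1)/mu_a(l2)`.
#' @param spectra A [hemoglobin_extinction()] table.
#' @param l1,l2 The two wavelengths, nm. Defaults 730 and 855.
#' @return Saturation fraction(s).
#' @export
rso2_from_ratio <- function(kappa, spectra, l1 = 730, l2 = 855) {
  e1 <- extinction_at(spectra, l1)
  e2 <- extinction_at(spectra, l2)
  den <- kappa * (e2$hbo2 - e2$hb) - (e1$hbo2 - e1$hb)
  if (any(abs(den) < 1e-12)) {
    stop("no unique saturation solution for this kappa / wavelength pair")
  }
  (e1$hb - e2$hb * kappa) / den
}

#' Regional oxygen saturation time series from telemetry
#'
#' Runs the full per-frame pipeline on a two-wavelength, two-detector
#' telemetry stream: flux -> OD -> OD difference per wavelength ->
#' absorption ratio -> saturation. A frame is one timestamp; it must carry
#' one near and one far optical sample at each of the two wavelengths.
#' Incomplete frames are skipped and counted. Saturations outside \[0, 1\]
#' are clipped and flagged per sample.
#'
#' @param telemetry Telemetry `data.frame` (see [read_telemetry()] for the
#'   schema).
#' @param geom A [probe_geometry()].
#' @param spectra A [hemoglobin_extinction()] table.
#' @param l1,l2 The two wavelengths, nm.
#' @param r_ref_method Passed to [r_reference()].
#' @return Object of class `rso2_series`: `data.frame` with columns
#'   `timestamp_s`, `rso2` (fraction in \[0, 1\]), `clipped` and `flagged`;
#'   attribute `n_skipped` counts skipped frames.
#' @export
rso2_series <- function(telemetry, geom, spectra, l1 = 730, l2 = 855,
                        r_ref_method = "logmean") {
  stopifnot(is.data.frame(telemetry), inherits(geom, "probe_geometry"))
  opt <- telemetry[telemetry$wavelength_nm %in% c(l1, l2) &
                     telemetry$detector_id %in% c("near", "far"), ]
  frames <- split(opt, opt$timestamp_s)
  r_ref <- r_reference(geom, r_ref_method)
  n_skipped <- 0L
  rows <- lapply(frames, function(fr) {
    d_od <- vapply(c(l1, l2), function(wl) {
      near <- fr$flux[fr$wavelength_nm == wl & fr$detector_id == "near"]
      far <- fr$flux[fr$wavelength_nm == wl & fr$detector_id == "far"]
      if (length(near) != 1 || length(far) != 1 ||
          !is.finite(near) || !is.finite(far) || near <= 0 || far <= 0) {
        return(NA_real_)
      }
      optical_density(far) - optical_density(near)
    }, numeric(1))
    if (any(is.na(d_od))) return(NULL)
    kap <- suppressWarnings(absorption_ratio(d_od[1], d_od[2], geom, r_ref))
    s <- rso2_from_ratio(as.numeric(kap), spectra, l1, l2)
    data.frame(timestamp_s = fr$timestamp_s[1],
               rso2_raw = s,
               flagged = attr(kap, "flagged"))
  })
  skipped <- vapply(rows, is.null, logical(1))
  n_skipped <- sum(skipped)
  if (n_skipped > 0) {
    message(sprintf("rso2_series: skipped %d incomplete frame(s)", n_skipped))
  }
  rows <- rows[!skipped]
  if (length(rows) == 0) {
    out <- data.frame(timestamp_s = numeric(0), rso2 = numeric(0),
                      clipped = logical(0), flagged = logical(0))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$timestamp_s), ]
    out$clipped <- out$rso2_raw < 0 | out$rso2_raw > 1
    out$rso2 <- pmin(pmax(out$rso2_raw, 0), 1)
    out <- out[, c("timestamp_s", "rso2", "clipped", "flagged")]
    rownames(out) <- NULL
  }
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("rso2_series", "data.frame")
  out
}

#' Summarize an occlusion-style saturation series
#'
#' Baseline (first sample), minimum with its time, and the recovery time:
#' the first time after the minimum at which the saturation is back within
#' `recovery_tol` (relative) of baseline.
#'
#' @param series An [rso2_series()] result.
#' @param recovery_tol Relative tolerance on return-to-baseline. Default 2%.
#' @return List with `baseline`, `minimum`, `t_minimum_s`,
#'   `t_recovery_s` (NA if never recovered) and `final`.
#' @export
rso2_summary <- function(series, recovery_tol = 0.02) {
  stopifnot(nrow(series) > 0)
  base <- series$rso2[1]
  i_min <- which.min(series$rso2)
  after <- series[series$timestamp_s > series$timestamp_s[i_min], ]
  rec <- after$timestamp_s[abs(after$rso2 - base) <= recovery_tol * base]
  list(baseline = base,
       minimum = series$rso2[i_min],
       t_minimum_s = series$timestamp_s[i_min],
       t_recovery_s = if (length(rec)) rec[1] else NA_real_,
       final = series$rso2[nrow(series)])
}

#' Write a saturation series to CSV
#'
#' @param series An [rso2_series()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rso2_csv <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
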