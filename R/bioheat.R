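#' Thermal properties for the Pennes bioheat model
#'
#' Parameters of the one-dimensional steady-state Pennes equation
#' `k T'' + mu_a phi0 exp(-mu_eff z) + rho_b c_b w_b (T0 - T) = 0`.
#' The perfusion decay constant is `m = sqrt(perfusion_product / k_tissue)`
#' unless overridden. Defaults reproduce the typical skin values
#' m = 0.0876 mm^-1 and core temperature T0 = 36.5 degC; the default
#' conductivity is 5e-4 W mm^-1 degC^-1 (0.5 W m^-1 K^-1) with the
#' perfusion product chosen to give exactly the default m.
#'
#' @param k_tissue Thermal conductivity, W mm^-1 degC^-1 (> 0).
#' @param perfusion_product Blood density x specific heat x perfusion rate
#'   (rho_b c_b w_b), W mm^-3 degC^-1 (>= 0).
#' @param T_core Arterial / core temperature T0, degC.
#' @param m_override Optional decay constant, mm^-1, taking precedence over
#'   the derived value.
#' @return Object of class `thermal_properties` with the fields above plus
#'   derived `m`.
#' @export
thermal_properties <- function(k_tissue = 5e-4,
                               perfusion_product = 0.0876^2 * k_tissue,
                               T_core = 36.5,
                               m_override = NULL) {
  if (k_tissue <= 0) stop("k_tissue must be > 0")
  if (perfusion_product < 0) stop("perfusion_product must be >= 0")
  m <- if (is.null(m_override)) {
    sqrt(perfusion_product / k_tissue)
  } else {
    if (m_override < 0) stop("m_override must be >= 0")
    m_override
  }
  structure(
    list(k_tissue = k_tissue,
         perfusion_product = perfusion_product,
         T_core = T_core,
         m = m),
    class = "thermal_properties"
  )
}

#' @export
print.thermal_properties <- function(x, ...) {
  cat(sprintf(
    "Thermal properties: k = %.3g W/mm/degC, rho_b c_b w_b = %.3g W/mm^3/degC\n",
    x$k_tissue, x$perfusion_product))
  cat(sprintf("  T_core = %.2f degC, m = %.4g mm^-1\n", x$T_core, x$m))
  invisible(x)
}

#' Perfusion decay constant m
#'
#' `m = sqrt(rho_b c_b w_b / k)`, the inverse length scale over which
#' perfusion pulls the tissue temperature back to the core value.
#'
#' @param thermal A [thermal_properties()] object.
#' @return Decay constant, mm^-1.
#' @export
m_param <- function(thermal) {
  stopifnot(inherits(thermal, "thermal_properties"))
  thermal$m
}

#' Surface heating terms
#'
#' The optical source term amplitude `phi0` (surface fluence rate) and the
#' measured surface temperature `Ts`. `phi0 = 0` selects the simple
#' perfusion-only regime.
#'
#' @param phi0 Surface fluence rate, W mm^-2 (>= 0).
#' @param T_surface Measured surface temperature Ts, degC.
#' @return Object of class `surface_heating`.
#' @export
surface_heating <- function(phi0 = 0, T_surface) {
  if (phi0 < 0) stop("phi0 must be >= 0")
  structure(list(phi0 = phi0, T_surface = T_surface),
            class = "surface_heating")
}

#' Full steady-state Pennes depth-temperature profile
#'
#' Analytic solution of
#' `k T'' + mu_a phi0 exp(-mu_eff z) + rho_b c_b w_b (T0 - T) = 0`
#' with boundary conditions `T(0) = Ts` and `T(inf) = T0`:
#' \deqn{T(z) = T_0 + (u_s + C) e^{-m z} - C e^{-\mu_{eff} z}, \quad
#'   C = \frac{\mu_a \phi_0}{k (\mu_{eff}^2 - m^2)}, \quad u_s = T_s - T_0.}
#' The resonant case `mu_eff = m` (coincident exponentials) is not covered
#' by this solution and is rejected.
#'
#' @param z Depth(s), mm (>= 0). Vectorized.
#' @param thermal A [thermal_properties()] object.
#' @param optics An [optical_properties()] object (supplies `mu_a`,
#'   `mu_eff`).
#' @param heat A [surface_heating()] object.
#' @return Temperature(s), degC.
#' @export
steady_profile_full <- function(z, thermal, optics, heat) {
  stopifnot(inherits(thermal, "thermal_properties"),
            inherits(optics, "optical_properties"),
            inherits(heat, "surface_heating"))
  if (any(z < 0)) stop("depth z must be >= 0")
  m <- thermal$m
  mu <- optics$mu_eff
  if (isTRUE(all.equal(mu, m))) {
    stop("resonant case mu_eff = m: the two-exponential solution does not apply")
  }
  us <- heat$T_surface - thermal$T_core
  C <- optics$mu_a * heat$phi0 / (thermal$k_tissue * (mu^2 - m^2))
  thermal$T_core + (us + C) * exp(-m * z) - C * exp(-mu * z)
}

#' Simplified perfusion-dominated depth-temperature profile
#'
#' In the regime `mu_eff >> m` the optical heating term contributes little
#' and the depth profile is governed by the surface temperature and
#' perfusion alone: `T(z) = T0 + (Ts - T0) exp(-m z)`.
#'
#' @param z Depth(s), mm. Vectorized.
#' @param Ts Surface temperature, degC.
#' @param T0 Core temperature, degC. Default 36.5.
#' @param m Perfusion decay constant, mm^-1 (>= 0). Default 0.0876.
#' @return Temperature(s), degC.
#' @examples
#' steady_profile_simple(10, Ts = 40)   # 36.5 + 3.5 * exp(-0.876)
#' @export
steady_profile_simple <- function(z, Ts, T0 = 36.5, m = 0.0876) {
  if (m < 0) stop("m must be >= 0")
  T0 + (Ts - T0) * exp(-m * z)
}

#' Depth-resolved temperature series from a surface-temperature record
#'
#' Applies the simplified steady-state profile quasi-statically to each
#' time point of a measured surface-temperature series, producing the
#' time-by-depth matrix used to visualize how surface temperature swings
#' attenuate with depth. Each time point is treated independently (no
#' transient heat equation); the depth-z oscillation amplitude is therefore
#' exactly the surface amplitude times `exp(-m z)`.
#'
#' @param ts_series `data.frame` with columns `timestamp_s` and `temp_c`,
#'   or a numeric vector of surface temperatures (then indexed 0, 1, ...).
#' @param depths Depths, mm (>= 0).
#' @param T0 Core temperature, degC.
#' @param m Perfusion decay constant, mm^-1.
#' @return `data.frame`: `timestamp_s` then one column `z<depth>_mm` per
#'   requested depth.
#' @export
depth_series <- function(ts_series, depths = c(0, 3, 5, 10),
                         T0 = 36.5, m = 0.0876) {
  if (is.numeric(ts_series)) {
    ts_series <- data.frame(timestamp_s = seq_along(ts_series) - 1,
                            temp_c = ts_series)
  }
  stopifnot(is.data.frame(ts_series),
            all(c("timestamp_s", "temp_c") %in% names(ts_series)))
  if (nrow(ts_series) == 0) stop("no data: empty surface-temperature series")
  if (any(depths < 0)) stop("depths must be >= 0")
  out <- data.frame(timestamp_s = ts_series$timestamp_s)
  for (z in depths) {
    out[[sprintf("z%g_mm", z)]] <-
      steady_profile_simple(z, ts_series$temp_c, T0 = T0, m = m)
  }
  out
}

#' Write a depth-temperature series to CSV
#'
#' @param ds A [depth_series()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_depth_series_csv <- function(ds, path) {
  write.csv(ds, path, row.names = FALSE)
  invisible(path)
}
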