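#' Optical properties of a homogeneous tissue phantom
#'
#' Bundles the absorption coefficient `mu_a` and reduced scattering
#' coefficient `mu_s_prime` of a homogeneous semi-infinite medium, together
#' with the derived diffusion quantities: the effective attenuation
#' coefficient `mu_eff = sqrt(3 * mu_a * mu_s_prime)`, the diffusion
#' coefficient `D = 1/(3 * (mu_a + mu_s_prime))` and the source depth
#' `z0 = 1/mu_s_prime`.
#'
#' The anisotropy factor `g` is used only by the Monte Carlo oracle
#' ([mc_oracle()]); the diffusion-model quantities depend on scattering only
#' through `mu_s_prime`. `boundary_A` is the internal-reflection boundary
#' correction factor; it defaults to 1 (matched boundary) and cancels in
#' every ratio the downstream pipeline uses, so it only sets the simulator's
#' absolute scale.
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param mu_s_prime Reduced scattering coefficient, mm^-1 (> 0).
#' @param g Scattering anisotropy, dimensionless, in (-1, 1).
#' @param boundary_A Boundary correction factor, dimensionless (> 0).
#' @return An object of class `optical_properties`: a list with the fields
#'   above plus `mu_eff`, `D` and `z0`.
#' @examples
#' op <- optical_properties(mu_a = 0.01, mu_s_prime = 1.41)
#' op$mu_eff
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.9, boundary_A = 1) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1, is.finite(mu_a),
            is.numeric(mu_s_prime), length(mu_s_prime) == 1,
            is.finite(mu_s_prime))
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s_prime <= 0) stop("mu_s_prime must be > 0")
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)")
  if (boundary_A <= 0) stop("boundary_A must be > 0")
  structure(
    list(
      mu_a = mu_a,
      mu_s_prime = mu_s_prime,
      g = g,
      boundary_A = boundary_A,
      mu_eff = sqrt(3 * mu_a * mu_s_prime),
      D = 1 / (3 * (mu_a + mu_s_prime)),
      z0 = 1 / mu_s_prime
    ),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("Optical properties (homogeneous semi-infinite medium)\n")
  cat(sprintf("  mu_a       = %.5g mm^-1\n", x$mu_a))
  cat(sprintf("  mu_s'      = %.5g mm^-1\n", x$mu_s_prime))
  cat(sprintf("  g          = %.3g   boundary A = %.3g\n", x$g, x$boundary_A))
  cat(sprintf("  mu_eff     = %.5g mm^-1   D = %.5g mm   z0 = %.5g mm\n",
              x$mu_eff, x$D, x$z0))
  invisible(x)
}

#' Two-distance probe geometry
#'
#' Near and far source-detector distances of the wearable probe.
#'
#' @param r1 Near source-detector distance, mm.
#' @param r2 Far source-detector distance, mm. Must satisfy `0 < r1 < r2`.
#' @return An object of class `probe_geometry`.
#' @seealso [probe_geometry_preset()] for the two geometries the device was
#'   operated with.
#' @export
probe_geometry <- function(r1, r2) {
  stopifnot(is.numeric(r1), is.numeric(r2), length(r1) == 1, length(r2) == 1)
  if (!(r1 > 0 && r2 > r1)) stop("probe geometry requires 0 < r1 < r2")
  structure(list(r1 = r1, r2 = r2), class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("Probe geometry: r1 = %.3g mm, r2 = %.3g mm\n", x$r1, x$r2))
  invisible(x)
}

#' Named probe-geometry presets
#'
#' The device was described with two slightly different detector placements:
#' nominal 4 / 20 mm and as-built 4.2 / 20.1 mm. The as-built values are the
#' default used throughout the package.
#'
#' @param name `"asbuilt"` (4.2 / 20.1 mm, default) or `"nominal"`
#'   (4 / 20 mm).
#' @return A [probe_geometry()].
#' @export
probe_geometry_preset <- function(name = c("asbuilt", "nominal")) {
  name <- match.arg(name)
  switch(name,
         asbuilt = probe_geometry(4.2, 20.1),
         nominal = probe_geometry(4, 20))
}

#' Effective attenuation coefficient
#'
#' `mu_eff = sqrt(3 * mu_a * mu_s_prime)`: the exponential decay rate of
#' diffuse light far from the source in a scattering-dominated medium.
#'
#' @param props An [optical_properties()] object.
#' @return Effective attenuation coefficient, mm^-1.
#' @export
effective_attenuation <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  sqrt(3 * props$mu_a * props$mu_s_prime)
}

#' Transport mean free path
#'
#' `1/(mu_a + mu_s_prime)`: the distance over which photon direction
#' randomizes. The diffusion approximation requires source-detector
#' separations of several transport mean free paths.
#'
#' @inheritParams effective_attenuation
#' @return Transport mean free path, mm.
#' @export
transport_mfp <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  mu_tr <- props$mu_a + props$mu_s_prime
  if (mu_tr <= 0) stop("mu_a + mu_s_prime must be > 0")
  1 / mu_tr
}

#' Express a distance in transport mean free paths
#'
#' Used to check the validity of the diffusion approximation: classical
#' theory asks for source-detector distances above about 5 transport mean
#' free paths.
#'
#' @param distance Distance, mm (> 0). Vectorized.
#' @inheritParams effective_attenuation
#' @param digits Optional reporting precision. `NULL` (default) returns the
#'   raw multiple.
#' @param mode How to reduce to `digits` decimals: `"round"` (default) or
#'   `"truncate"`. Both conventions occur in practice when such multiples are
#'   quoted, so both are provided.
#' @return Dimensionless multiple of the transport mean free path.
#' @export
distance_in_mfp <- function(distance, props, digits = NULL,
                            mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (any(distance <= 0)) stop("distance must be > 0")
  x <- distance / transport_mfp(props)
  if (is.null(digits)) return(x)
  if (mode == "round") round(x, digits) else trunc(x * 10^digits) / 10^digits
}

#' Forward diffuse reflectance of a semi-infinite medium
#'
#' Steady-state diffusion-approximation radiant flux detected at distance
#' `r` on the surface of a homogeneous semi-infinite medium:
#' \deqn{R(r) = \frac{3}{2\pi r^2}\left(1 + \tfrac{2}{3}A\right)
#'   \mu_a \mu_s' \, e^{-\mu_{eff} r}.}
#' Absolute units are arbitrary: every physically used downstream quantity
#' is a ratio of two such evaluations, in which the prefactor (including
#' `boundary_A`) cancels exactly.
#'
#' @inheritParams effective_attenuation
#' @param r Source-detector distance, mm (> 0). Vectorized.
#' @return Radiant flux, arbitrary units.
#' @export
reflectance <- function(props, r) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("invalid geometry: source-detector distance r must be > 0")
  }
  (3 / (2 * pi * r^2)) * (1 + (2 / 3) * props$boundary_A) *
    props$mu_a * props$mu_s_prime * exp(-props$mu_eff * r)
}

#' Invert the effective attenuation coefficient from two-distance fluxes
#'
#' Solves the ratio of the two forward reflectance readings for the
#' effective attenuation coefficient:
#' \deqn{\mu_{eff} = \frac{\ln\!\big(R_1 r_1^2 / (R_2 r_2^2)\big)}{r_2 - r_1}.}
#' The result is invariant to any common scaling of `R1` and `R2`
#' (detector gain independence). A negative inverted value is physically
#' suspect (`R1 r1^2 < R2 r2^2`); it is returned with a warning and recorded
#' in the `"flagged"` attribute rather than raised, so noisy streams do not
#' abort batch processing.
#'
#' @param R1,R2 Fluxes at the near and far detector, same arbitrary linear
#'   units (> 0). Vectorized.
#' @param geom A [probe_geometry()].
#' @return Effective attenuation coefficient(s), mm^-1, with a logical
#'   `"flagged"` attribute marking negative inversions.
#' @export
invert_mu_eff <- function(R1, R2, geom) {
  stopifnot(inherits(geom, "probe_geometry"))
  if (any(!is.finite(R1)) || any(!is.finite(R2)) ||
      any(R1 <= 0) || any(R2 <= 0)) {
    stop("sensor fault: detector fluxes must be positive and finite")
  }
  val <- log((R1 * geom$r1^2) / (R2 * geom$r2^2)) / (geom$r2 - geom$r1)
  neg <- val < 0
  if (any(neg)) {
    warning(sprintf(
      "%d negative inverted mu_eff value(s) flagged (R1*r1^2 < R2*r2^2)",
      sum(neg)))
  }
  attr(val, "flagged") <- neg
  val
}

#' Summarize repeated attenuation measurements
#'
#' Repeat measurements at one wavelength are reduced to their arithmetic
#' mean (the reported final value) and relative standard deviation.
#'
#' @param values Numeric vector of repeated estimates, mm^-1 (length >= 2).
#' @param digits Reporting precision for the mean (decimals); the raw mean is
#'   kept alongside.
#' @return Object of class `repeat_summary` with fields `values`, `mean`
#'   (raw), `mean_reported` (rounded to `digits`), `rsd` (percent) and `n`.
#' @examples
#' summarize_repeats(c(0.142, 0.141, 0.143))
#' @export
summarize_repeats <- function(values, digits = 3) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("insufficient repeats: need at least 2 values")
  if (any(!is.finite(values))) stop("repeat values must be finite")
  m <- mean(values)
  structure(
    list(
      values = values,
      n = length(values),
      mean = m,
      mean_reported = round(m, digits),
      rsd = 100 * sd(values) / m
    ),
    class = "repeat_summary"
  )
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("Repeat summary: n = %d, mean = %s mm^-1, RSD = %.3g%%\n",
              x$n, format(x$mean_reported), x$rsd))
  invisible(x)
}
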