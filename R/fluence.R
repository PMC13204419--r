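#' Internal photon fluence rate of an isotropic point source
#'
#' Taylor-expanded diffusion-approximation fluence rate at transverse
#' distance `r` and depth `z` beneath the surface of a homogeneous
#' semi-infinite medium, for an isotropic point source of power `P`:
#' \deqn{\Phi(r,z) \approx \frac{P}{4\pi D}\, 2 (z_0 + 2AD)\,
#'   \frac{z}{R^3}\,(1 + \mu_{eff} R)\, e^{-\mu_{eff} R}, \quad
#'   R = \sqrt{r^2 + z^2}.}
#' The expansion assumes `z0 << r` or `z0 << z`; evaluations with
#' `R < z0` trigger a soft validity warning (controllable via `warn`)
#' rather than an error, since dosimetry maps are routinely plotted into
#' that region. Under this approximation the fluence vanishes identically
#' at the surface `z = 0`.
#'
#' Only ratios of this quantity are physically used downstream; see
#' [relative_fluence()], in which `P`, `D`, `A` and `z0` cancel.
#'
#' @param props An [optical_properties()] object.
#' @param r Transverse distance, mm. Vectorized (recycled against `z`).
#' @param z Depth, mm (>= 0).
#' @param P Source power, arbitrary units (> 0).
#' @param warn Emit the small-`R` validity warning? Default `TRUE`.
#' @return Fluence rate, arbitrary units.
#' @export
fluence <- function(props, r, z, P = 1, warn = TRUE) {
  stopifnot(inherits(props, "optical_properties"))
  if (P <= 0) stop("source power P must be > 0")
  if (any(z < 0)) stop("depth z must be >= 0")
  R <- sqrt(r^2 + z^2)
  if (any(R == 0)) stop("singular point: fluence is undefined at R = 0")
  if (warn && any(R < props$z0)) {
    warning("evaluation point(s) with R < z0: outside the validity region ",
            "of the Taylor-expanded fluence formula")
  }
  mu <- props$mu_eff
  (P / (4 * pi * props$D)) * 2 * (props$z0 + 2 * props$boundary_A * props$D) *
    (z / R^3) * (1 + mu * R) * exp(-mu * R)
}

#' Relative photon fluence between a target and a reference point
#'
#' Ratio of the internal fluence rate at a target point to that at a fixed
#' reference point. All absolute system parameters (source power, diffusion
#' coefficient, boundary factor, source depth) cancel; the ratio depends only
#' on the measured effective attenuation coefficient and the coordinates:
#' \deqn{\frac{\Phi_2}{\Phi_1} = \frac{z_2 R_1^3}{z_1 R_2^3}\,
#'   \frac{1 + \mu_{eff} R_2}{1 + \mu_{eff} R_1}\, e^{\mu_{eff}(R_1 - R_2)}.}
#' This is what lets a wearable probe reconstruct the internal dose
#' distribution from a surface measurement of `mu_eff` alone.
#'
#' @param mu_eff Effective attenuation coefficient, mm^-1 (>= 0).
#' @param r,z Target point coordinates, mm (vectorized; `z = 0` yields 0).
#' @param ref Reference point `c(r, z)`, mm, with `ref[2] > 0`.
#' @return Dimensionless fluence ratio(s).
#' @examples
#' relative_fluence(0.136, r = 0, z = 5)    # vs default reference (0, 1)
#' @export
relative_fluence <- function(mu_eff, r, z, ref = c(0, 1)) {
  stopifnot(is.numeric(mu_eff), length(mu_eff) == 1, mu_eff >= 0,
            length(ref) == 2)
  if (ref[2] <= 0) {
    stop("invalid reference: reference depth must be > 0 (zero fluence at z = 0)")
  }
  if (any(z < 0)) stop("target depth z must be >= 0")
  R1 <- sqrt(ref[1]^2 + ref[2]^2)
  R2 <- sqrt(r^2 + z^2)
  out <- numeric(length(R2))
  pos <- z > 0
  out[pos] <- (z[pos] * R1^3) / (ref[2] * R2[pos]^3) *
    (1 + mu_eff * R2[pos]) / (1 + mu_eff * R1) *
    exp(mu_eff * (R1 - R2[pos]))
  out  # z = 0 rows stay exactly 0
}

#' Relative fluence field over an (r, z) grid
#'
#' Evaluates [relative_fluence()] on a regular grid and normalizes by
#' construction to 1 at the grid node nearest the reference point (the
#' shallow on-axis point (0, 1) mm by default, directly beneath the source).
#' A log10 companion is kept for display, floored at `log_floor` so the
#' zero-valued surface row stays plottable.
#'
#' @inheritParams relative_fluence
#' @param r_range,z_range Grid extents `c(min, max)`, mm.
#' @param step Grid step, mm (> 0).
#' @param ref Reference point `c(r, z)`; snapped to the nearest grid node and
#'   required to lie inside the grid.
#' @param log_floor Floor applied before taking log10. Default 1e-12.
#' @return Object of class `fluence_field`: list with `r_axis`, `z_axis`,
#'   `values` (matrix, rows = depths, columns = transverse positions),
#'   `log10_values`, `mu_eff`, `reference` and `step`.
#' @export
fluence_map <- function(mu_eff, r_range = c(-10, 10), z_range = c(0, 10),
                        step = 0.1, ref = c(0, 1), log_floor = 1e-12) {
  stopifnot(step > 0, length(r_range) == 2, length(z_range) == 2)
  r_axis <- seq(r_range[1], r_range[2], by = step)
  z_axis <- seq(z_range[1], z_range[2], by = step)
  # snap the reference to the grid so the reference cell is exactly 1
  ir <- which.min(abs(r_axis - ref[1]))
  iz <- which.min(abs(z_axis - ref[2]))
  ref_snapped <- c(r_axis[ir], z_axis[iz])
  if (ref_snapped[2] <= 0) stop("reference point must have depth > 0 inside the grid")
  g <- expand.grid(r = r_axis, z = z_axis)
  vals <- relative_fluence(mu_eff, g$r, g$z, ref = ref_snapped)
  values <- matrix(vals, nrow = length(z_axis), ncol = length(r_axis),
                   byrow = TRUE)
  structure(
    list(
      r_axis = r_axis,
      z_axis = z_axis,
      values = values,
      log10_values = log10(pmax(values, log_floor)),
      mu_eff = mu_eff,
      reference = ref_snapped,
      step = step
    ),
    class = "fluence_field"
  )
}

#' @export
print.fluence_field <- function(x, ...) {
  cat(sprintf(
    "Relative fluence field: mu_eff = %.4g mm^-1, %d x %d grid (z x r), step %.3g mm\n",
    x$mu_eff, nrow(x$values), ncol(x$values), x$step))
  cat(sprintf("  reference point (r = %.3g, z = %.3g) mm; range [%.3g, %.3g]\n",
              x$reference[1], x$reference[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Max-normalized surface or depth profile of a fluence field
#'
#' Extracts the one-dimensional profiles used to compare dose distributions
#' across subjects: the "surface" profile as a function of transverse
#' distance r (evaluated on a fixed shallow slice `z = z_eps`, because the
#' Taylor-expanded fluence vanishes identically at z = 0 while its r-shape
#' is preserved along any constant-z slice), and the "depth" profile on the
#' beam axis r = 0. Each curve is normalized to its own maximum.
#'
#' @param field A [fluence_map()] result.
#' @param axis `"surface"` or `"depth"`.
#' @param z_eps Depth of the shallow surface slice, mm. Default 0.1.
#' @return `data.frame` with columns `coordinate` (mm) and `intensity`
#'   (max-normalized).
#' @export
axis_profile <- function(field, axis = c("surface", "depth"), z_eps = 0.1) {
  stopifnot(inherits(field, "fluence_field"))
  axis <- match.arg(axis)
  if (axis == "surface") {
    r <- field$r_axis[field$r_axis >= 0]
    v <- relative_fluence(field$mu_eff, r, rep(z_eps, length(r)),
                          ref = field$reference)
    data.frame(coordinate = r, intensity = v / max(v))
  } else {
    z <- field$z_axis[field$z_axis > 0]
    v <- relative_fluence(field$mu_eff, rep(0, length(z)), z,
                          ref = field$reference)
    data.frame(coordinate = z, intensity = v / max(v))
  }
}

#' Export a fluence field as a CSV grid with a JSON metadata sidecar
#'
#' The CSV has the transverse axis as header row and the depth axis as first
#' column; cells hold the relative fluence. Metadata (`mu_eff`, reference
#' point, step, normalization convention) go to `meta_path` when given.
#'
#' @param field A [fluence_map()] result.
#' @param path Output CSV path.
#' @param meta_path Optional JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_fluence_csv <- function(field, path, meta_path = NULL) {
  stopifnot(inherits(field, "fluence_field"))
  df <- as.data.frame(field$values)
  names(df) <- format(field$r_axis, trim = TRUE)
  df <- cbind(z_mm = field$z_axis, df)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(meta_path)) {
    jsonlite::write_json(
      list(mu_eff = field$mu_eff,
           reference = list(r_mm = field$reference[1],
                            z_mm = field$reference[2]),
           step_mm = field$step,
           normalization = "relative to reference grid node"),
      meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
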