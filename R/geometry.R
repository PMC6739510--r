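#' Trabecula geometry
#'
#' Dimensions of the one-dimensional muscle preparation: optimal length
#' `L0` (the length at which developed force is maximal) and diameter.
#' The cross-section is taken as circular, so wall stress is
#' \eqn{\sigma = F / (\pi d^2/4)}.
#'
#' @param L0_mm Optimal muscle length, mm. Default 1.8 mm (a typical rat
#'   left-ventricular trabecula).
#' @param diameter_mm Muscle diameter, mm. Default 0.26 mm.
#' @return An object of class `trabecula_geometry` with SI fields `L0`,
#'   `diameter` and `area` (m, m, m^2).
#' @examples
#' geom <- trabecula_geometry(1.8, 0.26)
#' force_to_stress(3.5e-3, geom) / 1e3  # ~65.9 kPa
#' @export
trabecula_geometry <- function(L0_mm = 1.8, diameter_mm = 0.26) {
  if (!is.numeric(L0_mm) || length(L0_mm) != 1 || !is.finite(L0_mm) ||
      L0_mm <= 0)
    abort("`L0_mm` must be a single positive number.",
          class = "wkloop_invalid_geometry")
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1 ||
      !is.finite(diameter_mm) || diameter_mm <= 0)
    abort("`diameter_mm` must be a single positive number.",
          class = "wkloop_invalid_geometry")
  d <- diameter_mm * MM
  structure(
    list(L0 = L0_mm * MM, diameter = d, area = pi * d^2 / 4),
    class = "trabecula_geometry"
  )
}

#' @export
print.trabecula_geometry <- function(x, ...) {
  cat(sprintf(
    "<trabecula_geometry> L0 = %.3g mm, diameter = %.3g mm, area = %.4g mm^2\n",
    x$L0 / MM, x$diameter / MM, x$area / MM^2))
  invisible(x)
}

#' Equivalent ventricle geometry
#'
#' The thin-walled elastic sphere standing in for the left ventricle.
#' Muscle length maps linearly to chamber radius (`r_chamber = r_ref * L / L_ref`),
#' which gives the cubic length-volume relation; pressure follows from
#' Laplace's law \eqn{P = 2 \sigma h / r}. The thin-wall regime requires
#' `h < r_ref`.
#'
#' @param r_ref_mm Resting chamber radius, mm (rat left-ventricle scale:
#'   the 5 mm default holds an end-diastolic volume of about 0.52 mL).
#' @param wall_thickness_mm Wall thickness `h`, mm, held constant.
#' @param L_ref_mm Muscle length mapped to `r_ref`, mm; conventionally the
#'   optimal length `L0`.
#' @return An object of class `ventricle_geometry` with SI fields `r_ref`,
#'   `h`, `L_ref`.
#' @export
ventricle_geometry <- function(r_ref_mm = 5, wall_thickness_mm = 0.25,
                               L_ref_mm = 1.8) {
  vals <- c(r_ref_mm = r_ref_mm, wall_thickness_mm = wall_thickness_mm,
            L_ref_mm = L_ref_mm)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad))
    abort(paste0("ventricle_geometry: non-positive or non-finite: ",
                 paste(names(vals)[bad], collapse = ", ")),
          class = "wkloop_invalid_geometry")
  if (wall_thickness_mm >= r_ref_mm)
    abort("wall thickness must be smaller than the resting radius (thin-wall regime)",
          class = "wkloop_invalid_geometry")
  structure(
    list(r_ref = r_ref_mm * MM, h = wall_thickness_mm * MM,
         L_ref = L_ref_mm * MM),
    class = "ventricle_geometry"
  )
}

#' @export
print.ventricle_geometry <- function(x, ...) {
  cat(sprintf("<ventricle_geometry> r_ref = %.3g mm, h = %.3g mm, L_ref = %.3g mm\n",
              x$r_ref / MM, x$h / MM, x$L_ref / MM))
  invisible(x)
}

#' Convert muscle force to wall stress
#'
#' @param F Force, N (vectorised). Negative values are permitted but flagged
#'   with a warning (they indicate an over-stretched or pushing state that
#'   the loading model does not represent).
#' @param geom A [trabecula_geometry()].
#' @return Wall stress, Pa.
#' @export
force_to_stress <- function(F, geom) {
  stopifnot(inherits(geom, "trabecula_geometry"))
  if (!is.numeric(F)) abort("`F` must be numeric.")
  if (any(F < 0, na.rm = TRUE))
    warn("negative force converted to (negative) stress")
  F / geom$area
}

#' Convert wall stress to ventricular pressure (Laplace's law)
#'
#' Thin-walled sphere: \eqn{P = 2 \sigma h / r} with constant wall
#' thickness `h`.
#'
#' @param sigma Wall stress, Pa (vectorised).
#' @param vgeom A [ventricle_geometry()].
#' @param r Current chamber radius, m.
#' @return Ventricular pressure, Pa.
#' @export
stress_to_pressure <- function(sigma, vgeom, r) {
  stopifnot(inherits(vgeom, "ventricle_geometry"))
  if (any(!is.finite(r)) || any(r <= 0))
    abort("chamber radius must be positive and finite",
          class = "wkloop_invalid_state")
  2 * sigma * vgeom$h / r
}

#' Map muscle length to chamber radius
#'
#' Linear through the origin, `r_chamber = r_ref * L / L_ref`: the only mapping
#' consistent with a cubic length-volume relation.
#'
#' @param L Muscle length, m (vectorised).
#' @param vgeom A [ventricle_geometry()].
#' @return Radius, m.
#' @export
length_to_radius <- function(L, vgeom) {
  stopifnot(inherits(vgeom, "ventricle_geometry"))
  if (any(L <= 0, na.rm = TRUE))
    abort("muscle length must be positive", class = "wkloop_invalid_state")
  vgeom$r_ref * L / vgeom$L_ref
}

#' Sphere volume from radius, and inverse
#'
#' `radius_to_volume()` returns \eqn{V = (4/3)\pi r^3};
#' `volume_to_radius()` is the real cube root inverse. The round trip is
#' an identity to machine precision.
#'
#' @param r Radius, m (vectorised, non-negative).
#' @param V Volume, m^3 (vectorised, non-negative).
#' @return Volume (m^3) or radius (m).
#' @export
radius_to_volume <- function(r) {
  if (any(r < 0, na.rm = TRUE))
    abort("radius must be non-negative", class = "wkloop_invalid_state")
  (4 / 3) * pi * r^3
}

#' @rdname radius_to_volume
#' @export
volume_to_radius <- function(V) {
  if (any(V < 0, na.rm = TRUE))
    abort("volume must be non-negative", class = "wkloop_invalid_state")
  (3 * V / (4 * pi))^(1 / 3)
}

#' Net chamber flow to muscle-length rate
#'
#' Chain rule through the sphere mapping:
#' \eqn{dL/dt = (L_{ref}/r_{ref}) \, Q_{net} / (4 \pi r(L)^2)}, with
#' `Q_net = refill inflow - ejected flow`. Ejection (`Q_net < 0`) shortens
#' the muscle.
#'
#' @param Q_net Net inflow, m^3/s (vectorised).
#' @param L Muscle length, m.
#' @param vgeom A [ventricle_geometry()].
#' @return dL/dt, m/s.
#' @export
flow_to_length_rate <- function(Q_net, L, vgeom) {
  r <- length_to_radius(L, vgeom)
  if (any(r == 0))
    abort("zero chamber radius", class = "wkloop_invalid_state")
  (vgeom$L_ref / vgeom$r_ref) * Q_net / (4 * pi * r^2)
}
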