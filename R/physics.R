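## Closed-form per-segment physics: Poiseuille resistance, elastic-tube
## compliance, stiffness-product calibration and the Carreau viscosity law.
## All arithmetic is in SI units; millimetre conversion happens only at I/O.

segment_geometry <- function(segment) {
  ## Accept a single vessel_segment or a segment table (data.frame in SI).
  if (inherits(segment, "vessel_segment"))
    return(list(diameter = segment$diameter, length = segment$length,
                label = segment$label))
  if (is.data.frame(segment)) {
    req <- c("label", "diameter", "length")
    if (!all(req %in% names(segment)))
      stop("segment table must have columns label, diameter, length (SI units)",
           call. = FALSE)
    return(list(diameter = segment$diameter, length = segment$length,
                label = segment$label))
  }
  stop("`segment` must be a vessel_segment or a segment table", call. = FALSE)
}

#' Poiseuille hydraulic resistance of a vessel segment
#'
#' Resistance of fully developed laminar flow in a rigid cylindrical tube,
#' \deqn{R = \frac{128 \mu l}{\pi D^4},}
#' where \eqn{\mu} is the blood viscosity, \eqn{l} the segment length and
#' \eqn{D} the lumen diameter.  The value describes a single copy of the
#' segment; the parallel multiplicity of repeated branches is applied during
#' network reduction, not here.
#'
#' @param segment A [vessel_segment()] or a segment table (as returned by
#'   [read_segment_table()]); in the latter case the result is a named
#'   vector, one value per row.
#' @param fluid A [fluid_properties()] object.
#' @return Resistance in kg m^-4 s^-1.
#' @examples
#' s <- vessel_segment("B1", diameter = 5.6e-3, length = 33.1e-3)
#' poiseuille_resistance(s)  # ~4.80e6
#' @export
poiseuille_resistance <- function(segment, fluid = fluid_properties()) {
  g <- segment_geometry(segment)
  if (!inherits(fluid, "fluid_properties"))
    fluid <- fluid_properties(viscosity = fluid)
  bad <- which(!is.finite(g$diameter) | g$diameter <= 0)
  if (length(bad))
    stop_field("diameter", sprintf("must be > 0 (segment %s)", g$label[bad[1]]))
  bad <- which(!is.finite(g$length) | g$length <= 0)
  if (length(bad))
    stop_field("length", sprintf("must be > 0 (segment %s)", g$label[bad[1]]))
  r <- 128 * fluid$viscosity * g$length / (pi * g$diameter^4)
  stats::setNames(r, g$label)
}

#' Elastic compliance of a vessel segment
#'
#' Volume stored per unit pressure by a thin-walled elastic tube,
#' \deqn{C = \frac{\pi D^3 l}{4 G h},}
#' where \eqn{G h} is the product of the wall Young's modulus and wall
#' thickness (`stiffness_product`).  Single-copy value, as for resistance.
#'
#' @param segment A [vessel_segment()] or a segment table.
#' @param wall A [wall_properties()] object, or a numeric stiffness product
#'   (Pa m), possibly vectorised over segments.
#' @return Compliance in kg^-1 m^4 s^2.
#' @examples
#' s <- vessel_segment("B37", diameter = 4e-3, length = 20e-3)
#' elastic_compliance(s, wall_properties(2333))  # ~4.31e-13
#' @export
elastic_compliance <- function(segment, wall) {
  g <- segment_geometry(segment)
  gh <- if (inherits(wall, "wall_properties")) wall$stiffness_product else wall
  if (!is.numeric(gh) || any(!is.finite(gh)) || any(gh <= 0))
    stop_field("stiffness_product", "must be > 0")
  ans <- pi * g$diameter^3 * g$length / (4 * gh)
  stats::setNames(ans, g$label)
}

#' Calibrate a wall stiffness product from a known compliance
#'
#' Algebraic inverse of the elastic-tube compliance formula: given segment
#' geometry and a target compliance, returns the stiffness product
#' \eqn{G h = \pi D^3 l / (4 C)} that reproduces it.  Useful because
#' published compliance tables rarely state G or h; the product is all the
#' formula identifies.
#'
#' @param diameter Lumen diameter, m (vectorised).
#' @param length Segment length, m.
#' @param target_compliance Compliance to reproduce, kg^-1 m^4 s^2.
#' @return Stiffness product in Pa m.  Feeding the result back through
#'   [elastic_compliance()] recovers `target_compliance` to machine
#'   precision.
#' @export
calibrate_stiffness_product <- function(diameter, length, target_compliance) {
  for (f in c("diameter", "length", "target_compliance")) {
    v <- get(f)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop_field(f, "must be > 0")
  }
  pi * diameter^3 * length / (4 * target_compliance)
}

#' Carreau effective viscosity
#'
#' Shear-thinning viscosity law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'   \left(1 + (\lambda\dot\gamma)^2\right)^{(n-1)/2},}
#' monotonically non-increasing in the shear rate when
#' \eqn{\mu_0 \ge \mu_\infty}.
#'
#' @param shear_rate Shear rate(s) in s^-1, >= 0.
#' @param params A [carreau_params()] object.
#' @return Effective viscosity in Pa s, same length as `shear_rate`.
#' @export
carreau_viscosity <- function(shear_rate, params = carreau_params()) {
  if (!is.numeric(shear_rate) || any(!is.finite(shear_rate)) || any(shear_rate < 0))
    stop_field("shear_rate", "must be >= 0")
  if (!inherits(params, "carreau_params"))
    stop("`params` must be a carreau_params object", call. = FALSE)
  with(params, inf_shear_viscosity +
    (zero_shear_viscosity - inf_shear_viscosity) *
      (1 + (time_constant * shear_rate)^2)^((power_index - 1) / 2))
}
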