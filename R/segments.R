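#' @keywords internal
"_PACKAGE"

## Valid subtree tags for vessel segments.  "proximal" marks trunk segments
## that become the proximal resistor of an outlet boundary condition.
SEGMENT_GROUPS <- c("ICA-distal", "ECA-distal", "ophthalmic", "proximal")

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive_scalar <- function(x, field, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (allow_zero) {
    if (x < 0) stop_field(field, "must be >= 0")
  } else if (x <= 0) {
    stop_field(field, sprintf("must be > 0 (got %g)", x))
  }
  x
}

#' Vessel segment geometry
#'
#' A single vessel branch described by its lumen diameter, length and the
#' number of identical parallel copies it stands for.  Geometry is stored in
#' SI units (metres); the file readers and writers convert from/to the
#' millimetre columns used in segment tables.
#'
#' @param label Short unique identifier (e.g. `"B1"`).
#' @param diameter Lumen diameter in metres.
#' @param length Segment length in metres.
#' @param name Free-text description; defaults to the label.
#' @param multiplicity Number of identical parallel copies the record stands
#'   for (e.g. 9 lenticulostriate perforators).  Fractional counts are
#'   allowed: anatomical studies report mean branch counts such as 7.6.
#'   Multiplicity is metadata consumed only during network reduction; the
#'   per-segment physics always describes a single copy.
#' @param group Subtree tag, one of `"ICA-distal"`, `"ECA-distal"`,
#'   `"ophthalmic"`, `"proximal"`.
#' @return An object of class `vessel_segment`.
#' @examples
#' vessel_segment("B1", diameter = 5.6e-3, length = 33.1e-3)
#' @export
vessel_segment <- function(label, diameter, length, name = label,
                           multiplicity = 1, group = "ICA-distal") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop_field("label", "must be a non-empty string")
  check_positive_scalar(diameter, "diameter")
  check_positive_scalar(length, "length")
  check_positive_scalar(multiplicity, "multiplicity")
  group <- match.arg(group, SEGMENT_GROUPS)
  structure(
    list(label = label, name = name, diameter = diameter, length = length,
         multiplicity = multiplicity, group = group),
    class = "vessel_segment"
  )
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> %s (%s)\n", x$label, x$name))
  cat(sprintf("  D = %g mm, l = %g mm, n = %g, group = %s\n",
              x$diameter * 1e3, x$length * 1e3, x$multiplicity, x$group))
  invisible(x)
}

#' Blood fluid properties
#'
#' Dynamic viscosity and density of blood in SI units.  The default
#' viscosity, 0.0035 Pa s, is the infinite-shear Carreau viscosity and the
#' value under which the bundled atlas resistances reproduce; 0.004 Pa s is
#' a commonly used Newtonian alternative and may be selected explicitly.
#' Density is carried for documentation of simulator inputs; the lumped
#' resistance/compliance formulas do not use it.
#'
#' @param viscosity Dynamic viscosity, Pa s.
#' @param density Density, kg m^-3.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity = 0.0035, density = 1060) {
  check_positive_scalar(viscosity, "viscosity")
  check_positive_scalar(density, "density")
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' Vessel wall properties
#'
#' The elastic-tube compliance formula depends on the wall only through the
#' product of Young's modulus G and wall thickness h.  Neither factor is
#' identifiable on its own from a compliance value, so they are housed
#' jointly as `stiffness_product` (Pa m).
#'
#' @param stiffness_product G*h in Pa m.
#' @return An object of class `wall_properties`.
#' @export
wall_properties <- function(stiffness_product) {
  check_positive_scalar(stiffness_product, "stiffness_product")
  structure(list(stiffness_product = stiffness_product),
            class = "wall_properties")
}

#' Carreau viscosity model parameters
#'
#' Defaults are the blood values used for non-Newtonian carotid simulation:
#' relaxation time 3.313 s, power index 0.3568, zero-shear viscosity
#' 0.056 Pa s, infinite-shear viscosity 0.0035 Pa s.
#'
#' @param time_constant Relaxation time lambda, s.
#' @param power_index Power-law index n (dimensionless).
#' @param zero_shear_viscosity Viscosity at zero shear rate, Pa s.
#' @param inf_shear_viscosity Viscosity at infinite shear rate, Pa s.
#' @return An object of class `carreau_params`.
#' @export
carreau_params <- function(time_constant = 3.313, power_index = 0.3568,
                           zero_shear_viscosity = 0.056,
                           inf_shear_viscosity = 0.0035) {
  check_positive_scalar(time_constant, "time_constant")
  check_positive_scalar(power_index, "power_index")
  check_positive_scalar(zero_shear_viscosity, "zero_shear_viscosity")
  check_positive_scalar(inf_shear_viscosity, "inf_shear_viscosity")
  if (zero_shear_viscosity < inf_shear_viscosity)
    stop_field("zero_shear_viscosity",
               "must be >= inf_shear_viscosity for shear-thinning blood")
  structure(list(time_constant = time_constant, power_index = power_index,
                 zero_shear_viscosity = zero_shear_viscosity,
                 inf_shear_viscosity = inf_shear_viscosity),
            class = "carreau_params")
}

#' Lumped hydraulic element
#'
#' A resistance/compliance pair: the electrical-analog representation of a
#' vessel segment or of a reduced subtree.  Resistance in kg m^-4 s^-1,
#' compliance in kg^-1 m^4 s^2.
#'
#' @param resistance Hydraulic resistance, >= 0.
#' @param compliance Compliance, >= 0.
#' @return An object of class `lumped_element`.
#' @export
lumped_element <- function(resistance, compliance) {
  check_positive_scalar(resistance, "resistance", allow_zero = TRUE)
  check_positive_scalar(compliance, "compliance", allow_zero = TRUE)
  structure(list(resistance = resistance, compliance = compliance),
            class = "lumped_element")
}

#' @export
print.lumped_element <- function(x, ...) {
  cat(sprintf("<lumped_element> R = %.3g kg m^-4 s^-1, C = %.3g kg^-1 m^4 s^2\n",
              x$resistance, x$compliance))
  invisible(x)
}

is_lumped_element <- function(x) inherits(x, "lumped_element")
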