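#' Material specification
#'
#' Bulk material description used by the beam and collimator transport code.
#' The proton range in a material is modelled as the water CSDA-style range
#' times a dimensionless `range_scale` (water has `range_scale = 1`), and
#' multiple Coulomb scattering is driven by the radiation length.
#'
#' @param name material name.
#' @param density mass density in g/cm^3.
#' @param radiation_length radiation length X0 in cm.
#' @param range_scale factor converting the water range at equal energy to
#'   the range in this material (dimensionless, > 0).
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, density, radiation_length, range_scale) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(density) || density <= 0)
    stop("density must be > 0")
  if (!is.finite(radiation_length) || radiation_length <= 0)
    stop("radiation_length must be > 0")
  if (!is.finite(range_scale) || range_scale <= 0)
    stop("range_scale must be > 0")
  structure(
    list(name = name, density = density,
         radiation_length = radiation_length, range_scale = range_scale),
    class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: density %.3f g/cm^3, X0 %.3f cm, range_scale %.4f\n",
              x$name, x$density, x$radiation_length, x$range_scale))
  invisible(x)
}

#' Water material (reference medium)
#'
#' @return `material_spec` for liquid water (X0 = 36.08 cm).
#' @export
water_material <- function() {
  material_spec("water", density = 1, radiation_length = 36.08,
                range_scale = 1)
}

#' Brass material (collimator septa)
#'
#' Cu70/Zn30-like brass. The range scale makes both collimator thicknesses
#' (6.5 and 10 cm) opaque to primary protons at 226-228 MeV.
#'
#' @return `material_spec` for brass.
#' @export
brass_material <- function() {
  material_spec("brass", density = 8.49, radiation_length = 1.55,
                range_scale = 0.105)
}
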