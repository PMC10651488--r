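#' Define an isotropic linear-elastic material
#'
#' Materials are the per-region inputs of the elastic model: a Young's modulus
#' in pascal, a Poisson ratio and a mass density. Soft tissues sit in the
#' 1--1000 kPa range; implant silicones in the 0.05--1 MPa range; titanium at
#' ~110 GPa.
#'
#' @param name Material label, e.g. `"skin"` or `"silicone"`.
#' @param youngs_modulus Young's modulus E in Pa; must be positive.
#' @param poisson_ratio Poisson ratio nu, in `[0, 0.5)`. Values at or above 0.5
#'   (incompressible limit) are rejected: the constant-strain tetrahedron locks
#'   there and the isotropic stiffness tensor is singular.
#' @param density Mass density in kg/m^3 (used for body forces and the optional
#'   harmonic solver); nonnegative.
#'
#' @return An object of class `fbr_material` (a named list).
#' @examples
#' material_spec("skin", youngs_modulus = 100e3, poisson_ratio = 0.45)
#' @export
material_spec <- function(name, youngs_modulus, poisson_ratio = 0.45,
                          density = 1000) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.", class = "fbrmech_param_error")
  }
  if (!is.numeric(youngs_modulus) || length(youngs_modulus) != 1L ||
      !is.finite(youngs_modulus) || youngs_modulus <= 0) {
    abort("`youngs_modulus` must be a single positive number (Pa).",
          class = "fbrmech_param_error")
  }
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio < 0 || poisson_ratio >= 0.5) {
    abort("`poisson_ratio` must lie in [0, 0.5).",
          class = "fbrmech_param_error")
  }
  if (!is.numeric(density) || length(density) != 1L || density < 0) {
    abort("`density` must be nonnegative (kg/m^3).",
          class = "fbrmech_param_error")
  }
  structure(
    list(name = name,
         youngs_modulus = as.numeric(youngs_modulus),
         poisson_ratio = as.numeric(poisson_ratio),
         density = as.numeric(density)),
    class = "fbr_material"
  )
}

#' @export
print.fbr_material <- function(x, ...) {
  cat(sprintf("<fbr_material> %s: E = %.4g Pa, nu = %.3g, rho = %.4g kg/m^3\n",
              x$name, x$youngs_modulus, x$poisson_ratio, x$density))
  invisible(x)
}

as_material <- function(x) {
  if (inherits(x, "fbr_material")) return(x)
  if (is.list(x)) {
    return(material_spec(x$name,
                         youngs_modulus = x$youngs_modulus,
                         poisson_ratio = x$poisson_ratio %||% 0.45,
                         density = x$density %||% 1000))
  }
  abort("Cannot interpret object as a material specification.",
        class = "fbrmech_param_error")
}
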