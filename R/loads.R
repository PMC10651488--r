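#' Standard gravitational acceleration used throughout (m/s^2)
#'
#' Fixed at 9.8 m/s^2 exactly so that a 1.38 g vibration amplitude converts to
#' 13.524 N/kg of body force. Not 9.80665: the conversion is defined with the
#' round constant.
#' @export
FBR_GRAVITY <- 9.8

#' Construct a load specification
#'
#' A load is either a static point/resultant force on the implant (`static_force`,
#' magnitude in N), a per-mass body force over the implant (`body_force`, N/kg),
#' or a vibration described by its acceleration amplitude (in multiples of g)
#' and frequency (Hz). The load direction is horizontal (+x) by default, which
#' is the loading axis of all the implant models here.
#'
#' @param kind One of `"static_force"`, `"body_force"`, `"vibration"`.
#' @param magnitude Nonnegative magnitude: N for `static_force`, N/kg for
#'   `body_force`; ignored for `vibration` (derived from `amplitude_g`).
#' @param direction Length-3 load direction; normalized on construction.
#' @param amplitude_g,frequency Vibration amplitude (multiples of g = 9.8
#'   m/s^2) and frequency in Hz; required iff `kind = "vibration"`.
#'
#' @return An `fbr_load` object.
#' @examples
#' load_spec("static_force", magnitude = 0.02)
#' load_spec("vibration", amplitude_g = 1.38, frequency = 203)
#' @export
load_spec <- function(kind = c("static_force", "body_force", "vibration"),
                      magnitude = NULL, direction = c(1, 0, 0),
                      amplitude_g = NULL, frequency = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(direction) || length(direction) != 3L ||
      all(direction == 0)) {
    abort("`direction` must be a nonzero length-3 numeric vector.",
          class = "fbrmech_param_error")
  }
  direction <- direction / sqrt(sum(direction^2))
  if (kind == "vibration") {
    if (is.null(amplitude_g) || is.null(frequency)) {
      abort("Vibration loads need `amplitude_g` and `frequency`.",
            class = "fbrmech_param_error")
    }
    if (amplitude_g < 0) {
      abort("`amplitude_g` must be nonnegative.", class = "fbrmech_param_error")
    }
    if (frequency < 0) {
      abort("`frequency` must be nonnegative (Hz).",
            class = "fbrmech_param_error")
    }
    magnitude <- vibration_body_force(amplitude_g)  # N/kg peak
  } else {
    if (!is.null(amplitude_g) || !is.null(frequency)) {
      abort("`amplitude_g`/`frequency` only apply to vibration loads.",
            class = "fbrmech_param_error")
    }
    if (is.null(magnitude) || !is.numeric(magnitude) || magnitude < 0) {
      abort("`magnitude` must be a nonnegative number.",
            class = "fbrmech_param_error")
    }
  }
  structure(
    list(kind = kind, magnitude = as.numeric(magnitude),
         direction = direction,
         amplitude_g = if (kind == "vibration") as.numeric(amplitude_g),
         frequency = if (kind == "vibration") as.numeric(frequency)),
    class = "fbr_load"
  )
}

#' @export
print.fbr_load <- function(x, ...) {
  unit <- switch(x$kind, static_force = "N", body_force = "N/kg",
                 vibration = "N/kg (peak)")
  cat(sprintf("<fbr_load> %s: %.4g %s along (%.2f, %.2f, %.2f)",
              x$kind, x$magnitude, unit,
              x$direction[1], x$direction[2], x$direction[3]))
  if (x$kind == "vibration") {
    cat(sprintf(" [%.3g g @ %.4g Hz]", x$amplitude_g, x$frequency))
  }
  cat("\n")
  invisible(x)
}

#' Peak body force of a vibration, in N/kg
#'
#' Converts an acceleration amplitude expressed in multiples of standard
#' gravity into the peak per-mass force it exerts: `amplitude_g * 9.8`.
#' A 1.38 g amplitude gives 13.524 N/kg.
#'
#' @param amplitude_g Nonnegative acceleration amplitude in multiples of g.
#' @return Body-force magnitude in N/kg.
#' @examples
#' vibration_body_force(1.38)  # 13.524
#' @export
vibration_body_force <- function(amplitude_g) {
  if (!is.numeric(amplitude_g) || any(amplitude_g < 0)) {
    abort("`amplitude_g` must be nonnegative.", class = "fbrmech_param_error")
  }
  amplitude_g * FBR_GRAVITY
}

#' Static-equivalent peak load of a vibrating implant
#'
#' Treats the vibration quasi-statically: the peak of the periodic force is
#' `loaded_mass * amplitude_g * g` applied along the horizontal load axis.
#' This is the loading used for the headline vibrating-implant stress numbers;
#' the undamped harmonic solver ([harmonic_steady_state()]) is the dynamic
#' alternative.
#'
#' @param vibration An `fbr_load` of kind `"vibration"`.
#' @param loaded_mass Mass being accelerated (implant plus embedded motor), kg.
#' @return A static `fbr_load` whose magnitude is the peak force in N.
#' @examples
#' v <- load_spec("vibration", amplitude_g = 1.38, frequency = 203)
#' peak_quasistatic_load(v, loaded_mass = 1)  # 13.524 N
#' @export
peak_quasistatic_load <- function(vibration, loaded_mass) {
  if (!inherits(vibration, "fbr_load") || vibration$kind != "vibration") {
    abort("`vibration` must be an fbr_load of kind 'vibration'.",
          class = "fbrmech_param_error")
  }
  if (!is.numeric(loaded_mass) || length(loaded_mass) != 1L ||
      loaded_mass <= 0) {
    abort("`loaded_mass` must be a positive mass in kg.",
          class = "fbrmech_param_error")
  }
  load_spec("static_force",
            magnitude = loaded_mass * vibration_body_force(vibration$amplitude_g),
            direction = vibration$direction)
}

#' Static load from a resting tissue tension
#'
#' Wraps a dynamic resting tension (the net horizontal force the surrounding
#' tissue exerts on the implant at rest) into a validated static load. Species
#' default tensions are configuration values carried by the domain presets --
#' they come from the biomechanics literature, not from this function.
#'
#' @param tension Nonnegative resultant force, N.
#' @param direction Load direction (normalized on construction).
#' @return A static `fbr_load`.
#' @export
static_load_from_resting_tension <- function(tension, direction = c(1, 0, 0)) {
  if (!is.numeric(tension) || length(tension) != 1L || tension < 0) {
    abort("`tension` must be a nonnegative force in N.",
          class = "fbrmech_param_error")
  }
  load_spec("static_force", magnitude = tension, direction = direction)
}

#' Allometric scaling of tissue-scale forces with body mass
#'
#' Scales a reference force to a target body mass by a power law
#' `ref_force * (target_mass / ref_mass)^exponent`. The default exponent 2/3
#' corresponds to force scaling with load-bearing cross-sectional area under
#' isometric growth; it is a declared modelling choice, exposed for
#' sensitivity analysis. The scaling is multiplicative: chaining
#' mouse->rat->human equals mouse->human.
#'
#' @param ref_mass,target_mass Positive body masses, kg.
#' @param ref_force Reference force at `ref_mass`, N.
#' @param exponent Scaling exponent (dimensionless), default 2/3.
#' @return Scaled force in N.
#' @examples
#' allometric_force_scale(0.025, 0.02, 70)           # mouse -> human, 2/3 law
#' allometric_force_scale(1, 1, 1e4, exponent = 1)   # linear: 1e4
#' @export
allometric_force_scale <- function(ref_mass, ref_force, target_mass,
                                   exponent = 2 / 3) {
  if (!is.numeric(ref_mass) || !is.numeric(target_mass) ||
      any(ref_mass <= 0) || any(target_mass <= 0)) {
    abort("Masses must be positive.", class = "fbrmech_param_error")
  }
  if (!is.numeric(ref_force) || any(ref_force < 0)) {
    abort("`ref_force` must be nonnegative.", class = "fbrmech_param_error")
  }
  ref_force * (target_mass / ref_mass)^exponent
}

#' Build a stress-strain curve record
#'
#' @param strain Strictly increasing dimensionless compressive strain samples.
#' @param stress Stress samples in Pa, same length as `strain`.
#' @return A tibble of class `fbr_stress_strain` with columns `strain`, `stress`.
#' @export
stress_strain_curve <- function(strain, stress) {
  if (length(strain) != length(stress) || length(strain) < 2L) {
    abort("`strain` and `stress` must have equal length >= 2.",
          class = "fbrmech_param_error")
  }
  if (any(diff(strain) <= 0)) {
    abort("`strain` must be strictly increasing.",
          class = "fbrmech_param_error")
  }
  out <- tibble(strain = as.numeric(strain), stress = as.numeric(stress))
  class(out) <- c("fbr_stress_strain", class(out))
  out
}

#' Young's modulus from a compression stress-strain curve
#'
#' The modulus is the least-squares slope of stress against strain restricted
#' to the initial linear window, compressive strain 0 to `max_strain`
#' (default 0.10). Exact on noiseless linear data.
#'
#' @param curve A data frame with `strain` and `stress` columns (Pa), e.g. from
#'   [stress_strain_curve()] or [read_stress_strain_csv()].
#' @param max_strain Upper end of the fitting window (default 0.10).
#' @return Young's modulus in Pa.
#' @examples
#' curve <- stress_strain_curve(seq(0, 0.2, by = 0.01), 50e3 * seq(0, 0.2, by = 0.01))
#' youngs_modulus_from_curve(curve)  # 50000
#' @export
youngs_modulus_from_curve <- function(curve, max_strain = 0.10) {
  if (!is.data.frame(curve) || !all(c("strain", "stress") %in% names(curve))) {
    abort("`curve` must have `strain` and `stress` columns.",
          class = "fbrmech_param_error")
  }
  keep <- curve$strain >= 0 & curve$strain <= max_strain
  if (sum(keep) < 2L) {
    abort(sprintf("Need >= 2 samples with strain in [0, %g]; found %d.",
                  max_strain, sum(keep)),
          class = "fbrmech_param_error")
  }
  fit <- lm(stress ~ strain, data = curve[keep, , drop = FALSE])
  unname(coef(fit)[["strain"]])
}

#' Read a two-column stress-strain CSV
#'
#' Expects columns `strain` (dimensionless) and `stress` (Pa); extra columns
#' are ignored.
#' @param path CSV path.
#' @return An `fbr_stress_strain` tibble.
#' @export
read_stress_strain_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stress_strain_curve(df$strain, df$stress)
}
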