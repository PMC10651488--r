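#' Describe one tissue layer
#'
#' @param name Layer name (e.g. `"skin"`, `"subcutis"`, `"muscle_bone"`).
#' @param thickness Layer thickness in mm (> 0).
#' @param material An [material_spec()] object.
#' @return A named list describing the layer.
#' @export
layer_spec <- function(name, thickness, material) {
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0) {
    abort(sprintf("Layer '%s': thickness must be > 0 (mm).", name),
          class = "fbrmech_param_error")
  }
  list(name = name, thickness = as.numeric(thickness),
       material = as_material(material))
}

#' Assemble a layered tissue + disc implant domain description
#'
#' The domain is a rectangular block of stacked tissue layers (listed from the
#' bottom muscle/bone layer upwards, bottom face fixed) with a cylindrical disc
#' implant embedded in one host layer, centred laterally and vertically. The
#' load axis is horizontal (+x); z is vertical with the fixed support at z = 0.
#' Geometry is in mm, moduli in Pa; conversion to SI happens inside the solver.
#'
#' @param layers List of [layer_spec()] entries, bottom to top.
#' @param implant List with `radius` (mm), `height` (mm), `material`
#'   ([material_spec()]), and optionally `motor_mass` (kg) for vibrating
#'   implants; `NULL` for an implant-free domain.
#' @param lateral_extent Side length of the square footprint, mm.
#' @param implant_layer Name of the layer hosting the implant.
#' @param load An [load_spec()] object (may be `NULL` for geometry-only work).
#' @param species Optional species tag carried through to reports.
#' @param body_mass Optional body mass in kg (used by allometric scaling
#'   helpers and reports).
#'
#' @return A validated `fbr_domain` object with derived quantities attached
#'   (total height, implant bounding box, implant volume and mass).
#' @seealso [build_layered_domain()], [preset_domains()]
#' @export
domain_spec <- function(layers, implant = NULL, lateral_extent,
                        implant_layer = NULL, load = NULL,
                        species = NULL, body_mass = NULL) {
  spec <- structure(
    list(layers = layers, implant = implant,
         lateral_extent = as.numeric(lateral_extent),
         implant_layer = implant_layer, load = load,
         species = species, body_mass = body_mass),
    class = "fbr_domain"
  )
  build_layered_domain(spec)
}

#' Validate a domain and attach derived geometry
#'
#' Checks layer thicknesses, material validity, implant placement (the disc
#' must fit inside its host layer and within the lateral extent) and computes
#' the derived quantities used downstream: total height, the implant's
#' vertical placement box (vertically centred in the host layer), implant
#' volume (mm^3) and implant mass (kg, including any motor mass).
#' Validation problems are aggregated into a single error.
#'
#' @param spec An `fbr_domain` object (possibly not yet validated).
#' @return The validated spec with a `derived` element.
#' @export
build_layered_domain <- function(spec) {
  if (!inherits(spec, "fbr_domain")) {
    abort("`spec` must be an fbr_domain.", class = "fbrmech_param_error")
  }
  errors <- character()
  if (length(spec$layers) < 1L) errors <- c(errors, "at least one layer required")
  nms <- vapply(spec$layers, `[[`, "", "name")
  if (anyDuplicated(nms)) errors <- c(errors, "layer names must be unique")
  for (ly in spec$layers) {
    if (!is.numeric(ly$thickness) || ly$thickness <= 0) {
      errors <- c(errors, sprintf("layer '%s' has non-positive thickness", ly$name))
    }
    ok <- tryCatch({ as_material(ly$material); TRUE }, error = function(e) FALSE)
    if (!ok) errors <- c(errors, sprintf("layer '%s' has an invalid material", ly$name))
  }
  if (!is.numeric(spec$lateral_extent) || spec$lateral_extent <= 0) {
    errors <- c(errors, "lateral_extent must be > 0")
  }
  thick <- vapply(spec$layers, `[[`, 0, "thickness")
  total_height <- sum(thick)
  z_tops <- cumsum(thick)
  z_bottoms <- z_tops - thick
  derived <- list(total_height = total_height,
                  layer_z = tibble(name = nms, z_bottom = z_bottoms,
                                   z_top = z_tops, thickness = thick))
  if (!is.null(spec$implant)) {
    imp <- spec$implant
    if (is.null(spec$implant_layer) || !(spec$implant_layer %in% nms)) {
      errors <- c(errors, "implant_layer must name one of the layers")
    } else {
      host <- which(nms == spec$implant_layer)
      if (imp$height > thick[host]) {
        errors <- c(errors, sprintf(
          "implant height %.3g mm exceeds host layer '%s' thickness %.3g mm",
          imp$height, spec$implant_layer, thick[host]))
      }
      if (2 * imp$radius > spec$lateral_extent) {
        errors <- c(errors, "implant diameter exceeds lateral extent")
      }
      z_mid <- (z_bottoms[host] + z_tops[host]) / 2
      derived$implant_box <- list(
        radius = imp$radius,
        z_bottom = z_mid - imp$height / 2,
        z_top = z_mid + imp$height / 2)
      vol_mm3 <- pi * imp$radius^2 * imp$height
      mat <- as_material(imp$material)
      derived$implant_volume_mm3 <- vol_mm3
      derived$implant_mass_kg <-
        vol_mm3 * 1e-9 * mat$density + (imp$motor_mass %||% 0)
    }
    if (!is.numeric(imp$radius) || imp$radius <= 0 ||
        !is.numeric(imp$height) || imp$height <= 0) {
      errors <- c(errors, "implant radius and height must be > 0")
    }
  }
  if (length(errors)) {
    abort(paste0("Invalid domain specification:\n",
                 paste0("- ", errors, collapse = "\n")),
          class = "fbrmech_domain_error")
  }
  spec$derived <- derived
  spec
}

#' @export
print.fbr_domain <- function(x, ...) {
  cat(sprintf("<fbr_domain>%s %d layer(s), lateral extent %.3g mm, height %.3g mm\n",
              if (!is.null(x$species)) paste0(" [", x$species, "]") else "",
              length(x$layers), x$lateral_extent, x$derived$total_height))
  for (ly in x$layers) {
    cat(sprintf("  layer %-12s %6.3g mm  E = %.4g Pa\n", ly$name, ly$thickness,
                as_material(ly$material)$youngs_modulus))
  }
  if (!is.null(x$implant)) {
    cat(sprintf("  implant: disc r = %.3g mm, h = %.3g mm in '%s' (E = %.4g Pa)\n",
                x$implant$radius, x$implant$height, x$implant_layer,
                as_material(x$implant$material)$youngs_modulus))
  }
  if (!is.null(x$load)) print(x$load)
  invisible(x)
}

preset_names <- function() {
  dir <- system.file("extdata", "presets", package = "fbrmech")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Built-in species/implant domain presets
#'
#' Four study configurations are shipped as commented YAML configs under
#' `inst/extdata/presets/`: `mouse_standard` (subcutaneous silicone disc,
#' static resting-tension load), `mouse_msi` (same disc with an embedded coin
#' motor, 1.38 g / 203 Hz vibration), `human_breast` (silicone breast implant,
#' static resting-tension load) and `human_titanium` (identical to
#' `human_breast` except for the implant material record). Tissue moduli,
#' thicknesses and resting tensions are literature-scale configuration values
#' whose provenance is documented in the config comments; every value can be
#' overridden.
#'
#' @param preset Preset name.
#' @param overrides Named list merged over the raw config before construction
#'   (nested lists merge recursively), e.g.
#'   `list(load = list(magnitude_n = 0.05))`.
#' @return An `fbr_domain` with the preset's default mesh edge length attached
#'   as attribute `"edge_length"`.
#' @examples
#' d <- preset_domains("mouse_standard")
#' d$implant$radius  # 7.75 mm
#' @export
preset_domains <- function(preset, overrides = NULL) {
  path <- system.file("extdata", "presets", paste0(preset, ".yaml"),
                      package = "fbrmech")
  if (identical(path, "")) {
    abort(sprintf("Unknown preset '%s'. Available: %s", preset,
                  paste(preset_names(), collapse = ", ")),
          class = "fbrmech_param_error")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  domain_from_config(cfg)
}

#' Construct a domain from a parsed config list
#'
#' The list mirrors the preset YAML schema (see files under
#' `inst/extdata/presets/`).
#' @param cfg Named list as produced by `yaml::read_yaml()` on a preset file.
#' @return An `fbr_domain`.
#' @export
domain_from_config <- function(cfg) {
  mat_from <- function(m) {
    material_spec(m$name, youngs_modulus = m$youngs_modulus_pa,
                  poisson_ratio = m$poisson_ratio %||% 0.45,
                  density = m$density_kg_m3 %||% 1000)
  }
  layers <- lapply(cfg$layers, function(ly) {
    layer_spec(ly$name, ly$thickness_mm, mat_from(ly$material))
  })
  implant <- NULL
  if (!is.null(cfg$implant)) {
    implant <- list(radius = cfg$implant$radius_mm,
                    height = cfg$implant$height_mm,
                    material = mat_from(cfg$implant$material),
                    motor_mass = cfg$implant$motor_mass_kg)
  }
  load <- NULL
  if (!is.null(cfg$load)) {
    lc <- cfg$load
    dirv <- unlist(lc$direction %||% c(1, 0, 0))
    load <- switch(
      lc$kind,
      static_force = static_load_from_resting_tension(lc$magnitude_n, dirv),
      body_force = load_spec("body_force", magnitude = lc$magnitude_n_per_kg,
                             direction = dirv),
      vibration = load_spec("vibration", amplitude_g = lc$amplitude_g,
                            frequency = lc$frequency_hz, direction = dirv),
      abort(sprintf("Unknown load kind '%s'.", lc$kind),
            class = "fbrmech_param_error")
    )
  }
  spec <- domain_spec(layers = layers, implant = implant,
                      lateral_extent = cfg$lateral_extent_mm,
                      implant_layer = cfg$implant$layer,
                      load = load, species = cfg$species,
                      body_mass = cfg$body_mass_kg)
  attr(spec, "edge_length") <- cfg$default_edge_length_mm
  spec
}
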