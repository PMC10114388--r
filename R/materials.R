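#' Define a linear isotropic elastic material
#'
#' @param name Material label (e.g. `"collagen"`).
#' @param young_modulus Young's modulus in Pa; must be positive.
#' @param poisson_ratio Poisson's ratio; must satisfy `0 <= nu < 0.5`
#'   (the solver uses a standard displacement formulation, which degenerates
#'   at the incompressible limit).
#'
#' @return A one-row tibble with columns `name`, `young_modulus`,
#'   `poisson_ratio`.
#' @export
#' @examples
#' material("collagen", 8.9e6, 0.48)
material <- function(name, young_modulus, poisson_ratio) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    rlang::abort("`name` must be a non-empty string.", class = "ligafem_material_error")
  }
  if (!is.numeric(young_modulus) || length(young_modulus) != 1L ||
      !is.finite(young_modulus) || young_modulus <= 0) {
    rlang::abort("`young_modulus` must be a positive finite number (Pa).",
                 class = "ligafem_material_error")
  }
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      !is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5) {
    rlang::abort("`poisson_ratio` must satisfy 0 <= nu < 0.5.",
                 class = "ligafem_material_error")
  }
  tibble::tibble(name = name, young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio)
}

#' Reference material table for the ligament models
#'
#' Young's moduli and Poisson's ratios for the four constituents used
#' throughout the study: collagen fibres, interstitial elastin, the
#' homogenised sheet ligament, and bone.
#'
#' @return A tibble with one row per material (`collagen`, `elastin`,
#'   `sheet`, `bone`) and columns `name`, `young_modulus` (Pa),
#'   `poisson_ratio`.
#' @export
#' @examples
#' ligament_materials()
ligament_materials <- function() {
  dplyr::bind_rows(
    material("collagen", 8.9e6, 0.48),
    material("elastin",  4.0e6, 0.48),
    material("sheet",   12.7e6, 0.48),
    material("bone",    17.0e6, 0.30)
  )
}

# Map a component label (collagen / elastin / sheet / bone_fixed / bone_free)
# to its material name.
component_material_name <- function(component) {
  ifelse(component %in% c("bone_fixed", "bone_free"), "bone", component)
}

# Look up (E, nu) for a component label in a materials tibble.
lookup_material <- function(materials, component) {
  nm <- component_material_name(component)
  row <- materials[materials$name == nm, , drop = FALSE]
  if (nrow(row) != 1L) {
    rlang::abort(paste0("no material defined for component '", component, "'"),
                 class = "ligafem_lookup_error")
  }
  list(E = row$young_modulus, nu = row$poisson_ratio)
}
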