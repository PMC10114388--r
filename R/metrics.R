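#' @title Component summaries and derived mechanical metrics
#' @description
#' Post-processing of solved load cases: per-component von Mises and
#' displacement statistics, stress-strain slopes, percent changes, and
#' localization of the stress maximum relative to material interfaces.
#' Stress statistics are taken over element centroids (which suppresses
#' mesh-dependent nodal extrapolation spikes at re-entrant corners);
#' displacement statistics over the component's nodes.
#' @name metrics
NULL

#' Summarise stress and displacement over one material component
#'
#' @param result A `ligafem_result` from [run_load_case()].
#' @param component Component label present in the mesh (`"collagen"`,
#'   `"elastin"`, `"sheet"`, `"bone_fixed"`, `"bone_free"`).
#' @return A one-row tibble: `component`, `mean_vm`, `max_vm` (Pa, element
#'   centroids), `mean_disp`, `max_disp` (m, displacement magnitude over
#'   the component's nodes), `n_elements`.
#' @export
#' @examples
#' g <- build_sheet_model(c(60, 20, 20), bone_thickness = 20)
#' r <- tensile_case(g, voxelize(g, 10))
#' summarize_component(r, "sheet")
summarize_component <- function(result, component) {
  stopifnot(inherits(result, "ligafem_result"))
  mesh <- result$mesh
  sel <- which(mesh$material == component)
  if (length(sel) == 0L) {
    rlang::abort(paste0("component '", component, "' has no elements"),
                 class = "ligafem_query_error")
  }
  nodes <- sort(unique(as.vector(mesh$elems[sel, , drop = FALSE])))
  dmag <- sqrt(rowSums(result$u[nodes, , drop = FALSE]^2))
  vm <- result$stress$von_mises[sel]
  tibble::tibble(
    component = component,
    mean_vm = mean(vm), max_vm = max(vm),
    mean_disp = mean(dmag), max_disp = max(dmag),
    n_elements = length(sel)
  )
}

#' @describeIn summarize_component Summaries for every component in the mesh.
#' @export
component_summaries <- function(result) {
  purrr::map_dfr(unique(result$mesh$material),
                 function(cc) summarize_component(result, cc))
}

#' Stress-strain slope of a loading protocol
#'
#' Runs the tensile or shear protocol at several load scalings and fits the
#' least-squares slope of applied traction against the resulting global
#' strain through the origin. For this linear solver the slope is exact at
#' any scaling; a relative residual above `1e-8` flags an inconsistency.
#'
#' @param geometry,mesh Model and its mesh.
#' @param case_kind `"tensile"` or `"shear"` (the rotation protocol is
#'   torque-like and has no stress-strain slope).
#' @param scalings Numeric factors applied to the protocol's default
#'   traction; at least two.
#' @param materials Optional material table override.
#' @return A one-row tibble: `case`, `content` (elastin fraction or `NA`
#'   for the sheet), `slope` (Pa), `nonlinear` (logical flag).
#' @export
stress_strain_slope <- function(geometry, mesh, case_kind = c("tensile", "shear"),
                                scalings = c(0.5, 1, 1.5, 2), materials = NULL) {
  case_kind <- match.arg(case_kind)
  if (length(scalings) < 2L) {
    rlang::abort("need at least two load scalings", class = "ligafem_query_error")
  }
  base <- load_case(case_kind)$magnitude
  K <- assemble(mesh, if (is.null(materials)) geometry$materials else materials)
  fac <- NULL
  stress <- numeric(length(scalings))
  strain <- numeric(length(scalings))
  for (i in seq_along(scalings)) {
    r <- run_load_case(geometry, mesh, case_kind, magnitude = base * scalings[i],
                       materials = materials, K = K, factor = fac)
    fac <- r$factor
    stress[i] <- r$case$magnitude
    strain[i] <- r$strain
  }
  if (all(abs(strain) < .Machine$double.xmin)) {
    rlang::abort("degenerate (zero) strains; slope undefined",
                 class = "ligafem_slope_error")
  }
  slope <- sum(stress * strain) / sum(strain^2)
  resid <- sqrt(sum((stress - slope * strain)^2) / sum(stress^2))
  content <- if (geometry$model_kind == "fibre") elastin_fraction(geometry) else NA_real_
  tibble::tibble(case = case_kind, content = content, slope = slope,
                 nonlinear = resid > 1e-8)
}

#' Percent change from a reference value
#'
#' `percent_change(a, b)` is `100 * (a - b) / a`: the percent decrease from
#' the reference `a` to `b` (negative when `b` exceeds `a`).
#'
#' @param a Reference (nonzero) value.
#' @param b Comparison value.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(10, 3.5) # 65
percent_change <- function(a, b) {
  if (any(a == 0)) {
    rlang::abort("reference value must be nonzero", class = "ligafem_query_error")
  }
  100 * (a - b) / a
}

#' Locate the stress maximum and classify its interface
#'
#' Finds the element with the largest von Mises stress in a component and
#' reports whether it touches (shares a face or edge with) an element of a
#' different material, and which.
#'
#' @param result A `ligafem_result`.
#' @param component Component to search; `NULL` searches all non-bone
#'   (ligament) elements.
#' @return A one-row tibble: `element` (index), `component`, `max_vm` (Pa),
#'   `centroid_x/y/z` (um), `junction` (logical), `junction_with`
#'   (comma-separated labels or `NA`).
#' @export
locate_max_stress <- function(result, component = NULL) {
  stopifnot(inherits(result, "ligafem_result"))
  mesh <- result$mesh
  if (is.null(component)) {
    sel <- which(!(mesh$material %in% c("bone_fixed", "bone_free")))
  } else {
    sel <- which(mesh$material %in% component)
  }
  if (length(sel) == 0L) {
    rlang::abort("no elements to search", class = "ligafem_query_error")
  }
  e <- sel[which.max(result$stress$von_mises[sel])]
  enodes <- mesh$elems[e, ]
  # neighbours sharing >= 2 nodes (a face or an edge)
  touch <- rowSums(matrix(mesh$elems %in% enodes, nrow = nrow(mesh$elems))) >= 2L
  touch[e] <- FALSE
  others <- setdiff(unique(mesh$material[touch]), mesh$material[e])
  centroid <- colMeans(matrix(mesh$nodes[enodes, ], 8L, 3L)) * 1e6
  tibble::tibble(
    element = e, component = mesh$material[e],
    max_vm = result$stress$von_mises[e],
    centroid_x = centroid[1], centroid_y = centroid[2], centroid_z = centroid[3],
    junction = length(others) > 0L,
    junction_with = if (length(others)) paste(others, collapse = ",") else NA_character_
  )
}

# --- broom-style methods --------------------------------------------------

#' Tidy a solved load case into per-component summaries
#'
#' @param x A `ligafem_result`.
#' @param ... Unused.
#' @return A tibble with one row per material component (see
#'   [summarize_component()]) plus `case` and `magnitude` columns.
#' @method tidy ligafem_result
#' @export
tidy.ligafem_result <- function(x, ...) {
  dplyr::mutate(component_summaries(x),
                case = x$case$kind, magnitude = x$case$magnitude,
                .before = 1L)
}

#' One-row overview of a solved load case
#'
#' @param x A `ligafem_result`.
#' @param ... Unused.
#' @return A one-row tibble: case kind and magnitude, model kind, global
#'   strain, rotation required stresses (MPa), ligament maximum von Mises
#'   stress (Pa), and the solver residual.
#' @method glance ligafem_result
#' @export
glance.ligafem_result <- function(x, ...) {
  lig <- which(!(x$mesh$material %in% c("bone_fixed", "bone_free")))
  tibble::tibble(
    case = x$case$kind, magnitude = x$case$magnitude,
    model = x$geometry$model_kind,
    strain = x$strain,
    sigma_y_MPa = x$sigma_y_Pa / 1e6,
    sigma_z_MPa = x$sigma_z_Pa / 1e6,
    max_vm_ligament = max(x$stress$von_mises[lig]),
    residual = x$residual
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
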