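# Shared fixtures: all built in code, sized for fast solves.

# single homogeneous block meshed as n^3 cubes (label "sheet" by default)
block_geometry <- function(dims_um = c(12, 12, 12), label = "sheet",
                           materials = ligament_materials()) {
  g <- ligafem:::new_model_geometry(
    ligafem:::new_prism(label, c(0, 0, 0), dims_um),
    model_kind = "sheet", n_elastin = NA_integer_,
    lattice = list(dims = dims_um), materials = materials)
  g
}

# hand-built two-element bar along X with per-element materials
two_element_bar <- function(E1 = 2e6, E2 = 8e6, nu = 0, h_um = 10) {
  g <- block_geometry(c(2 * h_um, h_um, h_um), label = "m1")
  mesh <- voxelize(g, h_um)
  mesh$material <- c("m1", "m2")
  mats <- dplyr::bind_rows(material("m1", E1, nu), material("m2", E2, nu))
  list(mesh = mesh, materials = mats)
}

# small fibre model: 2 x 2 fibres, 100 um long, thin bones
mini_fibre <- function(n_elastin = 0, fibre_len = 100) {
  build_fibre_model(rows = 2, cols = 2,
                    fibre_dims = c(fibre_len, 20, 20),
                    elastin_dims = c(20, 12, 12),
                    gap = 20, n_elastin = n_elastin, bone_thickness = 20)
}

# tiny sheet model for protocol tests
mini_sheet <- function(dims = c(100, 20, 40), bone = 20) {
  build_sheet_model(dims, bone_thickness = bone)
}

# nodes of a component in a mesh
nodes_of <- function(mesh, comp) ligafem:::component_nodes(mesh, comp)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps), tol)
}
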