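#' Voxelize a ligament geometry into a conforming hexahedral mesh
#'
#' Overlays a structured axis-aligned grid on the geometry's bounding box
#' and keeps every voxel whose volume is covered by a prism, labelling it
#' with that prism's component. Every prism origin and dimension must be an
#' integer multiple of the grid spacing on each axis, so the mesh is exactly
#' conforming: element volumes sum to prism volumes and material interfaces
#' coincide with element faces.
#'
#' @param g A `ligafem_geometry`.
#' @param h Grid spacing in um; a scalar for cubic voxels or a length-3
#'   vector `c(hx, hy, hz)` for rectangular-brick voxels (needed e.g. for
#'   the 62-um-wide sheet, which no useful cube edge divides).
#'
#' @return A `ligafem_mesh`: node coordinates in metres (`nodes`, N x 3),
#'   element connectivity in VTK trilinear-hexahedron order (`elems`,
#'   E x 8), per-element component labels (`material`), and the element
#'   edge lengths in metres (`h_m`). Nodes and elements are in canonical
#'   x-fastest grid order, so identical inputs yield identical meshes.
#' @export
#' @examples
#' m <- voxelize(build_sheet_model(), h = c(20, 15.5, 16))
voxelize <- function(g, h = 4) {
  stopifnot(inherits(g, "ligafem_geometry"))
  if (length(h) == 1L) h <- rep(h, 3L)
  if (length(h) != 3L || any(!is.finite(h)) || any(h <= 0)) {
    rlang::abort("`h` must be one or three positive spacings (um)",
                 class = "ligafem_mesh_error")
  }
  pr <- g$prisms
  lo <- c(min(pr$ox), min(pr$oy), min(pr$oz))
  hi <- c(max(pr$ox + pr$dx), max(pr$oy + pr$dy), max(pr$oz + pr$dz))

  as_steps <- function(len, hh, what) {
    k <- len / hh
    if (abs(k - round(k)) > 1e-6) {
      rlang::abort(sprintf("%s (%g um) is not an integer multiple of the grid spacing %g um",
                           what, len, hh),
                   class = "ligafem_mesh_error")
    }
    as.integer(round(k))
  }
  n <- vapply(1:3, function(ax) as_steps(hi[ax] - lo[ax], h[ax], "bounding box extent"),
              integer(1))
  nx <- n[1]; ny <- n[2]; nz <- n[3]

  comp_levels <- unique(pr$component)
  arr <- integer(nx * ny * nz)
  for (p in seq_len(nrow(pr))) {
    i0 <- as_steps(pr$ox[p] - lo[1], h[1], "prism X origin offset")
    j0 <- as_steps(pr$oy[p] - lo[2], h[2], "prism Y origin offset")
    k0 <- as_steps(pr$oz[p] - lo[3], h[3], "prism Z origin offset")
    di <- as_steps(pr$dx[p], h[1], "prism X dimension")
    dj <- as_steps(pr$dy[p], h[2], "prism Y dimension")
    dk <- as_steps(pr$dz[p], h[3], "prism Z dimension")
    ii <- (i0 + 1L):(i0 + di)
    jj <- (j0 + 1L):(j0 + dj)
    kk <- (k0 + 1L):(k0 + dk)
    ids <- rep(ii, times = dj * dk) +
      nx * (rep(rep(jj - 1L, each = di), times = dk)) +
      nx * ny * rep(kk - 1L, each = di * dj)
    arr[ids] <- match(pr$component[p], comp_levels)
  }

  cells <- which(arr != 0L)              # ascending = canonical x-fastest order
  if (length(cells) == 0L) {
    rlang::abort("geometry produced an empty mesh", class = "ligafem_mesh_error")
  }
  cz <- (cells - 1L) %/% (nx * ny)
  cy <- ((cells - 1L) %/% nx) %% ny
  cx <- (cells - 1L) %% nx
  material <- comp_levels[arr[cells]]

  # corner ids on the (nx+1)(ny+1)(nz+1) node grid, VTK hexahedron order
  npx <- nx + 1L; npy <- ny + 1L
  nid <- function(i, j, k) 1L + i + npx * j + npx * npy * k
  corners <- cbind(
    nid(cx,      cy,      cz),
    nid(cx + 1L, cy,      cz),
    nid(cx + 1L, cy + 1L, cz),
    nid(cx,      cy + 1L, cz),
    nid(cx,      cy,      cz + 1L),
    nid(cx + 1L, cy,      cz + 1L),
    nid(cx + 1L, cy + 1L, cz + 1L),
    nid(cx,      cy + 1L, cz + 1L)
  )
  used <- sort(unique(as.vector(corners)))
  remap <- integer(npx * npy * (nz + 1L))
  remap[used] <- seq_along(used)
  elems <- matrix(remap[corners], ncol = 8L)

  gi <- (used - 1L) %% npx
  gj <- ((used - 1L) %/% npx) %% npy
  gk <- (used - 1L) %/% (npx * npy)
  nodes_um <- cbind(lo[1] + gi * h[1], lo[2] + gj * h[2], lo[3] + gk * h[3])

  structure(
    list(nodes = nodes_um * 1e-6, elems = elems, material = material,
         h_m = h * 1e-6, h_um = h, n_cells = length(cells),
         grid = list(lo_um = lo, n = n)),
    class = "ligafem_mesh"
  )
}

#' @method print ligafem_mesh
#' @export
print.ligafem_mesh <- function(x, ...) {
  cat("<ligafem_mesh> ", nrow(x$elems), " hexahedra, ", nrow(x$nodes), " nodes, spacing ",
      paste(signif(x$h_um, 4), collapse = " x "), " um\n", sep = "")
  print(table(x$material))
  invisible(x)
}

# Node indices touching any element of the given component(s).
component_nodes <- function(mesh, component) {
  sel <- mesh$material %in% component
  if (!any(sel)) {
    rlang::abort(paste0("component '", paste(component, collapse = ","),
                        "' not present in mesh"),
                 class = "ligafem_query_error")
  }
  sort(unique(as.vector(mesh$elems[sel, , drop = FALSE])))
}

element_volume <- function(mesh) prod(mesh$h_m)

#' Export a mesh (and optional fields) as an ASCII VTU file
#'
#' Writes a VTK unstructured-grid XML file with the mesh's hexahedral
#' cells, an integer cell field `material`, and optionally nodal
#' displacements and element von Mises stress from a solved load case.
#'
#' @param mesh A `ligafem_mesh`.
#' @param path Output file path (conventionally `.vtu`).
#' @param displacement Optional N x 3 matrix of nodal displacements (m).
#' @param von_mises Optional per-element von Mises stress vector (Pa).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, displacement = NULL, von_mises = NULL) {
  n_pts <- nrow(mesh$nodes)
  n_cel <- nrow(mesh$elems)
  fmt <- function(x) format(x, digits = 9, scientific = TRUE, trim = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n_pts, n_cel))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1L, function(r) paste(fmt(r), collapse = " ")), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1L, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(format(seq_len(n_cel) * 8L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("12", n_cel), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData Scalars="material">')
  w('        <DataArray type="Int32" Name="material" format="ascii">')
  writeLines(format(as.integer(factor(mesh$material, levels = unique(mesh$material))))
             , con)
  w('        </DataArray>')
  if (!is.null(von_mises)) {
    w('        <DataArray type="Float64" Name="von_mises" format="ascii">')
    writeLines(fmt(von_mises), con)
    w('        </DataArray>')
  }
  w('      </CellData>')
  if (!is.null(displacement)) {
    w('      <PointData Vectors="displacement">')
    w('        <DataArray type="Float64" NumberOfComponents="3" Name="displacement" format="ascii">')
    writeLines(apply(displacement, 1L, function(r) paste(fmt(r), collapse = " ")), con)
    w('        </DataArray>')
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
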