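#' @title Parametric ligament geometries
#' @description
#' The fibre model is a 3 x 5 lattice of square-prism collagen fibres
#' (20 x 20 x 300 um) capped by two bone blocks, with elastin blocks
#' (12 x 12 cross-section, 20 um span) bridging the gaps between adjacent
#' fibres. The sheet model is a single homogeneous prism (62 x 128 x 300 um)
#' with the same bone caps. All prisms are sharp-edged so a conforming voxel
#' mesh exists. Coordinates are micrometres; X is the long (tensile) axis,
#' Y the shear direction (fibre columns), Z orthogonal (fibre rows).
#' @name geometry
NULL

new_prism <- function(component, origin, dims) {
  tibble::tibble(
    component = component,
    ox = origin[1], oy = origin[2], oz = origin[3],
    dx = dims[1], dy = dims[2], dz = dims[3]
  )
}

new_model_geometry <- function(prisms, model_kind, n_elastin, lattice, materials) {
  structure(
    list(prisms = prisms, model_kind = model_kind, n_elastin = n_elastin,
         lattice = lattice, materials = materials),
    class = "ligafem_geometry"
  )
}

#' @method print ligafem_geometry
#' @export
print.ligafem_geometry <- function(x, ...) {
  cat("<ligafem_geometry> ", x$model_kind, " model\n", sep = "")
  counts <- table(x$prisms$component)
  for (nm in names(counts)) cat("  ", nm, ": ", counts[[nm]], " prism(s)\n", sep = "")
  if (x$model_kind == "fibre") {
    cat(sprintf("  elastin content: %.1f%%\n", 100 * elastin_fraction(x)))
  }
  invisible(x)
}

# Pairwise open-interval overlap test on all three axes.
check_no_overlap <- function(prisms) {
  n <- nrow(prisms)
  if (n < 2L) return(invisible(TRUE))
  lo <- as.matrix(prisms[, c("ox", "oy", "oz")])
  hi <- lo + as.matrix(prisms[, c("dx", "dy", "dz")])
  eps <- 1e-9
  for (i in seq_len(n - 1L)) {
    ov <- rep(TRUE, n - i)
    js <- (i + 1L):n
    for (ax in 1:3) {
      ov <- ov & (lo[i, ax] < hi[js, ax] - eps) & (hi[i, ax] > lo[js, ax] + eps)
    }
    if (any(ov)) {
      rlang::abort(
        sprintf("prisms %d and %d overlap in volume", i, js[which(ov)[1]]),
        class = "ligafem_geometry_error"
      )
    }
  }
  invisible(TRUE)
}

# Enumerate the adjacent-fibre gap lines of a rows x cols lattice in the
# deterministic round-robin order: Y-neighbour pairs row-major, then
# Z-neighbour pairs. Each entry gives the (row, col) of the lower fibre and
# the bridging axis ("y" or "z").
gap_lines <- function(rows, cols) {
  out <- list()
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols - 1L)) {
      out[[length(out) + 1L]] <- list(row = r, col = cc, axis = "y")
    }
  }
  for (r in seq_len(rows - 1L)) {
    for (cc in seq_len(cols)) {
      out[[length(out) + 1L]] <- list(row = r, col = cc, axis = "z")
    }
  }
  out
}

#' Build the collagen-elastin fibre model
#'
#' Places `rows x cols` collagen fibres (long axis along X) at equal
#' intervals, caps both X ends with full-footprint bone blocks, and bridges
#' adjacent fibres with `n_elastin` elastin blocks. Blocks are placed at
#' equally spaced axial stations, round-robin over the adjacent-pair gap
#' lines (Y-neighbour pairs row-major, then Z-neighbour pairs), advancing
#' one axial station after each full cycle, with the block cross-section
#' centred on the facing fibre surfaces.
#'
#' @param rows,cols Number of fibre rows (along Z) and columns (along Y).
#' @param fibre_dims Collagen fibre dimensions `c(length_x, width_y,
#'   height_z)` in um.
#' @param elastin_dims Elastin block dimensions `c(span, axial_x,
#'   transverse)` in um; `span` bridges the inter-fibre gap.
#' @param gap Inter-fibre gap in both Y and Z, um. Must equal the elastin
#'   span so blocks exactly bridge the gap.
#' @param n_elastin Number of elastin blocks; `0` gives the collagen-only
#'   model.
#' @param bone_thickness Thickness of each bone cap along X, um.
#' @param n_stations Number of axial placement stations. The default uses
#'   `ceiling(n_elastin / n_gap_lines)` stations spread at equal intervals
#'   over the full fibre length, so every content level distributes its
#'   blocks evenly along the ligament; the placement capacity is capped at
#'   one station per `gap`-sized slot.
#' @param station_snap_um Station origins are snapped to this grid (um) so
#'   the geometry stays voxelizable at the default spacing.
#' @param materials Material table, see [ligament_materials()].
#'
#' @return A `ligafem_geometry` object.
#' @export
#' @examples
#' g <- build_fibre_model(n_elastin = 105)
#' elastin_fraction(g) # ~0.144
build_fibre_model <- function(rows = 3, cols = 5,
                              fibre_dims = c(300, 20, 20),
                              elastin_dims = c(20, 12, 12),
                              gap = 20,
                              n_elastin = 0,
                              bone_thickness = 40,
                              n_stations = NULL,
                              station_snap_um = 4,
                              materials = ligament_materials()) {
  stopifnot(rows >= 1, cols >= 1, all(fibre_dims > 0), all(elastin_dims > 0),
            gap > 0, n_elastin >= 0, bone_thickness > 0)
  if (abs(elastin_dims[1] - gap) > 1e-9) {
    rlang::abort("elastin span (elastin_dims[1]) must equal the inter-fibre gap",
                 class = "ligafem_geometry_error")
  }
  if (elastin_dims[3] > min(fibre_dims[2:3])) {
    rlang::abort("elastin cross-section wider than the fibre face",
                 class = "ligafem_geometry_error")
  }
  L <- fibre_dims[1]
  pitch_y <- fibre_dims[2] + gap
  pitch_z <- fibre_dims[3] + gap

  lines <- gap_lines(rows, cols)
  max_stations <- floor(L / gap)
  if (is.null(n_stations)) {
    n_stations <- max(1L, min(max_stations, ceiling(n_elastin / length(lines))))
    capacity <- length(lines) * max_stations
  } else {
    capacity <- length(lines) * n_stations
  }
  if (n_elastin > capacity) {
    rlang::abort(
      sprintf("n_elastin = %d exceeds placement capacity %d (%d gap lines x %d stations)",
              n_elastin, capacity, length(lines), n_stations),
      class = "ligafem_capacity_error"
    )
  }

  prisms <- list()
  # collagen fibres, row-major (rows along Z, columns along Y)
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      prisms[[length(prisms) + 1L]] <- new_prism(
        "collagen",
        c(0, (cc - 1L) * pitch_y, (r - 1L) * pitch_z),
        fibre_dims
      )
    }
  }
  # bone caps spanning the full cross-sectional footprint
  foot_y <- (cols - 1L) * pitch_y + fibre_dims[2]
  foot_z <- (rows - 1L) * pitch_z + fibre_dims[3]
  prisms[[length(prisms) + 1L]] <- new_prism(
    "bone_fixed", c(-bone_thickness, 0, 0), c(bone_thickness, foot_y, foot_z))
  prisms[[length(prisms) + 1L]] <- new_prism(
    "bone_free", c(L, 0, 0), c(bone_thickness, foot_y, foot_z))

  # elastin blocks: round-robin over gap lines, advancing the axial station
  # after each full cycle
  slot <- L / n_stations
  margin_ax <- (slot - elastin_dims[2]) / 2
  if (margin_ax < 0) {
    rlang::abort("axial stations too dense for the elastin axial extent",
                 class = "ligafem_geometry_error")
  }
  # snap station origins to the placement grid so voxelization stays exact
  station_x <- round((seq_len(n_stations) - 1L) * slot + margin_ax) # um
  if (station_snap_um > 0) {
    station_x <- pmax(0, pmin(L - elastin_dims[2],
                              round(station_x / station_snap_um) * station_snap_um))
  }
  if (n_elastin > 0) {
    for (k in seq_len(n_elastin)) {
      line <- lines[[(k - 1L) %% length(lines) + 1L]]
      station <- (k - 1L) %/% length(lines)
      x0 <- station_x[station + 1L]
      fy <- (line$col - 1L) * pitch_y
      fz <- (line$row - 1L) * pitch_z
      if (line$axis == "y") {
        m <- (fibre_dims[3] - elastin_dims[3]) / 2
        origin <- c(x0, fy + fibre_dims[2], fz + m)
        dims <- c(elastin_dims[2], gap, elastin_dims[3])
      } else {
        m <- (fibre_dims[2] - elastin_dims[3]) / 2
        origin <- c(x0, fy + m, fz + fibre_dims[3])
        dims <- c(elastin_dims[2], elastin_dims[3], gap)
      }
      prisms[[length(prisms) + 1L]] <- new_prism("elastin", origin, dims)
    }
  }

  prisms <- dplyr::bind_rows(prisms)
  check_no_overlap(prisms)
  new_model_geometry(
    prisms, "fibre", n_elastin,
    lattice = list(rows = rows, cols = cols, gap = gap, n_stations = n_stations,
                   fibre_dims = fibre_dims, elastin_dims = elastin_dims,
                   bone_thickness = bone_thickness),
    materials = materials
  )
}

#' Build the homogeneous sheet model
#'
#' A single ligament prism of homogenised "sheet" material with the same
#' bone caps as the fibre model.
#'
#' @param dims Sheet dimensions `c(length_x, width_y, height_z)` in um.
#' @param bone_thickness Bone cap thickness along X, um.
#' @param materials Material table, see [ligament_materials()].
#' @return A `ligafem_geometry` object.
#' @export
#' @examples
#' build_sheet_model()
build_sheet_model <- function(dims = c(300, 62, 128), bone_thickness = 40,
                              materials = ligament_materials()) {
  if (!is.numeric(dims) || length(dims) != 3L || any(!is.finite(dims)) || any(dims <= 0)) {
    rlang::abort("`dims` must be three positive lengths (um)",
                 class = "ligafem_geometry_error")
  }
  stopifnot(bone_thickness > 0)
  prisms <- dplyr::bind_rows(
    new_prism("sheet", c(0, 0, 0), dims),
    new_prism("bone_fixed", c(-bone_thickness, 0, 0),
              c(bone_thickness, dims[2], dims[3])),
    new_prism("bone_free", c(dims[1], 0, 0),
              c(bone_thickness, dims[2], dims[3]))
  )
  check_no_overlap(prisms)
  new_model_geometry(
    prisms, "sheet", n_elastin = NA_integer_,
    lattice = list(dims = dims, bone_thickness = bone_thickness),
    materials = materials
  )
}

# Ligament span along X (bone caps excluded), um.
ligament_length_um <- function(g) {
  lig <- g$prisms[!(g$prisms$component %in% c("bone_fixed", "bone_free")), ]
  max(lig$ox + lig$dx) - min(lig$ox)
}

#' Serialize a model geometry to a YAML config
#'
#' Writes the parameters needed to rebuild the geometry (model kind,
#' lattice, dimensions in um, elastin block count, bone thickness and the
#' material table) to a structured YAML file; `read_geometry_config()`
#' rebuilds the geometry from it.
#'
#' @param g A `ligafem_geometry`.
#' @param path File path.
#' @return `write_geometry_config()` returns `path` invisibly;
#'   `read_geometry_config()` returns a `ligafem_geometry`.
#' @export
write_geometry_config <- function(g, path) {
  stopifnot(inherits(g, "ligafem_geometry"))
  mats <- g$materials
  x <- list(
    model_kind = g$model_kind,
    materials = stats::setNames(
      purrr::map(seq_len(nrow(mats)),
                 function(i) list(E_Pa = mats$young_modulus[i],
                                  nu = mats$poisson_ratio[i])),
      mats$name))
  if (g$model_kind == "fibre") {
    x <- c(x, list(
      rows = g$lattice$rows, cols = g$lattice$cols,
      fibre_dims_um = g$lattice$fibre_dims,
      elastin_dims_um = g$lattice$elastin_dims,
      gap_um = g$lattice$gap, n_elastin = g$n_elastin,
      bone_thickness_um = g$lattice$bone_thickness))
  } else {
    x <- c(x, list(dims_um = g$lattice$dims,
                   bone_thickness_um = g$lattice$bone_thickness))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_geometry_config
#' @export
read_geometry_config <- function(path) {
  x <- yaml::read_yaml(path)
  mats <- purrr::map_dfr(names(x$materials), function(nm) {
    material(nm, x$materials[[nm]]$E_Pa, x$materials[[nm]]$nu)
  })
  if (identical(x$model_kind, "fibre")) {
    n <- if (!is.null(x$n_elastin)) x$n_elastin else n_for_content(x$target_content)
    build_fibre_model(rows = x$rows, cols = x$cols,
                      fibre_dims = as.numeric(x$fibre_dims_um),
                      elastin_dims = as.numeric(x$elastin_dims_um),
                      gap = x$gap_um, n_elastin = n,
                      bone_thickness = x$bone_thickness_um,
                      materials = mats)
  } else {
    build_sheet_model(as.numeric(x$dims_um), x$bone_thickness_um, materials = mats)
  }
}

#' Elastin volume fraction of a fibre model
#'
#' Content is defined as `Ve / (Ve + Vc)` over sharp-corner prism volumes;
#' the bone caps are excluded.
#'
#' @param g A fibre-model `ligafem_geometry`.
#' @return The elastin volume fraction (dimensionless).
#' @export
#' @examples
#' elastin_fraction(build_fibre_model(n_elastin = 315)) # ~0.335
elastin_fraction <- function(g) {
  stopifnot(inherits(g, "ligafem_geometry"))
  if (g$model_kind != "fibre") {
    rlang::abort("elastin content is undefined for the sheet model",
                 class = "ligafem_content_error")
  }
  vol <- g$prisms$dx * g$prisms$dy * g$prisms$dz
  ve <- sum(vol[g$prisms$component == "elastin"])
  vc <- sum(vol[g$prisms$component == "collagen"])
  ve / (ve + vc)
}

#' Number of elastin blocks closest to a target content
#'
#' Inverse of [elastin_fraction()] for the default block volumes: returns
#' the block count `n` minimising `|Ve(n)/(Ve(n)+Vc) - target|`, ties broken
#' toward the smaller `n`.
#'
#' @param target Target elastin volume fraction in `[0, 1)`.
#' @inheritParams build_fibre_model
#' @return An integer block count.
#' @export
#' @examples
#' n_for_content(0.144) # 105
n_for_content <- function(target, rows = 3, cols = 5,
                          fibre_dims = c(300, 20, 20),
                          elastin_dims = c(20, 12, 12),
                          n_stations = NULL) {
  stopifnot(is.numeric(target), length(target) == 1L, target >= 0, target < 1)
  vc <- rows * cols * prod(fibre_dims)
  ve1 <- prod(elastin_dims)
  if (is.null(n_stations)) n_stations <- floor(fibre_dims[1] / elastin_dims[1])
  capacity <- length(gap_lines(rows, cols)) * n_stations
  frac <- function(n) n * ve1 / (vc + n * ve1)
  if (target > frac(capacity) + 1e-12) {
    rlang::abort(sprintf("target content %.3f is at or above the achievable maximum %.3f",
                         target, frac(capacity)),
                 class = "ligafem_capacity_error")
  }
  n_star <- vc * target / (ve1 * (1 - target))
  cand <- unique(pmax(0L, pmin(capacity, c(floor(n_star), ceiling(n_star)))))
  err <- abs(frac(cand) - target)
  # ties toward the smaller n
  as.integer(cand[order(err, cand)][1])
}
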