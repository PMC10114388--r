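#' @title Elastin-content sweep pipeline
#' @description
#' Orchestrates the full study: for each elastin block count (default 0 to
#' 315 in steps of 35, i.e. contents 0 to 33.5 percent), build the fibre
#' model, mesh it, run the tensile, shear and rotation protocols, and
#' summarise; then append the homogeneous sheet model. Emits the
#' bone-rotation required-stress table and the content-sweep metrics as
#' CSV, optionally with per-case VTU fields.
#' @name sweep_pipeline
NULL

#' Default study configuration
#'
#' Encodes the whole study: geometry constants, material table, load
#' magnitudes, voxel spacings and the content sweep. Serialisable to YAML
#' with [write_study_config()].
#'
#' @param n_blocks Elastin block counts to sweep.
#' @param cases Protocol kinds to run per content.
#' @param voxel_um Fibre-model voxel edge (um).
#' @param sheet_voxel_um Sheet-model spacings `c(hx, hy, hz)` (um); the
#'   default matches `voxel_um` except along Y where the 62-um width is not
#'   divisible by 4.
#' @param include_sheet Append the sheet-model row?
#' @param tensile_Pa,shear_Pa,rotation_deg Load magnitudes.
#' @param rows,cols,fibre_dims_um,elastin_dims_um,gap_um,bone_thickness_um
#'   Fibre-lattice geometry, see [build_fibre_model()].
#' @param sheet_dims_um Sheet dimensions, see [build_sheet_model()].
#' @param materials Material table.
#' @return A `ligafem_config` list.
#' @export
study_config <- function(n_blocks = seq(0L, 315L, by = 35L),
                         cases = c("tensile", "shear", "rotation"),
                         voxel_um = 4,
                         sheet_voxel_um = c(4, 3.875, 4),
                         include_sheet = TRUE,
                         tensile_Pa = 0.15, shear_Pa = 0.90e-3, rotation_deg = 30,
                         rows = 3L, cols = 5L,
                         fibre_dims_um = c(300, 20, 20),
                         elastin_dims_um = c(20, 12, 12),
                         gap_um = 20, bone_thickness_um = 40,
                         sheet_dims_um = c(300, 62, 128),
                         materials = ligament_materials()) {
  structure(
    list(n_blocks = as.integer(n_blocks), cases = cases, voxel_um = voxel_um,
         sheet_voxel_um = sheet_voxel_um, include_sheet = include_sheet,
         tensile_Pa = tensile_Pa, shear_Pa = shear_Pa, rotation_deg = rotation_deg,
         rows = as.integer(rows), cols = as.integer(cols),
         fibre_dims_um = fibre_dims_um, elastin_dims_um = elastin_dims_um,
         gap_um = gap_um, bone_thickness_um = bone_thickness_um,
         sheet_dims_um = sheet_dims_um, materials = materials),
    class = "ligafem_config"
  )
}

#' Read / write a study configuration as YAML
#'
#' @param config A `ligafem_config`.
#' @param path File path.
#' @return `read_study_config()` returns a `ligafem_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
write_study_config <- function(config, path) {
  x <- unclass(config)
  mats <- config$materials
  x$materials <- stats::setNames(
    purrr::map(seq_len(nrow(mats)),
               function(i) list(E_Pa = mats$young_modulus[i], nu = mats$poisson_ratio[i])),
    mats$name)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  mats <- purrr::map_dfr(names(x$materials), function(nm) {
    material(nm, x$materials[[nm]]$E_Pa, x$materials[[nm]]$nu)
  })
  x$materials <- NULL
  args <- c(x, list(materials = mats))
  args$fibre_dims_um <- as.numeric(args$fibre_dims_um)
  args$elastin_dims_um <- as.numeric(args$elastin_dims_um)
  args$sheet_dims_um <- as.numeric(args$sheet_dims_um)
  args$sheet_voxel_um <- as.numeric(args$sheet_voxel_um)
  do.call(study_config, args)
}

config_fibre_geometry <- function(config, n, materials = NULL) {
  build_fibre_model(
    rows = config$rows, cols = config$cols,
    fibre_dims = config$fibre_dims_um, elastin_dims = config$elastin_dims_um,
    gap = config$gap_um, n_elastin = n,
    bone_thickness = config$bone_thickness_um,
    materials = if (is.null(materials)) config$materials else materials
  )
}

summarise_model_row <- function(results, geometry, label, content_pct) {
  lig_comp <- if (geometry$model_kind == "fibre") "collagen" else "sheet"
  row <- tibble::tibble(model = label, content_pct = content_pct)
  for (kind in names(results)) {
    r <- results[[kind]]
    s <- summarize_component(r, lig_comp)
    if (kind == "rotation") {
      row$sigma_y_MPa <- r$sigma_y_Pa / 1e6
      row$sigma_z_MPa <- r$sigma_z_Pa / 1e6
      row$rotation_mean_vm_Pa <- s$mean_vm
      row$rotation_max_vm_Pa <- s$max_vm
    } else {
      row[[paste0(kind, "_mean_vm_Pa")]] <- s$mean_vm
      row[[paste0(kind, "_max_vm_Pa")]] <- s$max_vm
      row[[paste0(kind, "_mean_disp_m")]] <- s$mean_disp
      row[[paste0(kind, "_strain")]] <- r$strain
      row[[paste0(kind, "_slope_Pa")]] <- r$case$magnitude / r$strain
    }
  }
  row
}

#' Run the elastin-content sweep
#'
#' For each configured block count, builds and meshes the fibre model and
#' runs the configured protocols; optionally appends the sheet model. Each
#' model's stiffness is assembled once and the factorisation shared across
#' the traction protocols. Results can be cached on disk keyed by a hash
#' of (geometry parameters, spacing, case), so a rerun with an unchanged
#' configuration is read back instead of re-solved.
#'
#' @param config A `ligafem_config` from [study_config()].
#' @param out_dir Optional output directory: writes `table2.csv`
#'   (content vs required rotation stresses), `fig5.csv` (tensile/shear
#'   collagen stress, displacement and slopes vs content), `fig3_ratios.csv`
#'   (sheet-vs-fibre ratios at the content nearest 14.4 percent), and, when
#'   `write_vtu = TRUE`, per-case VTU fields.
#' @param cache_dir Optional directory for solve caching.
#' @param write_vtu Write displacement/von Mises VTU files per solve?
#' @param verbose Log stage timings to the console?
#' @return A `ligafem_sweep` tibble with one row per content plus one
#'   `"sheet"` row.
#' @export
run_sweep <- function(config = study_config(), out_dir = NULL, cache_dir = NULL,
                      write_vtu = FALSE, verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cache_dir)) dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)

  run_model <- function(geometry, mesh, label) {
    key <- NULL
    if (!is.null(cache_dir)) {
      key <- rlang::hash(list(geometry$prisms, geometry$materials, mesh$h_um,
                              config$cases, config$tensile_Pa, config$shear_Pa,
                              config$rotation_deg))
      cache_file <- file.path(cache_dir, paste0(key, ".rds"))
      if (file.exists(cache_file)) {
        say("cache hit for %s", label)
        return(readRDS(cache_file))
      }
    }
    t0 <- Sys.time()
    cases <- lapply(config$cases, function(k) {
      load_case(k, switch(k, tensile = config$tensile_Pa,
                          shear = config$shear_Pa, rotation = config$rotation_deg))
    })
    res <- run_study_cases(geometry, mesh, cases)
    say("%s: %d elements, %s", label, nrow(mesh$elems),
        format(Sys.time() - t0, digits = 3))
    if (!is.null(key)) saveRDS(res, file.path(cache_dir, paste0(key, ".rds")))
    res
  }

  rows <- list()
  for (n in config$n_blocks) {
    g <- config_fibre_geometry(config, n)
    m <- voxelize(g, config$voxel_um)
    content_pct <- 100 * elastin_fraction(g)
    label <- sprintf("fibre_%04.1f", content_pct)
    res <- tryCatch(
      run_model(g, m, label),
      error = function(e) {
        warning(sprintf("sweep row n=%d failed: %s", n, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    if (write_vtu && !is.null(out_dir)) {
      for (kind in names(res)) {
        write_vtu(m, file.path(out_dir, sprintf("%s_%s.vtu", label, kind)),
                  displacement = res[[kind]]$u,
                  von_mises = res[[kind]]$stress$von_mises)
      }
    }
    row <- summarise_model_row(res, g, "fibre", content_pct)
    row$n_elastin <- n
    rows[[length(rows) + 1L]] <- row
    rm(res); gc(verbose = FALSE)
  }

  if (config$include_sheet) {
    gs <- build_sheet_model(config$sheet_dims_um, config$bone_thickness_um,
                            config$materials)
    ms <- voxelize(gs, config$sheet_voxel_um)
    res <- run_model(gs, ms, "sheet")
    if (write_vtu && !is.null(out_dir)) {
      for (kind in names(res)) {
        write_vtu(ms, file.path(out_dir, sprintf("sheet_%s.vtu", kind)),
                  displacement = res[[kind]]$u,
                  von_mises = res[[kind]]$stress$von_mises)
      }
    }
    row <- summarise_model_row(res, gs, "sheet", NA_real_)
    row$n_elastin <- NA_integer_
    rows[[length(rows) + 1L]] <- row
    rm(res); gc(verbose = FALSE)
  }

  sweep <- dplyr::bind_rows(rows)
  incomplete <- length(setdiff(config$n_blocks,
                               sweep$n_elastin[sweep$model == "fibre"])) > 0
  attr(sweep, "partial") <- incomplete
  if (incomplete) warning("sweep table is partial: some rows failed", call. = FALSE)
  class(sweep) <- c("ligafem_sweep", class(sweep))

  if (!is.null(out_dir)) {
    if ("sigma_y_MPa" %in% names(sweep)) {
      t2 <- dplyr::transmute(
        sweep,
        elastin_content_pct = ifelse(model == "sheet", NA_real_, round(content_pct, 1)),
        model = model, sigma_y_MPa = sigma_y_MPa, sigma_z_MPa = sigma_z_MPa)
      readr::write_csv(t2, file.path(out_dir, "table2.csv"))
    }
    fig5_cols <- intersect(
      c("model", "content_pct", "n_elastin",
        "tensile_mean_vm_Pa", "tensile_max_vm_Pa", "tensile_mean_disp_m",
        "tensile_slope_Pa", "shear_mean_vm_Pa", "shear_max_vm_Pa",
        "shear_mean_disp_m", "shear_slope_Pa"), names(sweep))
    readr::write_csv(sweep[, fig5_cols], file.path(out_dir, "fig5.csv"))
    cmp <- tryCatch(compare_models(sweep, content = 0.144),
                    error = function(e) NULL)
    if (!is.null(cmp)) readr::write_csv(cmp, file.path(out_dir, "fig3_ratios.csv"))
  }
  sweep
}

#' Sheet-versus-fibre comparison ratios
#'
#' Ratios between the sheet row and the fibre row closest to a given
#' content: sheet/fibre required rotation stresses, and fibre/sheet maximum
#' ligament stresses per protocol.
#'
#' @param sweep A `ligafem_sweep` table containing a sheet row.
#' @param content Elastin fraction selecting the fibre row (nearest match).
#' @return A tibble with columns `quantity`, `ratio`, `direction`.
#' @export
compare_models <- function(sweep, content = 0.144) {
  fib <- sweep[sweep$model == "fibre", , drop = FALSE]
  sh <- sweep[sweep$model == "sheet", , drop = FALSE]
  if (nrow(fib) == 0L || nrow(sh) == 0L) {
    rlang::abort("sweep must contain both fibre and sheet rows",
                 class = "ligafem_comparison_error")
  }
  fib <- fib[which.min(abs(fib$content_pct - 100 * content)), , drop = FALSE]
  out <- list()
  add <- function(q, ratio) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      quantity = q, ratio = ratio,
      direction = dplyr::case_when(ratio > 1 ~ "greater", ratio < 1 ~ "smaller",
                                   TRUE ~ "equal"))
  }
  if ("sigma_y_MPa" %in% names(sweep)) {
    add("rotation_sigma_y_sheet_over_fibre", sh$sigma_y_MPa / fib$sigma_y_MPa)
    add("rotation_sigma_z_sheet_over_fibre", sh$sigma_z_MPa / fib$sigma_z_MPa)
    if ("rotation_max_vm_Pa" %in% names(sweep)) {
      add("rotation_max_vm_fibre_over_sheet",
          fib$rotation_max_vm_Pa / sh$rotation_max_vm_Pa)
    }
  }
  for (kind in c("tensile", "shear")) {
    col <- paste0(kind, "_max_vm_Pa")
    if (col %in% names(sweep)) {
      add(paste0(kind, "_max_vm_fibre_over_sheet"), fib[[col]] / sh[[col]])
    }
  }
  dplyr::bind_rows(out)
}
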