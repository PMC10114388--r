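# A desk-scale configuration: 2 x 2 fibres, 100 um long, coarse-but-exact
# voxels. Small enough that the whole sweep runs in seconds per row.
mini_config <- function(n_blocks = c(0L, 8L), cases = c("tensile", "shear"),
                        include_sheet = FALSE, ...) {
  study_config(n_blocks = n_blocks, cases = cases, voxel_um = 4,
               rows = 2L, cols = 2L, fibre_dims_um = c(100, 20, 20),
               bone_thickness_um = 20,
               sheet_dims_um = c(100, 20, 40), sheet_voxel_um = c(4, 4, 4),
               include_sheet = include_sheet, ...)
}

test_that("a single-content sweep yields one well-formed row", {
  sw <- run_sweep(mini_config(n_blocks = 0L), verbose = FALSE)
  expect_s3_class(sw, "ligafem_sweep")
  expect_equal(nrow(sw), 1)
  expect_equal(sw$content_pct, 0)
  expect_true(all(c("tensile_mean_vm_Pa", "shear_mean_vm_Pa",
                    "tensile_slope_Pa", "shear_slope_Pa") %in% names(sw)))
  expect_false(attr(sw, "partial"))
})

test_that("reruns with the same config are byte-identical", {
  cfg <- mini_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sw1 <- run_sweep(cfg, out_dir = d1, verbose = FALSE)
  sw2 <- run_sweep(cfg, out_dir = d2, verbose = FALSE)
  expect_identical(serialize(as.data.frame(sw1), NULL),
                   serialize(as.data.frame(sw2), NULL))
  f1 <- file.path(d1, "fig5.csv"); f2 <- file.path(d2, "fig5.csv")
  expect_true(file.exists(f1))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the disk cache returns identical results without re-solving", {
  cfg <- mini_config(n_blocks = 0L)
  cache <- withr::local_tempdir()
  sw1 <- run_sweep(cfg, cache_dir = cache, verbose = FALSE)
  t0 <- Sys.time()
  sw2 <- run_sweep(cfg, cache_dir = cache, verbose = FALSE)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_gt(length(list.files(cache)), 0)
})

test_that("shear metrics are content-sensitive, tensile nearly insensitive", {
  sw <- run_sweep(mini_config(n_blocks = c(0L, 16L)), verbose = FALSE)
  # strong shear effect of adding bridges
  expect_lt(sw$shear_mean_vm_Pa[2], 0.8 * sw$shear_mean_vm_Pa[1])
  expect_gt(sw$shear_slope_Pa[2], 1.5 * sw$shear_slope_Pa[1])
  # weak tensile effect
  expect_lt(abs(percent_change(sw$tensile_mean_vm_Pa[1], sw$tensile_mean_vm_Pa[2])), 10)
})

test_that("removing elastin equals never placing it", {
  # construction-path equivalence: n=0 geometry vs n>0 geometry with the
  # elastin prisms deleted must voxelize to the identical mesh
  g0 <- mini_fibre(n_elastin = 0)
  g8 <- mini_fibre(n_elastin = 8)
  g8$prisms <- g8$prisms[g8$prisms$component != "elastin", ]
  g8$n_elastin <- 0L
  expect_identical(serialize(voxelize(g0, 4), NULL),
                   serialize(voxelize(g8, 4), NULL))
})

test_that("setting the elastin material to collagen equals relabelling", {
  # material-degeneracy identity: solving with elastin given collagen's
  # constants is identical to the same mesh with those elements labelled
  # collagen (the solver sees materials, not labels)
  g <- mini_fibre(n_elastin = 8)
  m <- voxelize(g, 4)
  mats_deg <- g$materials
  mats_deg[mats_deg$name == "elastin", c("young_modulus", "poisson_ratio")] <-
    mats_deg[mats_deg$name == "collagen", c("young_modulus", "poisson_ratio")]
  r_deg <- shear_case(g, m, materials = mats_deg)
  m_rel <- m
  m_rel$material[m_rel$material == "elastin"] <- "collagen"
  r_rel <- shear_case(g, m_rel)
  expect_equal(r_deg$u, r_rel$u, tolerance = 1e-12)
  expect_equal(r_deg$strain, r_rel$strain, tolerance = 1e-12)
})

test_that("compare_models reports unit ratios for identical models", {
  cfg <- mini_config(n_blocks = 8L, cases = c("tensile", "shear", "rotation"),
                     include_sheet = TRUE)
  sw <- run_sweep(cfg, verbose = FALSE)
  expect_equal(nrow(sw), 2)
  cmp <- compare_models(sw, content = sw$content_pct[1] / 100)
  expect_true(all(c("quantity", "ratio", "direction") %in% names(cmp)))
  expect_true(all(is.finite(cmp$ratio)))
  # degenerate comparison of a sweep against itself
  sw_same <- sw
  sw_same$model <- c("fibre", "sheet")
  fake <- sw[c(1, 1), ]
  fake$model <- c("fibre", "sheet")
  cmp2 <- compare_models(fake, content = fake$content_pct[1] / 100)
  expect_true(all(abs(cmp2$ratio - 1) < 1e-12))
  expect_error(compare_models(sw[sw$model == "fibre", ]),
               class = "ligafem_comparison_error")
})

test_that("study config round-trips through YAML", {
  cfg <- mini_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  cfg2 <- read_study_config(path)
  expect_equal(cfg2$n_blocks, cfg$n_blocks)
  expect_equal(cfg2$fibre_dims_um, cfg$fibre_dims_um)
  expect_equal(cfg2$materials, cfg$materials)
  expect_equal(cfg2$sheet_voxel_um, cfg$sheet_voxel_um)
})
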