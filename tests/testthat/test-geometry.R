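test_that("default fibre model has the study lattice and footprint", {
  g <- build_fibre_model(n_elastin = 0)
  counts <- table(g$prisms$component)
  expect_equal(unname(counts["collagen"]), 15)
  expect_equal(sum(g$prisms$component %in% c("bone_fixed", "bone_free")), 2)
  expect_false("elastin" %in% names(counts))
  # cross-sectional footprint: 5 columns along Y, 3 rows along Z
  expect_equal(max(g$prisms$oy + g$prisms$dy) - min(g$prisms$oy), 180)
  expect_equal(max(g$prisms$oz + g$prisms$dz) - min(g$prisms$oz), 100)
  # bones cap both X ends and span the footprint
  bones <- g$prisms[g$prisms$component %in% c("bone_fixed", "bone_free"), ]
  expect_setequal(bones$ox, c(-40, 300))
  expect_true(all(bones$dy == 180 & bones$dz == 100))
})

test_that("elastin placement bridges adjacent fibres and respects capacity", {
  g <- build_fibre_model(n_elastin = 105)
  el <- g$prisms[g$prisms$component == "elastin", ]
  co <- g$prisms[g$prisms$component == "collagen", ]
  expect_equal(nrow(el), 105)
  # every block's span axis ends coincide with faces of two collagen fibres
  for (i in seq_len(nrow(el))) {
    if (el$dy[i] == 20) { # Y-bridge
      lower <- any(abs(co$oy + co$dy - el$oy[i]) < 1e-9 &
                     co$oz <= el$oz[i] & co$oz + co$dz >= el$oz[i] + el$dz[i])
      upper <- any(abs(co$oy - (el$oy[i] + el$dy[i])) < 1e-9)
      expect_true(lower && upper)
    } else { # Z-bridge
      lower <- any(abs(co$oz + co$dz - el$oz[i]) < 1e-9)
      upper <- any(abs(co$oz - (el$oz[i] + el$dz[i])) < 1e-9)
      expect_true(lower && upper)
    }
  }
  # blocks spread over the whole fibre length, not clumped at one end
  expect_gt(max(el$ox), 250)
  expect_lt(min(el$ox), 50)
  expect_error(build_fibre_model(n_elastin = 1e6), class = "ligafem_capacity_error")
})

test_that("no two prisms overlap in any built model", {
  for (n in c(0, 35, 105, 315)) {
    g <- build_fibre_model(n_elastin = n)
    pr <- g$prisms
    lo <- as.matrix(pr[, c("ox", "oy", "oz")])
    hi <- lo + as.matrix(pr[, c("dx", "dy", "dz")])
    np <- nrow(pr)
    for (i in seq_len(np - 1)) {
      js <- (i + 1):np
      ov <- (lo[i, 1] < hi[js, 1] - 1e-9) & (hi[i, 1] > lo[js, 1] + 1e-9) &
        (lo[i, 2] < hi[js, 2] - 1e-9) & (hi[i, 2] > lo[js, 2] + 1e-9) &
        (lo[i, 3] < hi[js, 3] - 1e-9) & (hi[i, 3] > lo[js, 3] + 1e-9)
      expect_false(any(ov))
    }
  }
})

test_that("elastin content arithmetic matches sharp-corner volumes", {
  expect_equal(elastin_fraction(build_fibre_model(n_elastin = 0)), 0)
  expect_equal(round(elastin_fraction(build_fibre_model(n_elastin = 315)), 3), 0.335)
  expect_equal(round(elastin_fraction(build_fibre_model(n_elastin = 35)), 3), 0.053)
  expect_equal(round(elastin_fraction(build_fibre_model(n_elastin = 105)), 3), 0.144)
  expect_error(elastin_fraction(build_sheet_model()), class = "ligafem_content_error")
})

test_that("n_for_content inverts elastin_fraction with ties toward smaller n", {
  expect_equal(n_for_content(0), 0L)
  expect_equal(n_for_content(0.144), 105L)
  expect_equal(n_for_content(0.101), 70L)
  # round-trip identity over feasible n
  for (n in c(0L, 1L, 35L, 106L, 200L, 315L, 330L)) {
    g <- build_fibre_model(n_elastin = n)
    expect_equal(n_for_content(elastin_fraction(g)), n)
  }
  # strict monotonicity of the fraction in n
  fr <- vapply(0:50, function(n) elastin_fraction(build_fibre_model(n_elastin = n)),
               numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_error(n_for_content(0.99), class = "ligafem_capacity_error")
})

test_that("the sweep block counts give the study's content series", {
  # printed labels: 0 5.3 10.1 14.4 18.3 21.8 25.1 28.1 30.9 33.5;
  # sharp-corner volumes give 21.9 (21.875 exactly) and 28.2 (28.16) where
  # the filleted reference volumes round to 21.8 / 28.1
  computed <- vapply(seq(0L, 315L, 35L), function(n) {
    round(100 * elastin_fraction(build_fibre_model(n_elastin = n)), 1)
  }, numeric(1))
  expect_equal(computed, c(0, 5.3, 10.1, 14.4, 18.3, 21.9, 25.1, 28.2, 30.9, 33.5))
  # every label is still reproduced to within 0.1 percentage points
  printed <- c(0, 5.3, 10.1, 14.4, 18.3, 21.8, 25.1, 28.1, 30.9, 33.5)
  expect_true(all(abs(computed - printed) <= 0.1))
})

test_that("sheet model has the printed dimensions and volume", {
  g <- build_sheet_model()
  expect_equal(nrow(g$prisms), 3)
  lig <- g$prisms[g$prisms$component == "sheet", ]
  expect_equal(lig$dx * lig$dy * lig$dz, 2380800)
  bones <- g$prisms[g$prisms$component != "sheet", ]
  expect_true(all(bones$dy == 62 & bones$dz == 128))
  expect_error(build_sheet_model(c(300, 0, 128)), class = "ligafem_geometry_error")
})

test_that("geometry round-trips through its YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  g <- build_fibre_model(n_elastin = 70)
  write_geometry_config(g, path)
  g2 <- read_geometry_config(path)
  expect_equal(g2$prisms, g$prisms)
  expect_equal(g2$materials, g$materials)
  gs <- build_sheet_model()
  write_geometry_config(gs, path)
  expect_equal(read_geometry_config(path)$prisms, gs$prisms)
})
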