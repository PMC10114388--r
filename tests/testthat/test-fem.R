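# Independent element-stiffness oracle: direct B' D B quadrature at high
# order (Gauss-Legendre 4^3), coded separately from the implementation.
oracle_stiffness <- function(E, nu, h) {
  gl <- pracma::gaussLegendre(4, -1, 1)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- rbind(cbind(matrix(lam, 3, 3) + 2 * mu * diag(3), matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), mu * diag(3)))
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  Ke <- matrix(0, 24, 24)
  for (a in seq_len(4)) for (b in seq_len(4)) for (cc in seq_len(4)) {
    xi <- gl$x[a]; eta <- gl$x[b]; zeta <- gl$x[cc]
    w <- gl$w[a] * gl$w[b] * gl$w[cc]
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      gx <- sx[i] * (1 + sy[i] * eta) * (1 + sz[i] * zeta) / 8 * 2 / h[1]
      gy <- sy[i] * (1 + sx[i] * xi) * (1 + sz[i] * zeta) / 8 * 2 / h[2]
      gz <- sz[i] * (1 + sx[i] * xi) * (1 + sy[i] * eta) / 8 * 2 / h[3]
      col <- 3 * i - 2
      B[1, col] <- gx; B[2, col + 1] <- gy; B[3, col + 2] <- gz
      B[4, col] <- gy; B[4, col + 1] <- gx
      B[5, col + 1] <- gz; B[5, col + 2] <- gy
      B[6, col] <- gz; B[6, col + 2] <- gx
    }
    Ke <- Ke + t(B) %*% D %*% B * w * prod(h) / 8
  }
  Ke
}

test_that("element stiffness matches a high-order quadrature oracle", {
  for (h in list(c(1, 1, 1) * 4e-6, c(4, 3.875, 4) * 1e-6)) {
    Ke <- element_stiffness(8.9e6, 0.48, h)
    Ko <- oracle_stiffness(8.9e6, 0.48, h)
    expect_lt(max(abs(Ke - Ko)) / max(abs(Ko)), 1e-12)
  }
})

test_that("element stiffness is symmetric PSD with a 6-dim rigid nullspace", {
  Ke <- element_stiffness(1, 0, 1)
  expect_equal(Ke, t(Ke))
  ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10 * max(ev)), 6)
  expect_true(all(ev > -1e-10 * max(ev)))
  # translations map to zero
  for (comp in 1:3) {
    tvec <- rep(0, 24); tvec[seq(comp, 24, 3)] <- 1
    expect_lt(max(abs(Ke %*% tvec)), 1e-12 * max(abs(Ke)))
  }
  # linearised rotation about X maps to zero: u = (0, -z, y) at corners
  s <- ligafem:::hex_signs()
  rot <- as.vector(t(cbind(0, -s[, 3], s[, 2])))
  expect_lt(max(abs(Ke %*% rot)), 1e-10 * max(abs(Ke)))
  expect_error(element_stiffness(1, 0.5, 1), class = "ligafem_material_error")
})

test_that("assembly reproduces the element matrix and is order-invariant", {
  g <- block_geometry(c(10, 10, 10), label = "m1")
  m <- voxelize(g, 10)
  mats <- material("m1", 3e6, 0.3)
  K <- assemble(m, mats)
  Ke <- element_stiffness(3e6, 0.3, m$h_m)
  dofs <- ligafem:::element_dofs(m$elems)[1, ]
  expect_lt(max(abs(as.matrix(K)[dofs, dofs] - Ke)), 1e-9 * max(abs(Ke)))

  gf <- mini_fibre(n_elastin = 4)
  mf <- voxelize(gf, 4)
  K1 <- assemble(mf, gf$materials)
  perm <- rev(seq_len(nrow(mf$elems)))
  mf2 <- mf
  mf2$elems <- mf$elems[perm, , drop = FALSE]
  mf2$material <- mf$material[perm]
  K2 <- assemble(mf2, gf$materials)
  expect_lt(max(abs(K1 - K2)), 1e-9 * max(abs(K1@x)))
})

test_that("two-material bar matches the series-spring solution", {
  bar <- two_element_bar(E1 = 2e6, E2 = 8e6, nu = 0, h_um = 10)
  m <- bar$mesh
  K <- assemble(m, bar$materials)
  left <- which(m$nodes[, 1] < 1e-9)
  fixed <- as.vector(rbind(3L * left - 2L, 3L * left - 1L, 3L * left))
  t_applied <- 50
  f <- numeric(3 * nrow(m$nodes))
  right <- which(abs(m$nodes[, 1] - 20e-6) < 1e-9)
  A <- (10e-6)^2
  f[3 * right - 2] <- t_applied * A / 4
  sol <- solve_elastostatics(K, fixed, 0, f)
  # end displacement = t * (L1/E1 + L2/E2)
  delta <- t_applied * (10e-6 / 2e6 + 10e-6 / 8e6)
  expect_rel_equal(mean(sol$u[right, 1]), delta, 1e-10)
})

test_that("uniaxial bar reproduces sigma/E strain and uniform stress", {
  g <- block_geometry(c(60, 20, 20), label = "collagen")
  m <- voxelize(g, 5)
  mats <- material("collagen", 8.9e6, 0) # nu = 0 for the exact 1D state
  K <- assemble(m, mats)
  left <- which(m$nodes[, 1] < 1e-9)
  fixed <- as.vector(rbind(3L * left - 2L, 3L * left - 1L, 3L * left))
  right <- which(abs(m$nodes[, 1] - 60e-6) < 1e-9)
  t_applied <- 0.15
  f <- numeric(3 * nrow(m$nodes))
  # consistent uniform traction on the right face:
  # corner nodes carry 1/4 share from one face, edges 2, interior 4
  counts <- numeric(nrow(m$nodes))
  for (e in which(abs(m$nodes[m$elems[, 2], 1] - 60e-6) < 1e-9)) {
    fn <- m$elems[e, c(2, 3, 6, 7)]
    counts[fn] <- counts[fn] + 1
  }
  f[3 * seq_len(nrow(m$nodes)) - 2] <- t_applied * (5e-6)^2 / 4 * counts
  sol <- solve_elastostatics(K, fixed, 0, f)
  expect_rel_equal(mean(sol$u[right, 1]) / 60e-6, t_applied / 8.9e6, 1e-9)
  st <- recover_stress(m, mats, sol$u)
  expect_lt(max(abs(st$sigma[, 1] - t_applied)) / t_applied, 1e-9)
  expect_lt(max(abs(st$von_mises - t_applied)) / t_applied, 1e-9)
  # global force balance at the clamped face
  expect_rel_equal(sum(sol$reactions[seq(1, length(fixed), 3)]),
                   -t_applied * (20e-6)^2, 1e-8)
  # energy consistency: strain energy equals external work
  uvec <- as.vector(t(sol$u))
  expect_rel_equal(0.5 * sum(uvec * as.vector(K %*% uvec)),
                   0.5 * sum(f * uvec), 1e-9)
})

test_that("linear patch test: affine fields are reproduced exactly", {
  g <- block_geometry(c(16, 16, 16), label = "sheet")
  m <- voxelize(g, 4)
  mats <- material("sheet", 12.7e6, 0.48)
  K <- assemble(m, mats)
  G <- matrix(c(1e-3, 2e-4, -1e-4,
                3e-4, -5e-4, 2e-4,
                1e-4, 4e-4, 8e-4), 3, 3, byrow = TRUE)
  a <- c(1e-6, -2e-6, 5e-7)
  u_exact <- sweep(m$nodes %*% t(G), 2, a, "+")
  xmn <- range(m$nodes[, 1]); ymn <- range(m$nodes[, 2]); zmn <- range(m$nodes[, 3])
  on_bd <- m$nodes[, 1] %in% xmn | m$nodes[, 2] %in% ymn | m$nodes[, 3] %in% zmn
  bd <- which(on_bd)
  fixed <- c(3L * bd - 2L, 3L * bd - 1L, 3L * bd)
  vals <- c(u_exact[bd, 1], u_exact[bd, 2], u_exact[bd, 3])
  sol <- solve_elastostatics(K, fixed, vals, NULL)
  expect_lt(max(abs(sol$u - u_exact)), 1e-10 * max(abs(u_exact)))
})

test_that("hydrostatic and rigid-rotation fields recover zero von Mises", {
  g <- block_geometry(c(20, 20, 20), label = "sheet")
  m <- voxelize(g, 5)
  mats <- material("sheet", 12.7e6, 0.3)
  u_hydro <- m$nodes * 1e-3            # pure dilation
  st <- recover_stress(m, mats, u_hydro)
  expect_lt(max(st$von_mises) / max(abs(st$sigma)), 1e-12)
  theta <- 1e-3                        # linearised rigid rotation about X
  u_rot <- cbind(0, -theta * m$nodes[, 3], theta * m$nodes[, 2])
  st2 <- recover_stress(m, mats, u_rot)
  expect_lt(max(abs(st2$sigma)), 1e-9 * 12.7e6 * theta)
})

test_that("solutions scale linearly with the load", {
  g <- mini_sheet()
  m <- voxelize(g, 20)
  r1 <- shear_case(g, m, 1e-3)
  r2 <- shear_case(g, m, 2e-3)
  expect_lt(max(abs(r2$u - 2 * r1$u)), 1e-12 * max(abs(r1$u)) * 2 + 1e-30)
})
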