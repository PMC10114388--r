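#' @title Small-strain linear elastostatics on voxel hexahedral meshes
#' @description
#' Standard displacement-based finite elements: trilinear 8-node hexahedra
#' with full 2 x 2 x 2 Gauss integration (exact for the rectangular-brick
#' Jacobian), sparse symmetric assembly, Dirichlet elimination, CHOLMOD
#' Cholesky factorisation, and centroid stress recovery with von Mises
#' post-processing. Voigt order is (xx, yy, zz, xy, yz, zx) with
#' engineering shear strains.
#' @name fem_core
NULL

# local corner signs, VTK hexahedron ordering
hex_signs <- function() {
  cbind(xi   = c(-1,  1,  1, -1, -1,  1,  1, -1),
        eta  = c(-1, -1,  1,  1, -1, -1,  1,  1),
        zeta = c(-1, -1, -1, -1,  1,  1,  1,  1))
}

# isotropic elasticity matrix, engineering-shear Voigt convention
elastic_matrix <- function(E, nu) {
  if (nu >= 0.5) {
    rlang::abort("Poisson's ratio must be < 0.5", class = "ligafem_material_error")
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# strain-displacement matrix (6 x 24) at a local point (xi, eta, zeta)
# for a brick with edge lengths h (metres)
hex_B <- function(h, xi, eta, zeta) {
  s <- hex_signs()
  dNdxi   <- s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta) / 8
  dNdeta  <- s[, 2] * (1 + s[, 1] * xi)  * (1 + s[, 3] * zeta) / 8
  dNdzeta <- s[, 3] * (1 + s[, 1] * xi)  * (1 + s[, 2] * eta)  / 8
  dNdx <- dNdxi * 2 / h[1]
  dNdy <- dNdeta * 2 / h[2]
  dNdz <- dNdzeta * 2 / h[3]
  B <- matrix(0, 6, 24)
  ix <- 3 * (1:8) - 2
  B[1, ix]     <- dNdx
  B[2, ix + 1] <- dNdy
  B[3, ix + 2] <- dNdz
  B[4, ix]     <- dNdy; B[4, ix + 1] <- dNdx
  B[5, ix + 1] <- dNdz; B[5, ix + 2] <- dNdy
  B[6, ix]     <- dNdz; B[6, ix + 2] <- dNdx
  B
}

#' Stiffness matrix of a trilinear brick element
#'
#' Full 2 x 2 x 2 Gauss integration of `B' D B` for an axis-aligned
#' rectangular brick of a linear isotropic material. For this constant
#' Jacobian the integrand is at most biquadratic per direction, so the
#' 2-point rule is exact.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson's ratio, `0 <= nu < 0.5`.
#' @param h Element edge lengths in metres; scalar or length-3.
#' @return A 24 x 24 symmetric positive semi-definite matrix whose
#'   nullspace is spanned by the 3 translations and 3 linearised rotations.
#' @export
element_stiffness <- function(E, nu, h) {
  stopifnot(is.numeric(E), E > 0, is.numeric(h), all(h > 0))
  if (length(h) == 1L) h <- rep(h, 3L)
  D <- elastic_matrix(E, nu)
  gp <- 1 / sqrt(3)
  detJ <- prod(h) / 8
  Ke <- matrix(0, 24, 24)
  for (a in c(-gp, gp)) for (b in c(-gp, gp)) for (cc in c(-gp, gp)) {
    B <- hex_B(h, a, b, cc)
    Ke <- Ke + crossprod(B, D %*% B) * detJ
  }
  (Ke + t(Ke)) / 2
}

# element dof indices (E x 24), interleaved (ux, uy, uz) per node
element_dofs <- function(elems) {
  E <- nrow(elems)
  out <- matrix(0L, E, 24L)
  for (a in 1:8) {
    out[, 3L * a - 2L] <- 3L * elems[, a] - 2L
    out[, 3L * a - 1L] <- 3L * elems[, a] - 1L
    out[, 3L * a]      <- 3L * elems[, a]
  }
  out
}

#' Assemble the global stiffness matrix of a voxel mesh
#'
#' All elements of one material share one element stiffness (identical
#' bricks), so assembly reduces to scattering per-material blocks into a
#' sparse triplet list.
#'
#' @param mesh A `ligafem_mesh`.
#' @param materials Material table with a row for each component label's
#'   material (see [ligament_materials()]).
#' @return A sparse symmetric `ndof x ndof` stiffness matrix
#'   (`Matrix::dgCMatrix`), `ndof = 3 * n_nodes`.
#' @export
assemble <- function(mesh, materials = ligament_materials()) {
  ndof <- 3L * nrow(mesh$nodes)
  dofs <- element_dofs(mesh$elems)
  labs <- unique(mesh$material)
  nE <- nrow(mesh$elems)
  ii <- integer(576L * nE)
  jj <- integer(576L * nE)
  xx <- numeric(576L * nE)
  a_idx <- rep(1:24, times = 24)
  b_idx <- rep(1:24, each = 24)
  pos <- 0L
  for (k in seq_along(labs)) {
    m <- lookup_material(materials, labs[k])
    Ke <- element_stiffness(m$E, m$nu, mesh$h_m)
    sel <- which(mesh$material == labs[k])
    Dk <- t(dofs[sel, , drop = FALSE])        # 24 x m
    rng <- pos + seq_len(576L * length(sel))
    ii[rng] <- as.vector(Dk[a_idx, , drop = FALSE])
    jj[rng] <- as.vector(Dk[b_idx, , drop = FALSE])
    xx[rng] <- rep(as.vector(Ke), length(sel))
    pos <- pos + 576L * length(sel)
  }
  rm(Dk, dofs)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof),
                            repr = "C")
  K
}

#' Solve the constrained elastostatic system
#'
#' Eliminates the prescribed (Dirichlet) degrees of freedom, factorises the
#' free-free block with a sparse Cholesky decomposition, performs one step
#' of iterative refinement, and recovers reaction forces at the prescribed
#' dofs as `K u - f`.
#'
#' @param K Global stiffness (from [assemble()]).
#' @param fixed_dofs Integer dof indices with prescribed displacements.
#' @param fixed_values Prescribed displacement values (m), recycled.
#' @param f External nodal force vector (N), length `ndof`.
#' @param factor Optional factorisation object returned by a previous call
#'   with the same `K` and `fixed_dofs` (field `factor` of the result);
#'   reusing it skips the sparse Cholesky, so repeated load cases on one
#'   mesh cost only triangular solves.
#' @return A list: `u` (N x 3 nodal displacements, m), `reactions`
#'   (vector of reaction forces at `fixed_dofs`, N), `residual`
#'   (relative residual of the reduced solve), and `factor` (reusable
#'   factorisation, see above).
#' @export
solve_elastostatics <- function(K, fixed_dofs, fixed_values = 0, f = NULL,
                                factor = NULL) {
  ndof <- nrow(K)
  if (is.null(f)) f <- numeric(ndof)
  stopifnot(length(f) == ndof)
  fixed_dofs <- as.integer(fixed_dofs)
  if (anyDuplicated(fixed_dofs)) {
    rlang::abort("a (node, component) dof is prescribed more than once",
                 class = "ligafem_bc_error")
  }
  fixed_values <- rep_len(fixed_values, length(fixed_dofs))
  if (length(fixed_dofs) < 6L) {
    rlang::abort("constraints do not eliminate rigid-body modes",
                 class = "ligafem_bc_error")
  }
  if (is.null(factor)) {
    free <- setdiff(seq_len(ndof), fixed_dofs)
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    ch <- tryCatch(
      Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE, super = TRUE),
      error = function(e) {
        rlang::abort("constrained system is singular (under-constrained model)",
                     class = "ligafem_bc_error", parent = e)
      }
    )
    factor <- list(ch = ch, free = free, Kff = Kff,
                   key = c(ndof, length(fixed_dofs)))
  } else {
    if (!identical(factor$key, c(ndof, length(fixed_dofs)))) {
      rlang::abort("supplied factor does not match this system",
                   class = "ligafem_solver_error")
    }
    free <- factor$free
    Kff <- factor$Kff
    ch <- factor$ch
  }
  rhs <- f[free]
  if (any(fixed_values != 0)) {
    rhs <- rhs - as.vector(K[free, fixed_dofs, drop = FALSE] %*% fixed_values)
  }
  uf <- as.vector(Matrix::solve(ch, rhs))
  # one step of iterative refinement
  r <- rhs - as.vector(Kff %*% uf)
  uf <- uf + as.vector(Matrix::solve(ch, r))
  res <- sqrt(sum((rhs - as.vector(Kff %*% uf))^2))
  nr <- sqrt(sum(rhs^2))
  residual <- if (nr > 0) res / nr else res
  if (is.finite(residual) && nr > 0 && residual > 1e-9) {
    rlang::abort(sprintf("solver residual %.3e exceeds tolerance 1e-9", residual),
                 class = "ligafem_solver_error")
  }
  u <- numeric(ndof)
  u[free] <- uf
  u[fixed_dofs] <- fixed_values
  reactions <- as.vector(K[fixed_dofs, , drop = FALSE] %*% u) - f[fixed_dofs]
  list(u = matrix(u, ncol = 3L, byrow = TRUE), reactions = reactions,
       residual = residual, factor = factor)
}

#' Recover element stresses and von Mises intensity
#'
#' Evaluates the stress tensor `sigma = D B u_e` at each element centroid
#' and the von Mises invariant
#' `sqrt(0.5 * ((s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2) + 3 * (s12^2 + s23^2 + s31^2))`.
#'
#' @param mesh A `ligafem_mesh`.
#' @param materials Material table.
#' @param u N x 3 nodal displacement matrix (m).
#' @return A list: `sigma` (E x 6 Voigt stresses, Pa, order
#'   xx, yy, zz, xy, yz, zx) and `von_mises` (length-E vector, Pa).
#' @export
recover_stress <- function(mesh, materials, u) {
  stopifnot(nrow(u) == nrow(mesh$nodes), ncol(u) == 3L)
  B0 <- hex_B(mesh$h_m, 0, 0, 0)
  dofs <- element_dofs(mesh$elems)
  uvec <- as.vector(t(u))
  nE <- nrow(mesh$elems)
  sigma <- matrix(0, nE, 6L)
  for (lab in unique(mesh$material)) {
    m <- lookup_material(materials, lab)
    DB <- elastic_matrix(m$E, m$nu) %*% B0
    sel <- which(mesh$material == lab)
    Ue <- matrix(uvec[t(dofs[sel, , drop = FALSE])], nrow = 24L)
    sigma[sel, ] <- t(DB %*% Ue)
  }
  vm <- sqrt(pmax(0,
    0.5 * ((sigma[, 1] - sigma[, 2])^2 + (sigma[, 2] - sigma[, 3])^2 +
             (sigma[, 3] - sigma[, 1])^2) +
      3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2)))
  list(sigma = sigma, von_mises = vm)
}
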