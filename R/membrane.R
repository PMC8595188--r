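# Skalak hyperelastic membrane: material parameter relations, per-element
# kinematics and invariants, strain energy, nodal restoring forces and
# Green-Lagrange principal strains.

#' Membrane material from bulk parameters
#'
#' The Skalak surface shear modulus Gs is recovered from the membrane
#' Young's modulus E, thickness t and area incompressibility coefficient C
#' through the surface Poisson ratio nu_s = C/(C+1) and
#' E = 2 Gs (1 + nu_s) / t.
#'
#' @param E membrane Young's modulus (Pa); default 4471
#' @param t membrane thickness (nm); default 10 (lipid bilayer)
#' @param C area incompressibility coefficient (dimensionless); default 10
#' @return a `canaflow_material`: Gs (pN/nm), C, nu_s, E (Pa), t (nm)
#' @export
membrane_material <- function(E = 4471, t = 10, C = 10) {
  stopifnot(E > 0, t > 0, C > 0)
  nu_s <- C / (C + 1)
  Gs <- (E * PA) * t / (2 * (1 + nu_s))   # pN/nm
  structure(list(Gs = Gs, C = C, nu_s = nu_s, E = E, t = t),
            class = "canaflow_material")
}

# E recomputed from (Gs, nu_s, t); used to verify the relations round-trip
material_roundtrip_E <- function(mat) {
  2 * mat$Gs * (1 + mat$nu_s) / mat$t / PA
}

#' In-plane kinematics of one triangle
#'
#' Computes the in-plane deformation gradient of the affine map between the
#' reference and current triangle planes, its principal stretches, the
#' Skalak invariants I1 = lam1^2 + lam2^2 - 2 and I2 = lam1^2 lam2^2 - 1,
#' and the in-plane Green-Lagrange tensor E = (C - I)/2.
#'
#' @param ref,cur 3 x 3 matrices; rows are the triangle vertices
#' @return list: `lambda` (principal stretches, decreasing), `I1`, `I2`,
#'   `E` (2 x 2 Green-Lagrange tensor in the element plane),
#'   `max_principal` (largest eigenvalue of E), `degenerate`
#' @export
element_kinematics <- function(ref, cur) {
  to2d <- function(tri) {
    d1 <- tri[2, ] - tri[1, ]
    d2 <- tri[3, ] - tri[1, ]
    l1 <- sqrt(sum(d1^2))
    e1 <- d1 / l1
    p2 <- d2 - e1 * sum(d2 * e1)
    c1 <- sqrt(sum(p2^2))
    matrix(c(l1, 0, sum(d2 * e1), c1), 2, 2)
  }
  Dm <- to2d(ref)
  if (abs(det(Dm)) <= 2e-6)
    stop("degenerate reference triangle")
  Ds <- to2d(cur)
  if (abs(det(Ds)) <= 1e-10)
    return(list(lambda = c(NA, NA), I1 = NA, I2 = NA,
                E = matrix(NA, 2, 2), max_principal = NA, degenerate = TRUE))
  Fm <- Ds %*% solve(Dm)
  Cm <- t(Fm) %*% Fm
  ev <- eigen(Cm, symmetric = TRUE)$values
  lambda <- sqrt(pmax(ev, 0))
  Egl <- (Cm - diag(2)) / 2
  list(lambda = lambda,
       I1 = sum(lambda^2) - 2,
       I2 = prod(lambda^2) - 1,
       E = Egl,
       max_principal = max(eigen(Egl, symmetric = TRUE)$values),
       degenerate = FALSE)
}

#' Skalak strain energy density
#'
#' W = (Gs/4) (I1^2 + 2 I1 - 2 I2 + C I2^2), per unit reference area.
#'
#' @param I1,I2 Skalak strain invariants
#' @param Gs surface shear modulus (pN/nm)
#' @param C area incompressibility coefficient
#' @return energy per unit reference area (pN/nm)
#' @export
skalak_energy <- function(I1, I2, Gs, C) {
  0.25 * Gs * (I1^2 + 2 * I1 - 2 * I2 + C * I2^2)
}

#' Membrane nodal restoring forces
#'
#' Assembles q_m = -d(sum_el W A_ref)/d x_m over constant-strain triangles.
#' Zero at the reference configuration; invariant under rigid translation
#' and rotation; degenerate current elements are excluded and counted.
#'
#' @param mesh membrane mesh; forces are evaluated at `V` (current) against
#'   `Vref`
#' @param material a `canaflow_material`
#' @param V optional current vertex coordinates (defaults to `mesh$V`)
#' @return list: `force` (n x 3, pN), `energy` (pN nm), `n_degenerate`
#' @export
membrane_nodal_forces <- function(mesh, material, V = NULL) {
  if (is.null(V)) V <- mesh$V
  force <- matrix(0, nrow(V), 3)
  res <- membrane_forces_cpp(V, mesh$tri, mesh$zoff, mesh$refinv, mesh$refA,
                             material$Gs, material$C, force,
                             FALSE, matrix(0, 0, 0))
  if (res$n_degenerate > 0)
    warning(res$n_degenerate, " degenerate element(s) excluded")
  list(force = force, energy = res$energy, n_degenerate = res$n_degenerate)
}

#' Per-element strain state of the whole membrane
#'
#' @param mesh membrane mesh
#' @param V optional current coordinates (defaults to `mesh$V`)
#' @return data frame: lambda1, lambda2, I1, I2, max_principal (one row per
#'   element; NA for degenerate elements)
#' @export
membrane_strain_state <- function(mesh, V = NULL) {
  if (is.null(V)) V <- mesh$V
  m <- nrow(mesh$tri)
  strain <- matrix(0, m, 5)
  force <- matrix(0, nrow(V), 3)
  membrane_forces_cpp(V, mesh$tri, mesh$zoff, mesh$refinv, mesh$refA,
                      1, 1, force, TRUE, strain)
  data.frame(lambda1 = strain[, 1], lambda2 = strain[, 2],
             I1 = strain[, 3], I2 = strain[, 4],
             max_principal = strain[, 5])
}

#' Maximum principal Green-Lagrange strain per element
#'
#' The largest eigenvalue of the in-plane Green-Lagrange tensor for each
#' membrane element, the mechanostimulus readout of the model.
#'
#' @inheritParams membrane_strain_state
#' @return numeric vector, one value per element
#' @export
max_principal_strain_field <- function(mesh, V = NULL) {
  membrane_strain_state(mesh, V)$max_principal
}
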