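# Immersed-boundary coupling: the smoothed delta kernel, force spreading
# membrane -> lattice, velocity interpolation lattice -> membrane, and
# membrane advection.

#' Smoothed three-dimensional delta kernel
#'
#' The separable cosine kernel
#' D(x) = prod_i (1 + cos(pi x_i / (2 dx))) / (4 dx) for |x_i| <= 2 dx and
#' 0 otherwise (total prefactor 1/(64 dx^3)). Summed over lattice nodes
#' times dx^3 it partitions unity for any offset.
#'
#' @param offset 3-vector or n x 3 matrix of physical offsets (nm)
#' @param dx lattice spacing (nm)
#' @return kernel weight(s) in nm^-3
#' @export
delta3 <- function(offset, dx) {
  offset <- rbind(offset)
  w <- ifelse(abs(offset) < 2 * dx,
              (1 + cos(pi * offset / (2 * dx))) / (4 * dx), 0)
  unname(w[, 1] * w[, 2] * w[, 3])
}

#' Spread membrane forces to the fluid lattice
#'
#' F(x_f) = sum_m D(x_f - x_m) q(x_m), with periodic wrapping on periodic
#' axes. The spread field conserves total force; force falling on solid
#' voxels is reported as leakage instead of entering the fluid.
#'
#' @param nodes membrane node positions (n x 3, nm)
#' @param q nodal forces (n x 3, pN)
#' @param lat a `canaflow_lattice`
#' @return list: `F` (nf x 3 force density, pN/nm^3) and `leak`
#'   (3-vector, pN, force lost to solid regions)
#' @export
spread_forces <- function(nodes, q, lat) {
  d <- lat$domain
  Fx <- numeric(lat$nf); Fy <- numeric(lat$nf); Fz <- numeric(lat$nf)
  leak <- ibm_spread_cpp(rbind(nodes), rbind(q), d$origin, d$dx,
                         as.integer(d$dims), lat$fidx, d$periodic,
                         Fx, Fy, Fz)
  list(F = cbind(Fx, Fy, Fz), leak = leak)
}

#' Interpolate fluid velocity to membrane nodes
#'
#' U(x_m) = sum_f D(x_m - x_f) u(x_f) dx^3. Solid voxels contribute their
#' bounce-back velocity (zero).
#'
#' @param u fluid velocity per fluid cell (nf x 3, any units; returned in
#'   the same units). Defaults to the lattice's current physical velocity.
#' @param nodes membrane node positions (n x 3, nm)
#' @param lat a `canaflow_lattice`
#' @return n x 3 matrix of node velocities
#' @export
interpolate_velocity <- function(nodes, lat, u = NULL) {
  d <- lat$domain
  if (is.null(u)) u <- macroscopic(lat)$u
  ibm_interp_cpp(rbind(nodes), u[, 1], u[, 2], u[, 3],
                 d$origin, d$dx, as.integer(d$dims), lat$fidx, d$periodic)
}

#' Advect the membrane with the interpolated velocity
#'
#' Forward Euler: x_m <- x_m + U dt. Reference coordinates and
#' connectivity are untouched. A node displacement exceeding one lattice
#' spacing in a single step aborts (time-step guard).
#'
#' @param mesh membrane mesh
#' @param U node velocities (n x 3, nm/s)
#' @param dt time step (s)
#' @param dx lattice spacing for the displacement guard (nm); NULL skips
#'   the guard
#' @return the mesh with updated current coordinates
#' @export
advect_membrane <- function(mesh, U, dt, dx = NULL) {
  disp <- U * dt
  if (!is.null(dx)) {
    dmax <- max(abs(disp))
    if (dmax > dx)
      stop("membrane advection guard: node displacement ", signif(dmax, 3),
           " nm exceeds one lattice spacing per step")
  }
  mesh$V <- mesh$V + disp
  mesh
}
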