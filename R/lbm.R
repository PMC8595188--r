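# D3Q19 BGK lattice Boltzmann solver for Brinkman-damped Stokes flow:
# body-force drive and Darcy drag in the pericellular region, halfway
# bounce-back at solid walls, periodic wrapping on flagged axes, Guo
# forcing with semi-implicit drag.

# D3Q19 velocity set; must match the compiled kernel.
LBM_EX <- c(0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0)
LBM_EY <- c(0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1)
LBM_EZ <- c(0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1)
LBM_W <- c(1/3, rep(1/18, 6), rep(1/36, 12))

#' Physical/lattice unit scaling record
#'
#' Maps between physical units (nm, s, pN, Pa) and lattice units. `C_u` is
#' the physical velocity of one lattice velocity unit; the force-density
#' and time scales follow from the viscosity matching
#' mu = C_f nu dx^2 / C_u. The relaxation time must lie in (0.5, 2].
#'
#' @param dx lattice spacing (nm)
#' @param mu fluid viscosity (Pa s)
#' @param k_p pericellular permeability (nm^2)
#' @param tau BGK relaxation time (lattice units)
#' @param C_u velocity scale (nm/s per lattice unit)
#' @return a `canaflow_scaling` record
#' @export
make_scaling <- function(dx, mu, k_p, tau, C_u) {
  if (tau <= 0.5 || tau > 2)
    stop("relaxation time tau = ", tau, " outside the stable range (0.5, 2]")
  stopifnot(dx > 0, mu > 0, k_p > 0, C_u > 0)
  nu <- (tau - 0.5) / 3
  mu_i <- mu * PA                 # pN s / nm^2
  k_lat <- k_p / dx^2
  structure(list(
    dx = dx, tau = tau, nu = nu,
    mu = mu, k_p = k_p,
    C_u = C_u,                    # nm/s per lattice velocity
    C_t = dx / C_u,               # s per lattice step
    C_f = mu_i * C_u / (nu * dx^2),  # pN/nm^3 per lattice force density
    k_lat = k_lat,
    cd = nu / k_lat               # lattice drag coefficient
  ), class = "canaflow_scaling")
}

# round-trip helpers (physical <-> lattice)
u_to_lattice <- function(sc, u) u / sc$C_u
u_from_lattice <- function(sc, u_lat) u_lat * sc$C_u
fdens_to_lattice <- function(sc, f) f / sc$C_f        # f in pN/nm^3
fdens_from_lattice <- function(sc, f_lat) f_lat * sc$C_f
gradp_to_lattice <- function(sc, g) g * PA / sc$C_f   # g in Pa/nm
gradp_from_lattice <- function(sc, g_lat) g_lat * sc$C_f / PA
mu_from_lattice <- function(sc) sc$C_f * sc$nu * sc$dx^2 / sc$C_u / PA
kp_from_lattice <- function(sc) sc$k_lat * sc$dx^2

#' Initialize a fluid lattice on a voxel domain
#'
#' Builds the indexed D3Q19 lattice over the non-solid voxels, with pull
#' neighbor tables (periodic wrap on flagged axes, bounce-back into solid)
#' and distributions at rest equilibrium. Brinkman drag and the pressure
#' gradient drive act only in PERICELLULAR cells; INTRACELLULAR fluid is
#' plain viscous fluid moved only through membrane coupling.
#'
#' @param domain a `canaflow_domain`
#' @param mu fluid viscosity (Pa s)
#' @param k_p pericellular permeability (nm^2)
#' @param tau BGK relaxation time
#' @param C_u velocity scale (nm/s per lattice unit); default chosen so a
#'   Darcy plug at `gradp_ref` sits at lattice velocity `u_lat_target`
#' @param gradp_ref reference pressure gradient for the default scaling
#'   (Pa/nm)
#' @param u_lat_target target lattice Mach scale for the Darcy velocity
#' @return a `canaflow_lattice` environment
#' @export
init_lattice <- function(domain, mu = 1.0e-3, k_p = 7.0, tau = 1.0,
                         C_u = NULL, gradp_ref = 1.0, u_lat_target = 2e-3) {
  if (is.null(C_u)) {
    # undriven lattices scale against the unit-gradient Darcy velocity
    gref <- if (gradp_ref > 0) gradp_ref else 1
    C_u <- k_p * (gref * PA) / (mu * PA) / u_lat_target
  }
  sc <- make_scaling(domain$dx, mu, k_p, tau, C_u)
  lab <- domain$labels
  d <- dim(lab)
  fluid <- which(lab != WALL_SOLID)
  nf <- length(fluid)
  if (nf == 0) stop("domain has no fluid voxels")
  fidx <- rep(-1L, length(lab))
  fidx[fluid] <- seq_len(nf) - 1L
  i0 <- fluid - 1L
  ix <- i0 %% d[1] + 1L
  iy <- (i0 %/% d[1]) %% d[2] + 1L
  iz <- i0 %/% (d[1] * d[2]) + 1L
  nbr <- integer(19L * nf)
  for (q in 1:19) {
    sx <- ix - LBM_EX[q]; sy <- iy - LBM_EY[q]; sz <- iz - LBM_EZ[q]
    ok <- rep(TRUE, nf)
    if (domain$periodic[1]) sx <- (sx - 1L) %% d[1] + 1L else ok <- ok & sx >= 1L & sx <= d[1]
    if (domain$periodic[2]) sy <- (sy - 1L) %% d[2] + 1L else ok <- ok & sy >= 1L & sy <= d[2]
    if (domain$periodic[3]) sz <- (sz - 1L) %% d[3] + 1L else ok <- ok & sz >= 1L & sz <= d[3]
    v <- rep(-1L, nf)
    lin <- sx[ok] + (sy[ok] - 1L) * d[1] + (sz[ok] - 1L) * d[1] * d[2]
    v[ok] <- fidx[lin]
    nbr[((q - 1L) * nf + 1L):((q) * nf)] <- v
  }
  lat <- new.env(parent = emptyenv())
  lat$domain <- domain
  lat$nf <- nf
  lat$fluid <- fluid
  lat$fidx <- fidx
  lat$ctype <- lab[fluid]          # 1 pericellular, 2 intracellular
  lat$nbr <- nbr
  lat$f <- rep(LBM_W, times = nf)   # cell-major layout f[(i-1)*19 + q]
  lat$fpost <- numeric(19L * nf)
  lat$rho <- rep(1, nf)
  lat$ux <- numeric(nf); lat$uy <- numeric(nf); lat$uz <- numeric(nf)
  lat$Fx <- numeric(nf); lat$Fy <- numeric(nf); lat$Fz <- numeric(nf)
  # Brinkman drag acts in the pericellular matrix only
  lat$cdv <- ifelse(lat$ctype == PERICELLULAR, sc$cd, 0)
  lat$scaling <- sc
  lat$steps <- 0L
  class(lat) <- "canaflow_lattice"
  lat
}

#' One lattice Boltzmann collide-stream cycle
#'
#' Advances the lattice one step under a uniform pericellular drive
#' (signed z pressure gradient, as an equivalent body force) plus an
#' optional immersed-boundary force field, with Brinkman drag applied
#' semi-implicitly in the pericellular cells.
#'
#' @param lat a `canaflow_lattice`
#' @param drive signed z pressure gradient (Pa/nm); positive drives +z flow
#' @param F optional nf x 3 physical force density (pN/nm^3) on the fluid
#'   cells; when NULL the stored (lattice-unit) force field is used as-is
#' @return the lattice, invisibly (state advanced in place)
#' @export
lbm_step <- function(lat, drive = 0, F = NULL) {
  sc <- lat$scaling
  if (!is.null(F)) {
    lat$Fx <- F[, 1] / sc$C_f
    lat$Fy <- F[, 2] / sc$C_f
    lat$Fz <- F[, 3] / sc$C_f
  }
  lbm_collide_stream_cpp(lat$f, lat$fpost, lat$nbr, lat$ctype,
                         lat$Fx, lat$Fy, lat$Fz,
                         gradp_to_lattice(sc, drive), sc$tau, lat$cdv,
                         lat$rho, lat$ux, lat$uy, lat$uz)
  tmp <- lat$f; lat$f <- lat$fpost; lat$fpost <- tmp  # push-scheme swap
  lat$steps <- lat$steps + 1L
  invisible(lat)
}

#' Macroscopic fields in physical units
#'
#' @param lat a `canaflow_lattice`
#' @return list: `u` (nf x 3, nm/s), `p` (Pa, periodic part), `rho`
#'   (lattice density)
#' @export
macroscopic <- function(lat) {
  sc <- lat$scaling
  list(u = cbind(lat$ux, lat$uy, lat$uz) * sc$C_u,
       p = (lat$rho - 1) / 3 * sc$C_f * sc$dx / PA,
       rho = lat$rho)
}

total_mass <- function(lat) sum(lat$f)

#' Relax the lattice to steady state under a fixed drive
#'
#' Iterates collide-stream cycles until the maximum velocity change over
#' `check_every` steps, relative to the maximum speed, falls below `tol`.
#'
#' @param lat a `canaflow_lattice`
#' @param drive signed z pressure gradient (Pa/nm)
#' @param tol relative velocity-change tolerance
#' @param max_steps step budget; exceeding it is an error carrying the
#'   residual history
#' @param check_every convergence check interval (steps)
#' @return list: `u` (nf x 3, nm/s), `p` (Pa), `steps`, `residuals`
#' @export
solve_steady <- function(lat, drive = 0, tol = 1e-6, max_steps = 50000L,
                         check_every = 100L) {
  stopifnot(tol > 0)
  u_prev <- cbind(lat$ux, lat$uy, lat$uz)
  residuals <- numeric(0)
  repeat {
    for (i in seq_len(check_every)) lbm_step(lat, drive = drive)
    u_now <- cbind(lat$ux, lat$uy, lat$uz)
    if (any(!is.finite(u_now)))
      stop("lattice Boltzmann instability: non-finite velocities at step ",
           lat$steps)
    umax <- max(abs(u_now))
    res <- max(abs(u_now - u_prev)) / max(umax, 1e-300)
    residuals <- c(residuals, res)
    if (res < tol) break
    if (lat$steps >= max_steps) {
      cond <- structure(
        class = c("canaflow_convergence_error", "error", "condition"),
        list(message = paste0("solve_steady: no convergence within ",
                              max_steps, " steps; last residuals: ",
                              paste(signif(utils::tail(residuals, 5), 3),
                                    collapse = ", ")),
             call = sys.call(-1), residuals = residuals))
      stop(cond)
    }
    u_prev <- u_now
  }
  mac <- macroscopic(lat)
  list(u = mac$u, p = mac$p, steps = lat$steps, residuals = residuals)
}
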