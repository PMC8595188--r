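# Synthetic process/canaliculus geometry: smooth random radius fields,
# structured triangulated membrane tubes, voxelized fluid domains, and the
# mirror-periodic extension in z.

WALL_SOLID <- 0L
PERICELLULAR <- 1L
INTRACELLULAR <- 2L

# ---- radius fields ---------------------------------------------------------

# A tube surface r(z, phi) = base + perturbation, with the perturbation a
# truncated random Fourier series: axial basis cos(j*pi*z/L) (zero slope at
# z = 0 and z = L, so the mirror extension is smooth), azimuthal basis
# cos(m*phi), sin(m*phi). A, B hold the scaled coefficients.
new_radius_field <- function(base, L, A = NULL, B = NULL) {
  if (is.null(A)) A <- matrix(0, 1, 1)
  if (is.null(B)) B <- matrix(0, 1, 1)
  structure(list(base = base, L = L, A = A, B = B),
            class = "canaflow_field")
}

# Fold z into [0, L] by the mirror-periodic rule (period 2L, reflection at L)
fold_z <- function(z, L) {
  zm <- z %% (2 * L)
  pmin(zm, 2 * L - zm)
}

# Evaluate r(z, phi) for equal-length vectors z, phi (z in nm, any value;
# folded into the generating half-period)
eval_field <- function(field, z, phi) {
  zf <- fold_z(z, field$L)
  J <- nrow(field$A) - 1L
  M <- ncol(field$A) - 1L
  if (J == 0L && M == 0L && field$A[1, 1] == 0 && field$B[1, 1] == 0)
    return(rep(field$base, length(z)))
  cz <- cos(outer(zf, (0:J) * pi / field$L))       # n x (J+1)
  am <- cz %*% field$A                             # n x (M+1)
  bm <- cz %*% field$B
  mm <- outer(phi, 0:M)
  field$base + rowSums(am * cos(mm) + bm * sin(mm))
}

# Draw a random perturbation field with RMS `amplitude` (nm), Gaussian
# spectral weights with correlation length `corr_len` (nm), azimuthal
# harmonics up to `n_harmonics`. Uses the current RNG stream.
draw_radius_field <- function(base, L, amplitude, corr_len, n_harmonics) {
  if (amplitude <= 0) return(new_radius_field(base, L))
  J <- 2L
  wz <- function(j) exp(-0.25 * (j * pi * corr_len / L)^2)
  while (wz(J) > 1e-3 && J < 60L) J <- J + 1L
  M <- as.integer(n_harmonics)
  wgt <- outer(exp(-0.25 * ((0:J) * pi * corr_len / L)^2),
               exp(-0.25 * ((0:M) * corr_len / base)^2))
  A <- matrix(rnorm((J + 1) * (M + 1)), J + 1, M + 1) * wgt
  B <- matrix(rnorm((J + 1) * (M + 1)), J + 1, M + 1) * wgt
  A[1, 1] <- 0  # keep the mean radius at `base`
  B[, 1] <- 0   # sin(0 * phi) is degenerate
  f <- new_radius_field(base, L, A, B)
  # rescale so the realized RMS over the surface equals `amplitude`
  zg <- seq(0, L, length.out = 97)
  pg <- seq(0, 2 * pi, length.out = 129)[-129]
  grd <- expand.grid(z = zg, phi = pg)
  pert <- eval_field(f, grd$z, grd$phi) - base
  rms <- sqrt(mean(pert^2))
  if (rms > 0) {
    f$A <- f$A * amplitude / rms
    f$B <- f$B * amplitude / rms
  }
  f
}

scale_field <- function(field, s) {
  field$A <- field$A * s
  field$B <- field$B * s
  field
}

# minimum wall-process gap and field extrema on a fine surface sample
field_gap_stats <- function(proc, wall, L) {
  zg <- seq(0, L, length.out = 161)
  pg <- seq(0, 2 * pi, length.out = 161)[-161]
  grd <- expand.grid(z = zg, phi = pg)
  rp <- eval_field(proc, grd$z, grd$phi)
  rw <- eval_field(wall, grd$z, grd$phi)
  list(min_gap = min(rw - rp), min_proc = min(rp), max_wall = max(rw))
}

# ---- membrane mesh ---------------------------------------------------------

# Structured triangulated tube on rows of n_phi vertices. Open tubes span
# [0, L] with n_rows + 1 rows; closed (z-periodic) tubes span [0, Lz) with
# n_rows rows and wrap-around connectivity.
build_tube_mesh <- function(field, n_phi, n_rows, closed, Lz) {
  phi <- (0:(n_phi - 1)) * 2 * pi / n_phi
  jmax <- if (closed) n_rows - 1L else n_rows
  dz <- Lz / n_rows
  zs <- rep((0:jmax) * dz, each = n_phi)
  ps <- rep(phi, jmax + 1L)
  r <- eval_field(field, zs, ps)
  V <- cbind(r * cos(ps), r * sin(ps), zs)
  vid <- function(j, i) (j %% (jmax + 1L)) * n_phi + (i %% n_phi) + 1L
  jj <- rep(0:(n_rows - 1L), each = n_phi)
  ii <- rep(0:(n_phi - 1L), n_rows)
  a <- vid(jj, ii); b <- vid(jj, ii + 1L)
  cc <- vid(jj + 1L, ii); d <- vid(jj + 1L, ii + 1L)
  tri <- rbind(cbind(a, b, cc), cbind(b, d, cc))
  dimnames(tri) <- NULL
  mesh <- structure(list(
    V = V, Vref = V, tri = tri,
    Lz = if (closed) Lz else NA_real_,
    closed = closed,
    n_phi = n_phi, n_rows = n_rows
  ), class = "canaflow_mesh")
  mesh_precompute(mesh)
}

# Precompute the per-triangle reference frame used by the Skalak FEM:
# z-unwrap offsets across the periodic seam, the inverse reference shape
# matrix, reference areas and per-vertex areas.
mesh_precompute <- function(mesh) {
  tri <- mesh$tri
  Vr <- mesh$Vref
  m <- nrow(tri)
  zoff <- matrix(0, m, 3)
  if (mesh$closed) {
    Lz <- mesh$Lz
    z1 <- Vr[tri[, 1], 3]
    for (k in 2:3) {
      dzk <- Vr[tri[, k], 3] - z1
      zoff[, k] <- ifelse(dzk > Lz / 2, -Lz, ifelse(dzk < -Lz / 2, Lz, 0))
    }
  }
  A <- Vr[tri[, 1], , drop = FALSE]
  B <- Vr[tri[, 2], , drop = FALSE]
  C <- Vr[tri[, 3], , drop = FALSE]
  B[, 3] <- B[, 3] + zoff[, 2]
  C[, 3] <- C[, 3] + zoff[, 3]
  d1 <- B - A
  d2 <- C - A
  l1 <- sqrt(rowSums(d1^2))
  e1 <- d1 / l1
  b1 <- rowSums(d2 * e1)
  p2 <- d2 - e1 * b1
  c1 <- sqrt(rowSums(p2^2))
  area <- 0.5 * l1 * c1
  if (any(area <= 1e-6))
    stop("degenerate membrane triangles (area <= 1e-6 nm^2): ",
         paste(head(which(area <= 1e-6), 10), collapse = ", "))
  # Dm = [l1 b1; 0 c1]; refinv stores Dm^-1 as (i11, i21, i12, i22)
  refinv <- cbind(1 / l1, 0, -b1 / (l1 * c1), 1 / c1)
  varea <- rep(0, nrow(Vr))
  for (k in 1:3) {
    acc <- tapply(rep(area / 3, 1), tri[, k], sum)
    varea[as.integer(names(acc))] <- varea[as.integer(names(acc))] + acc
  }
  mesh$zoff <- zoff
  mesh$refinv <- refinv
  mesh$refA <- area
  mesh$vertex_area <- varea
  mesh
}

#' Membrane surface area (reference configuration)
#' @param mesh a membrane mesh
#' @return total area in nm^2
#' @export
mesh_area <- function(mesh) sum(mesh$refA)

# per-element reference centroids, z-unwrapped across the seam
mesh_centroids <- function(mesh) {
  tri <- mesh$tri
  Vr <- mesh$Vref
  ctr <- (Vr[tri[, 1], , drop = FALSE] +
          Vr[tri[, 2], , drop = FALSE] +
          Vr[tri[, 3], , drop = FALSE]) / 3
  ctr[, 3] <- ctr[, 3] + rowSums(mesh$zoff) / 3
  ctr
}

# ---- voxel domain ----------------------------------------------------------

#' Voxelize a process/canaliculus surface pair
#'
#' Classifies cubic voxel centers by signed containment against the two
#' tube surfaces: inside the membrane surface -> INTRACELLULAR (2), between
#' membrane and canalicular wall -> PERICELLULAR (1), outside the wall ->
#' WALL_SOLID (0).
#'
#' @param proc_field,wall_field radius fields (see geometry generators)
#' @param Lz domain length in z (nm); must be an integer multiple of `dx`
#' @param dx lattice spacing (nm)
#' @param periodic_z logical; is the domain z-periodic (mirrored)?
#' @return a `canaflow_domain`: lattice spacing, grid shape, per-voxel
#'   labels, per-axis periodicity and grid origin
#' @export
voxelize <- function(proc_field, wall_field, Lz, dx, periodic_z = FALSE) {
  st <- field_gap_stats(proc_field, wall_field, proc_field$L)
  if (st$min_gap < 2 * dx)
    stop("pericellular gap (", signif(st$min_gap, 4),
         " nm) is below 2*dx; unresolvable pericellular space")
  nz <- as.integer(round(Lz / dx))
  if (abs(nz * dx - Lz) > 1e-6)
    stop("Lz must be an integer multiple of dx")
  half <- st$max_wall + 3.5 * dx
  nx <- 2L * as.integer(ceiling(half / dx))
  ny <- nx
  origin <- c(-nx * dx / 2, -ny * dx / 2, 0)
  cx <- origin[1] + (seq_len(nx) - 0.5) * dx
  cy <- origin[2] + (seq_len(ny) - 0.5) * dx
  cz <- origin[3] + (seq_len(nz) - 0.5) * dx
  xg <- rep(cx, times = ny * nz)
  yg <- rep(rep(cy, each = nx), times = nz)
  zg <- rep(cz, each = nx * ny)
  rho <- sqrt(xg^2 + yg^2)
  phi <- atan2(yg, xg)
  rp <- eval_field(proc_field, zg, phi)
  rw <- eval_field(wall_field, zg, phi)
  lab <- ifelse(rho < rp, INTRACELLULAR,
                ifelse(rho < rw, PERICELLULAR, WALL_SOLID))
  labels <- array(as.integer(lab), dim = c(nx, ny, nz))
  structure(list(dx = dx, dims = c(nx, ny, nz), origin = origin,
                 labels = labels,
                 periodic = c(FALSE, FALSE, periodic_z)),
            class = "canaflow_domain")
}

# voxel center coordinates of every grid cell (nx*ny*nz x 3), grid order
voxel_centers <- function(domain) {
  d <- domain$dims
  cx <- domain$origin[1] + (seq_len(d[1]) - 0.5) * domain$dx
  cy <- domain$origin[2] + (seq_len(d[2]) - 0.5) * domain$dx
  cz <- domain$origin[3] + (seq_len(d[3]) - 0.5) * domain$dx
  cbind(rep(cx, times = d[2] * d[3]),
        rep(rep(cy, each = d[1]), times = d[3]),
        rep(cz, each = d[1] * d[2]))
}

#' Validate a voxel domain
#'
#' Checks that WALL_SOLID fully encloses the fluid in x and y, and that the
#' pericellular voxels form a single connected component (6-connectivity,
#' periodic in z when flagged) spanning the whole z extent.
#'
#' @param domain a `canaflow_domain`
#' @return invisibly TRUE; stops with a diagnostic otherwise
#' @export
validate_domain <- function(domain) {
  lab <- domain$labels
  d <- dim(lab)
  if (any(lab[c(1, d[1]), , ] != WALL_SOLID) ||
      any(lab[, c(1, d[2]), ] != WALL_SOLID))
    stop("fluid is not enclosed by WALL_SOLID in x/y")
  peri <- which(lab == PERICELLULAR)
  if (length(peri) == 0) stop("no pericellular voxels")
  nxy <- d[1] * d[2]
  isperi <- logical(length(lab))
  isperi[peri] <- TRUE
  visited <- logical(length(lab))
  frontier <- peri[1]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    i0 <- frontier - 1L
    ix <- i0 %% d[1]
    iy <- (i0 %/% d[1]) %% d[2]
    iz <- i0 %/% nxy
    nb <- c(frontier[ix > 0] - 1L, frontier[ix < d[1] - 1L] + 1L,
            frontier[iy > 0] - d[1], frontier[iy < d[2] - 1L] + d[1])
    zm <- i0 - iz * nxy
    if (domain$periodic[3]) {
      nb <- c(nb, zm + ((iz + 1L) %% d[3]) * nxy + 1L,
              zm + ((iz - 1L) %% d[3]) * nxy + 1L)
    } else {
      nb <- c(nb, frontier[iz < d[3] - 1L] + nxy, frontier[iz > 0] - nxy)
    }
    nb <- unique(nb[isperi[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  if (!all(visited[peri]))
    stop("pericellular space is not a single connected component (",
         sum(!visited[peri]), " unreachable voxels); no through-flow possible")
  slice_has <- vapply(seq_len(d[3]), function(k) any(lab[, , k] == PERICELLULAR),
                      logical(1))
  if (!all(slice_has))
    stop("pericellular space does not span z (blocked column)")
  invisible(TRUE)
}

# ---- geometry constructors -------------------------------------------------

geometry_core <- function(proc_field, wall_field, L, target_edge, dx, meta) {
  n_phi <- max(8L, as.integer(round(2 * pi * proc_field$base / target_edge)))
  n_rows <- max(2L, as.integer(round(L / (target_edge * sqrt(3) / 2))))
  mesh <- build_tube_mesh(proc_field, n_phi, n_rows, closed = FALSE, Lz = L)
  domain <- voxelize(proc_field, wall_field, L, dx, periodic_z = FALSE)
  structure(list(membrane = mesh, domain = domain,
                 proc_field = proc_field, wall_field = wall_field,
                 L_pre = L, Lz = L, mirrored = FALSE,
                 metadata = meta),
            class = "canaflow_geometry")
}

#' Coaxial circular process/canaliculus geometry
#'
#' Idealized smooth validation geometry: circular cylinders for the process
#' membrane (radius `process_radius`) and canalicular wall
#' (`canal_radius`), triangulated at `target_edge` and voxelized at `dx`.
#' The length is snapped to an integer number of voxels so the mirror plane
#' is an exact lattice reflection.
#'
#' @param process_radius,canal_radius radii in nm (0 < process < canal)
#' @param length pre-mirror length in nm
#' @param target_edge target membrane element edge (nm)
#' @param dx lattice spacing (nm)
#' @return a `canaflow_geometry` (not yet mirror-extended)
#' @export
make_annulus_geometry <- function(process_radius, canal_radius, length,
                                  target_edge = 4.7, dx = 5.1) {
  stopifnot(process_radius > 0, target_edge > 0, dx > 0, length > 0)
  if (process_radius >= canal_radius)
    stop("process_radius must be smaller than canal_radius (empty annulus)")
  if (canal_radius - process_radius < 2 * dx)
    stop("gap (canal_radius - process_radius) < 2*dx: unresolvable ",
         "pericellular space")
  L <- round(length / dx) * dx
  pf <- new_radius_field(process_radius, L)
  wf <- new_radius_field(canal_radius, L)
  geometry_core(pf, wf, L, target_edge, dx,
                meta = list(type = "annulus",
                            process_radius = process_radius,
                            canal_radius = canal_radius,
                            length_requested = length, length = L,
                            target_edge = target_edge, dx = dx))
}

#' Irregular process/canaliculus geometry
#'
#' Both tube radii are smooth random fields: a truncated random Fourier
#' series in (z, phi), band-limited by `axial_correlation_length` and
#' `n_harmonics`, drawn independently for the process and the wall. The
#' axial basis cos(j pi z / L) has zero slope at both ends, so the
#' mirror-periodic extension of the surface is smooth. Perturbations are
#' rescaled, if necessary, so the wall-process gap stays above 2*dx.
#'
#' @param base_process_radius,base_canal_radius mean radii (nm)
#' @param length pre-mirror length (nm, snapped to a voxel multiple)
#' @param roughness_amplitude RMS radius perturbation (nm)
#' @param axial_correlation_length correlation length of the roughness (nm)
#' @param n_harmonics highest azimuthal harmonic
#' @param target_edge membrane element edge target (nm)
#' @param dx lattice spacing (nm)
#' @param seed RNG seed; the same seed reproduces the geometry bit for bit
#' @return a `canaflow_geometry` (not yet mirror-extended)
#' @export
make_irregular_geometry <- function(base_process_radius = 52,
                                    base_canal_radius = 130,
                                    length = 227,
                                    roughness_amplitude = 10,
                                    axial_correlation_length = 20,
                                    n_harmonics = 12,
                                    target_edge = 4.7, dx = 5.1,
                                    seed = 1L) {
  stopifnot(base_process_radius > 0, target_edge > 0, dx > 0)
  gap0 <- base_canal_radius - base_process_radius
  if (roughness_amplitude >= gap0 / 2)
    stop("roughness_amplitude must be below half the mean gap")
  if (gap0 < 2 * dx)
    stop("gap (canal_radius - process_radius) < 2*dx: unresolvable ",
         "pericellular space")
  L <- round(length / dx) * dx
  set.seed(seed)
  pf <- draw_radius_field(base_process_radius, L, roughness_amplitude,
                          axial_correlation_length, n_harmonics)
  wf <- draw_radius_field(base_canal_radius, L, roughness_amplitude,
                          axial_correlation_length, n_harmonics)
  rescale <- 1
  if (roughness_amplitude > 0) {
    st <- field_gap_stats(pf, wf, L)
    margin <- 2 * dx + 0.5
    if (st$min_gap < margin) {
      deficit <- gap0 - st$min_gap  # largest perturbation-induced closure
      rescale <- (gap0 - margin) / deficit
      if (rescale < 0.05)
        stop("roughness constraint unsatisfiable: gap closes to ",
             signif(st$min_gap, 4), " nm; rescale factor ",
             signif(rescale, 3), " below floor")
      pf <- scale_field(pf, rescale)
      wf <- scale_field(wf, rescale)
    }
  }
  geometry_core(pf, wf, L, target_edge, dx,
                meta = list(type = "irregular",
                            base_process_radius = base_process_radius,
                            base_canal_radius = base_canal_radius,
                            length_requested = length, length = L,
                            roughness_amplitude = roughness_amplitude,
                            axial_correlation_length = axial_correlation_length,
                            n_harmonics = n_harmonics,
                            target_edge = target_edge, dx = dx,
                            seed = seed, gap_rescale = rescale))
}

#' Mirror-periodic extension
#'
#' Reflects the geometry across the x-y plane at z = L and concatenates,
#' yielding a z-periodic domain of length 2L. Membrane seam vertices are
#' welded (single vertex set with wrap-around connectivity), and the voxel
#' labels are mirror-symmetric about z = L by construction.
#'
#' @param geom an unmirrored `canaflow_geometry`
#' @return the mirrored, z-periodic geometry
#' @export
mirror_extend <- function(geom) {
  if (geom$mirrored) stop("geometry is already mirror-extended")
  L <- geom$L_pre
  mesh0 <- geom$membrane
  mesh <- build_tube_mesh(geom$proc_field, mesh0$n_phi, 2L * mesh0$n_rows,
                          closed = TRUE, Lz = 2 * L)
  domain <- voxelize(geom$proc_field, geom$wall_field, 2 * L, geom$domain$dx,
                     periodic_z = TRUE)
  geom$membrane <- mesh
  geom$domain <- domain
  geom$Lz <- 2 * L
  geom$mirrored <- TRUE
  geom
}
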