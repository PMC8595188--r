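# Tethering elements (TEs): random placement on the membrane, anchoring to
# the nearest wall point, natural lengths from the no-flow configuration,
# tension-only spring forces and orientation angles.

#' Place TE attachment points on the membrane
#'
#' Samples `round(density * Lz)` distinct membrane vertices, weighted by
#' vertex area (so attachments are uniform over the membrane surface).
#'
#' @param mesh membrane mesh (reference configuration)
#' @param Lz domain length in z (nm)
#' @param density TE number density along z (per nm); the canalicular
#'   value is 12/37.5 per nm
#' @param seed RNG seed; same seed, same attachment set
#' @return integer vector of membrane vertex indices
#' @export
place_tether_attachments <- function(mesh, Lz, density = 12 / 37.5, seed = 1L) {
  stopifnot(density > 0, Lz >= 0)
  n_te <- as.integer(round(density * Lz))
  nv <- nrow(mesh$Vref)
  if (n_te > nv)
    stop("requested ", n_te, " TEs but the mesh has only ", nv, " vertices")
  if (n_te == 0L) return(integer(0))
  set.seed(seed)
  sort(sample.int(nv, n_te, replace = FALSE, prob = mesh$vertex_area))
}

#' Anchor attachment points to the nearest wall point
#'
#' For each membrane attachment, finds the closest point on the continuous
#' canalicular wall surface (Euclidean metric, periodic in z), by a coarse
#' surface grid search refined locally. Grid candidates are ordered by
#' ascending z then azimuth, so exact ties resolve to the smallest z first.
#'
#' @param points attachment coordinates (n x 3 matrix, nm)
#' @param wall_field the wall radius field
#' @param Lz domain period in z (nm)
#' @return n x 3 matrix of wall anchor points; the z coordinate is
#'   unwrapped to lie within half a period of the attachment
#' @export
anchor_to_wall <- function(points, wall_field, Lz) {
  points <- rbind(points)
  n <- nrow(points)
  nzg <- 192L
  npg <- 192L
  zg <- (0:(nzg - 1)) * Lz / nzg
  pg <- (0:(npg - 1)) * 2 * pi / npg
  zz <- rep(zg, each = npg)
  pp <- rep(pg, nzg)
  rr <- eval_field(wall_field, zz, pp)
  wx <- rr * cos(pp)
  wy <- rr * sin(pp)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    dz <- (zz - points[i, 3] + Lz / 2) %% Lz - Lz / 2
    d2 <- (wx - points[i, 1])^2 + (wy - points[i, 2])^2 + dz^2
    best <- which.min(d2)
    zb <- points[i, 3] + dz[best]
    pb <- pp[best]
    hz <- Lz / nzg
    hp <- 2 * pi / npg
    for (lev in 1:3) {
      zl <- zb + seq(-hz, hz, length.out = 13)
      pl <- pb + seq(-hp, hp, length.out = 13)
      zc <- rep(zl, each = 13)
      pc <- rep(pl, 13)
      rc <- eval_field(wall_field, zc, pc)
      d2l <- (rc * cos(pc) - points[i, 1])^2 +
             (rc * sin(pc) - points[i, 2])^2 + (zc - points[i, 3])^2
      b <- which.min(d2l)
      zb <- zc[b]
      pb <- pc[b]
      hz <- hz / 6
      hp <- hp / 6
    }
    rb <- eval_field(wall_field, zb, pb)
    out[i, ] <- c(rb * cos(pb), rb * sin(pb), zb)
  }
  out
}

#' Natural lengths from the no-flow configuration
#'
#' l0 is the attachment-to-anchor distance in the reference (no-flow)
#' membrane configuration, so every TE carries exactly zero tension before
#' flow is applied. TEs with l0 below `min_l0` (membrane touching the
#' wall) are rejected.
#'
#' @param x_m reference attachment coordinates (n x 3)
#' @param x_w wall anchors (n x 3)
#' @param min_l0 rejection threshold (nm)
#' @return list with `l0` and logical `keep`
#' @export
set_natural_lengths <- function(x_m, x_w, min_l0 = 1e-9) {
  l0 <- sqrt(rowSums((rbind(x_m) - rbind(x_w))^2))
  keep <- l0 >= min_l0
  if (any(!keep))
    message(sum(!keep), " TE(s) rejected: zero natural length")
  list(l0 = l0, keep = keep)
}

#' TE spring constant
#'
#' k_sp = pi r_sp^2 E_sp / l0, the axial stiffness of a linear elastic
#' fiber of radius `r_sp` and Young's modulus `E_sp`.
#'
#' @param E_sp Young's modulus of the TE (Pa); perlecan-like value 71e6
#' @param r_sp TE radius (nm)
#' @param l0 natural length (nm)
#' @return spring constant in pN/nm (1 pN/nm = 1e-3 N/m)
#' @export
spring_constant <- function(E_sp, r_sp, l0) {
  stopifnot(all(E_sp > 0), all(r_sp > 0), all(l0 > 0))
  pi * r_sp^2 * (E_sp * PA) / l0
}

#' Tension-only TE spring force
#'
#' The restoring force on the membrane attachment: zero while the TE is at
#' or below its natural length, and k_sp (|x_m - x_w| - l0) directed from
#' x_m toward x_w when stretched.
#'
#' @param x_m current attachment position(s) (n x 3)
#' @param x_w wall anchor(s) (n x 3)
#' @param k_sp spring constant(s) (pN/nm)
#' @param l0 natural length(s) (nm)
#' @return list: `force` (n x 3, pN, acting on the membrane) and
#'   `tension` (pN, >= 0)
#' @export
tether_force <- function(x_m, x_w, k_sp, l0) {
  x_m <- rbind(x_m)
  x_w <- rbind(x_w)
  d <- x_m - x_w
  len <- sqrt(rowSums(d^2))
  ext <- len - l0
  tension <- ifelse(ext > 0, k_sp * ext, 0)
  scale <- ifelse(len > 0, tension / len, 0)
  list(force = -d * scale, tension = tension)
}

#' TE orientation angle
#'
#' Angle theta in [0, pi] between the no-flow attachment-to-anchor vector
#' (x_w - x_m) and the +z axis. Under +z flow the membrane is dragged
#' toward +z, so TEs with anchors upstream (theta > pi/2) are stretched.
#'
#' @param x_m reference attachment coordinates (n x 3)
#' @param x_w wall anchors (n x 3)
#' @return angles in radians
#' @export
orientation_angle <- function(x_m, x_w) {
  v <- rbind(x_w) - rbind(x_m)
  len <- sqrt(rowSums(v^2))
  acos(pmin(1, pmax(-1, v[, 3] / len)))
}

#' Build a tether set on a mirrored geometry
#'
#' Runs placement, wall anchoring, natural-length assignment and spring
#' constant evaluation; drops zero-length TEs.
#'
#' @param geom a mirrored `canaflow_geometry`
#' @param density TE density along z (per nm)
#' @param seed placement seed
#' @param E_sp,r_sp TE Young's modulus (Pa) and radius (nm)
#' @return a `canaflow_tethers` set
#' @export
place_tethers <- function(geom, density = 12 / 37.5, seed = 1L,
                          E_sp = 71e6, r_sp = 1) {
  if (!geom$mirrored)
    stop("tethers are placed on the mirrored, z-periodic geometry")
  mesh <- geom$membrane
  att <- place_tether_attachments(mesh, geom$Lz, density, seed)
  x_m <- mesh$Vref[att, , drop = FALSE]
  x_w <- anchor_to_wall(x_m, geom$wall_field, geom$Lz)
  nl <- set_natural_lengths(x_m, x_w)
  att <- att[nl$keep]
  x_w <- x_w[nl$keep, , drop = FALSE]
  l0 <- nl$l0[nl$keep]
  k_sp <- spring_constant(E_sp, r_sp, l0)
  theta <- orientation_angle(mesh$Vref[att, , drop = FALSE], x_w)
  structure(list(attachment = att, x_w = x_w, l0 = l0, k_sp = k_sp,
                 theta = theta, density = density, seed = seed,
                 E_sp = E_sp, r_sp = r_sp),
            class = "canaflow_tethers")
}

# total TE force field on the membrane vertices (n x 3, pN) + tensions
tether_forces_all <- function(tethers, V) {
  n <- nrow(V)
  F <- matrix(0, n, 3)
  if (length(tethers$attachment) == 0)
    return(list(force = F, tension = numeric(0)))
  tf <- tether_force(V[tethers$attachment, , drop = FALSE],
                     tethers$x_w, tethers$k_sp, tethers$l0)
  for (k in 1:3) {
    acc <- tapply(tf$force[, k], tethers$attachment, sum)
    ix <- as.integer(names(acc))
    F[ix, k] <- F[ix, k] + acc
  }
  list(force = F, tension = tf$tension)
}
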