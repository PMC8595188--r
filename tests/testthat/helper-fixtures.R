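# Shared fixtures: small geometries (cached across test files) and ad-hoc
# voxel domains for the closed-form flow cases.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small coaxial annulus, mirrored: process 20, canal 48, pre-mirror 60 nm
small_annulus <- function() cached("small_annulus", {
  mirror_extend(make_annulus_geometry(20, 48, 60, target_edge = 8, dx = 4))
})

# small irregular geometry, mirrored
small_irregular <- function() cached("small_irregular", {
  mirror_extend(make_irregular_geometry(
    25, 60, 70, roughness_amplitude = 6, axial_correlation_length = 20,
    n_harmonics = 12, target_edge = 8, dx = 5.1, seed = 2))
})

small_config <- function(...) {
  sim_config(
    geometry = list(process_radius = 25, canal_radius = 60, length = 70,
                    roughness_amplitude = 6, target_edge = 8, dx = 5.1,
                    seed = 2),
    ...)
}

# hand-built voxel domain (labels supplied directly)
make_domain <- function(dims, labels, periodic, dx, origin = c(0, 0, 0)) {
  structure(list(dx = dx, dims = as.integer(dims), origin = origin,
                 labels = labels, periodic = periodic),
            class = "canaflow_domain")
}

# fully periodic pericellular box (Darcy plug / IBM conservation tests)
periodic_box <- function(n = 8L, dx = 5.1) {
  make_domain(c(n, n, n), array(1L, c(n, n, n)), c(TRUE, TRUE, TRUE), dx)
}

# plane channel: solid walls at the y extremes, periodic in x and z;
# ny_fluid fluid layers of spacing dx -> half-width h = ny_fluid * dx / 2
channel_domain <- function(ny_fluid = 20L, dx = 2.5) {
  ny <- ny_fluid + 2L
  lab <- array(1L, c(2L, ny, 2L))
  lab[, 1, ] <- 0L
  lab[, ny, ] <- 0L
  make_domain(c(2L, ny, 2L), lab, c(TRUE, FALSE, TRUE), dx)
}

# y coordinate (relative to the channel center plane) of each fluid cell
channel_y <- function(lat) {
  d <- lat$domain
  iy <- ((lat$fluid - 1L) %/% d$dims[1]) %% d$dims[2] + 1L
  (iy - 0.5) * d$dx - d$dims[2] * d$dx / 2
}
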