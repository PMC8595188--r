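# Immersed-boundary coupling: delta kernel properties, conservative force
# spreading, velocity interpolation and membrane advection.

test_that("delta kernel matches its closed form and support", {
  dx <- 5.1
  expect_equal(delta3(c(0, 0, 0), dx), 1 / (8 * dx^3), tolerance = 1e-12)
  expect_identical(delta3(c(2 * dx, 0, 0), dx), 0)
  expect_identical(delta3(c(0, -2 * dx, 1), dx), 0)
  expect_true(all(delta3(matrix(runif(30, -12, 12), 10, 3), dx) >= 0))
})

test_that("the kernel partitions unity over the lattice for any offset", {
  dx <- 5.1
  set.seed(2)
  for (k in 1:5) {
    p <- runif(3, -dx, dx)
    grid <- expand.grid(i = -3:3, j = -3:3, k = -3:3) * dx
    s <- sum(delta3(sweep(as.matrix(grid), 2, p), dx)) * dx^3
    expect_equal(s, 1, tolerance = 1e-12)
  }
})

test_that("force spreading conserves the total force to 1e-12", {
  lat <- init_lattice(periodic_box(8))
  set.seed(3)
  nodes <- matrix(runif(15, 0, 8 * 5.1), 5, 3)
  q <- matrix(rnorm(15), 5, 3)
  sp <- spread_forces(nodes, q, lat)
  expect_lt(max(abs(colSums(sp$F) * 5.1^3 - colSums(q))) / max(abs(q)), 1e-12)
  expect_identical(max(abs(sp$leak)), 0)
  # zero forces spread to an identically zero field
  z <- spread_forces(nodes, q * 0, lat)
  expect_identical(max(abs(z$F)), 0)
  # coincident nodes with opposite forces cancel
  two <- spread_forces(rbind(nodes[1, ], nodes[1, ]),
                       rbind(q[1, ], -q[1, ]), lat)
  expect_lt(max(abs(two$F)), 1e-14)
})

test_that("force landing on solid voxels is reported as leakage", {
  dom <- channel_domain(8L, 5)
  lat <- init_lattice(dom)
  # node one lattice spacing from the wall: kernel support reaches solid
  node <- matrix(c(5, 1.2 * 5, 5), 1, 3)
  q <- matrix(c(0, 1, 0), 1, 3)
  sp <- spread_forces(node, q, lat)
  expect_gt(abs(sp$leak[2]), 0)
  expect_equal(sum(sp$F[, 2]) * 5^3 + sp$leak[2], 1, tolerance = 1e-12)
})

test_that("velocity interpolation is exact for constants and 2% for linear fields", {
  lat <- init_lattice(periodic_box(8))
  nf <- lat$nf
  u_const <- cbind(rep(1.5, nf), rep(-2, nf), rep(3, nf))
  set.seed(5)
  nodes <- matrix(runif(12, 5, 35), 4, 3)
  U <- interpolate_velocity(nodes, lat, u_const)
  expect_lt(max(abs(sweep(U, 2, c(1.5, -2, 3)))), 1e-12)
  expect_identical(max(abs(interpolate_velocity(nodes, lat, u_const * 0))), 0)
  ctr <- canaflow:::voxel_centers(lat$domain)[lat$fluid, ]
  u_lin <- cbind(0.02 * ctr[, 1], rep(0, nf), rep(0, nf))
  nodes2 <- matrix(c(15, 20, 20, 22, 17, 13), 2, 3, byrow = TRUE)
  U2 <- interpolate_velocity(nodes2, lat, u_lin)
  expect_lt(max(abs(U2[, 1] - 0.02 * nodes2[, 1]) / (0.02 * nodes2[, 1])),
            0.02)
})

test_that("membrane advection is forward Euler with a step guard", {
  gm <- small_annulus()
  mesh <- gm$membrane
  U0 <- matrix(0, nrow(mesh$V), 3)
  m0 <- advect_membrane(mesh, U0, 1)
  expect_identical(m0$V, mesh$V)
  Uc <- U0; Uc[, 3] <- 100
  m1 <- advect_membrane(mesh, Uc, 0.01, dx = 4)
  expect_equal(m1$V[, 3] - mesh$V[, 3], rep(1, nrow(mesh$V)))
  expect_identical(m1$tri, mesh$tri)
  expect_identical(m1$Vref, mesh$Vref)
  expect_error(advect_membrane(mesh, Uc, 1, dx = 4), "guard")
})
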