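# Tethering elements: placement counts, wall anchoring, natural lengths,
# the tension-only spring law and orientation angles.

test_that("attachment count is round(density * Lz) and reproducible", {
  gm <- small_annulus()
  mesh <- gm$membrane
  att <- place_tether_attachments(mesh, Lz = 453.9, density = 12 / 37.5,
                                  seed = 5)
  expect_length(att, 145L)  # 453.9 * 0.32 = 145.248
  expect_length(place_tether_attachments(mesh, Lz = 0.1, density = 1e-3), 0L)
  expect_error(place_tether_attachments(mesh, Lz = 1e6, density = 1),
               "vertices")
  expect_identical(att, place_tether_attachments(mesh, 453.9, 12 / 37.5, 5))
  att2 <- place_tether_attachments(mesh, 453.9, 12 / 37.5, seed = 6)
  expect_false(identical(att, att2))
})

test_that("annulus anchors are radial with exact gap natural lengths", {
  gm <- small_annulus()
  te <- place_tethers(gm, density = 12 / 37.5, seed = 3)
  expect_equal(length(te$attachment), round(12 / 37.5 * gm$Lz))
  # anchor on the wall cylinder, radially outward at the same (z, phi)
  rw <- sqrt(rowSums(te$x_w[, 1:2]^2))
  expect_lt(max(abs(rw - 48)), 0.01)
  expect_lt(max(abs(te$l0 - 28)), 0.01)
  expect_lt(max(abs(te$theta - pi / 2)), 0.01)
  xm <- gm$membrane$Vref[te$attachment, ]
  expect_lt(max(abs(te$x_w[, 3] - xm[, 3])), 0.01)
  # all tensions exactly zero in the no-flow reference
  tf <- tether_force(xm, te$x_w, te$k_sp, te$l0)
  expect_identical(max(tf$tension), 0)
})

test_that("axis point anchors to the smallest-z, smallest-azimuth candidate", {
  gm <- small_annulus()
  z0 <- gm$Lz * 24 / 192
  xw <- anchor_to_wall(matrix(c(0, 0, z0), 1, 3), gm$wall_field, gm$Lz)
  expect_lt(abs(xw[1, 3] - z0), 0.05)
  expect_gt(xw[1, 1], 47)       # phi ~ 0 side wins the tie
  expect_lt(abs(xw[1, 2]), 2)   # within one coarse-grid arc of phi = 0
})

test_that("wall protrusions produce inclined anchors on irregular walls", {
  gi <- small_irregular()
  te <- place_tethers(gi, density = 12 / 37.5, seed = 1)
  # anchors lie on the wall surface
  zf <- te$x_w[, 3]
  phi <- atan2(te$x_w[, 2], te$x_w[, 1])
  rw <- canaflow:::eval_field(gi$wall_field, zf, phi)
  expect_lt(max(abs(sqrt(rowSums(te$x_w[, 1:2]^2)) - rw)), 0.05)
  # inclination: spread of theta well away from uniformly radial
  expect_gt(sd(te$theta), 0.05)
  expect_gt(max(abs(te$theta - pi / 2)), 0.15)
  # natural lengths vary with the local gap
  expect_gt(diff(range(te$l0)), 1)
})

test_that("spring constant follows pi r^2 E / l0 exactly", {
  k <- spring_constant(71e6, 1, 40)
  expect_equal(k, 5.576327e-3 * 1e3, tolerance = 1e-6)  # N/m -> pN/nm
  expect_equal(spring_constant(71e6, 1, 80), k / 2, tolerance = 1e-12)
  expect_equal(spring_constant(71e6, 2, 40), 4 * k, tolerance = 1e-12)
  expect_error(spring_constant(71e6, 1, 0))
})

test_that("the spring is tension-only, continuous, directed toward the anchor", {
  x_w <- matrix(c(10, 0, 0), 1, 3)
  k <- spring_constant(71e6, 1, 40)
  # slack branch: shorter than l0
  slack <- tether_force(matrix(c(49, 0, 0), 1, 3), x_w, k, 40)
  expect_identical(slack$tension, 0)
  expect_identical(max(abs(slack$force)), 0)
  # taut branch: extension 8 nm at k = 5.576e-3 N/m -> ~44.6 pN toward x_w
  taut <- tether_force(matrix(c(58, 0, 0), 1, 3), x_w, k, 40)
  expect_equal(taut$tension, 44.61061, tolerance = 1e-5)
  expect_lt(taut$force[1, 1], 0)  # pulls back toward the anchor
  expect_equal(abs(taut$force[1, 1]), taut$tension, tolerance = 1e-12)
  # continuity at the natural length
  eps <- tether_force(matrix(c(50 + 1e-9, 0, 0), 1, 3), x_w, k, 40)
  expect_lt(eps$tension, 1e-8)
})

test_that("orientation angle spans [0, pi] with the stated conventions", {
  x_m <- matrix(0, 3, 3)
  x_w <- rbind(c(0, 0, 5), c(5, 0, 0), c(0, 0, -5))
  th <- orientation_angle(x_m, x_w)
  expect_equal(th, c(0, pi / 2, pi), tolerance = 1e-12)
})

test_that("zero-length tethers are rejected", {
  nl <- set_natural_lengths(rbind(c(0, 0, 0), c(1, 0, 0)),
                            rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_identical(nl$keep, c(FALSE, TRUE))
})
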