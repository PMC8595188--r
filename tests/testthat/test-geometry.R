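# Synthetic geometry: mesh/area oracles, roughness determinism,
# mirror-periodic extension and voxel classification.

test_that("annulus membrane area matches the closed-form cylinder area", {
  g <- make_annulus_geometry(52, 130, 227, target_edge = 4.7, dx = 5.1)
  L <- g$metadata$length
  expect_lt(abs(mesh_area(g$membrane) - 2 * pi * 52 * 227) / (2 * pi * 52 * 227),
            0.02)
  expect_lt(abs(mesh_area(g$membrane) - 2 * pi * 52 * L) / (2 * pi * 52 * L),
            0.005)
  r <- sqrt(rowSums(g$membrane$Vref[, 1:2]^2))
  expect_lt(max(abs(r - 52)), 0.1)
  edges <- sqrt(rowSums((g$membrane$Vref[g$membrane$tri[, 1], ] -
                         g$membrane$Vref[g$membrane$tri[, 2], ])^2))
  expect_lt(abs(median(edges) - 4.7) / 4.7, 0.25)
})

test_that("degenerate and unresolvable annuli are rejected", {
  expect_error(make_annulus_geometry(52, 52, 227), "smaller")
  expect_error(make_annulus_geometry(52, 58, 227, dx = 5.1), "2\\*dx")
})

test_that("zero roughness reproduces the annulus and seeds are reproducible", {
  ga <- make_annulus_geometry(25, 60, 70, target_edge = 8, dx = 5.1)
  g0 <- make_irregular_geometry(25, 60, 70, roughness_amplitude = 0,
                                target_edge = 8, dx = 5.1, seed = 1)
  expect_equal(g0$membrane$Vref, ga$membrane$Vref)
  expect_identical(g0$domain$labels, ga$domain$labels)

  g1 <- make_irregular_geometry(25, 60, 70, roughness_amplitude = 6,
                                target_edge = 8, dx = 5.1, seed = 1)
  g1b <- make_irregular_geometry(25, 60, 70, roughness_amplitude = 6,
                                 target_edge = 8, dx = 5.1, seed = 1)
  g2 <- make_irregular_geometry(25, 60, 70, roughness_amplitude = 6,
                                target_edge = 8, dx = 5.1, seed = 2)
  expect_identical(g1$membrane$Vref, g1b$membrane$Vref)
  expect_gt(max(abs(g1$membrane$Vref - g2$membrane$Vref)), 0)
})

test_that("roughness amplitude is realized as the surface RMS", {
  g <- make_irregular_geometry(52, 130, 150, roughness_amplitude = 10,
                               target_edge = 7, dx = 5.1, seed = 3)
  r <- sqrt(rowSums(g$membrane$Vref[, 1:2]^2))
  # vertex sample of the field; RMS close to the requested 10 nm
  expect_gt(sd(r), 6)
  expect_lt(sd(r), 14)
})

test_that("mirror extension doubles the period and is label-symmetric", {
  g <- make_annulus_geometry(20, 48, 60, target_edge = 8, dx = 4)
  gm <- mirror_extend(g)
  expect_equal(gm$Lz, 2 * g$metadata$length)
  expect_true(gm$mirrored)
  expect_error(mirror_extend(gm), "already")
  lab <- gm$domain$labels
  nz <- dim(lab)[3]
  expect_identical(lab, lab[, , nz:1])  # reflection about z = L
  # annulus stays axisymmetric: all membrane vertex radii equal
  r <- sqrt(rowSums(gm$membrane$Vref[, 1:2]^2))
  expect_lt(diff(range(r)), 1e-9)
  # irregular mirror: membrane vertices symmetric under z -> Lz - z
  gi <- mirror_extend(make_irregular_geometry(
    25, 60, 70, roughness_amplitude = 6, target_edge = 8, dx = 5.1, seed = 2))
  V <- gi$membrane$Vref
  zref <- (gi$Lz - V[, 3]) %% gi$Lz
  key <- paste(round(V[, 1], 6), round(V[, 2], 6), round(zref %% gi$Lz, 6))
  key0 <- paste(round(V[, 1], 6), round(V[, 2], 6), round(V[, 3], 6))
  expect_setequal(key, key0)
})

test_that("voxel classification reproduces the analytic annulus volume", {
  g <- make_annulus_geometry(52, 130, 227, target_edge = 7, dx = 5.1)
  gm <- mirror_extend(g)
  dom <- gm$domain
  n_peri <- sum(dom$labels == 1L)
  vol <- pi * (130^2 - 52^2) * gm$Lz
  expect_lt(abs(n_peri * dom$dx^3 - vol) / vol, 0.05)
  n_intra <- sum(dom$labels == 2L)
  expect_lt(abs(n_intra * dom$dx^3 - pi * 52^2 * gm$Lz) / (pi * 52^2 * gm$Lz),
            0.05)
})

test_that("voxel volumes converge to the analytic value as dx shrinks", {
  err <- sapply(c(4, 2, 1), function(dx) {
    g <- make_annulus_geometry(20, 48, 40, target_edge = 10, dx = dx)
    vol <- pi * (48^2 - 20^2) * g$metadata$length
    abs(sum(g$domain$labels == 1L) * dx^3 - vol) / vol
  })
  # observed order >= 1 between the coarsest and finest resolution
  order_est <- log(err[1] / err[3]) / log(4)
  expect_gt(order_est, 0.8)
})

test_that("domain validation accepts tubes and rejects blocked columns", {
  gm <- small_annulus()
  expect_true(validate_domain(gm$domain))
  dom <- gm$domain
  dom$labels[, , 3] <- ifelse(dom$labels[, , 3] == 1L, 0L, dom$labels[, , 3])
  expect_error(validate_domain(dom), "span|connected")
})

test_that("mirror-consistent domains stay valid and periodic", {
  gi <- small_irregular()
  expect_true(validate_domain(gi$domain))
  expect_true(gi$domain$periodic[3])
  expect_false(any(gi$domain$periodic[1:2]))
})
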