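# Skalak membrane: material relations, element kinematics, energy law,
# force assembly consistency and principal strains.

test_that("material relations nu_s = C/(C+1), E = 2Gs(1+nu_s)/t hold", {
  mat <- membrane_material(E = 4471, t = 10, C = 10)
  expect_equal(mat$nu_s, 10 / 11, tolerance = 1e-15)
  expect_equal(mat$Gs * 1e-3, 1.1710e-5, tolerance = 1e-4)   # N/m
  expect_equal(canaflow:::material_roundtrip_E(mat), 4471, tolerance = 1e-12)
  expect_gt(membrane_material(C = 1e6)$nu_s, 0.999999)
})

test_that("element kinematics reproduce closed-form stretch states", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 1.1, 0))
  id <- element_kinematics(ref, ref)
  expect_equal(id$lambda, c(1, 1), tolerance = 1e-12)
  expect_equal(id$I1, 0, tolerance = 1e-12)
  expect_equal(id$I2, 0, tolerance = 1e-12)
  expect_equal(id$max_principal, 0, tolerance = 1e-12)

  eq <- element_kinematics(ref, ref * 1.1)
  expect_equal(eq$I1, 0.42, tolerance = 1e-12)
  expect_equal(eq$I2, 0.4641, tolerance = 1e-12)

  uni <- ref
  uni[, 1] <- uni[, 1] * 1.1
  ek <- element_kinematics(ref, uni)
  expect_equal(ek$max_principal, 0.105, tolerance = 1e-12)

  comp <- element_kinematics(ref, ref * 0.9)
  expect_equal(comp$max_principal, (0.81 - 1) / 2, tolerance = 1e-12)
})

test_that("Skalak energy density matches Eq-level hand values", {
  expect_identical(skalak_energy(0, 0, 1, 10), 0)
  expect_equal(skalak_energy(0.42, 0.4641, 1, 10), 0.560522, tolerance = 1e-6)
  # positive in a neighborhood of the reference
  set.seed(1)
  lam <- matrix(1 + rnorm(40, sd = 0.02), 20, 2)
  I1 <- lam[, 1]^2 + lam[, 2]^2 - 2
  I2 <- lam[, 1]^2 * lam[, 2]^2 - 1
  expect_true(all(skalak_energy(I1, I2, 1, 10) >= 0))
})

test_that("nodal forces are the exact negative energy gradient", {
  gm <- small_annulus()
  mesh <- gm$membrane
  mat <- membrane_material()
  f0 <- membrane_nodal_forces(mesh, mat)
  expect_lt(max(abs(f0$force)), 1e-12)
  # rigid translation leaves forces at zero
  ft <- membrane_nodal_forces(mesh, mat, mesh$Vref +
                                rep(c(3, -2, 5), each = nrow(mesh$Vref)))
  expect_lt(max(abs(ft$force)), 1e-12)
  # finite-difference oracle on a randomly perturbed configuration
  set.seed(11)
  V <- mesh$Vref + matrix(rnorm(length(mesh$Vref), sd = 0.3), ncol = 3)
  fr <- membrane_nodal_forces(mesh, mat, V)
  en <- function(V) membrane_nodal_forces(mesh, mat, V)$energy
  h <- 1e-4
  idx <- cbind(sample(nrow(V), 10), sample(3, 10, replace = TRUE))
  scale <- max(abs(fr$force))
  for (k in seq_len(nrow(idx))) {
    Vp <- V; Vm <- V
    Vp[idx[k, 1], idx[k, 2]] <- Vp[idx[k, 1], idx[k, 2]] + h
    Vm[idx[k, 1], idx[k, 2]] <- Vm[idx[k, 1], idx[k, 2]] - h
    fd <- -(en(Vp) - en(Vm)) / (2 * h)
    expect_lt(abs(fd - fr$force[idx[k, 1], idx[k, 2]]) / scale, 1e-4)
  }
  # internal forces are self-equilibrated
  expect_lt(max(abs(colSums(fr$force))), 1e-10 * scale)
})

test_that("strain measures are objective under rigid rotation", {
  gm <- small_annulus()
  mesh <- gm$membrane
  set.seed(4)
  V <- mesh$Vref + matrix(rnorm(length(mesh$Vref), sd = 0.2), ncol = 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s1 <- membrane_strain_state(mesh, V)
  s2 <- membrane_strain_state(mesh, V %*% t(R))
  expect_lt(max(abs(s1$max_principal - s2$max_principal)), 1e-12)
  expect_lt(max(abs(s1$I1 - s2$I1)), 1e-12)
  expect_lt(max(abs(s1$I2 - s2$I2)), 1e-12)
})

test_that("strain field is uniform under a prescribed affine stretch", {
  # open (unmirrored) tube so a global scaling is seam-consistent
  g <- make_annulus_geometry(20, 48, 60, target_edge = 8, dx = 4)
  mesh <- g$membrane
  expect_true(all(abs(max_principal_strain_field(mesh)) < 1e-14))
  # equal principal stretches: eigenvalue splitting is sqrt(eps)-limited
  s <- max_principal_strain_field(mesh, mesh$Vref * 1.1)
  expect_equal(s, rep(0.105, length(s)), tolerance = 1e-6)
  s2 <- max_principal_strain_field(mesh, mesh$Vref * 0.9)
  expect_equal(s2, rep(-0.095, length(s2)), tolerance = 1e-6)
})

test_that("degenerate current elements are flagged and excluded", {
  g <- make_annulus_geometry(20, 48, 60, target_edge = 8, dx = 4)
  mesh <- g$membrane
  V <- mesh$Vref
  tri1 <- mesh$tri[1, ]
  V[tri1[2], ] <- V[tri1[1], ]
  V[tri1[3], ] <- V[tri1[1], ]
  expect_warning(res <- membrane_nodal_forces(mesh, membrane_material(), V),
                 "degenerate")
  expect_gte(res$n_degenerate, 1)
  s <- membrane_strain_state(mesh, V)
  expect_true(is.na(s$max_principal[1]))
})
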