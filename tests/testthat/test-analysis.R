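# Strain/tension post-processing: near-far partition, concentration
# ratio, tension statistics, angle correlation and ensemble pooling.

test_that("near/far partition matches a brute-force distance check", {
  gm <- small_annulus()
  te <- place_tethers(gm, density = 2 / 37.5, seed = 9)
  part <- partition_near_far(gm$membrane, te, radius = 10.2)
  # independent brute force: loop over elements and attachments
  ctr <- canaflow:::mesh_centroids(gm$membrane)
  att <- gm$membrane$Vref[te$attachment, , drop = FALSE]
  Lz <- gm$Lz
  near_bf <- logical(nrow(ctr))
  for (e in seq_len(nrow(ctr))) {
    for (a in seq_len(nrow(att))) {
      dz <- abs(ctr[e, 3] - att[a, 3])
      dz <- min(dz %% Lz, Lz - dz %% Lz)
      d <- sqrt((ctr[e, 1] - att[a, 1])^2 + (ctr[e, 2] - att[a, 2])^2 + dz^2)
      if (d <= 10.2) { near_bf[e] <- TRUE; break }
    }
  }
  expect_identical(part$near, near_bf)
  expect_equal(part$n_near + part$n_far, nrow(ctr))
})

test_that("partition guards: zero radius is all FAR, huge radius rejected", {
  gm <- small_annulus()
  te <- place_tethers(gm, density = 2 / 37.5, seed = 9)
  p0 <- partition_near_far(gm$membrane, te, radius = 0)
  expect_identical(p0$n_near, 0L)
  expect_error(partition_near_far(gm$membrane, te, radius = 1e6), "FAR")
})

test_that("strain concentration ratio behaves on constructed fields", {
  gm <- small_annulus()
  te <- place_tethers(gm, density = 2 / 37.5, seed = 9)
  part <- partition_near_far(gm$membrane, te, radius = 10.2)
  m <- length(part$near)
  expect_equal(strain_concentration_ratio(rep(0.3, m), part)$ratio, 1)
  field <- ifelse(part$near, 2, 1)
  expect_equal(strain_concentration_ratio(field, part)$ratio, 2)
  expect_message(
    r0 <- strain_concentration_ratio(rep(0, m), part), "undefined")
  expect_true(is.na(r0$ratio))
})

test_that("tension statistics normalize by the nonzero median", {
  ts <- tension_statistics(rep(0.4, 10))
  expect_equal(ts$median_nonzero, 0.4)
  expect_equal(ts$normalized, rep(1, 10))
  expect_equal(ts$taut_fraction, 1)
  expect_message(ts0 <- tension_statistics(rep(0, 5)), "slack")
  expect_equal(ts0$taut_fraction, 0)
  expect_true(is.na(ts0$median_nonzero))
  mix <- c(0, 0, 1, 2, 3, 50)
  tsm <- tension_statistics(mix)
  expect_equal(tsm$median_nonzero, 2.5)
  expect_equal(tsm$taut_fraction, 4 / 6)
  expect_equal(sum(tsm$counts), 4L)
})

test_that("tension-angle correlation is exact for monotone constructions", {
  th <- seq(0.1, 3, length.out = 20)
  tva <- tension_vs_angle(th, th)
  expect_equal(tva$spearman, 1)
  tvn <- tension_vs_angle(th, rev(th))
  expect_equal(tvn$spearman, -1)
  few <- tension_vs_angle(th, c(1, 2, rep(0, 18)))
  expect_true(is.na(few$spearman))
})

# minimal fake result bundles over a shared mesh/tether set
fake_bundle <- function(gm, te, strain, tension, seed = 1, direction = 1,
                        cfg = sim_config()) {
  structure(list(config = cfg, direction = direction, te_seed = seed,
                 mesh = gm$membrane, tethers = te, tension = tension,
                 theta = te$theta, taut = tension > 0, strain = strain),
            class = "canaflow_result")
}

test_that("ensemble pooling is consistent and bounded by per-run ratios", {
  gm <- small_annulus()
  te <- place_tethers(gm, density = 2 / 37.5, seed = 9)
  part <- partition_near_far(gm$membrane, te, 10.2)
  m <- length(part$near)
  nt <- length(te$attachment)
  mk <- function(scale) fake_bundle(gm, te,
    ifelse(part$near, 0.02 * scale, 0.01), rep(0.1, nt))
  same <- replicate(3, mk(1.5), simplify = FALSE)
  s_same <- ensemble_summary(same)
  expect_equal(s_same$pooled$ratio, s_same$per_run$ratio[1])
  one <- ensemble_summary(list(mk(2)))
  expect_equal(one$pooled$ratio, 4)  # 0.02*2 / 0.01
  set.seed(8)
  varied <- lapply(c(1.2, 1.6, 2.4), mk)
  sv <- ensemble_summary(varied)
  expect_gte(sv$pooled$ratio, min(sv$per_run$ratio))
  expect_lte(sv$pooled$ratio, max(sv$per_run$ratio))
})

test_that("mixed configurations are rejected as non-comparable", {
  gm <- small_annulus()
  te <- place_tethers(gm, density = 2 / 37.5, seed = 9)
  b1 <- fake_bundle(gm, te, rep(0.1, nrow(gm$membrane$tri)),
                    rep(0.1, length(te$attachment)))
  b2 <- fake_bundle(gm, te, rep(0.1, nrow(gm$membrane$tri)),
                    rep(0.1, length(te$attachment)),
                    cfg = sim_config(fluid = list(k_p = 14)))
  expect_error(ensemble_summary(list(b1, b2)), "comparable")
})
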