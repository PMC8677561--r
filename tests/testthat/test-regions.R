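test_that("structural labels form the expected shells around a spherical lesion", {
  d <- c(40, 40, 40); vs <- c(2, 2, 2); ctr <- d * vs / 2
  brain <- metabpet:::ellipsoid_mask(d, vs, ctr, c(38, 38, 38))
  core <- metabpet:::sphere_mask(d, vs, ctr, 10) & brain
  pen <- metabpet:::sphere_mask(d, vs, ctr, 15) & brain & !core
  lab <- build_structural_labels(core, pen, brain, vs, cuff_mm = 10)
  cx <- metabpet:::voxel_centres(d[1], 2)
  dist <- sqrt(outer(outer((cx - ctr[1])^2, (cx - ctr[2])^2, "+"),
                     (cx - ctr[3])^2, "+"))
  peri_r <- range(dist[lab$labels == 3L])
  # peri-penumbral shell spans r in (15, 25] within one voxel of discretization
  expect_gt(peri_r[1], 15 - 2)
  expect_lt(peri_r[2], 25 + 2)
  # labels partition the brain: volume conservation
  expect_true(all((lab$labels > 0) == brain))
  expect_equal(sum(lab$labels %in% 1:4), sum(brain))
})

test_that("degenerate lesion inputs are handled deliberately", {
  d <- c(16, 16, 16); vs <- c(2, 2, 2)
  brain <- metabpet:::ellipsoid_mask(d, vs, d * vs / 2, c(14, 14, 14))
  none <- array(FALSE, d)
  lab <- build_structural_labels(none, none, brain, vs)
  expect_true(all(lab$labels[brain] == 4L)) # all normal-appearing
  core <- metabpet:::sphere_mask(d, vs, d * vs / 2, 5) & brain
  lab0 <- build_structural_labels(core, none, brain, vs, cuff_mm = 0)
  expect_equal(sum(lab0$labels == 3L), 0) # zero cuff: no peri-penumbra
  expect_warning(build_structural_labels(core, core, brain, vs), "overlap")
  out <- array(FALSE, d); out[1, 1, 1] <- TRUE
  expect_error(build_structural_labels(out, none, brain, vs), "inside")
})

test_that("the catheter cuff is a brain-clipped sphere of the right volume", {
  d <- c(24, 24, 24); vs <- c(2, 2, 2); ctr <- d * vs / 2
  brain <- cube_mask(d)
  cuff <- catheter_cuff_mask(ctr, brain, vs, 10)
  vol <- sum(cuff) * prod(vs) / 1000
  shell <- 4 * pi * 100 * 2 / 1000 # one-voxel shell on a 10 mm sphere
  expect_lt(abs(vol - 4 / 3 * pi * 1000 / 1000), shell)
  # zero radius keeps only the tip voxel
  expect_equal(sum(catheter_cuff_mask(ctr, brain, vs, 0)), 1)
  # a tip near the mask edge is clipped strictly smaller
  edge <- c(3, ctr[2], ctr[3])
  expect_lt(sum(catheter_cuff_mask(edge, brain, vs, 10)), sum(cuff))
  brain_small <- array(FALSE, d); brain_small[10:14, 10:14, 10:14] <- TRUE
  expect_error(catheter_cuff_mask(c(1, 1, 1), brain_small, vs, 10), "outside")
})

test_that("the hotspot threshold is the normal-appearing mean plus z SDs", {
  d <- c(10, 10, 10)
  k3 <- array(0.029, d)
  normal <- cube_mask(d)
  # constructed moments: mean 0.029, population SD 0.010
  k3[1:500] <- 0.019; k3[501:1000] <- 0.039
  hs <- k3_hotspot(k3, normal, cube_mask(d), c(2, 2, 2))
  expect_equal(hs$threshold, 0.029 + 1.96 * 0.010, tolerance = 1e-12)
  expect_warning(k3_hotspot(array(0.03, d), normal, cube_mask(d), c(2, 2, 2)),
                 "zero SD")
})

test_that("hotspot flagging matches the Gaussian upper tail on a null field", {
  set.seed(11)
  d <- c(24, 24, 24)
  k3 <- array(rnorm(prod(d), 0.029, 0.01), d)
  hs <- k3_hotspot(k3, cube_mask(d), cube_mask(d), c(2, 2, 2))
  frac <- sum(hs$mask) / prod(d)
  p <- pnorm(1.96, lower.tail = FALSE)
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / prod(d)))
})

test_that("the lesion-excluded hotspot variant removes lesion voxels", {
  set.seed(12)
  d <- c(16, 16, 16)
  k3 <- array(rnorm(prod(d), 0.029, 0.01), d)
  lesion <- array(FALSE, d); lesion[1:8, , ] <- TRUE
  k3[lesion] <- 0.2
  normal <- !lesion
  hs_all <- k3_hotspot(k3, normal, cube_mask(d), c(2, 2, 2))
  hs_ex <- k3_hotspot(k3, normal, cube_mask(d), c(2, 2, 2),
                      exclude_mask = lesion)
  expect_true(hs_all$volume_ml > hs_ex$volume_ml)
  expect_equal(sum(hs_ex$mask & lesion), 0)
})

test_that("the critical OEF threshold obeys its venous-reserve algebra", {
  bl <- blood_chemistry(Hb = 13, SaO2 = 0.98, PaO2 = 13)
  crit <- critical_oef_threshold(bl, sv_crit = 0.50, pv_kpa = 4)
  expect_equal(as.numeric(crit), 0.493, tolerance = 1e-3)
  expect_equal(attr(crit, "strategy"), "venous-reserve")
  # critical venous saturation equal to arterial: only dissolved O2 remains
  near0 <- critical_oef_threshold(bl, sv_crit = bl$SaO2, pv_kpa = bl$PaO2)
  expect_lt(as.numeric(near0), 0.01)
  # lowering the critical venous saturation raises the threshold
  crits <- vapply(c(0.7, 0.6, 0.5, 0.4), function(s) {
    as.numeric(critical_oef_threshold(bl, sv_crit = s))
  }, numeric(1))
  expect_true(all(diff(crits) > 0))
  # demand-supply strategy is per-voxel
  ds <- critical_oef_threshold(bl, strategy = "demand-supply",
                               cmro2_crit = 40, cbf = c(20, 40))
  expect_equal(as.numeric(ds), 40 / (c(20, 40) * arterial_o2_content(bl)))
})

test_that("ischaemic brain volume responds monotonically to its threshold", {
  d <- c(16, 16, 16); vs <- c(2, 2, 2)
  oef <- array(0.42, d)
  expect_equal(ischaemic_brain_volume(oef, 0.49, cube_mask(d), vs)$volume_ml, 0)
  set.seed(5)
  oef <- array(runif(prod(d), 0.2, 0.7), d)
  vols <- vapply(seq(0.3, 0.65, 0.05), function(cr) {
    ischaemic_brain_volume(oef, cr, cube_mask(d), vs)$volume_ml
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
  expect_error(ischaemic_brain_volume(oef, 1.2, cube_mask(d), vs), "0, 1")
})

test_that("Dice overlap matches analytic values and handles empty masks", {
  d <- c(10, 10, 10); vs <- c(2, 2, 2)
  a <- array(FALSE, d); a[1:5, , ] <- TRUE
  expect_equal(mask_overlap(a, a, vs)$dice, 1)
  b <- array(FALSE, d); b[6:10, , ] <- TRUE
  ov <- mask_overlap(a, b, vs)
  expect_equal(ov$dice, 0)
  expect_equal(ov$overlap_ml, 0)
  e <- array(FALSE, d)
  ov0 <- mask_overlap(e, e, vs)
  expect_equal(ov0$dice, 0)
  expect_true(ov0$both_empty)
  # overlap bounded by the smaller input
  set.seed(8)
  x <- array(runif(prod(d)) < 0.3, d)
  y <- array(runif(prod(d)) < 0.5, d)
  oxy <- mask_overlap(x, y, vs)
  expect_lte(oxy$overlap_ml, min(oxy$volume_a_ml, oxy$volume_b_ml))
  expect_equal(oxy$dice, mask_overlap(y, x, vs)$dice)
})

test_that("region tables reproduce constant maps exactly and mark empty regions", {
  d <- c(12, 12, 12); vs <- c(2, 2, 2)
  brain <- cube_mask(d)
  labels <- array(4L, d); labels[1:3, , ] <- 1L # core + normal only
  lab <- region_labels(labels, vs)
  mk <- function(v) array(v, d)
  maps <- physio_maps(list(K1 = mk(0.091), k3 = mk(0.029), CBF = mk(28.6),
                           OEF = mk(0.421)), vs, brain)
  rt <- region_table(maps, lab)
  expect_equal(rt$median[rt$region == "normal_appearing" & rt$variable == "K1"],
               0.091)
  expect_equal(rt$median[rt$region == "core" & rt$variable == "OEF"], 42.1)
  expect_true(all(is.na(rt$median[rt$region == "penumbra"])))
  expect_equal(rt$n_voxels[rt$region == "penumbra"][1], 0L)
  # invariance to voxel ordering: shuffling voxels leaves medians unchanged
  set.seed(4)
  km <- array(rnorm(prod(d), 0.09, 0.01), d)
  m1 <- physio_maps(list(K1 = km), vs, brain)
  perm <- sample(prod(d))
  lab_p <- region_labels(array(labels[perm], d), vs)
  m2 <- physio_maps(list(K1 = array(km[perm], d)), vs, brain)
  r1 <- region_table(m1, lab)
  r2 <- region_table(m2, lab_p)
  expect_equal(r1$median, r2$median)
})
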