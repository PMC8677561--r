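test_that("a zero-SD phantom reproduces its configured means exactly", {
  rp <- region_param_defaults()
  rp$sd <- 0
  ph <- build_phantom_maps(
    phantom_spec(dim = c(24, 24, 24), region_params = rp,
                 hotspot_volume_ml = 0, high_oef_volume_ml = 0,
                 core_radius_mm = 6, penumbra_radius_mm = 9, cuff_mm = 6,
                 lesion_centre_mm = c(24, 24, 24)),
    seed = 1
  )
  rt <- region_table(ph$maps, ph$labels)
  for (rg in c("core", "normal_appearing")) {
    for (v in c("K1", "k3", "CBF")) {
      expect_equal(rt$median[rt$region == rg & rt$variable == v],
                   rp$mean[rp$region == rg & rp$variable == v],
                   tolerance = 1e-12)
      expect_equal(rt$iqr[rt$region == rg & rt$variable == v], 0)
    }
  }
})

test_that("phantom maps satisfy the macro identities exactly", {
  ph <- build_phantom_maps(phantom_spec(dim = c(24, 24, 24),
                                        lesion_centre_mm = c(30, 24, 24),
                                        hotspot_volume_ml = 2,
                                        hotspot_centre_mm = c(16, 24, 24),
                                        high_oef_volume_ml = 2,
                                        high_oef_centre_mm = c(24, 33, 24)),
                           seed = 3)
  m <- ph$maps$maps
  sel <- ph$maps$mask
  expect_equal(m$Ki[sel], (m$K1 * m$k3 / (m$k2 + m$k3))[sel], tolerance = 1e-12)
  expect_true(all(m$Ki[sel] <= m$K1[sel] + 1e-12))
  expect_equal(m$OEF[sel], (m$CMRO2 / (m$CBF * ph$truth$cao2))[sel],
               tolerance = 1e-12)
  lc <- m$LC[sel]
  expect_true(all(lc >= ph$truth$lc$phi - 1e-12 & lc <= ph$truth$lc$tau + 1e-12))
  # masked voxels carry NA and never reach summaries
  expect_true(all(is.na(m$K1[!sel])))
})

test_that("the default phantom preserves the regional CBF ordering", {
  ph <- build_phantom_maps(phantom_spec(), seed = 2)
  rt <- region_table(ph$maps, ph$labels)
  cbf <- setNames(rt$median[rt$variable == "CBF"],
                  rt$region[rt$variable == "CBF"])
  expect_true(cbf[["core"]] < cbf[["penumbra"]])
  expect_true(cbf[["penumbra"]] < cbf[["peri_penumbra"]])
  expect_true(cbf[["peri_penumbra"]] < cbf[["normal_appearing"]])
})

test_that("planted hotspots are recovered by the k3 hotspot detector", {
  ph <- build_phantom_maps(phantom_spec(), seed = 4)
  hs <- k3_hotspot(ph$maps$maps$k3, ph$labels$labels == 4L, ph$maps$mask,
                   ph$maps$voxel_size_mm)
  r <- metabpet:::radius_for_volume_ml(ph$truth$hotspot_volume_ml)
  shell_ml <- 4 * pi * r^2 * 2 / 1000
  expect_lt(abs(hs$volume_ml - ph$truth$hotspot_volume_ml), shell_ml)
  # the recovered mask is essentially the planted sphere
  expect_gt(mask_overlap(hs$mask, ph$truth$hotspot_mask,
                         ph$maps$voxel_size_mm)$dice, 0.9)
})

test_that("a hotspot larger than the brain is rejected", {
  expect_error(build_phantom_maps(phantom_spec(dim = c(12, 12, 12),
                                               hotspot_volume_ml = 500),
                                  seed = 1), "exceeds")
})

test_that("TAC noise is seeded, proportional and reproducible", {
  tac <- simulate_tac_irreversible(fdg_params(0.09, 0.13, 0.04),
                                   fix_aif, fix_sched)
  expect_equal(add_tac_noise(tac, 0), tac)
  n1 <- add_tac_noise(tac, 0.05, seed = 99)
  n2 <- add_tac_noise(tac, 0.05, seed = 99)
  expect_equal(n1, n2)
  # empirical coefficient of variation matches the requested scale
  late <- nrow(tac) # a high-count frame
  reps <- vapply(1:1000, function(i) {
    add_tac_noise(tac$value[late], 0.05, seed = 5000 + i)
  }, numeric(1))
  expect_equal(sd(reps) / mean(reps), 0.05, tolerance = 0.01)
  cnt <- add_tac_noise(tac, 0.05, model = "count", seed = 1)
  expect_equal(nrow(cnt), nrow(tac))
})

test_that("cohorts carry the configured structure and dependences", {
  coh <- simulate_cohort(cohort_spec(), seed = 10)
  expect_equal(nrow(coh), 34 + 9)
  expect_equal(sum(coh$group == "patient"), 34)
  expect_equal(as.vector(table(coh$epoch)[c("early", "intermediate", "late")]),
               c(12L, 8L, 14L))
  expect_true(all(is.na(coh$epoch[coh$group == "volunteer"])))
  expect_equal(sum(!is.na(coh$md_glucose)), 10)
  # LPR is computed from lactate and pyruvate with unit conversion
  md <- coh[!is.na(coh$md_glucose), ]
  expect_equal(md$md_lpr, 1000 * md$md_lactate / md$md_pyruvate)
  # plasma glucose centred near the configured group medians
  expect_equal(median(coh$plasma_glucose[coh$group == "patient"]), 5.8,
               tolerance = 0.15 * 5.8)
  expect_equal(median(coh$plasma_glucose[coh$group == "volunteer"]), 4.6,
               tolerance = 0.15 * 4.6)
})

test_that("glucose coupling drives the expected rank correlations", {
  # null coupling: rho centred on zero
  rhos0 <- vapply(1:40, function(s) {
    coh <- simulate_cohort(cohort_spec(k3_coupling = 0), seed = 100 + s)
    md <- coh[!is.na(coh$md_glucose), ]
    md$k3 <- cohort_regional(md, "k3")
    spearman_assoc(md, md_glucose, k3)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos0)), 0.15)
  # strong negative coupling: negative rho recovered in >= 90% of seeds
  rhos1 <- vapply(1:40, function(s) {
    coh <- simulate_cohort(cohort_spec(), seed = 200 + s)
    md <- coh[!is.na(coh$md_glucose), ]
    md$k3 <- cohort_regional(md, "k3")
    spearman_assoc(md, md_glucose, k3)$rho
  }, numeric(1))
  expect_gte(mean(rhos1 < 0), 0.9)
})

test_that("microdialysis glucose rises with plasma glucose and is significant", {
  hits <- vapply(1:50, function(s) {
    coh <- simulate_cohort(cohort_spec(), seed = 300 + s)
    md <- coh[!is.na(coh$md_glucose), ]
    out <- spearman_assoc(md, plasma_glucose, md_glucose)
    out$rho > 0 && out$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
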