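test_that("diaphragm apex of a flat-based lung is its base plane", {
  # base slice 11 (1-based) at 3-mm slices, origin 0: z = 30 mm
  labels <- array(0L, c(20, 20, 20))
  labels[4:16, 4:16, 11:18] <- 2L
  mask <- region_mask(labels, c(4, 4, 3))
  expect_equal(find_diaphragm_apex(mask, "right_lung"), 30)
  expect_error(find_diaphragm_apex(mask, "left_lung"), "empty")
})

test_that("diaphragm apex finds the top of a dome indenting the lung base", {
  # lung slab with a hemispherical dome carved from below, peaking at z = 51
  d <- c(40, 40, 30)
  sp <- c(3, 3, 3)
  xs <- axis_coords(d[1], sp[1]); ys <- axis_coords(d[2], sp[2])
  zs <- axis_coords(d[3], sp[3])
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  lung <- X >= 15 & X <= 100 & Y >= 15 & Y <= 100 & Z >= 9 & Z <= 81
  dome <- (X - 57)^2 + (Y - 57)^2 + (Z - 9)^2 <= 42^2   # apex 9 + 42 = 51
  labels <- array(0L, d)
  labels[lung & !dome] <- 2L
  mask <- region_mask(labels, sp)
  apex <- find_diaphragm_apex(mask, "right_lung")
  expect_lte(abs(apex - 51), sp[3])
})

test_that("phantom diaphragm apex is detected within a slice of the analytic dome", {
  ph <- local_coarse_phantom()
  apex_r <- find_diaphragm_apex(ph$labels, "right_lung")
  expect_lte(abs(apex_r - ph$manifest$apex_z_mm[["right"]]), ph$labels$spacing[3])
})

test_that("exclusion-zone cutoffs sit margin above each apex and retain strictly-above voxels", {
  # 3-mm slices with centers at 1.5 + 3k mm; flat bases at 30 (right) / 45 (left)
  d <- c(30, 20, 40)
  labels <- array(0L, d)
  labels[3:13, 5:15, 11:36] <- 2L    # right base center z = 1.5 + 3*10 = 31.5
  labels[17:27, 5:15, 16:36] <- 1L   # left base center z = 46.5
  mask <- region_mask(labels, c(4, 4, 3), origin = c(0, 0, 1.5))
  zone <- apply_exclusion_zone(mask, margin_mm = 15,
                               apex_z = list(right_lung = 30, left_lung = 45))
  expect_equal(unname(zone$cutoff_z[["right_lung"]]), 45)
  expect_equal(unname(zone$cutoff_z[["left_lung"]]), 60)
  # first retained slice center strictly above the cutoff: 46.5 (right)
  right_kept <- mask_array(zone$mask_above, "right_lung")
  zs <- axis_coords(d[3], 3, 1.5)
  kept_z <- zs[apply(right_kept, 3, any)]
  expect_equal(min(kept_z), 46.5)
  left_kept <- mask_array(zone$mask_above, "left_lung")
  expect_equal(min(zs[apply(left_kept, 3, any)]), 61.5)
  # explicit override is passed through unchanged
  expect_equal(unname(zone$apex_z[["right_lung"]]), 30)
})

test_that("margin 0 retains exactly the voxels strictly above the apex plane", {
  labels <- array(0L, c(10, 10, 12))
  labels[2:9, 2:9, 4:10] <- 2L
  labels[2:9, 2:9, 3:10] <- labels[2:9, 2:9, 3:10]  # base center z = 9 (slice 4, dz 3)
  mask <- region_mask(labels, c(4, 4, 3))
  zone <- apply_exclusion_zone(mask, margin_mm = 0,
                               apex_z = list(right_lung = 9, left_lung = NA))
  kept <- mask_array(zone$mask_above, "right_lung")
  zs <- axis_coords(12, 3)
  zc <- array(rep(zs, each = 100), c(10, 10, 12))
  expect_identical(kept, mask_array(mask, "right_lung") & zc > 9)
})

test_that("exclusion zone is a subset of the lung, monotone in the margin, and can fail loudly", {
  ph <- local_coarse_phantom()
  z5 <- apply_exclusion_zone(ph$labels, margin_mm = 5)
  z15 <- apply_exclusion_zone(ph$labels, margin_mm = 15)
  for (side in c("left_lung", "right_lung")) {
    m5 <- mask_array(z5$mask_above, side)
    m15 <- mask_array(z15$mask_above, side)
    expect_true(all(mask_array(ph$labels, side)[m5]))   # subset of lung
    expect_true(all(m5[m15]))                            # larger margin keeps less
  }
  expect_error(apply_exclusion_zone(ph$labels, margin_mm = 500),
               "entire")
})

test_that("background count density is total counts over VOI volume", {
  spect <- voxel_volume(array(2, c(10, 10, 10)), c(1, 1, 1), "SPECT")
  voi <- array(TRUE, c(10, 10, 10))
  expect_equal(background_count_density(spect, voi), 2000)
  spect0 <- voxel_volume(array(0, c(10, 10, 10)), c(1, 1, 1), "SPECT")
  expect_equal(background_count_density(spect0, voi), 0)
  expect_error(background_count_density(spect, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("phantom background VOI recovers the generator blood-pool density", {
  ph <- generate_phantom(coarse_spec(noise = "poisson", seed = 5))
  d <- background_count_density(ph$spect, ph$labels)
  # soft tissue at 40 HU carries (1040/1000)/1.04 = 1 of the nominal density
  truth <- ph$manifest$bg_count_density
  n <- ph$manifest$n_voxels[["background_voi"]]
  lam <- truth * voxel_cm3(ph$spect)
  se <- sqrt(lam * n) / (n * voxel_cm3(ph$spect))
  expect_lt(abs(d - truth), 4 * se)
})

test_that("the cylindrical background VOI builder validates soft tissue", {
  ph <- local_coarse_phantom()
  voi <- background_voi_cylinder(ph$ct, c(230, 275), 10, c(24, 120), ct = ph$ct)
  expect_true(any(voi))
  expect_true(all(ph$ct$data[voi] == 40))
  expect_error(
    background_voi_cylinder(ph$ct, c(188, 185), 10, c(150, 250), ct = ph$ct),
    "soft tissue"
  )
  expect_error(background_voi_cylinder(ph$ct, c(230, 275), 10, c(5000, 6000)),
               "outside")
})

test_that("lung count correction follows the tissue-volume arithmetic chain", {
  r <- corrected_lung_counts(10000, 520, 2, 2000, 2800)
  expect_equal(r$tissue_vol_cm3, 500)
  expect_equal(r$bg_counts, 1000)
  expect_equal(r$corrected_above, 9000)
  expect_equal(r$mean_count_density, 4.5)
  expect_equal(r$total_lung_counts, 12600)
  # zero background: identity up to the volume-ratio extrapolation
  r0 <- corrected_lung_counts(10000, 520, 0, 2000, 2800)
  expect_equal(r0$corrected_above, 10000)
  expect_equal(r0$total_lung_counts, 10000 * 2800 / 2000)
  expect_error(corrected_lung_counts(1, 1, 1, 0, 1), "positive")
  expect_warning(rneg <- corrected_lung_counts(100, 5200, 2, 2000, 2800), "clamped")
  expect_equal(rneg$corrected_above, 0)
})

test_that("lung count correction is homogeneous of degree 1 in counts", {
  set.seed(9)
  for (rep in 1:5) {
    raw <- runif(1, 1e3, 1e5); mass <- runif(1, 300, 900)
    bg <- runif(1, 0, 5); va <- runif(1, 1000, 3000); vt <- va * runif(1, 1, 2)
    c0 <- runif(1, 0.1, 10)
    r1 <- corrected_lung_counts(raw, mass, bg, va, vt)
    r2 <- corrected_lung_counts(c0 * raw, mass, c0 * bg, va, vt)
    expect_equal(r2$total_lung_counts, c0 * r1$total_lung_counts)
  }
})

test_that("shunt fraction combines lung and territory counts conventionally", {
  r <- spectct_lsf(600, 9400)
  expect_equal(r$lsf, 0.06)
  expect_equal(r$lsf_pct, 6)
  expect_error(spectct_lsf(0, 0), "both zero")
})

test_that("noiseless phantom LSF is recovered within 1% relative through the full pipeline", {
  ph <- local_coarse_phantom()
  seg <- segment_lungs(ph$ct, segmentation_preset("diagnostic"))
  res <- spect_lsf_pipeline(ph$spect, ph$ct, seg, ph$manifest$territory_counts,
                            bg_voi = mask_array(ph$labels, "background_voi"))
  expect_lt(abs(res$lsf - ph$manifest$true_lsf) / ph$manifest$true_lsf, 0.01)
  # audit fields are internally consistent
  expect_lte(res$lung_counts_above_zone_corrected, res$lung_counts_above_zone_raw)
  expect_equal(res$lsf, res$lung_counts_total /
                 (res$lung_counts_total + res$territory_counts))
})

test_that("uniform lung activity: extrapolated whole-lung counts equal the direct sum", {
  ph <- local_coarse_phantom()
  res <- spect_lsf_pipeline(ph$spect, ph$ct, ph$labels, ph$manifest$territory_counts,
                            bg_voi = mask_array(ph$labels, "background_voi"))
  lungs <- mask_array(ph$labels, c("left_lung", "right_lung"))
  direct <- sum(ph$spect$data[lungs]) -
    ph$manifest$lung_bg_counts  # background-corrected direct sum
  expect_equal(res$lung_counts_total, direct, tolerance = 1e-8)
})

test_that("exclusion zone reduces the LSF error under diaphragmatic mis-registration", {
  ph <- local_coarse_phantom("freebreathing")
  seg <- segment_lungs(ph$ct, segmentation_preset("spectct"), atelectasis = ph$labels)
  bgv <- mask_array(ph$labels, "background_voi")
  on <- spect_lsf_pipeline(ph$spect, ph$ct, seg, ph$manifest$territory_counts,
                           bg_voi = bgv)
  off <- spect_lsf_pipeline(ph$spect, ph$ct, seg, ph$manifest$territory_counts,
                            margin_mm = NULL, bg_voi = bgv)
  truth <- ph$manifest$true_lsf
  expect_lt(abs(on$lsf - truth), abs(off$lsf - truth))
  expect_gt(off$lsf, truth)   # naive whole-lung estimate overestimates
})
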