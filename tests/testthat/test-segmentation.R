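test_that("slice region growing captures exactly the seeded connected blob", {
  sl <- matrix(40, 30, 30)
  sl[5:12, 5:12] <- -800          # seeded blob
  sl[20:26, 20:26] <- -800        # disconnected second blob
  roi <- grow_slice_roi(sl, c(8, 8))
  expect_identical(roi, sl == -800 & row(sl) <= 12)
  expect_false(any(roi[20:26, 20:26]))
})

test_that("region growing follows in-band corridors and matches the BFS oracle", {
  sl <- matrix(40, 40, 40)
  sl[5:15, 5:15] <- -800
  sl[25:35, 25:35] <- -800
  sl[15:25, 10] <- -900           # corridor joining the blobs, still in band
  sl[25, 10:25] <- -900
  params <- segmentation_params(upper_hu = -600)
  roi <- grow_slice_roi(sl, c(10, 10), params)
  oracle <- bfs_flood_oracle(sl >= -1000 & sl <= -600, c(10, 10), 4)[, , 1]
  expect_identical(roi, oracle)
  expect_true(any(roi[25:35, 25:35]))
})

test_that("8-connectivity growth also matches the oracle on random blobs", {
  set.seed(7)
  for (rep in 1:3) {
    sl <- matrix(ifelse(runif(900) < 0.45, -800, 40), 30, 30)
    seeds <- which(sl == -800, arr.ind = TRUE)[1, ]
    for (conn in c(4, 8)) {
      roi <- grow_slice_roi(sl, seeds, segmentation_params(connectivity = conn))
      oracle <- bfs_flood_oracle(sl <= -400, seeds, conn)[, , 1]
      expect_identical(roi, oracle)
    }
  }
})

test_that("a seed outside the threshold band is rejected by name", {
  sl <- matrix(40, 10, 10)
  sl[3:6, 3:6] <- -800
  expect_error(grow_slice_roi(sl, c(1, 1)), "seed \\(1, 1\\)")
})

test_that("segmentation parameters are validated", {
  expect_error(segmentation_params(upper_hu = -100), "-600, -150")
  expect_error(segmentation_params(pleural_sliver_mm = 2), "0, 1")
  expect_error(segmentation_params(connectivity = 6), "4 or 8")
})

test_that("automatic lung segmentation recovers the phantom lungs and drops the trachea", {
  ph <- local_coarse_phantom()
  seg <- segment_lungs(ph$ct, segmentation_preset("diagnostic"))
  expect_gte(dice_coefficient(seg, ph$labels, "left_lung"), 0.98)
  expect_gte(dice_coefficient(seg, ph$labels, "right_lung"), 0.98)
  # left/right disjoint by construction
  expect_false(any(mask_array(seg, "left_lung") & mask_array(seg, "right_lung")))
  # trachea voxels (in band, midline) are in neither lung label
  trachea <- ph$ct$data == -1000 &
    array(abs(axis_coords(48, 8) - 188) < 10, c(48, 48, 42)) &
    mask_array(ph$labels, c("left_lung", "right_lung")) == FALSE
  lungs <- mask_array(seg, c("left_lung", "right_lung"))
  expect_false(any(lungs & trachea))
  # only in-band voxels make it into the mask (no sliver, no atelectasis here)
  expect_true(all(ph$ct$data[lungs] >= -1000 & ph$ct$data[lungs] <= -400))
})

test_that("whole-lung masks equal an independent 3-D flood fill from in-lung seeds", {
  ph <- local_coarse_phantom()
  seg <- segment_lungs(ph$ct, segmentation_preset("diagnostic"))
  band <- ph$ct$data >= -1000 & ph$ct$data <= -400
  for (side in c("left_lung", "right_lung")) {
    truth <- mask_array(ph$labels, side)
    seed <- which(truth, arr.ind = TRUE)[1, ]
    oracle <- bfs_flood_oracle(band, seed, 4, link_z = TRUE)
    expect_identical(unname(mask_array(seg, side)), unname(oracle))
  }
})

test_that("raising the upper threshold never shrinks the segmentation", {
  ph <- local_coarse_phantom()
  lo <- segment_lungs(ph$ct, segmentation_params(upper_hu = -600))
  hi <- segment_lungs(ph$ct, segmentation_params(upper_hu = -400))
  for (side in c("left_lung", "right_lung")) {
    expect_true(all(mask_array(hi, side)[mask_array(lo, side)]))
  }
})

test_that("pleural sliver dilates each lung by at most one in-plane voxel ring", {
  # fine in-plane grid so a 1-mm sliver is one voxel
  d <- c(60, 40, 6)
  arr <- array(-1000, d)  # air outside
  arr[4:57, 4:37, ] <- 40 # body
  arr[10:25, 12:30, 2:5] <- -780
  arr[36:51, 12:30, 2:5] <- -780
  ct <- voxel_volume(arr, c(1, 1, 8), "CT")
  base <- segment_lungs(ct, segmentation_params(), min_component_cm3 = 1)
  grown <- segment_lungs(ct, segmentation_params(pleural_sliver_mm = 1),
                         min_component_cm3 = 1)
  for (side in c("left_lung", "right_lung")) {
    m0 <- mask_array(base, side)
    m1 <- mask_array(grown, side)
    expect_true(all(m1[m0]))               # superset
    expect_gt(sum(m1), sum(m0))            # strictly grew
    # growth confined to the immediate in-plane neighbourhood
    ring <- m1 & !m0
    idx <- which(ring, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
      nb <- m0[max(1, i - 1):min(d[1], i + 1), max(1, j - 1):min(d[2], j + 1), k]
      expect_true(any(nb))
    }
  }
})

test_that("atelectasis flagged voxels are merged into the lung labels on request", {
  ph <- local_coarse_phantom("freebreathing")
  seg <- segment_lungs(ph$ct, segmentation_preset("spectct"), atelectasis = ph$labels)
  atel <- mask_array(ph$labels, "atelectasis")
  lungs <- mask_array(seg, c("left_lung", "right_lung"))
  expect_true(all(lungs[atel]))
  seg0 <- segment_lungs(ph$ct, segmentation_preset("spectct",
                                                   include_atelectasis = FALSE))
  expect_false(any(mask_array(seg0, c("left_lung", "right_lung"))[atel]))
})

test_that("segmentation fails informatively without two lung candidates", {
  arr <- array(40, c(20, 20, 10))
  arr[5:16, 5:16, 2:7] <- -800    # a single central blob spanning the midline
  arr[9:12, 9:12, 9:10] <- -1000  # detached midline airway above it
  ct <- voxel_volume(arr, c(4, 4, 4), "CT")
  # spanning blob is split left/right rather than erroring
  seg <- segment_lungs(ct, min_component_cm3 = 1)
  expect_true(any(mask_array(seg, "left_lung")) && any(mask_array(seg, "right_lung")))
  arr2 <- array(40, c(20, 20, 10))
  arr2[2:8, 5:16, 2:7] <- -800    # one off-midline blob only
  arr2[9:12, 9:12, 9:10] <- -1000
  expect_error(segment_lungs(voxel_volume(arr2, c(4, 4, 4), "CT"),
                             min_component_cm3 = 1),
               "fewer than 2 lung candidates")
})

test_that("ROI-stack volumes follow the slice-area convention", {
  labels <- array(0L, c(20, 20, 12))
  labels[1:10, 1:10, 2:11] <- 1L           # 100 px of 1 mm^2, 10 slices, 3 mm thick
  mask <- region_mask(labels, c(1, 1, 3))
  v <- lung_volume_from_rois(mask, "left_lung")
  expect_equal(v$volume_cm3, 3.0)
  expect_equal(v$n_slices, 10L)
  expect_error(lung_volume_from_rois(mask, "right_lung"), "empty")
})

test_that("cylinder volume matches the analytic value within 2%", {
  d <- c(40, 40, 30)
  xs <- axis_coords(d[1], 2); ys <- axis_coords(d[2], 2)
  in_xy <- outer((xs - 39)^2, (ys - 39)^2, `+`) <= 30^2
  labels <- array(0L, d)
  labels[, , 3:27] <- in_xy * 2L
  mask <- region_mask(labels, c(2, 2, 4))
  v <- lung_volume_from_rois(mask, "right_lung")
  analytic <- pi * 30^2 * 25 * 4 / 1000
  expect_lt(abs(v$volume_cm3 - analytic) / analytic, 0.02)
})

test_that("interpolated and summed volume modes agree on a smooth ellipsoid", {
  ph <- local_coarse_phantom()
  vs <- lung_volume_from_rois(ph$labels, method = "sum")
  vi <- lung_volume_from_rois(ph$labels, method = "interpolate")
  expect_lt(max(abs(vs$volume_cm3 - vi$volume_cm3) / vs$volume_cm3), 0.02)
})
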