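test_that("roi_stats matches the definition on constant fields and the brute-force oracle on noise", {
  vol <- image_volume(array(100, dim = c(32, 32, 3)), c(0.43, 0.43, 3))
  roi <- data.frame(slice = 2, cx = 16, cy = 16, area_mm2 = 20)
  st <- roi_stats(vol, roi)
  expect_equal(st$mean_si, 100)
  expect_equal(st$sd_si, 0)

  ph <- gen_nm_phantom(small_truth(noise_sd = 10), seed = 5)
  for (k in c(1, 3, 8, nrow(ph$rois))) {
    got <- roi_stats(ph$volume, ph$rois[k, ])
    want <- oracle_roi_stats(ph$volume, ph$rois[k, ])
    expect_equal(got$mean_si, want$mean_si)
    expect_equal(got$sd_si, want$sd_si)
    expect_identical(got$n_pixels, want$n_pixels)
  }
})

test_that("roi_stats errors when the disc captures no pixel centre", {
  vol <- image_volume(array(1, dim = c(32, 32, 1)), c(4, 4, 3))
  expect_error(roi_stats(vol, data.frame(slice = 1, cx = 16.5, cy = 16.5,
                                         area_mm2 = 2)),
               "no pixel centres")
})

test_that("locate_lc finds planted bright discs within one pixel", {
  truth <- small_truth(noise_sd = 10)
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    ph <- gen_nm_phantom(truth, seed = s)
    loc <- locate_lc(ph$volume, lc_search_boxes(), 1:3)
    for (k in seq_len(nrow(loc))) {
      ctr <- truth$lc_centers[[loc$side[k]]]
      total <- total + 1L
      if (max(abs(c(loc$cx[k], loc$cy[k]) - ctr)) <= 1) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("locate_lc breaks flat-field ties lexicographically and respects the search region", {
  vol <- image_volume(array(50, dim = c(64, 64, 3)), c(0.43, 0.43, 3))
  loc <- locate_lc(vol, lc_search_boxes(), 1:3)
  # smallest admissible (row, column) centre inside each box
  expect_true(all(loc$cx[loc$side == "left"] == 16))
  expect_true(all(loc$cy[loc$side == "left"] == 15))

  # a bright disc outside the search region is ignored
  truth <- small_truth(noise_sd = 0)
  ph <- gen_nm_phantom(truth, seed = 1)
  box_away <- list(left = c(2, 12, 40, 60), right = c(52, 62, 40, 60))
  loc2 <- locate_lc(ph$volume, box_away, 1:3)
  expect_true(all(loc2$cx[loc2$side == "left"] >= 4 &
                    loc2$cx[loc2$side == "left"] <= 10))
  expect_true(all(loc2$cx[loc2$side == "right"] >= 54 &
                    loc2$cx[loc2$side == "right"] <= 60))
  expect_true(all(loc2$mean_si == truth$si_map[["background"]]))

  expect_error(locate_lc(vol, list(left = c(1, 4, 1, 4), right = c(5, 8, 1, 4)),
                         1:3),
               "smaller than the ROI disc")
  expect_error(locate_lc(vol, lc_search_boxes(), 1:2), "3 contiguous")
})

test_that("cnr implements (target - reference) / sd and is affine invariant", {
  expect_identical(cnr(120, 100, 10), 2)
  expect_identical(cnr(100, 100, 10), 0)
  expect_error(cnr(120, 100, 0), "sd_ref")

  # common affine rescaling a*SI + b of the whole volume leaves CNR unchanged
  ph <- gen_nm_phantom(small_truth(noise_sd = 10), seed = 9)
  scaled <- image_volume(3.7 * ph$volume$intensities + 55, ph$volume$voxel_size)
  lc <- ph$rois[ph$rois$label == "LC_left" & ph$rois$slice == 2, ]
  pt <- ph$rois[ph$rois$label == "PT" & ph$rois$slice == 2, ]
  v1 <- cnr(roi_stats(ph$volume, lc)$mean_si, roi_stats(ph$volume, pt)$mean_si,
            roi_stats(ph$volume, pt)$sd_si)
  v2 <- cnr(roi_stats(scaled, lc)$mean_si, roi_stats(scaled, pt)$mean_si,
            roi_stats(scaled, pt)$sd_si)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("aggregate_cnr_lc averages all session x side x slice cells against per-slice references", {
  grid <- expand.grid(session = 1:2, side = c("left", "right"), slice = 1:3,
                      stringsAsFactors = FALSE)
  # constant case
  lc <- data.frame(grid, mean_si = 120)
  pt <- expand.grid(session = 1:2, slice = 1:3)
  pt$mean_si <- 100; pt$sd_si <- 10
  res <- aggregate_cnr_lc(lc, pt)
  expect_equal(res$aggregate, 2)
  expect_equal(nrow(res$per_measurement), 12)

  # 12 distinct values: aggregate is their mean, order-invariant
  lc$mean_si <- 100 + seq_len(12)
  res2 <- aggregate_cnr_lc(lc, pt)
  expect_equal(res2$aggregate, mean(seq_len(12) / 10))
  shuffled <- lc[sample(nrow(lc)), ]
  expect_equal(aggregate_cnr_lc(shuffled, pt)$aggregate, res2$aggregate)

  expect_error(aggregate_cnr_lc(lc[-1, ], pt), "missing LC cells")
  expect_error(aggregate_cnr_lc(lc, pt[-1, ]), "missing PT reference")
})

test_that("aggregate_cnr_sn averages the six divisions per session", {
  grid <- expand.grid(session = 1, side = c("left", "right"),
                      subregion = c("lateral", "central", "medial"),
                      stringsAsFactors = FALSE)
  sn <- data.frame(grid, mean_si = 110)
  cp <- data.frame(session = 1, side = c("left", "right"),
                   mean_si = 90, sd_si = 10)
  res <- aggregate_cnr_sn(sn, cp)
  expect_equal(res$aggregate, 2)
  expect_equal(nrow(res$per_measurement), 6)

  sn$mean_si <- 90 + seq_len(6)
  expect_equal(aggregate_cnr_sn(sn, cp)$aggregate, mean(seq_len(6) / 10))
  shuffled <- sn[sample(nrow(sn)), ]
  expect_equal(aggregate_cnr_sn(shuffled, cp)$aggregate,
               aggregate_cnr_sn(sn, cp)$aggregate)
  expect_error(aggregate_cnr_sn(sn[-2, ], cp), "missing SN cells")
})

test_that("intra-rater ICC matches the ANOVA oracle and its limiting cases", {
  s1 <- c(1.2, 1.8, 0.9, 2.1, 1.5, 1.1)
  expect_equal(icc_intra_rater(s1, s1), 1)

  s2 <- c(1.25, 1.7, 1.05, 2.0, 1.6, 1.0)
  expect_equal(icc_intra_rater(s1, s2), oracle_icc(s1, s2), tolerance = 1e-10)

  # independent noise dominating subject variance pushes ICC toward 0
  set.seed(1)
  vals <- replicate(200, {
    subj <- rnorm(8, sd = 0.01)
    icc_intra_rater(subj + rnorm(8), subj + rnorm(8))
  })
  expect_lt(abs(mean(vals)), 0.1)

  expect_error(icc_intra_rater(rep(1, 5), rep(1, 5)), "between-subject")
  expect_error(icc_intra_rater(1:4, 1:3), "equal length")
})
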