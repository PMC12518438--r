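small_phantom <- function(seed = 1, ...) {
  gen_tats_volume(tats_phantom_spec(cell_extent = c(24, 12, 6),
                                    voxel_size = c(0.3, 0.3, 0.5),
                                    seed = seed, ...))
}

test_that("distance transform equals the exhaustive oracle", {
  set.seed(11)
  for (i in 1:3) {
    dims <- sample(8:20, 3, replace = TRUE)
    vs <- runif(3, 0.2, 0.8)
    m <- array(runif(prod(dims)) < 0.05, dims)
    if (!any(m)) m[1, 1, 1] <- TRUE
    expect_lt(max(abs(distance_transform(m, vs) - brute_force_edt(m, vs))),
              1e-9)
  }
})

test_that("distance map handles the degenerate geometries analytically", {
  # tubules everywhere -> zero distance
  cube <- array(TRUE, c(8, 8, 8))
  lv <- labeled_volume(cube, cube, voxel_size = c(1, 1, 1))
  expect_equal(distance_map(lv), 0)
  # a single tubule plane at x = 0 in a slab: mean distance = mean of x
  d <- c(21, 5, 5)
  cell <- array(TRUE, d)
  tats <- array(FALSE, d); tats[1, , ] <- TRUE
  lv2 <- labeled_volume(cell, tats, voxel_size = c(0.5, 0.5, 0.5))
  expect_equal(distance_map(lv2), mean((0:20) * 0.5))
  # empty tubule mask is undefined
  lv3 <- labeled_volume(cell, array(FALSE, d), voxel_size = c(1, 1, 1))
  expect_error(distance_map(lv3), "undefined")
})

test_that("volume and skeleton densities behave at the extremes", {
  d <- c(10, 10, 6)
  cell <- array(TRUE, d)
  none <- array(FALSE, d)
  expect_equal(volume_density(labeled_volume(cell, none, voxel_size = rep(1, 3))), 0)
  expect_equal(volume_density(labeled_volume(cell, cell, voxel_size = rep(1, 3))), 100)
  expect_equal(skeleton_density(labeled_volume(cell, none, voxel_size = rep(1, 3))), 0)
  # one-voxel-thin tubes are their own skeleton
  thin <- array(FALSE, d); thin[, 4, 3] <- TRUE
  skel <- myoequiv:::skeletonize_3d(thin)
  expect_true(all(skel[thin]))
  expect_true(all(!skel[!thin]))
})

test_that("skeleton stays within the tubule mask", {
  ph <- small_phantom(seed = 2)
  skel <- myoequiv:::skeletonize_3d(ph$truth$tats_mask)
  expect_true(all(!skel[!ph$truth$tats_mask]))
  ratio <- sum(skel) / sum(ph$truth$tats_mask)
  expect_gt(ratio, 0.2)   # thin tubes: skeleton close to the mask itself
})

test_that("segmentation recovers phantom geometry", {
  ph <- gen_tats_volume(tats_phantom_spec(seed = 3, noise_sd = 0))
  cm <- segment_cell(ph$image)
  expect_lt(abs(sum(cm) - sum(ph$truth$cell_mask)) / sum(ph$truth$cell_mask),
            0.05)
  # mask is a single connected component
  labs <- myoequiv:::label_components_3d(cm)
  expect_equal(length(unique(labs[labs > 0])), 1L)
  tm <- segment_tats(ph$image, cm)
  interior <- myoequiv:::erode_rim_um(cm, c(0.5, 0.5, 1), c(0.25, 0.25, 0.5))
  truth <- ph$truth$tats_mask & interior
  tp <- sum(tm & truth); fp <- sum(tm & !truth); fn <- sum(!tm & truth)
  expect_gt(2 * tp / (2 * tp + fp + fn), 0.9)
  expect_error(segment_cell(volume_image(array(0, c(8, 8, 4)), rep(1, 3))),
               "constant")
})

test_that("full dropout yields an empty tubule mask", {
  ph <- small_phantom(seed = 4, dropout_prob = 1)
  cm <- segment_cell(ph$image)
  expect_equal(sum(segment_tats(ph$image, cm)), 0)
  expect_equal(sum(ph$truth$tats_mask), 0)
})

test_that("higher explicit thresholds give nested masks", {
  ph <- small_phantom(seed = 5)
  cm <- segment_cell(ph$image)
  m1 <- segment_tats(ph$image, cm, threshold = 0.4)
  m2 <- segment_tats(ph$image, cm, threshold = 0.6)
  expect_true(all(!m2[!m1]))   # m2 subset of m1
})

test_that("rim erosion wider than the cell is rejected", {
  ph <- small_phantom(seed = 6)
  cm <- segment_cell(ph$image)
  expect_error(segment_tats(ph$image, cm, rim_um = c(20, 20, 20)),
               "consumed the whole cell")
})

test_that("spectral density finds the lattice period and beats a shuffle", {
  ph <- gen_tats_volume(tats_phantom_spec(seed = 7, dropout_prob = 0,
                                          position_jitter_sd = 0))
  lv <- labeled_volume(ph$truth$cell_mask, ph$truth$tats_mask,
                       voxel_size = c(0.25, 0.25, 0.5))
  sd1 <- spectral_density(lv)
  expect_equal(sd1$peak_frequency, 1 / 2.0, tolerance = 0.05)
  # shuffled control scores lower
  set.seed(1)
  perm <- sample(dim(lv$tats_mask)[1])
  lv_sh <- labeled_volume(lv$cell_mask[perm, , ], lv$tats_mask[perm, , ],
                          voxel_size = c(0.25, 0.25, 0.5))
  expect_gt(sd1$score, spectral_density(lv_sh)$score)
  # translation invariance along the long axis
  roll <- c(2:dim(lv$tats_mask)[1], 1)
  lv_t <- labeled_volume(lv$cell_mask, lv$tats_mask[roll, , ] &
                           lv$cell_mask, voxel_size = c(0.25, 0.25, 0.5))
  # (mask support shifts within a uniform cell interior slab)
  expect_equal(spectral_density(lv_t)$score, sd1$score, tolerance = 0.05)
  # empty mask scores zero
  lv0 <- labeled_volume(lv$cell_mask,
                        array(FALSE, dim(lv$cell_mask)),
                        voxel_size = c(0.25, 0.25, 0.5))
  expect_equal(spectral_density(lv0)$score, 0)
})

test_that("metrics are invariant to intensity rescaling before segmentation", {
  ph <- small_phantom(seed = 8, noise_sd = 0)
  m1 <- {
    cm <- segment_cell(ph$image)
    tats_metrics(labeled_volume(cm, segment_tats(ph$image, cm),
                                voxel_size = c(0.3, 0.3, 0.5)))
  }
  img2 <- volume_image(ph$image$voxels * 7.3, ph$image$voxel_size,
                       ph$image$channel)
  m2 <- {
    cm <- segment_cell(img2)
    tats_metrics(labeled_volume(cm, segment_tats(img2, cm),
                                voxel_size = c(0.3, 0.3, 0.5)))
  }
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("more dropout means sparser tubules and longer distances", {
  res <- sapply(c(0.05, 0.45), function(dp) {
    vals <- sapply(1:6, function(s) {
      ph <- small_phantom(seed = 100 + s, dropout_prob = dp)
      lv <- labeled_volume(ph$truth$cell_mask, ph$truth$tats_mask,
                           voxel_size = c(0.3, 0.3, 0.5))
      c(volume_density(lv), distance_map(lv))
    })
    rowMeans(vals)
  })
  expect_gt(res[1, 1], res[1, 2])   # density falls with dropout
  expect_lt(res[2, 1], res[2, 2])   # mean distance grows with dropout
})
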