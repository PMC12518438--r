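small_mito <- function(seed = 1, ...) {
  gen_mito_volume(mito_phantom_spec(cell_extent = c(24, 12, 6),
                                    voxel_size = c(0.3, 0.3, 0.4),
                                    seed = seed, ...))
}

test_that("mode+2SD threshold matches an independent histogram oracle", {
  set.seed(21)
  for (i in 1:5) {
    d <- c(20, 15, 8)
    cell <- array(TRUE, d)
    vals <- c(rnorm(prod(d) * 0.7, 10, 1), rnorm(prod(d) * 0.3, 30, 2))
    v <- array(sample(vals, prod(d)), d)
    th <- threshold_mito(volume_image(v, rep(1, 3), "mtg"), cell)
    expect_equal(th$threshold, naive_mode_2sd(as.numeric(v)),
                 tolerance = 1e-12)
  }
  # constant intensities are degenerate
  expect_error(threshold_mito(volume_image(array(1, c(5, 5, 5)), rep(1, 3)),
                              array(TRUE, c(5, 5, 5))), "degenerate")
})

test_that("a bimodal phantom with 30% truth fraction is recovered", {
  mv <- gen_mito_volume(mito_phantom_spec(
    target_channel_correlation = 0.995, seed = 2))
  cm <- mask_cell_autofluorescence(mv$mtg)
  expect_lt(abs(sum(cm) - sum(mv$truth$cell_mask)) / sum(mv$truth$cell_mask),
            0.05)
  th <- threshold_mito(mv$mtg, cm)
  expect_lt(abs(th$density_pct - 30), 5)
  # everything below threshold -> zero density
  dim3 <- c(10, 10, 5)
  low <- volume_image(array(runif(prod(dim3), 0, 1), dim3), rep(1, 3))
  cell <- array(TRUE, dim3)
  th0 <- threshold_mito(low, cell)
  if (th0$threshold > max(low$voxels)) {
    expect_equal(th0$density_pct, 0)
  }
})

test_that("the summed-signal ratio is exact, permutation-proof and linear", {
  d <- c(12, 10, 6)
  set.seed(3)
  mtg <- volume_image(array(runif(prod(d), 1, 5), d), rep(1, 3), "mtg")
  tmrm <- volume_image(2 * mtg$voxels, rep(1, 3), "tmrm")
  cell <- array(TRUE, d)
  expect_equal(channel_ratio(tmrm, mtg, cell), 2)
  # permuting voxels inside the mask leaves the ratio unchanged
  perm <- sample(prod(d))
  tmrm_p <- volume_image(array(tmrm$voxels[perm], d), rep(1, 3))
  mtg_p <- volume_image(array(mtg$voxels[perm], d), rep(1, 3))
  expect_equal(channel_ratio(tmrm_p, mtg_p, cell), 2)
  # uncoupler-style collapse: scaling TMRM by 0.2 scales the ratio by 0.2
  tmrm_fccp <- volume_image(0.2 * tmrm$voxels, rep(1, 3))
  expect_equal(channel_ratio(tmrm_fccp, mtg, cell),
               0.2 * channel_ratio(tmrm, mtg, cell))
  zero <- volume_image(array(0, d), rep(1, 3))
  expect_error(channel_ratio(tmrm, zero, cell), "undefined")
})

test_that("colocalization recovers exact and simulated correlations", {
  d <- c(12, 10, 6)
  set.seed(4)
  a <- volume_image(array(rnorm(prod(d)), d), rep(1, 3))
  b <- volume_image(-a$voxels, rep(1, 3))
  cell <- array(TRUE, d)
  expect_equal(colocalization_pearson(a, a, cell), 1)
  expect_equal(colocalization_pearson(a, b, cell), -1)

  mv <- gen_mito_volume(mito_phantom_spec(seed = 5))  # r = 0.7, full size
  cm <- mask_cell_autofluorescence(mv$mtg)
  expect_gt(sum(cm), 1e5)
  r <- colocalization_pearson(mv$tmrm, mv$mtg, cm)
  expect_lt(abs(r - 0.7), 0.05)
})

test_that("perfect-correlation phantoms have proportional channels", {
  mv <- small_mito(seed = 6, target_channel_correlation = 1)
  cell <- mv$truth$cell_mask
  ratio <- mv$tmrm$voxels[cell] / mv$mtg$voxels[cell]
  expect_lt(diff(range(ratio)), 1e-9)
  expect_equal(mv$truth$fraction, 0.3, tolerance = 0.01)
})

test_that("ratio and correlation are gain-invariant; ratio is equivariant", {
  mv <- small_mito(seed = 7)
  cm <- mv$truth$cell_mask
  g <- 3.7
  tmrm_g <- volume_image(g * mv$tmrm$voxels, mv$tmrm$voxel_size)
  mtg_g <- volume_image(g * mv$mtg$voxels, mv$mtg$voxel_size)
  expect_equal(channel_ratio(tmrm_g, mtg_g, cm),
               channel_ratio(mv$tmrm, mv$mtg, cm), tolerance = 1e-12)
  expect_equal(colocalization_pearson(tmrm_g, mtg_g, cm),
               colocalization_pearson(mv$tmrm, mv$mtg, cm),
               tolerance = 1e-12)
  expect_equal(channel_ratio(tmrm_g, mv$mtg, cm),
               g * channel_ratio(mv$tmrm, mv$mtg, cm), tolerance = 1e-12)
})

test_that("a blank volume cannot be masked", {
  expect_error(mask_cell_autofluorescence(
    volume_image(array(0, c(6, 6, 4)), rep(1, 3))), "constant")
})
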