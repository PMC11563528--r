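test_that("grid geometry: voxel volume honours spacing and interslice gap", {
  g <- volume_grid(c(10, 10, 10), c(2, 2, 2))
  expect_equal(voxel_volume_ml(g), 8 / 1000)
  # slice pitch = thickness + gap: 5.5 + 0.55 = 6.05 mm
  g2 <- volume_grid(c(80, 80, 20), c(3, 3, 5.5), slice_gap_mm = 0.55)
  expect_equal(voxel_volume_ml(g2), 3 * 3 * 6.05 / 1000)
  expect_true(grids_match(g, volume_grid(c(10, 10, 10), c(2, 2, 2))))
  expect_false(grids_match(g, g2))
  expect_error(volume_grid(c(10, 10), c(2, 2, 2)), "shape")
  expect_error(volume_grid(c(10, 10, 10), c(2, -2, 2)), "spacing")
  expect_error(volume_grid(c(10, 10, 10), c(2, 2, 2), lr_axis = 4), "lr_axis")
})

test_that("GM thresholding is boundary-inclusive at the declared cut", {
  g <- volume_grid(c(4, 4, 2), c(1, 1, 1))
  ones <- function(v) mask_count(threshold_gm(array(v, g$shape), g))
  expect_equal(ones(0.7), prod(g$shape))
  expect_equal(ones(0.6), prod(g$shape))   # inclusive rule at the boundary
  expect_equal(ones(0.59), 0L)
  expect_error(threshold_gm(array(1.2, g$shape), g), "\\[0, 1\\]")
  expect_error(threshold_gm(array(0.5, g$shape), g, threshold = 0), "threshold")
})

test_that("mirroring reflects indices about the mid-plane and is an involution", {
  g <- volume_grid(c(10, 4, 3), c(1, 1, 1))
  m <- array(0, g$shape); m[3, 2, 2] <- 1
  mm <- mirror_mask(mask_volume(m, g))
  expect_equal(unname(which(mm$data == 1, arr.ind = TRUE)[1, ]), c(8, 2, 2))

  set.seed(11)
  for (i in 1:10) {
    sh <- sample(3:9, 3)
    gi <- volume_grid(sh, c(1, 1, 1), lr_axis = sample(1:3, 1))
    msk <- mask_volume(array(rbinom(prod(sh), 1, 0.3), sh), gi)
    back <- mirror_mask(mirror_mask(msk))
    expect_equal(back$data, msk$data)                       # involution
    expect_equal(mask_count(mirror_mask(msk)), mask_count(msk))  # count preserved
  }

  # a mask symmetric about the mid-plane is a fixed point; central slice of
  # an odd-extent axis maps onto itself
  g2 <- volume_grid(c(5, 4, 3), c(1, 1, 1))
  sym <- array(0, g2$shape); sym[c(1, 5), 2, 2] <- 1; sym[3, 3, 1] <- 1
  ms <- mask_volume(sym, g2)
  expect_equal(mirror_mask(ms)$data, ms$data)
})

test_that("hematoma exclusion is a set difference, disjoint from the hematoma", {
  g <- volume_grid(c(10, 10, 2), c(1, 1, 1))
  inf <- array(0, g$shape); inf[1:5, 1:10, 1:2] <- 1   # 100 voxels
  hem <- array(0, g$shape); hem[1:3, 1:5, 1:2] <- 1    # 30 voxels inside
  infm <- mask_volume(inf, g, "infarct"); hemm <- mask_volume(hem, g, "hematoma")
  out <- exclude_hematoma(infm, hemm)
  expect_equal(mask_count(out), 70L)
  expect_equal(sum(out$data * hemm$data), 0)           # disjoint

  empty <- mask_volume(array(0, g$shape), g)
  expect_equal(exclude_hematoma(infm, empty)$data, infm$data)   # identity
  all1 <- mask_volume(array(1, g$shape), g)
  expect_equal(mask_count(exclude_hematoma(infm, all1)), 0L)    # annihilation
  g2 <- volume_grid(c(9, 10, 2), c(1, 1, 1))
  expect_error(exclude_hematoma(infm, mask_volume(array(0, g2$shape), g2)),
               "grid mismatch")
})

test_that("intersection is voxelwise AND with grid validation", {
  g <- volume_grid(c(6, 6, 2), c(1, 1, 1))
  a <- mask_volume(array(rbinom(72, 1, 0.5), g$shape), g, "a")
  empty <- mask_volume(array(0, g$shape), g, "empty")
  b <- mask_volume(1 - a$data, g, "b")
  expect_equal(intersect_masks(a, a)$data, a$data)
  expect_equal(mask_count(intersect_masks(a, empty)), 0L)
  expect_equal(mask_count(intersect_masks(a, b)), 0L)   # disjoint -> empty
  g2 <- volume_grid(c(6, 6, 3), c(1, 1, 1))
  expect_error(intersect_masks(a, mask_volume(array(0, g2$shape), g2)),
               "grid mismatch")
})

test_that("mask volume in ml is count x voxel volume and additive", {
  g <- volume_grid(c(25, 25, 10), c(2, 2, 2))
  m <- array(0, g$shape); m[seq_len(6250)] <- 1
  expect_equal(mask_volume_ml(mask_volume(m, g)), 50.0)
  expect_equal(mask_volume_ml(mask_volume(array(0, g$shape), g)), 0)

  gp <- volume_grid(c(10, 10, 10), c(3, 3, 5.5), slice_gap_mm = 0.55)
  mp <- array(0, gp$shape); mp[seq_len(1000)] <- 1
  expect_equal(mask_volume_ml(mask_volume(mp, gp)), 54.45)

  # additivity over disjoint masks
  a <- array(0, g$shape); a[1:10, , ] <- 1
  b <- array(0, g$shape); b[11:20, , ] <- 1
  expect_equal(mask_volume_ml(mask_volume(a, g)) + mask_volume_ml(mask_volume(b, g)),
               mask_volume_ml(mask_volume(a + b, g)))
})
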