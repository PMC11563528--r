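test_that("masked CBF means: uniform, two-voxel, empty and median cases", {
  g <- volume_grid(c(4, 4, 2), c(1, 1, 1))
  cbf <- array(50, g$shape)
  all1 <- mask_volume(array(1, g$shape), g)
  expect_equal(as.numeric(mean_cbf_in_mask(cbf, all1)), 50)

  two <- array(0, g$shape); two[1:2, 1, 1] <- 1
  cbf2 <- cbf; cbf2[1, 1, 1] <- 40; cbf2[2, 1, 1] <- 60
  expect_equal(as.numeric(mean_cbf_in_mask(cbf2, mask_volume(two, g))), 50)
  expect_equal(as.numeric(mean_cbf_in_mask(cbf2, mask_volume(two, g), "median")), 50)

  expect_error(mean_cbf_in_mask(cbf, mask_volume(array(0, g$shape), g, "roi")),
               "empty readout region")
})

test_that("missing CBF voxels are excluded from means and flagged when frequent", {
  g <- volume_grid(c(4, 4, 2), c(1, 1, 1))
  cbf <- array(50, g$shape)
  m <- array(0, g$shape); m[1:4, 1, 1] <- 1
  cbf[1, 1, 1] <- NA; cbf[2, 1, 1] <- NA   # 50% of the region missing
  expect_warning(v <- mean_cbf_in_mask(cbf, mask_volume(m, g, "roi")), "missing")
  expect_equal(as.numeric(v), 50)
  expect_equal(attr(v, "n_missing"), 2L)
})

test_that("percent CBF difference follows the printed formula on a hand-built subject", {
  s <- tiny_subject(cbf_infarct = 20, cbf_contra = 25)
  ro <- percent_cbf_difference(s$cbf, s$infarct, s$hematoma, s$gm)
  expect_equal(ro$cbf_infarct_mask, 20)
  expect_equal(ro$cbf_mirrored_mask, 25)
  expect_equal(ro$percent_cbf_difference, -20)
  expect_equal(ro$n_voxels_infarct_gm, 16L)
  expect_equal(ro$infarct_volume_ml, 16 * 8 / 1000)

  # identical CBF both sides -> exactly zero
  s0 <- tiny_subject(cbf_infarct = 25, cbf_contra = 25)
  expect_equal(percent_cbf_difference(s0$cbf, s0$infarct, s0$hematoma,
                                      s0$gm)$percent_cbf_difference, 0)
})

test_that("the statistic is invariant to global CBF rescaling", {
  g <- asl_grid(c(16, 16, 8))
  an <- generate_anatomy(g, 0.05, seed = 2)
  gm <- threshold_gm(an$gm_prob, g)
  for (s in 1:5) {
    perf <- generate_perfusion(an, ground_truth(50, 0.7, noise_sd = 3, seed = s))
    perf <- pmax(perf, 1)   # keep strictly positive under noise
    a <- runif(1, 0.2, 5)
    r1 <- percent_cbf_difference(perf, an$infarct_mask, an$hematoma_mask, gm)
    r2 <- percent_cbf_difference(a * perf, an$infarct_mask, an$hematoma_mask, gm)
    expect_equal(r2$percent_cbf_difference, r1$percent_cbf_difference,
                 tolerance = 1e-10)
    expect_equal(r2$hypoperfused_fraction, r1$hypoperfused_fraction)
  }
})

test_that("hematoma voxels never influence the readout once excluded", {
  g <- asl_grid(c(16, 16, 8))
  an <- generate_anatomy(g, 0.06, with_hematoma = TRUE, seed = 4)
  gm <- threshold_gm(an$gm_prob, g)
  perf <- generate_perfusion(an, ground_truth(50, 0.6, 0))
  r1 <- percent_cbf_difference(perf, an$infarct_mask, an$hematoma_mask, gm)
  corrupted <- perf
  corrupted[an$hematoma_mask$data > 0] <- 1e6   # arbitrary bleed signal
  r2 <- percent_cbf_difference(corrupted, an$infarct_mask, an$hematoma_mask, gm)
  expect_equal(r2$percent_cbf_difference, r1$percent_cbf_difference)
  expect_equal(r2$infarct_volume_ml, r1$infarct_volume_ml)
})

test_that("hypoperfused fraction implements the voxelwise homologue rule", {
  s <- tiny_subject(cbf_infarct = 25, cbf_contra = 25)
  expect_equal(hypoperfused_fraction(s$cbf, s$infarct, s$hematoma, s$gm), 0)

  shalf <- tiny_subject(cbf_infarct = 12.5, cbf_contra = 25)  # all at 50%
  expect_equal(hypoperfused_fraction(shalf$cbf, shalf$infarct, shalf$hematoma,
                                     shalf$gm), 1)

  # phantom with half the lesion at ratio 0.5 and half at 1.0
  g <- asl_grid(c(16, 16, 8))
  an <- generate_anatomy(g, 0.05, seed = 1)
  idx <- which(an$infarct_mask$data > 0)
  ratio <- array(1, g$shape)
  ratio[idx[seq_len(length(idx) / 2)]] <- 0.5
  perf <- generate_perfusion(an, ground_truth(50, 1, 0), ratio_volume = ratio)
  gm_all <- mask_volume(array(1, g$shape), g, "gm")   # read the whole lesion
  expect_equal(hypoperfused_fraction(perf, an$infarct_mask, an$hematoma_mask,
                                     gm_all), 0.5)
})

test_that("degenerate readout regions raise side-naming errors", {
  s <- tiny_subject()
  # undersized region: raise the minimum above the 16 available voxels
  expect_error(percent_cbf_difference(s$cbf, s$infarct, s$hematoma, s$gm,
                                      min_voxels = 50),
               "infarct side")
  # mirrored side emptied via an asymmetric GM mask
  gm_one_sided <- array(0, s$grid$shape); gm_one_sided[1:4, , ] <- 1
  expect_error(percent_cbf_difference(s$cbf, s$infarct, s$hematoma,
                                      mask_volume(gm_one_sided, s$grid, "gm")),
               "mirrored side")
  # hematoma swallowing the infarct -> empty readout
  expect_error(percent_cbf_difference(s$cbf, s$infarct,
                                      mask_volume(array(1, s$grid$shape), s$grid),
                                      s$gm),
               "infarct side")
  # non-positive mirrored mean -> undefined statistic
  bad <- s$cbf; bad[6:7, 2:5, 2:3] <- -5
  expect_error(percent_cbf_difference(bad, s$infarct, s$hematoma, s$gm),
               "undefined statistic")
})
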