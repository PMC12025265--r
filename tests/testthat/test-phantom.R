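test_that("soft backgrounds are seeded, bounded and seed-sensitive", {
  a <- make_soft_background(64, seed = 7)
  b <- make_soft_background(64, seed = 7)
  expect_identical(a, b)
  expect_gte(min(a), 0)
  expect_lte(max(a), 1)
  c <- make_soft_background(64, seed = 8)
  expect_gt(mean(a != c), 0.01)
  expect_error(make_soft_background(16, seed = 1), "size")
})

test_that("vertebra templates follow the documented affine attenuation map", {
  lo <- make_vertebra_template(64, bmd = 0.5, seed = 3)
  hi <- make_vertebra_template(64, bmd = 1.2, seed = 3)
  expect_gt(mean(hi$raster[hi$mask]), mean(lo$raster[lo$mask]))
  expect_true(all(lo$raster[!lo$mask] == 0))
  ## mean-in-mask recomputed against the documented map 0.08 + 0.38 * bmd;
  ## texture is zero-mean with sd 0.04, so the mask mean sits within it
  v <- make_vertebra_template(64, bmd = 0.9, seed = 3)
  expect_lt(abs(mean(v$raster[v$mask]) - (0.08 + 0.38 * 0.9)), 0.04)
  expect_error(make_vertebra_template(64, bmd = 2.5, seed = 1), "bmd")
})

test_that("jitter is affine plus rotation with clamping", {
  m <- matrix(runif(64 * 64), 64, 64)
  expect_equal(jitter_template(m, 1, 0, 0), m)
  const <- matrix(0.3, 32, 32)
  expect_equal(jitter_template(const, 2, 0, 0), matrix(0.6, 32, 32))
  ## tilt = 90 must match an independent exact quarter-turn remap
  asym <- matrix(seq(0, 1, length.out = 48 * 48), 48, 48)
  rotated <- jitter_template(asym, 1, 0, 90)
  n <- 48
  oracle <- matrix(0, n, n)
  for (r in seq_len(n)) for (cc in seq_len(n)) {
    oracle[r, cc] <- asym[n + 1 - cc, r]
  }
  expect_equal(rotated, oracle, tolerance = 1e-10)
  expect_error(jitter_template(m, contrast = 0, brightness = 0, tilt = 0),
               "contrast")
})

test_that("compositing four templates is the clamped pixel-wise mean", {
  m <- matrix(runif(16), 4, 4)
  expect_equal(composite_bone_mask(list(m, m, m, m)), m)
  consts <- lapply(c(0.2, 0.4, 0.6, 0.8), function(v) matrix(v, 3, 3))
  expect_equal(composite_bone_mask(consts), matrix(0.5, 3, 3))
  quartet <- lapply(1:4, function(i) matrix(runif(25), 5, 5))
  oracle <- (quartet[[1]] + quartet[[2]] + quartet[[3]] + quartet[[4]]) / 4
  expect_equal(composite_bone_mask(quartet), oracle)
  expect_error(composite_bone_mask(quartet[1:3]), "four")
  expect_error(
    composite_bone_mask(c(quartet[1:3], list(matrix(0, 2, 2)))), "shape"
  )
})

test_that("augmentation is lossless and invertible", {
  m <- matrix(runif(36), 6, 6)
  expect_identical(augment_raster(m, 0, "none"), m)
  expect_identical(augment_raster(augment_raster(m, 180), 180), m)
  expect_identical(
    augment_raster(augment_raster(m, 0, "horizontal"), 0, "horizontal"), m
  )
  expect_identical(
    augment_raster(augment_raster(m, 0, "vertical"), 0, "vertical"), m
  )
  for (rot in c(90, 180, 270)) {
    expect_identical(
      augment_raster(augment_raster(m, rot), 360 - rot), m
    )
  }
  expect_error(augment_raster(m, 45), "rotation")
})

test_that("sample synthesis is deterministic and satisfies decomposition", {
  cfg <- tiny_phantom()
  s1 <- synthesize_sample(cfg, 4)
  s2 <- synthesize_sample(cfg, 4)
  expect_identical(s1, s2)
  s3 <- synthesize_sample(cfg, 5)
  expect_false(identical(s1$input_image, s3$input_image))
  ## decomposition consistency on the pre-noise raster, exactly
  expect_identical(s1$input_prenoise,
                   clamp(s1$soft_label + s1$bone_truth))
  expect_true(s1$bmd_true >= cfg$bmd_range[1] &&
                s1$bmd_true <= cfg$bmd_range[2])
})

test_that("cohort BMD support, covariate model and density signal hold", {
  co <- property_cohort()
  bmd <- co$manifest$bmd
  cfg_range <- c(0.35, 1.35)
  expect_true(all(bmd >= cfg_range[1] & bmd <= cfg_range[2]))
  ## analytic correlation of weight = 40 + 25 * bmd + N(0, 16):
  ## sd(bmd) = 1/sqrt(12), r = 25 sd / sqrt((25 sd)^2 + 16)
  sd_b <- 1 / sqrt(12)
  r_theory <- 25 * sd_b / sqrt((25 * sd_b)^2 + 16)
  expect_lt(abs(cor(co$manifest$weight, bmd) - r_theory), 0.1)
  expect_gt(cor(co$manifest$area, bmd), 0)
  ## monotone density: mean bone intensity inside the mask tracks bmd
  mean_in_mask <- vapply(co$samples, function(s) {
    mean(s$bone_truth[s$bone_mask])
  }, numeric(1))
  fit <- lm(mean_in_mask ~ bmd)
  expect_gt(coef(fit)[2], 0)
  expect_gt(cor(mean_in_mask, bmd), 0.9)
})
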