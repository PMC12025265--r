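test_that("the five-region partition is exact on divisible and ragged ROIs", {
  p <- partition_regions(matrix(0, 9, 9))
  central <- which(p$central, arr.ind = TRUE)
  expect_equal(sort(unique(central[, "row"])), 4:6)
  expect_equal(sort(unique(central[, "col"])), 4:6)
  expect_equal(sum(p$central), 9)
  total <- p$upper + p$lower + p$left + p$central + p$right
  expect_true(all(total == 1))   # disjoint and exhaustive
  ## ragged 10x10: boundaries at floor(i * 10 / 3) = 3, 6
  q <- partition_regions(matrix(0, 10, 10))
  expect_true(all(which(rowSums(q$upper) > 0) == 1:3))
  expect_true(all(which(rowSums(q$lower) > 0) == 7:10))
  expect_true(all(which(colSums(q$left) > 0) == 1:3))
  expect_true(all(which(colSums(q$right) > 0) == 7:10))
  total <- q$upper + q$lower + q$left + q$central + q$right
  expect_true(all(total == 1))
  expect_equal(sum(total), 100)
  expect_error(partition_regions(matrix(0, 2, 5)), "3x3")
})

test_that("threshold sets encode the documented sigma multipliers", {
  s1 <- threshold_spec(100, 10, 1)
  expect_equal(c(s1$A1, s1$A2), c(90, 119.6))
  s2 <- threshold_spec(100, 10, 2)
  expect_equal(c(s2$A1, s2$A2), c(80.4, 119.6))
  s3 <- threshold_spec(100, 10, 3)
  expect_equal(c(s3$A1, s3$A2), c(80.4, 110))
  expect_error(threshold_spec(1, 1, 4), "set_id")
})

test_that("clipping matches the per-pixel conditional oracle and is idempotent", {
  s2 <- threshold_spec(100, 10, 2)
  expect_equal(clip_to_threshold(c(75, 130, 100), s2), c(80.4, 119.6, 100))
  ## degenerate constant region: A1 = A2 = mu leaves values unchanged
  s0 <- threshold_spec(0.4, 0, 1)
  expect_equal(clip_to_threshold(rep(0.4, 5), s0), rep(0.4, 5))
  set.seed(17)
  for (set_id in 1:3) {
    px <- rnorm(200, 0.5, 0.2)
    spec <- threshold_spec(mean(px), sd(px), set_id)
    oracle <- vapply(px, function(g) {
      if (g < spec$A1) spec$A1 else if (g > spec$A2) spec$A2 else g
    }, numeric(1))
    clipped <- clip_to_threshold(px, spec)
    expect_equal(clipped, oracle)
    expect_equal(clip_to_threshold(clipped, spec), clipped)
  }
  expect_error(clip_to_threshold(numeric(0), s2), "empty")
})

test_that("region means behave like arithmetic means", {
  expect_equal(region_mean(rep(0.4, 7)), 0.4)
  expect_equal(region_mean(c(0, 1)), 0.5)
  s1 <- threshold_spec(0.5, 0.1, 1)
  px <- clip_to_threshold(runif(50), s1)
  m <- region_mean(px)
  expect_gte(m, s1$A1)
  expect_lte(m, s1$A2)
  expect_error(region_mean(numeric(0)), "empty")
})

test_that("feature extraction yields the documented 23-element vector", {
  img <- matrix(runif(64 * 64), 64, 64)
  box <- c(r0 = 10, r1 = 50, c0 = 15, c1 = 45)
  f <- extract_features(img, box, weight = 60, area = 14)
  expect_length(f, 23)
  expect_identical(names(f), bmdnet:::feature_names())
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["weight"]), 60)
  expect_equal(unname(f["area"]), 14)
  ## constant image: all 21 image features equal the constant
  cimg <- matrix(0.37, 32, 32)
  fc <- extract_features(cimg, c(r0 = 1, r1 = 32, c0 = 1, c1 = 32),
                         weight = 55, area = 12)
  expect_true(all(abs(fc[1:21] - 0.37) < 1e-12))
  ## permuting pixels inside one region leaves that region's features alone
  p <- partition_regions(img[10:50, 15:45])
  img2 <- img
  roi <- img[10:50, 15:45]
  px <- roi[p$central]
  roi[p$central] <- sample(px)
  img2[10:50, 15:45] <- roi
  f2 <- extract_features(img2, box, weight = 60, area = 14)
  central_feats <- grep("^central", names(f))
  expect_equal(f[central_feats], f2[central_feats])
  expect_error(extract_features(img, c(r0 = 1, r1 = 2, c0 = 1, c1 = 70),
                                weight = 60, area = 14), "roi_box")
})

test_that("raising every pixel by delta shifts raw region means by delta", {
  img <- matrix(runif(48 * 48), 48, 48)
  box <- c(r0 = 5, r1 = 44, c0 = 8, c1 = 40)
  f0 <- extract_features(img, box, weight = 60, area = 14)
  delta <- 0.123
  f1 <- extract_features(img + delta, box, weight = 60, area = 14)
  raw <- grep("_raw$|^roi_mean$", names(f0))
  expect_equal(unname(f1[raw] - f0[raw]), rep(delta, 6), tolerance = 1e-12)
})

test_that("feature tables carry one canonical row per sample", {
  co <- synthesize_cohort(tiny_phantom(seed = 4), n = 6)
  imgs <- stats::setNames(lapply(co$samples, `[[`, "bone_truth"),
                          co$manifest$sample_id)
  ft <- extract_feature_table(co$manifest, images = imgs)
  expect_equal(nrow(ft), 6)
  expect_identical(names(ft), c("sample_id", bmdnet:::feature_names(), "bmd"))
  expect_equal(ft$bmd, co$manifest$bmd)
  f1 <- extract_features(
    imgs[[co$manifest$sample_id[1]]],
    c(r0 = co$manifest$roi_r0[1], r1 = co$manifest$roi_r1[1],
      c0 = co$manifest$roi_c0[1], c1 = co$manifest$roi_c1[1]),
    weight = co$manifest$weight[1], area = co$manifest$area[1]
  )
  expect_equal(unlist(ft[1, bmdnet:::feature_names()]), f1)
})
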