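test_that("background subtraction removes constants and never goes negative", {
  expect_equal(subtract_background(matrix(7, 32, 32), sigma = 5),
               matrix(0, 32, 32))
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_gte(min(subtract_background(img, sigma = 3)), 0)
  bad <- img; bad[5, 5] <- NaN
  expect_error(subtract_background(bad, 3), "non-finite")
  expect_error(subtract_background(img, sigma = 0), "positive")
})

test_that("background subtraction agrees with a direct convolution oracle", {
  img <- matrix(0.1, 64, 64)
  d2 <- (row(img) - 32)^2 + (col(img) - 32)^2
  img[d2 <= 36] <- 1
  sigma <- 6
  got <- subtract_background(img, sigma)
  oracle <- pmax(img - direct_gaussian_blur(img, sigma), 0)
  interior <- 20:44  # away from borders, where padding conventions differ
  expect_equal(got[interior, interior], oracle[interior, interior],
               tolerance = 1e-6)
  expect_gt(got[32, 32], 0)          # disk interior keeps positive residual
  expect_lt(max(got[1:5, 1:5]), 0.02)  # far field ~ 0
})

test_that("percentile saturation demotes outliers and maps to [0, 1]", {
  set.seed(2)
  img <- matrix(runif(400), 20, 20)
  img[7, 7] <- 50
  out <- saturate_normalize(img, 95)
  # rank-statistics oracle: the cap equals the 95th percentile, so every
  # pixel at or above it (including the outlier) shares the maximum
  expect_equal(out[7, 7], 1)
  expect_gte(sum(out == 1), 0.05 * length(img) - 1)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(saturate_normalize(matrix(3, 5, 5)), matrix(0, 5, 5))
  set.seed(3)
  r <- matrix(rnorm(100), 10, 10)
  out2 <- saturate_normalize(r, 80)
  expect_true(all(out2 >= 0 & out2 <= 1))
})

test_that("binarization is exact and monotone in the threshold", {
  expect_false(any(binarize(matrix(0, 8, 8), 0.4)))
  disk <- matrix(0, 32, 32)
  disk[(row(disk) - 16)^2 + (col(disk) - 16)^2 <= 25] <- 1
  expect_equal(unname(binarize(disk, 0.4)), disk == 1)
  set.seed(4)
  img <- matrix(runif(256), 16, 16)
  m1 <- binarize(img, 0.3); m2 <- binarize(img, 0.6)
  expect_true(all(m1 | !m2))  # raising the threshold never grows the mask
  expect_error(binarize(img, 1.2), "in \\(0, 1\\)")
})

test_that("connected-component labelling respects connectivity and size filter", {
  mask <- matrix(FALSE, 64, 64)
  ctr <- cbind(c(12, 12, 32, 52, 52), c(12, 52, 32, 12, 52))
  for (i in 1:5)
    mask[(row(mask) - ctr[i, 1])^2 + (col(mask) - ctr[i, 2])^2 <= 25] <- TRUE
  seg <- label_nuclei(mask, min_object_px = 20)
  expect_equal(seg$n_cells, 5)
  expect_true(all(seg$areas >= 20))
  expect_setequal(unique(as.vector(seg$label_image)), 0:5)

  blob <- matrix(FALSE, 16, 16); blob[5:8, 5:7] <- TRUE  # 12 px
  expect_equal(label_nuclei(blob, 20)$n_cells, 0)
  expect_equal(label_nuclei(matrix(FALSE, 8, 8), 20)$n_cells, 0)

  diagp <- matrix(FALSE, 8, 8); diagp[3, 3] <- TRUE; diagp[4, 4] <- TRUE
  expect_equal(max(label_components(diagp, 8)), 1)
  expect_equal(max(label_components(diagp, 4)), 2)
})

test_that("size filtering is exact: no surviving object is below the minimum", {
  set.seed(5)
  for (k in 1:5) {
    mask <- matrix(runif(64 * 64) < 0.25, 64, 64)
    seg <- label_nuclei(mask, min_object_px = 20)
    if (seg$n_cells > 0) expect_true(all(seg$areas >= 20))
    # every dropped component really was below the limit
    all_lab <- label_components(mask, 8)
    expect_equal(seg$n_cells, sum(label_areas(all_lab) >= 20))
  }
})

test_that("analysis regions match a brute-force nearest-centroid oracle", {
  mask <- matrix(FALSE, 32, 32)
  mask[(row(mask) - 10)^2 + (col(mask) - 12)^2 <= 9] <- TRUE
  mask[(row(mask) - 20)^2 + (col(mask) - 18)^2 <= 9] <- TRUE
  seg <- label_nuclei(mask, min_object_px = 5)
  expect_equal(seg$n_cells, 2)
  got <- build_analysis_region(seg, 5)$analysis_region
  oracle <- brute_force_regions(seg$label_image, 5)
  expect_identical(got, oracle)
  # supersets of the nuclei, every contested pixel assigned exactly once
  expect_true(all(got[seg$label_image > 0] == seg$label_image[seg$label_image > 0]))
})

test_that("analysis region degenerate cases behave", {
  mask <- matrix(FALSE, 40, 40)
  mask[(row(mask) - 10)^2 + (col(mask) - 10)^2 <= 9] <- TRUE
  mask[(row(mask) - 30)^2 + (col(mask) - 30)^2 <= 9] <- TRUE
  seg <- label_nuclei(mask, 5)
  expect_identical(build_analysis_region(seg, 0)$analysis_region,
                   seg$label_image)
  reg <- build_analysis_region(seg, 3)$analysis_region
  # distant nuclei keep disjoint regions
  expect_equal(sum(reg > 0), sum(reg == 1) + sum(reg == 2))
  expect_gt(sum(reg == 1), sum(seg$label_image == 1))
  expect_error(build_analysis_region(seg, -1), ">= 0")
})

test_that("per-cell quantification recovers planted marker levels", {
  tr <- random_image_truth(20, image_shape = c(256, 256),
                           radius_range = c(9, 11), min_gap = 6,
                           markers = list(GFP = 1),
                           marker_level_range = c(0.5, 1.0),
                           noise_sd = 0, seed = 6)
  img <- generate_image_set(tr, seed = 6)
  seg <- segment_nuclei(img$channels$DAPI)
  expect_equal(seg$n_cells, 20)
  mk <- subtract_background(img$channels$GFP, 40)
  q <- quantify_cells(seg, mk, "GFP")
  expect_equal(nrow(q$cells), 20)
  # match segmented cells to planted cells via the center pixel
  id <- seg$label_image[cbind(round(tr$centers[, 1]), round(tr$centers[, 2]))]
  lvl <- img$cells$GFP_level
  rec <- q$cells$marker_mean[id]
  # region means are proportional to truth, attenuated by the blob/region
  # area ratio and the high-pass halo (both multiplicative)
  s <- coef(lm(rec ~ 0 + lvl))
  expect_gt(cor(rec, lvl), 0.95)
  expect_true(s > 0.4 && s < 0.9)
  expect_lt(max(abs(rec - s * lvl)) / (s * mean(lvl)), 0.2)
})

test_that("marker levels are recovered near-unit when the blob fills the region", {
  tr <- random_image_truth(16, image_shape = c(256, 256),
                           radius_range = c(9, 11), min_gap = 8,
                           markers = list(GFP = 1),
                           marker_level_range = c(0.5, 1.0),
                           marker_margin = 5,  # blob = analysis region
                           noise_sd = 0, seed = 16)
  img <- generate_image_set(tr, seed = 16)
  seg <- segment_nuclei(img$channels$DAPI)
  rec <- quantify_cells(seg, subtract_background(img$channels$GFP, 40))$cells$marker_mean
  id <- seg$label_image[cbind(round(tr$centers[, 1]), round(tr$centers[, 2]))]
  lvl <- img$cells$GFP_level
  s <- coef(lm(rec[id] ~ 0 + lvl))
  expect_gt(s, 0.8)
  expect_lt(s, 1.0)
  expect_gt(cor(rec[id], lvl), 0.95)
})

test_that("quantification trivial and degenerate cases", {
  mask <- matrix(FALSE, 32, 32)
  mask[(row(mask) - 16)^2 + (col(mask) - 16)^2 <= 16] <- TRUE
  seg <- build_analysis_region(label_nuclei(mask, 5), 3)
  z <- quantify_cells(seg, matrix(0, 32, 32))
  expect_equal(z$cells$marker_mean, 0)
  cst <- quantify_cells(seg, matrix(2.5, 32, 32))
  expect_equal(cst$cells$marker_mean, 2.5)
  empty <- label_nuclei(matrix(FALSE, 8, 8), 5)
  q0 <- quantify_cells(empty, matrix(1, 8, 8))
  expect_equal(nrow(q0$cells), 0)
  expect_true(is.na(q0$slide_mean))
})

test_that("fold change handles identity, scaling and planted shifts", {
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3))$fold_change, 1)
  expect_equal(fold_change(c(2, 4), c(1, 2))$fold_change, 2)
  expect_error(fold_change(numeric(0), 1), "at least one")
  expect_error(fold_change(1, c(0, 0)), "> 0")
})

test_that("the mask is invariant to a positive gain on the raw image", {
  tr <- random_image_truth(15, image_shape = c(256, 256),
                           radius_range = c(9, 11), min_gap = 6, seed = 8)
  img <- generate_image_set(tr, seed = 8)$channels$DAPI
  s1 <- segment_nuclei(img)
  s2 <- segment_nuclei(img * 37.5)
  expect_identical(s1$label_image, s2$label_image)
})

test_that("segmentation count is exact on clean scenes and robust under noise", {
  tr0 <- random_image_truth(30, noise_sd = 0, seed = 9)
  seg0 <- segment_nuclei(generate_image_set(tr0, 9)$channels$DAPI)
  expect_equal(seg0$n_cells, 30)
  tr1 <- random_image_truth(30, noise_sd = 0.1, seed = 9)
  seg1 <- segment_nuclei(generate_image_set(tr1, 9)$channels$DAPI)
  m <- match_nuclei(seg1, tr1)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})
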