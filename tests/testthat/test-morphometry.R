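test_that("size classification honours the exact class boundaries", {
  eps <- 1e-9
  expect_equal(as.character(classify_droplet_area(c(0.5, 1 - eps, 1, 100 - eps, 100))),
               c("tiny", "tiny", "small", "small", "large"))
  expect_error(classify_droplet_area(0), "positive")
  expect_error(classify_droplet_area(-5), "positive")
})

test_that("tissue mask recovers the generated tissue fraction", {
  im <- generate_image(image_spec(n_tiny = 8, n_small = 4, n_large = 1,
                                  tissue_fraction = 0.8, seed = 31))
  mask <- segment_tissue(im$image)
  target <- 0.8 * length(im$image)
  expect_lt(abs(sum(mask) - target) / target, 0.10)
  # droplet lumina belong to tissue
  expect_true(all(mask[im$image >= 220]))
})

test_that("blank and uniform rasters raise an explicit no-tissue error", {
  expect_error(segment_tissue(matrix(0L, 64, 64)), "no tissue")
  expect_error(segment_tissue(matrix(128L, 64, 64)), "no tissue")
})

test_that("tissue segmentation is idempotent under masking", {
  im <- generate_image(image_spec(n_tiny = 5, n_small = 2, n_large = 1, seed = 13))
  mask <- segment_tissue(im$image)
  mask2 <- segment_tissue(im$image * mask)
  expect_identical(mask, mask2)
})

test_that("segmentation recovers non-overlapping droplets with accurate areas", {
  spec <- image_spec(n_tiny = 10, n_small = 5, n_large = 2, seed = 4)
  im <- generate_image(spec)
  mask <- segment_tissue(im$image)
  dr <- segment_droplets(im$image, mask, spec$pixel_size_um)
  m <- match_droplets(im$droplets, dr)
  expect_equal(m$matched, nrow(im$droplets))
  expect_equal(m$n_detected, nrow(im$droplets))
  rel <- abs(dr$area_um2[m$det_idx] - im$droplets$area_um2[m$truth_idx]) /
    im$droplets$area_um2[m$truth_idx]
  expect_true(all(rel <= 0.10))
  expect_equal(as.character(dr$size_class[m$det_idx]),
               im$droplets$size_class[m$truth_idx])
})

test_that("elongated bright artifacts are removed by the shape filter", {
  im <- generate_image(image_spec(n_tiny = 0, n_small = 0, n_large = 0, seed = 2))
  img <- im$image
  img[200:201, 150:209] <- 240L  # 2x60 bar: circularity ~ 0.1
  mask <- segment_tissue(img)
  dr <- segment_droplets(img, mask, 0.25)
  expect_equal(nrow(dr), 0)
})

test_that("an image without droplets yields an empty droplet table", {
  im <- generate_image(image_spec(n_tiny = 0, n_small = 0, n_large = 0, seed = 3))
  mask <- segment_tissue(im$image)
  dr <- segment_droplets(im$image, mask, 0.25)
  expect_equal(nrow(dr), 0)
  expect_named(dr, c("droplet_id", "centroid_x", "centroid_y", "area_um2",
                     "perimeter_um", "circularity", "size_class"))
})

test_that("segmentation validates calibration and mask geometry", {
  im <- generate_image(image_spec(n_tiny = 2, n_small = 0, n_large = 0, seed = 11))
  mask <- segment_tissue(im$image)
  expect_error(segment_droplets(im$image, mask, -1), "pixel_size_um")
  expect_error(segment_droplets(im$image, mask[1:100, 1:100], 0.25), "dimensions")
  expect_error(segment_droplets(im$image, mask & FALSE, 0.25), "empty")
})

test_that("doubling the calibration quadruples areas and keeps circularity", {
  spec <- image_spec(n_tiny = 4, n_small = 3, n_large = 1, seed = 19)
  im <- generate_image(spec)
  mask <- segment_tissue(im$image)
  d1 <- segment_droplets(im$image, mask, 0.25)
  d2 <- segment_droplets(im$image, mask, 0.50)
  expect_equal(d2$area_um2, 4 * d1$area_um2)
  expect_equal(d2$circularity, d1$circularity)
  expect_equal(d2$perimeter_um, 2 * d1$perimeter_um)
})

test_that("profiles are additive and match hand arithmetic", {
  one <- data.frame(area_um2 = 100, size_class = classify_droplet_area(100))
  p <- compute_profile(one, tissue_area_um2 = 1e4)
  expect_equal(p$large_pct, 1.0)
  expect_equal(p$total_pct, 1.0)

  empty <- data.frame(area_um2 = numeric(), size_class = character())
  p0 <- compute_profile(empty, tissue_area_um2 = 5000)
  expect_equal(p0$total_pct, 0)
  expect_equal(p0$tiny_pct + p0$small_pct + p0$large_pct, 0)

  im <- generate_image(image_spec(n_tiny = 12, n_small = 6, n_large = 2, seed = 23))
  mask <- segment_tissue(im$image)
  dr <- segment_droplets(im$image, mask, 0.25)
  prof <- compute_profile(dr, sum(mask) * 0.25^2)
  expect_lt(abs(prof$tiny_pct + prof$small_pct + prof$large_pct - prof$total_pct),
            1e-9)
  truth <- compute_profile(
    data.frame(area_um2 = im$droplets$area_um2,
               size_class = im$droplets$size_class),
    sum(im$tissue_mask) * 0.25^2)
  expect_lt(abs(prof$total_pct - truth$total_pct) / truth$total_pct, 0.10)

  expect_error(compute_profile(data.frame(area_um2 = 200,
                                          size_class = classify_droplet_area(200)),
                               tissue_area_um2 = 100),
               "calibration")
})

test_that("watershed splitting separates touching droplets", {
  img <- matrix(110L, 128, 128)
  # two overlapping discs forming a dumbbell
  for (ctr in list(c(60, 55), c(60, 75))) {
    for (r in 1:128) for (c in 1:128) {
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 12^2) img[r, c] <- 235L
    }
  }
  mask <- matrix(TRUE, 128, 128)
  merged <- segment_droplets(img, mask, 0.25, watershed = FALSE)
  split <- segment_droplets(img, mask, 0.25, watershed = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(nrow(split), 2)
})
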