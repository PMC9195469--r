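test_that("Otsu threshold separates a bimodal image and matches the exhaustive oracle", {
  set.seed(31)
  v <- c(rep(10, 900), rep(200, 100)) + rnorm(1000, 0, 1)
  img <- matrix(v, 40, 25)
  th <- otsu_threshold(img)
  expect_gt(th, max(v[v < 100]))
  expect_lt(th, min(v[v > 100]))
  mask <- otsu_mask(img)
  expect_equal(sum(mask), 100)
  expect_equal(attr(mask, "threshold"), th)
  expect_error(otsu_threshold(matrix(5, 3, 3)), "constant")

  # exhaustive-search oracle equality over random images
  for (i in 1:5) {
    r <- matrix(c(rnorm(300, 0.2, 0.05), rnorm(120, 0.8, 0.08)), 20, 21)
    expect_equal(otsu_threshold(r), otsu_oracle(as.vector(r)),
                 tolerance = 1e-12)
  }

  # affine rescaling moves the threshold affinely (up to bin quantization)
  r <- matrix(c(rnorm(200, 0.3, 0.05), rnorm(100, 0.7, 0.05)), 20, 15)
  th0 <- otsu_threshold(r)
  th1 <- otsu_threshold(3 * r + 2)
  expect_equal(th1, 3 * th0 + 2, tolerance = 3 * diff(range(r)) / 256)

  # swapping foreground/background proportions yields the complementary mask
  inv <- max(r) + min(r) - r
  m0 <- otsu_mask(r); m1 <- otsu_mask(inv)
  expect_gte(mean(m0 == !m1), 0.99)  # equality up to bin-edge pixels
})

test_that("8-connected component counting respects min_area", {
  m <- matrix(FALSE, 20, 20)
  expect_equal(nrow(count_nuclei(m)), 0)
  m[2:6, 2:6] <- TRUE
  m[10:14, 12:16] <- TRUE
  got <- count_nuclei(m, min_area = 4)
  expect_equal(nrow(got), 2)
  expect_equal(sort(got$area), c(25, 25))
  expect_equal(sort(got$centroid_row), c(4, 12))

  # diagonal-only touching pixels belong to one 8-connected component
  d <- matrix(FALSE, 5, 5)
  d[cbind(1:4, 1:4)] <- TRUE
  expect_equal(nrow(count_nuclei(d, min_area = 1)), 1)

  # speck below min_area is discarded
  m[18, 18] <- TRUE
  expect_equal(nrow(count_nuclei(m, min_area = 4)), 2)
})

test_that("labeling agrees with a 4-connectivity-safe reference on blob images", {
  img <- generate_nuclei_image(image_sim_config(n_nuclei = 40, seed = 77,
                                                background_sd = 0.005))
  mask <- otsu_mask(img$nuclear)
  ours <- count_nuclei(mask, min_area = 1)
  # round blobs have no diagonal-only joins, so 4- and 8-connectivity agree
  ref <- max(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  expect_equal(nrow(ours), ref)
})

test_that("marker-positive percentage behaves at the trivial extremes", {
  img <- generate_nuclei_image(image_sim_config(n_nuclei = 60,
                                                positive_fraction = 0,
                                                background_sd = 0,
                                                seed = 5))
  # positive_fraction 0 -> marker channel is pure background (all zero)
  expect_equal(max(img$marker), 0)
  r0 <- percent_positive(img, cutoff = 0.5)
  expect_equal(r0$percent_positive, 0)

  # marker identical to nuclear with a permissive cutoff -> 100%
  full <- two_channel_image(img$nuclear, img$nuclear)
  r1 <- percent_positive(full, cutoff = 1e-6)
  expect_equal(r1$percent_positive, 100)

  # zero segmentable nuclei (only a sub-min_area speck) -> undefined, not 0%
  speck <- matrix(0, 20, 20); speck[2:4, 2:4] <- 1
  flat <- two_channel_image(speck, matrix(0.5, 20, 20))
  rz <- percent_positive(flat, cutoff = 0.1, min_area = 50)
  expect_true(rz$undefined)
  expect_true(is.na(rz$percent_positive))

  # raising the cutoff never increases the percentage
  img2 <- generate_nuclei_image(image_sim_config(n_nuclei = 80,
                                                 positive_fraction = 0.5,
                                                 seed = 6))
  cuts <- seq(0.05, 0.9, by = 0.05)
  pcts <- vapply(cuts, function(ct)
    percent_positive(img2, cutoff = ct)$percent_positive, numeric(1))
  expect_true(all(diff(pcts) <= 1e-12))
})

test_that("ground-truth recovery on a rendered 40% fixture is within 2 points", {
  img <- generate_nuclei_image(image_sim_config(n_nuclei = 100,
                                                positive_fraction = 0.4,
                                                background_sd = 0.01,
                                                seed = 41))
  gt <- ground_truth(img)
  expect_equal(gt$total_nuclei, 100)
  expect_equal(gt$positive_nuclei, 40)
  expect_equal(gt$percent_positive, 40)
  res <- percent_positive(img, cutoff = "otsu")
  expect_lte(abs(res$total_nuclei - 100), 2)
  expect_lte(abs(res$percent_positive - 40), 2)

  # the EdU regime: a 5% positive fraction reads back below 7%
  edu <- generate_nuclei_image(image_sim_config(n_nuclei = 100,
                                                positive_fraction = 0.05,
                                                background_sd = 0.01,
                                                seed = 42))
  re <- percent_proliferating(edu, cutoff = "otsu")
  expect_lt(re$percent_positive, 7)
  expect_gt(re$percent_positive, 1)
})

test_that("intensity ratio is the DAPI-normalized mean and gain-invariant", {
  a <- matrix(runif(100, 0.1, 1), 10)
  expect_equal(mean_intensity_ratio(two_channel_image(a, a)), 1)
  expect_equal(mean_intensity_ratio(two_channel_image(a, 2 * a)), 2)
  expect_equal(mean_intensity_ratio(two_channel_image(0.5 * a, 0.5 * 2 * a)),
               2, tolerance = 1e-12)
  expect_error(mean_intensity_ratio(two_channel_image(matrix(0, 5, 5),
                                                      matrix(0, 5, 5))),
               "zero mean")
})

test_that("percent_positive is invariant to a joint translation of both channels", {
  img <- generate_nuclei_image(image_sim_config(width = 200, height = 200,
                                                n_nuclei = 30,
                                                positive_fraction = 0.5,
                                                seed = 8))
  r0 <- percent_positive(img, cutoff = 0.3)
  shift <- function(m, k) rbind(m[(k + 1):nrow(m), ], m[1:k, ])
  # blobs sit >= 3 sigma from the border, so a small cyclic shift is wrap-free
  img2 <- two_channel_image(shift(img$nuclear, 5), shift(img$marker, 5))
  r1 <- percent_positive(img2, cutoff = 0.3)
  expect_equal(r1$percent_positive, r0$percent_positive)
  expect_equal(r1$total_nuclei, r0$total_nuclei)
})

test_that("two-channel TIFF round-trips", {
  img <- generate_nuclei_image(image_sim_config(width = 64, height = 64,
                                                n_nuclei = 6,
                                                min_separation = 15,
                                                seed = 3))
  f <- withr::local_tempfile(fileext = ".tif")
  write_two_channel_tiff(img, f)
  back <- read_two_channel_tiff(f)
  expect_equal(back$nuclear, img$nuclear, tolerance = 1e-6)
  expect_equal(back$marker, img$marker, tolerance = 1e-6)
})

test_that("image generator validates config and errors on impossible packing", {
  expect_error(image_sim_config(positive_fraction = 1.2), "positive_fraction")
  tight <- image_sim_config(width = 60, height = 60, n_nuclei = 200,
                            min_separation = 20, seed = 1)
  expect_error(generate_nuclei_image(tight), "could not place")
})
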