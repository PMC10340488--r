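# Handcrafted segmentation pipeline: color constancy, channel extraction,
# Hadamard enhancement, bilateral smoothing, Otsu, morphological refinement.

test_that("color constancy fixes gray images and conserves the gray mean", {
  img <- array(128, c(4, 4, 3))
  expect_identical(color_constancy(img), img)

  # channel means (200, 100, 50) under BT.601: gray mean 124.2 and weights
  # (0.621, 1.242, 2.484); each unclipped output channel mean equals 124.2
  set.seed(1)
  img <- rand_image(32, 32)
  for (c in 1:3) img[, , c] <- img[, , c] - mean(img[, , c]) + c(200, 100, 50)[c]
  img <- pmin(pmax(img, 0), 255)
  means <- apply(img, 3, mean)
  w <- c(0.299, 0.587, 0.114)
  gray <- sum(w * means)
  out <- color_constancy(img, w, clip = FALSE)
  for (c in 1:3)
    expect_equal(mean(out[, , c]), gray, tolerance = 1e-6)

  # the pure spec example, computed by independent summation
  expect_equal(sum(w * c(200, 100, 50)), 124.2)
  expect_equal(124.2 / c(200, 100, 50), c(0.621, 1.242, 2.484))
})

test_that("color constancy conserves means on random images (invariant)", {
  set.seed(42)
  for (i in 1:10) {
    img <- rand_image(16, 16)
    img[, , 1] <- pmax(img[, , 1], 1) # avoid degenerate channels
    gray <- sum(c(0.299, 0.587, 0.114) * apply(img, 3, mean))
    out <- color_constancy(img, clip = FALSE)
    expect_equal(apply(out, 3, mean), rep(gray, 3), tolerance = 1e-6)
  }
})

test_that("an all-zero channel raises a degenerate-channel error", {
  img <- rand_image(8, 8)
  img[, , 3] <- 0
  expect_error(color_constancy(img), "degenerate channel.*B")
})

test_that("magenta extraction follows the naive CMYK device conversion", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(extract_magenta(px(255, 0, 255))[1, 1], 1)
  expect_equal(extract_magenta(px(0, 255, 0))[1, 1], 0)
  expect_equal(extract_magenta(px(128, 128, 128))[1, 1], 0) # K = 1 - 128/255
  expect_equal(extract_magenta(px(0, 0, 0))[1, 1], 0)       # K = 1 convention
  # generic pixel: M = (max - g)/max on the normalized triple
  expect_equal(extract_magenta(px(200, 100, 50))[1, 1], (200 - 100) / 200)
})

test_that("saturation extraction matches (max - min)/max", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(extract_saturation(px(77, 77, 77))[1, 1], 0)
  expect_equal(extract_saturation(px(255, 0, 255))[1, 1], 1)
  expect_equal(extract_saturation(px(200, 100, 50))[1, 1], 0.75)
  expect_equal(extract_saturation(px(0, 0, 0))[1, 1], 0)
})

test_that("Hadamard product is pointwise dominated by both factors", {
  expect_equal(hadamard_enhance(matrix(1), matrix(1))[1, 1], 1)
  expect_equal(hadamard_enhance(matrix(0), matrix(0.7))[1, 1], 0)
  expect_equal(hadamard_enhance(matrix(0.8), matrix(0.5))[1, 1], 0.4)
  set.seed(3)
  m <- matrix(runif(64), 8); s <- matrix(runif(64), 8)
  out <- hadamard_enhance(m, s)
  expect_true(all(out <= pmin(m, s) + 1e-12))
  expect_error(hadamard_enhance(m, matrix(0.5, 4, 4)), "dimension")
})

test_that("bilateral filter smooths noise but keeps constants and edges", {
  cfg <- seg_config()
  flat <- matrix(0.4, 20, 20)
  expect_equal(bilateral_smooth(flat, cfg), flat)

  # salt-and-pepper on a flat region: variance strictly decreases
  set.seed(7)
  noisy <- flat
  hit <- sample(400, 40)
  noisy[hit] <- rep(c(0.35, 0.45), 20)
  out <- bilateral_smooth(noisy, cfg)
  expect_lt(stats::var(as.vector(out)), stats::var(as.vector(noisy)))

  # ideal step edge with range sigma << step: edge column preserved
  step <- cbind(matrix(0.1, 16, 8), matrix(0.9, 16, 8))
  sm <- bilateral_smooth(step, cfg)
  grad_in <- abs(diff(t(step)))[, 1]
  grad_out <- abs(diff(t(sm)))[, 1]
  expect_lte(abs(which.max(grad_out) - which.max(grad_in)), 1)
  # output bounded by input range
  expect_gte(min(sm), min(step)); expect_lte(max(sm), max(step))
})

test_that("Otsu splits a bimodal image and warns on constant input", {
  ch <- matrix(rep(c(0.1, 0.9), each = 32), 8, 8)
  mask <- otsu_binarize(ch)
  expect_identical(mask, ch > 0.5)
  expect_warning(out <- otsu_binarize(matrix(0.5, 5, 5)), "degenerate")
  expect_false(any(out))
})

test_that("Otsu equals the exhaustive brute-force threshold (oracle)", {
  set.seed(11)
  for (i in 1:20) {
    h <- sample(4:32, 1); w <- sample(4:32, 1)
    ch <- matrix(sample(0:255, h * w, replace = TRUE) / 255, h, w)
    t_oracle <- otsu_brute(ch)
    mask <- otsu_binarize(ch)
    expect_identical(mask, matrix(floor(ch * 255 + 0.5) > t_oracle, h, w))
  }
})

test_that("refinement fills holes, enforces the area floor, merges gaps", {
  # interior hole gets filled, square otherwise unchanged
  sq <- matrix(FALSE, 26, 26); sq[4:23, 4:23] <- TRUE
  holed <- sq; holed[12, 12] <- FALSE
  out <- refine_mask(holed, seg_config(closing_radius = 1, min_area = 5))
  expect_identical(out, sq)

  # area filter removes small components
  small <- matrix(FALSE, 20, 20); small[3:7, 3:4] <- TRUE # area 10
  expect_false(any(refine_mask(small, seg_config(min_area = 50))))
  expect_true(all(refine_mask(small, seg_config(min_area = 10))[3:7, 3:4]))

  # closing with radius 2 bridges a 1-px gap between two blocks
  two <- matrix(FALSE, 20, 20)
  two[5:15, 4:9] <- TRUE; two[5:15, 11:16] <- TRUE
  merged <- refine_mask(two, seg_config(closing_radius = 2, min_area = 5))
  lab <- EBImage::bwlabel(matrix(as.numeric(merged), 20, 20))
  expect_equal(max(lab), 1)

  # every surviving component respects the area floor (property)
  set.seed(5)
  for (i in 1:5) {
    m <- rand_mask(24, 24, 0.35)
    ref <- refine_mask(m, seg_config(closing_radius = 1, min_area = 12))
    lab <- EBImage::bwlabel(matrix(as.numeric(ref), 24, 24))
    if (max(lab) > 0)
      expect_true(all(tabulate(lab[lab > 0]) >= 12))
  }
})

test_that("full handcrafted pipeline segments a synthetic smear", {
  sm <- make_smear(smear_params(seed = 1))
  seg <- segment_handcrafted(sm$image)
  expect_gte(evaluate_masks(seg$mask, sm$mask)$iou, 0.9)
  # masked image zeroes the background
  expect_true(all(seg$masked[, , 1][!seg$mask] == 0))

  # determinism: identical input + config -> identical mask
  seg2 <- segment_handcrafted(sm$image)
  expect_identical(seg$mask, seg2$mask)
})

test_that("pipeline degenerate inputs give empty masks", {
  flat <- array(200, c(32, 32, 3))
  flat[, , 2] <- 180; flat[, , 3] <- 190
  expect_false(any(segment_handcrafted(flat)$mask))

  nuc <- array(0, c(32, 32, 3))
  nuc[, , 1] <- 115; nuc[, , 2] <- 35; nuc[, , 3] <- 150
  big <- seg_config(min_area = 32 * 32 + 1)
  expect_false(any(segment_handcrafted(nuc, big)$mask))
})

test_that("config validation rejects bad values", {
  expect_error(seg_config(bilateral_sigma_color = -1), "positive")
  expect_error(seg_config(grayscale_weights = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("segmentation config round-trips through YAML", {
  skip_if_not_installed("yaml")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  cfg <- seg_config(closing_radius = 2, min_area = 40)
  write_seg_config(cfg, tmp)
  expect_equal(read_seg_config(tmp), cfg)
  # NA min_area (relative default) survives the round trip
  cfg2 <- seg_config()
  write_seg_config(cfg2, tmp)
  expect_true(is.na(read_seg_config(tmp)$min_area))
})
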