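test_that("RGB to LUV conversion matches the CIE reference points", {
  rect <- array(0, c(1, 3, 3))
  rect[1, 2, ] <- 1            # white
  rect[1, 3, ] <- 0.5          # mid gray
  luv <- rgb_to_luv(rect)
  expect_equal(luv[1, 1, 1], 0)            # black: L* = 0
  expect_equal(luv[1, 2, 1], 100)          # white: L* = 100
  # mid sRGB gray against the standard sRGB -> L* value
  expect_equal(luv[1, 3, 1], 53.389, tolerance = 1e-3)
  expect_equal(luv[1, 3, 2], 0, tolerance = 1e-6)
  expect_equal(luv[1, 3, 3], 0, tolerance = 1e-6)
})

test_that("LUV means are mask-aware and equal the brute-force average", {
  img <- uniform_image(6, 6, c(0.3, 0.7, 0.5))
  reg <- full_region(img)
  luv <- rgb_to_luv(reg$rect)
  f <- luv_means(luv, reg$mask)
  one <- rgb_to_luv(array(c(0.3, 0.7, 0.5), c(1, 1, 3)))
  expect_equal(f, as.vector(one), tolerance = 1e-9)

  # half colour a, half colour b: channel-wise midpoint
  px <- array(0, c(4, 4, 3))
  px[, 1:2, 1] <- 0.2; px[, 1:2, 2] <- 0.4; px[, 1:2, 3] <- 0.6
  px[, 3:4, 1] <- 0.8; px[, 3:4, 2] <- 0.6; px[, 3:4, 3] <- 0.2
  img2 <- raster_image(px, "ab")
  reg2 <- full_region(img2)
  luv2 <- rgb_to_luv(reg2$rect)
  f2 <- luv_means(luv2, reg2$mask)
  expect_equal(f2, (luv_means(luv2, (col(reg2$mask) <= 2) + 0L) +
                      luv_means(luv2, (col(reg2$mask) > 2) + 0L)) / 2)

  # brute-force per-pixel average on a random region
  set.seed(31)
  px3 <- array(runif(48), c(4, 4, 3))
  img3 <- raster_image(px3, "r")
  mask_px <- as.matrix(expand.grid(1:4, 1:4))[sample(16, 9), ]
  reg3 <- min_covering_rect(region("r", mask_px), img3)
  luv3 <- rgb_to_luv(reg3$rect)
  keep <- reg3$mask == 1L
  brute <- c(mean(luv3[, , 1][keep]), mean(luv3[, , 2][keep]),
             mean(luv3[, , 3][keep]))
  expect_equal(luv_means(luv3, reg3$mask), brute)
  expect_error(luv_means(luv3, reg3$mask * 0L), "masked")
})

test_that("block DWT energies detect oriented structure in the right sub-band", {
  # constant region: all detail coefficients zero
  img <- uniform_image(8, 8, c(0.5, 0.5, 0.5))
  grid <- block_grid(full_region(img)$rect, m = 4)
  expect_equal(block_dwt_features(grid), c(0, 0, 0))

  # vertical step edges inside every 2x2 Haar cell (columns a b a b):
  # hand expansion gives LH = HH = 0 and HL = a - b in luminance units,
  # so t_HL = (a-b)^2 while the other bands stay silent
  l_a <- rgb_to_luv(array(0.3, c(1, 1, 3)))[1, 1, 1]
  l_b <- rgb_to_luv(array(0.7, c(1, 1, 3)))[1, 1, 1]
  px2 <- array(0.3, c(4, 8, 3)); px2[, seq(2, 8, 2), ] <- 0.7
  imgv2 <- raster_image(px2, "v2")
  fv2 <- block_dwt_features(block_grid(full_region(imgv2)$rect, m = 4))
  expect_equal(fv2[1], 0)                       # LH
  expect_equal(fv2[2], (l_a - l_b)^2)           # HL
  expect_equal(fv2[3], 0)                       # HH

  # 90-degree rotation swaps LH and HL and preserves HH
  set.seed(8)
  px3 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  img3 <- raster_image(px3, "t")
  f3 <- block_dwt_features(block_grid(full_region(img3)$rect, m = 4))
  rot <- raster_image(aperm(px3[8:1, , , drop = FALSE], c(2, 1, 3)), "t90")
  f3r <- block_dwt_features(block_grid(full_region(rot)$rect, m = 4))
  expect_equal(f3r[1], f3[2], tolerance = 1e-10)
  expect_equal(f3r[2], f3[1], tolerance = 1e-10)
  expect_equal(f3r[3], f3[3], tolerance = 1e-10)
})

test_that("totally black blocks are eliminated and padding never leaks into f4-f6", {
  set.seed(12)
  px <- array(runif(8 * 8 * 3, 0.2, 0.9), c(8, 8, 3))
  img <- raster_image(px, "pad")
  reg <- full_region(img)
  f <- block_dwt_features(block_grid(reg$rect, m = 4))
  # append all-black rows/columns of padding to the rectangle
  padded <- array(0, c(12, 12, 3))
  padded[1:8, 1:8, ] <- reg$rect
  f_pad <- block_dwt_features(block_grid(padded, m = 4))
  expect_equal(f_pad, f)
  all_black <- array(0, c(8, 8, 3))
  expect_error(block_dwt_features(block_grid(all_black, m = 4)),
               "no kept blocks")
})

test_that("normalized inertia scores a disc at 1 and is translation invariant", {
  g <- as.matrix(expand.grid(x = -15:15, y = -15:15))
  disc <- g[g[, 1]^2 + g[, 2]^2 <= 12^2, ]
  l <- normalized_inertia(disc + 20L) # shift into positive pixel coords
  expect_true(all(l >= 0.95 & l <= 1.05))

  expect_equal(normalized_inertia(cbind(5L, 7L)), c(0, 0, 0)) # single pixel

  set.seed(4)
  pts <- as.matrix(expand.grid(1:9, 1:6))[sample(54, 30), ]
  expect_equal(normalized_inertia(pts),
               normalized_inertia(pts + matrix(c(100L, 40L), 30, 2,
                                               byrow = TRUE)))
})

test_that("the DWT9 descriptor has length 9 and is translation invariant", {
  img <- uniform_image(10, 12, c(0.45, 0.55, 0.65))
  sq1 <- min_covering_rect(region("u", as.matrix(expand.grid(1:6, 1:6))), img)
  sq2 <- min_covering_rect(region("u", as.matrix(expand.grid(4:9, 6:11))), img)
  f1 <- extract_dwt9(sq1); f2 <- extract_dwt9(sq2)
  expect_s3_class(f1, "feature_vector")
  expect_length(f1$values, 9L)
  expect_equal(f1$values, f2$values)
  # uniform gray region: texture energies all zero
  expect_equal(f1$values[4:6], c(0, 0, 0))
  # deterministic bit-for-bit
  expect_identical(extract_dwt9(sq1)$values, f1$values)
})

test_that("features stay finite on fuzzed random regions", {
  set.seed(99)
  for (k in 1:20) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    img <- raster_image(array(runif(h * w * 3, 0.05, 1), c(h, w, 3)), "f")
    npix <- sample(seq_len(h * w), 1)
    pts <- as.matrix(expand.grid(seq_len(h), seq_len(w)))[
      sample(h * w, npix), , drop = FALSE]
    reg <- min_covering_rect(region("f", pts), img)
    expect_true(all(is.finite(extract_dwt9(reg)$values)))
  }
})
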