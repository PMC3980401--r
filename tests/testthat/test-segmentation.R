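test_that("pixel-graph weights follow the colour x proximity Gaussian", {
  # 2 x 2 image whose rows differ by 0.3 per channel: edge weights follow
  # the product form on every vertical/horizontal neighbour pair
  px <- array(0, c(2, 2, 3)); px[2, , ] <- 0.3
  img <- raster_image(px, "2x2")
  g <- build_pixel_graph(img, sigma_i = 0.2, sigma_x = 3, radius = 1.5)
  # vertical neighbours differ by 0.3 in each channel, horizontal by 0
  w_vert <- exp(-(3 * 0.3^2) / 0.2^2) * exp(-1 / 3^2)
  w_horz <- exp(0) * exp(-1 / 3^2)
  expect_equal(g$W[1, 2], w_vert)
  expect_equal(g$W[3, 4], w_vert)
  expect_equal(g$W[1, 3], w_horz)
  expect_equal(g$W[2, 4], w_horz)
  expect_true(Matrix::isSymmetric(g$W))

  # radius 1 connects nothing (strict inequality)
  expect_error(build_pixel_graph(img, radius = 1), "empty graph")

  # 3 x 3 uniform image: radius 1.2 gives the pure 4-neighbour lattice
  # (12 undirected edges, one shared weight); radius 1.5 adds the 8
  # diagonals (sqrt(2) < 1.5), enumerated by hand
  u <- uniform_image(3, 3)
  gu <- build_pixel_graph(u, sigma_x = 2, radius = 1.2)
  expect_equal(length(gu$W@x), 2L * 12L)
  expect_equal(length(unique(round(gu$W@x, 12))), 1L)
  gu2 <- build_pixel_graph(u, sigma_x = 2, radius = 1.5)
  expect_equal(length(gu2$W@x), 2L * 20L)
  expect_equal(length(unique(round(gu2$W@x, 12))), 2L)
})

test_that("ncut_value matches hand expansion and is symmetric in the sides", {
  # two vertices, one edge of weight w: Ncut = w/w + w/w = 2
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.37
  g <- pixel_graph(W)
  expect_equal(ncut_value(g, c(TRUE, FALSE)), 2)

  # 4-vertex weighted toy graph, hand expansion of the definition
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- W4[2, 1] <- 0.9
  W4[3, 4] <- W4[4, 3] <- 0.8
  W4[2, 3] <- W4[3, 2] <- 0.1
  W4[1, 4] <- W4[4, 1] <- 0.2
  g4 <- pixel_graph(W4)
  in_a <- c(TRUE, TRUE, FALSE, FALSE)
  cut <- 0.1 + 0.2
  assoc_a <- (0.9 + 0.2) + (0.9 + 0.1)
  assoc_b <- (0.1 + 0.8) + (0.8 + 0.2)
  expect_equal(ncut_value(g4, in_a), cut / assoc_a + cut / assoc_b)
  expect_equal(ncut_value(g4, !in_a), ncut_value(g4, in_a))

  # split along disconnected components costs 0
  Wd <- matrix(0, 4, 4)
  Wd[1, 2] <- Wd[2, 1] <- 1; Wd[3, 4] <- Wd[4, 3] <- 1
  expect_equal(ncut_value(pixel_graph(Wd), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_error(ncut_value(g4, c(TRUE, TRUE, TRUE, TRUE)), "non-empty")
})

test_that("bipartition recovers planted clusters and approaches the brute-force optimum", {
  for (seed in 1:12) {
    rg <- random_two_cluster_graph(n = sample(6:11, 1), seed = seed * 17L)
    g <- pixel_graph(rg$W)
    bp <- bipartition(g)
    oracle <- ncut_bruteforce_min(rg$W)
    expect_lte(bp$value, oracle * 1.05)
    expect_equal(ncut_value(g, bp$in_a), bp$value)
    # planted clusters recovered exactly
    expect_true(all(bp$in_a == (rg$grp == 1L)) ||
                  all(bp$in_a == (rg$grp == 2L)))
  }
})

test_that("bipartition of a disconnected graph returns the components at Ncut 0", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 0.5; W[2, 3] <- W[3, 2] <- 0.5
  W[4, 5] <- W[5, 4] <- 0.9
  bp <- bipartition(pixel_graph(W))
  expect_equal(bp$value, 0)
  expect_equal(bp$in_a, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("complete equal-weight graph bipartition equals the enumeration optimum", {
  W <- matrix(0.6, 4, 4); diag(W) <- 0
  bp <- bipartition(pixel_graph(W))
  expect_equal(bp$value, ncut_bruteforce_min(W))
})

test_that("segment_image returns exactly p connected regions that tile the image", {
  px <- array(0.2, c(12, 12, 3)); px[, 7:12, ] <- 0.9
  img <- raster_image(px, "halves")
  regs <- segment_image(img, 2, radius = 2)
  lab <- segmentation_labels(regs, c(12, 12))
  truth <- matrix(1L, 12, 12); truth[, 7:12] <- 2L
  expect_gte(max(mean(lab == truth), mean(lab == 3L - truth)), 0.99)

  one <- segment_image(img, 1, radius = 2)
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$pixels), 144L)

  set.seed(77)
  px2 <- array(runif(10 * 14 * 3), c(10, 14, 3))
  img2 <- raster_image(px2, "noise")
  for (p in c(3L, 8L)) {
    regs2 <- segment_image(img2, p, sigma_i = 0.5, radius = 2)
    expect_length(regs2, p)
    lab2 <- segmentation_labels(regs2, c(10, 14))
    expect_true(all(lab2 >= 1L)) # coverage: every pixel owned
    expect_equal(sum(vapply(regs2, function(r) nrow(r$pixels), numeric(1))),
                 140) # disjointness + coverage
  }
})

test_that("nested granularities never re-merge separated disconnected pieces", {
  px <- array(0.1, c(10, 10, 3)); px[, 6:10, ] <- 0.9
  img <- raster_image(px, "two")
  multi <- segment_image_multi(img, c(2, 3, 4), radius = 2)
  lab2 <- segmentation_labels(multi$p2, c(10, 10))
  for (pn in c("p3", "p4")) {
    labk <- segmentation_labels(multi[[pn]], c(10, 10))
    # every region at the finer level lies within one region of the coarser
    # level up to the small-fragment repair: check the two halves stay apart
    left <- labk[, 1:4]; right <- labk[, 7:10]
    expect_length(intersect(unique(as.vector(left)),
                            unique(as.vector(right))), 0L)
  }
  expect_error(segment_image(img, 101, radius = 2), "p exceeds")
})

test_that("minimum covering rectangles pad with black and mask the originals", {
  img <- uniform_image(5, 5, c(0.6, 0.4, 0.2))
  # L-shaped region: 3x3 square minus its top-right corner
  px_set <- rbind(c(2, 2), c(3, 2), c(4, 2), c(2, 3), c(3, 3), c(4, 3),
                  c(3, 4), c(4, 4))
  reg <- min_covering_rect(region("u", px_set), img)
  expect_equal(dim(reg$rect)[1:2], c(3L, 3L))
  expect_equal(sum(reg$mask), 8L)
  expect_equal(reg$mask[1, 3], 0L) # the missing corner
  expect_true(all(reg$rect[1, 3, ] == 0)) # padded black
  expect_true(all(reg$rect[, , 1][reg$mask == 1L] == 0.6))

  # a rectangular region needs no padding
  rect_reg <- min_covering_rect(
    region("u", as.matrix(expand.grid(2:3, 2:4))), img)
  expect_true(all(rect_reg$mask == 1L))
  # single pixel
  single <- min_covering_rect(region("u", cbind(3, 3)), img)
  expect_equal(dim(single$rect)[1:2], c(1L, 1L))
})
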