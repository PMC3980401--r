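#' Feature vectors
#'
#' Ordered numeric descriptors of one region, tagged with the scheme that
#' produced them: `DWT9` (9 values f1..f9: LUV channel means, Haar sub-band
#' energies, normalized inertia of orders 1-3) or `SIFT128` (a 128-value
#' aggregated keypoint descriptor).
#'
#' @param values numeric vector; length 9 for `DWT9`, 128 for `SIFT128`.
#' @param scheme `"DWT9"` or `"SIFT128"`.
#' @return A `feature_vector`.
#' @export
feature_vector <- function(values, scheme = c("DWT9", "SIFT128")) {
  scheme <- match.arg(scheme)
  need <- if (scheme == "DWT9") 9L else 128L
  values <- as.numeric(values)
  if (length(values) != need)
    stop(scheme, " feature vector must have length ", need)
  if (!all(is.finite(values))) stop("feature values must be finite")
  structure(list(values = values, scheme = scheme), class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector %s: %s%s>\n", x$scheme,
              paste(signif(utils::head(x$values, 6L), 4L), collapse = ", "),
              if (length(x$values) > 6L) ", ..." else ""))
  invisible(x)
}

#' Convert an RGB rectangle to CIE L*u*v*
#'
#' sRGB on `[0, 1]` to CIE 1976 L*u*v* under the D65 white point. L* ranges
#' over `[0, 100]` with black at 0 and white at 100.
#'
#' @param rect H x W x 3 RGB array with values in `[0, 1]`.
#' @return H x W x 3 array of (L, u, v).
#' @export
rgb_to_luv <- function(rect) {
  stopifnot(length(dim(rect)) == 3L, dim(rect)[3] == 3L)
  d <- dim(rect)
  flat <- cbind(as.vector(rect[, , 1]), as.vector(rect[, , 2]),
                as.vector(rect[, , 3]))
  luv <- grDevices::convertColor(flat, from = "sRGB", to = "Luv")
  array(luv, c(d[1], d[2], 3L))
}

#' LUV channel means of a region (features f1-f3)
#'
#' Means of the L, u, v channels taken over the region's original pixels
#' only: the black padding introduced by the covering rectangle is excluded
#' through the mask.
#'
#' @param luv H x W x 3 L*u*v* array (see [rgb_to_luv()]).
#' @param mask H x W 0/1 matrix; 1 marks original region pixels.
#' @return Numeric c(f1, f2, f3).
#' @export
luv_means <- function(luv, mask) {
  stopifnot(identical(dim(luv)[1:2], dim(mask)))
  keep <- mask == 1L
  if (!any(keep)) stop("luv_means: region is fully masked")
  c(mean(luv[, , 1][keep]), mean(luv[, , 2][keep]), mean(luv[, , 3][keep]))
}

#' Tile a region rectangle into m x m blocks
#'
#' The rectangle is divided into disjoint `m` x `m` tiles; partial tiles at
#' the right/bottom edge are dropped. Tiles whose source pixels are all pure
#' black `(0,0,0)` — i.e. pure padding — are eliminated so padding does not
#' contaminate the texture statistics.
#'
#' @param rect H x W x 3 RGB rectangle (padded, `[0, 1]`).
#' @param m block edge in pixels (default 4).
#' @return list with `blocks` (list of m x m luminance-channel matrices from
#'   [rgb_to_luv()]), `kept` (logical per tile) and the tile grid size.
#' @export
block_grid <- function(rect, m = 4L) {
  d <- dim(rect)
  nb_r <- d[1] %/% m; nb_c <- d[2] %/% m
  if (nb_r < 1L || nb_c < 1L)
    return(list(blocks = list(), kept = logical(0), grid = c(nb_r, nb_c)))
  luv <- rgb_to_luv(rect)
  black <- rect[, , 1] == 0 & rect[, , 2] == 0 & rect[, , 3] == 0
  blocks <- list(); kept <- logical(0)
  for (q in seq_len(nb_c)) for (p in seq_len(nb_r)) {
    rr <- ((p - 1L) * m + 1L):(p * m); cc <- ((q - 1L) * m + 1L):(q * m)
    keep <- !all(black[rr, cc])
    kept <- c(kept, keep)
    if (keep) blocks[[length(blocks) + 1L]] <- luv[rr, cc, 1]
  }
  list(blocks = blocks, kept = kept, grid = c(nb_r, nb_c))
}

# one-level 2-D Haar transform of an even-sized matrix; returns the LH
# (horizontal-detail), HL (vertical-detail) and HH (diagonal) sub-bands.
# On a 2x2 cell (a b / c d) the orthonormal coefficients are
#   LL=(a+b+c+d)/2, LH=(a+b-c-d)/2, HL=(a-b+c-d)/2, HH=(a-b-c+d)/2.
haar2d <- function(x) {
  a <- x[seq(1, nrow(x), 2), seq(1, ncol(x), 2), drop = FALSE]
  b <- x[seq(1, nrow(x), 2), seq(2, ncol(x), 2), drop = FALSE]
  c_ <- x[seq(2, nrow(x), 2), seq(1, ncol(x), 2), drop = FALSE]
  d <- x[seq(2, nrow(x), 2), seq(2, ncol(x), 2), drop = FALSE]
  list(LL = (a + b + c_ + d) / 2, LH = (a + b - c_ - d) / 2,
       HL = (a - b + c_ - d) / 2, HH = (a - b - c_ + d) / 2)
}

#' Block-wise wavelet texture energies (features f4-f6)
#'
#' Each kept m x m block of the luminance channel is passed through a
#' one-level 2-D Haar transform; the LH, HL and HH detail sub-bands each
#' yield the statistic \eqn{t_x = \frac{1}{4} x^T x} (mean squared
#' coefficient energy over the four band coefficients of a 4 x 4 block).
#' Features f4, f5, f6 are the averages of \eqn{t_{LH}, t_{HL}, t_{HH}}
#' over all kept blocks. Optionally the square root of the energy is used
#' instead (`stat = "sqrt_energy"`).
#'
#' @param grid a [block_grid()] result with at least one kept block.
#' @param stat `"energy"` (default, \eqn{(1/4) x^T x}) or `"sqrt_energy"`.
#' @return Numeric c(f4, f5, f6).
#' @export
block_dwt_features <- function(grid, stat = c("energy", "sqrt_energy")) {
  stat <- match.arg(stat)
  if (!length(grid$blocks)) stop("region fully padded: no kept blocks")
  t_mat <- vapply(grid$blocks, function(blk) {
    h <- haar2d(blk)
    vapply(h[c("LH", "HL", "HH")],
           function(band) mean(band^2), numeric(1))
  }, numeric(3))
  f <- rowMeans(t_mat)
  if (stat == "sqrt_energy") f <- sqrt(f)
  unname(f)
}

# the N pixel positions nearest the origin: a discrete disc of N pixels
disc_pixels <- function(N) {
  r <- ceiling(sqrt(N / pi)) + 2L
  gx <- rep(-r:r, times = 2L * r + 1L)
  gy <- rep(-r:r, each = 2L * r + 1L)
  d2 <- gx^2 + gy^2
  ord <- order(d2, gx, gy)[seq_len(N)]
  cbind(gx[ord], gy[ord])
}

raw_inertia <- function(xy, gamma) {
  n <- nrow(xy)
  ctr <- colMeans(xy)
  r2 <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2
  sum(r2^gamma) / n^(1 + gamma)
}

#' Normalized inertia shape features (f7-f9)
#'
#' The order-\eqn{\gamma} inertia of a pixel set,
#' \deqn{l(\gamma) = \frac{\sum_{(x,y)} ((x-\bar x)^2+(y-\bar y)^2)^\gamma}
#'       {N^{1+\gamma}},}
#' normalized by the same quantity computed for a discrete disc of the same
#' pixel count, so a disc scores ~1. Translation-invariant by construction
#' (centroid-relative) and scale-comparable across region sizes.
#'
#' @param pixels N x 2 matrix of (row, col) positions.
#' @param orders inertia orders (default 1:3, giving f7, f8, f9).
#' @return Numeric vector, one value per order.
#' @export
normalized_inertia <- function(pixels, orders = 1:3) {
  pixels <- matrix(as.numeric(pixels), ncol = 2L)
  if (nrow(pixels) < 1L) stop("empty pixel set")
  disc <- disc_pixels(nrow(pixels))
  vapply(orders, function(g) {
    num <- raw_inertia(pixels, g)
    den <- raw_inertia(disc, g)
    if (den == 0) 0 else num / den
  }, numeric(1))
}

#' The 9-dimensional region descriptor (f1-f9)
#'
#' Runs the full per-region pipeline: covering rectangle to L*u*v*, channel
#' means over unmasked pixels (f1-f3), block-wise Haar detail energies over
#' non-black m x m tiles (f4-f6), and normalized inertia of orders 1-3 of
#' the pixel set (f7-f9). Deterministic and invariant to translation of the
#' region within its image.
#'
#' @param reg a [region] with `rect` and `mask` populated (see
#'   [min_covering_rect()]).
#' @param m DWT block edge (default 4).
#' @param stat energy statistic, see [block_dwt_features()].
#' @return A [feature_vector] of scheme `DWT9`.
#' @export
extract_dwt9 <- function(reg, m = 4L, stat = "energy") {
  stopifnot(inherits(reg, "region"))
  if (is.null(reg$rect) || is.null(reg$mask))
    stop("region lacks rect/mask; call min_covering_rect() first")
  luv <- rgb_to_luv(reg$rect)
  f123 <- luv_means(luv, reg$mask)
  grid <- block_grid(reg$rect, m = m)
  f456 <- if (length(grid$blocks)) block_dwt_features(grid, stat = stat)
          else c(0, 0, 0) # region thinner than one block: no texture signal
  f789 <- normalized_inertia(reg$pixels)
  feature_vector(c(f123, f456, f789), "DWT9")
}
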