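#' SIFT-style region descriptors
#'
#' A scale-invariant keypoint descriptor in the classic mould: keypoints are
#' detected as local extrema of a difference-of-Gaussians scale stack inside
#' the region's unmasked area, each keypoint is assigned its dominant
#' gradient orientation, and an 8-orientation x 4 x 4-cell gradient
#' histogram is accumulated over a rotated, scale-proportional patch,
#' yielding 8 x 16 = 128 values per keypoint (normalized, clipped at 0.2,
#' renormalized). [extract_sift()] averages the per-keypoint descriptors
#' into one 128-vector per region, keeping one instance per region as the
#' bag representation requires.
#'
#' @name sift
NULL

# separable Gaussian blur with replicate padding
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * mp[t:(t + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(x))))
}

image_gradients <- function(x) {
  H <- nrow(x); W <- ncol(x)
  gx <- (x[, c(2:W, W), drop = FALSE] - x[, c(1, 1:(W - 1)), drop = FALSE]) / 2
  gy <- (x[c(2:H, H), , drop = FALSE] - x[c(1, 1:(H - 1)), , drop = FALSE]) / 2
  list(mag = sqrt(gx^2 + gy^2), ang = atan2(gy, gx))
}

bilinear_at <- function(x, r, c) {
  H <- nrow(x); W <- ncol(x)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- floor(r); c0 <- floor(c)
  r0 <- pmin(r0, H - 1L); c0 <- pmin(c0, W - 1L)
  fr <- r - r0; fc <- c - c0
  x[cbind(r0, c0)] * (1 - fr) * (1 - fc) + x[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    x[cbind(r0, c0 + 1)] * (1 - fr) * fc + x[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# DoG keypoints: (row, col, sigma) triples inside the mask
detect_keypoints <- function(gray, mask, contrast = 0.02) {
  sigmas <- 1.6 * 2^((0:4) / 2)
  stack <- lapply(sigmas, function(s) gauss_blur(gray, s))
  dogs <- lapply(seq_len(length(stack) - 1L),
                 function(i) stack[[i + 1L]] - stack[[i]])
  H <- nrow(gray); W <- ncol(gray)
  kps <- NULL
  for (s in 2:(length(dogs) - 1L)) {
    d <- dogs[[s]]
    cand <- which(abs(d) > contrast, arr.ind = TRUE)
    cand <- cand[cand[, 1] > 1 & cand[, 1] < H & cand[, 2] > 1 & cand[, 2] < W,
                 , drop = FALSE]
    if (!nrow(cand)) next
    keep <- vapply(seq_len(nrow(cand)), function(k) {
      r <- cand[k, 1]; c <- cand[k, 2]
      if (mask[r, c] != 1L) return(FALSE)
      v <- d[r, c]
      nb <- c(as.vector(dogs[[s - 1L]][(r - 1):(r + 1), (c - 1):(c + 1)]),
              as.vector(d[(r - 1):(r + 1), (c - 1):(c + 1)]),
              as.vector(dogs[[s + 1L]][(r - 1):(r + 1), (c - 1):(c + 1)]))
      (v >= max(nb) && v > 0) || (v <= min(nb) && v < 0)
    }, logical(1))
    if (any(keep))
      kps <- rbind(kps, cbind(cand[keep, , drop = FALSE],
                              sigma = sigmas[s + 1L]))
  }
  kps
}

dominant_orientation <- function(grad, r, c, sigma) {
  rad <- max(2L, round(2.5 * sigma))
  H <- nrow(grad$mag); W <- ncol(grad$mag)
  rr <- max(1L, r - rad):min(H, r + rad)
  cc <- max(1L, c - rad):min(W, c + rad)
  m <- grad$mag[rr, cc]; a <- grad$ang[rr, cc]
  wt <- exp(-(outer((rr - r)^2, (cc - c)^2, "+")) / (2 * (1.5 * sigma)^2))
  bins <- (floor((a + pi) / (2 * pi) * 36) %% 36) + 1L
  h <- vapply(1:36, function(b) sum((m * wt)[bins == b]), numeric(1))
  (which.max(h) - 0.5) / 36 * 2 * pi - pi
}

descriptor_at <- function(grad, r, c, sigma, theta) {
  n_cell <- 4L; n_ori <- 8L; samples_per_cell <- 4L
  span <- samples_per_cell * n_cell                 # 16 x 16 sample lattice
  step <- 0.75 * sigma
  offs <- (seq_len(span) - (span + 1) / 2) * step
  os <- expand.grid(dy = offs, dx = offs)
  ct <- cos(theta); st <- sin(theta)
  ry <- r + os$dx * st + os$dy * ct
  cx <- c + os$dx * ct - os$dy * st
  m <- bilinear_at(grad$mag, ry, cx)
  a <- bilinear_at(grad$ang, ry, cx) - theta
  w <- exp(-(os$dx^2 + os$dy^2) / (2 * (0.5 * span * step)^2))
  cell_r <- rep(ceiling(seq_len(span) / samples_per_cell), times = span)
  cell_c <- rep(ceiling(seq_len(span) / samples_per_cell), each = span)
  obin <- (floor((a %% (2 * pi)) / (2 * pi) * n_ori) %% n_ori) + 1L
  idx <- (cell_r - 1L) * n_cell * n_ori + (cell_c - 1L) * n_ori + obin
  desc <- vapply(seq_len(n_cell * n_cell * n_ori),
                 function(i) sum((m * w)[idx == i]), numeric(1))
  nrm <- sqrt(sum(desc^2))
  if (nrm < 1e-12) return(rep(0, 128L))
  desc <- pmin(desc / nrm, 0.2)
  desc / max(sqrt(sum(desc^2)), 1e-12)
}

#' Per-keypoint SIFT-style descriptors of a region
#'
#' @param reg a [region] with `rect` and `mask` populated.
#' @param contrast difference-of-Gaussians contrast threshold.
#' @return k x 128 matrix (k keypoints), or a 0 x 128 matrix when the
#'   region yields no keypoints.
#' @export
sift_keypoint_descriptors <- function(reg, contrast = 0.02) {
  stopifnot(inherits(reg, "region"))
  if (is.null(reg$rect) || is.null(reg$mask))
    stop("region lacks rect/mask; call min_covering_rect() first")
  d <- dim(reg$rect)
  if (d[1] < 16L || d[2] < 16L) {
    warning("region rectangle smaller than 16 x 16; no SIFT keypoints")
    return(matrix(0, 0L, 128L))
  }
  gray <- 0.299 * reg$rect[, , 1] + 0.587 * reg$rect[, , 2] +
    0.114 * reg$rect[, , 3]
  kps <- detect_keypoints(gray, reg$mask, contrast = contrast)
  if (is.null(kps) || !nrow(kps)) return(matrix(0, 0L, 128L))
  grad <- image_gradients(gray)
  t(apply(kps, 1L, function(kp) {
    th <- dominant_orientation(grad, kp[1L], kp[2L], kp[3L])
    descriptor_at(grad, kp[1L], kp[2L], kp[3L], th)
  }))
}

#' Aggregated 128-dimensional SIFT descriptor of a region (SIFT128)
#'
#' Averages the per-keypoint descriptors (8 orientations x 4 x 4 cells =
#' 128 values each) into one vector. Regions with no keypoints — including
#' blank, gradient-free regions and rectangles smaller than 16 x 16 pixels —
#' yield the zero vector.
#'
#' @inheritParams sift_keypoint_descriptors
#' @return A [feature_vector] of scheme `SIFT128`.
#' @export
extract_sift <- function(reg, contrast = 0.02) {
  descs <- suppressWarnings(sift_keypoint_descriptors(reg, contrast))
  if (!nrow(descs)) return(feature_vector(rep(0, 128L), "SIFT128"))
  feature_vector(colMeans(descs), "SIFT128")
}
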