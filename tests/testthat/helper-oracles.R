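# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (double loops, exhaustive enumeration) and
# never call the implementation paths they check.

# brute-force average Hausdorff distance, straight off the definition
ahd_bruteforce <- function(A, B) {
  A <- if (inherits(A, "bag")) A$instances else as.matrix(A)
  B <- if (inherits(B, "bag")) B$instances else as.matrix(B)
  mins_a <- numeric(nrow(A)); mins_b <- numeric(nrow(B))
  for (i in seq_len(nrow(A))) {
    d <- Inf
    for (j in seq_len(nrow(B))) d <- min(d, sqrt(sum((A[i, ] - B[j, ])^2)))
    mins_a[i] <- d
  }
  for (j in seq_len(nrow(B))) {
    d <- Inf
    for (i in seq_len(nrow(A))) d <- min(d, sqrt(sum((A[i, ] - B[j, ])^2)))
    mins_b[j] <- d
  }
  (sum(mins_a) + sum(mins_b)) / (nrow(A) + nrow(B))
}

# exhaustive minimum Ncut over all 2^(n-1)-1 proper bipartitions
ncut_bruteforce_min <- function(W) {
  n <- nrow(W)
  d <- rowSums(W)
  best <- Inf
  for (code in 1:(2^(n - 1L) - 1L)) {
    in_a <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2L)))))
    assoc_a <- sum(d[in_a]); assoc_b <- sum(d[!in_a])
    if (assoc_a <= 0 || assoc_b <= 0) next
    cut <- sum(W[in_a, !in_a])
    best <- min(best, cut / assoc_a + cut / assoc_b)
  }
  best
}

# random two-cluster weighted graph: strong within, weak across
random_two_cluster_graph <- function(n, seed) {
  set.seed(seed)
  n1 <- sample(2:(n - 2L), 1L)
  grp <- c(rep(1L, n1), rep(2L, n - n1))
  W <- matrix(0, n, n)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    w <- if (grp[i] == grp[j]) stats::runif(1, 0.5, 1) else
      stats::runif(1, 0, 0.05)
    W[i, j] <- W[j, i] <- w
  }
  list(W = W, grp = grp)
}

# uniform colour block image
uniform_image <- function(h, w, col = c(0.5, 0.5, 0.5), id = "u") {
  px <- array(0, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- col[ch]
  raster_image(px, id)
}

# full-rectangle region over an image
full_region <- function(img) {
  d <- dim(img$pixels)
  min_covering_rect(
    region(img$id, as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2])))), img)
}

# image of bright blobs on a dark background: reliable DoG keypoints
spot_image <- function(h, w, n_spots, seed, id = "spots") {
  set.seed(seed)
  px <- array(0.15, c(h, w, 3L))
  for (k in seq_len(n_spots)) {
    r0 <- sample(5:(h - 5), 1); c0 <- sample(5:(w - 5), 1)
    rad <- sample(2:3, 1)
    for (r in (r0 - rad):(r0 + rad)) for (c in (c0 - rad):(c0 + rad))
      if ((r - r0)^2 + (c - c0)^2 <= rad^2) px[r, c, ] <- 0.9
  }
  raster_image(px, id)
}

# random small bag
random_bag <- function(n_inst, dim, seed, id = "b") {
  set.seed(seed)
  bag(matrix(stats::rnorm(n_inst * dim), n_inst, dim), image_id = id)
}

# shared synthetic layered-image pipeline fixture, built once per test run.
# Small (20 images) so segmentation stays fast; the full-scale benchmark
# lives in the acceptance tests.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_images = 20L, seed = 301L)
      gen <- generate_images(spec)
      bs <- images_to_bags(gen$images, gen$annotation, p_values = c(6, 8))
      cache <<- list(gen = gen, bags = bs)
    }
    cache
  }
})
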