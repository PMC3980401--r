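#' Pixel similarity graphs
#'
#' Normalized Cut operates on a weighted undirected graph whose vertices are
#' pixels and whose edge weights measure pixel similarity. The graph is
#' locally connected: only pixel pairs closer than `radius` (strictly) get an
#' edge. `pixel_graph()` is also usable directly with an arbitrary symmetric
#' weight matrix, which the test oracles exploit.
#'
#' @param W symmetric sparse (or dense) non-negative weight matrix with a
#'   zero diagonal.
#' @param coords optional n x 2 matrix of (row, col) pixel coordinates.
#' @param dims optional c(H, W) image dimensions.
#' @return A `pixel_graph` with fields `W` (dgCMatrix), `degree`, `coords`,
#'   `dims`.
#' @export
pixel_graph <- function(W, coords = NULL, dims = NULL) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (!Matrix::isSymmetric(W, tol = 1e-10)) stop("weight matrix must be symmetric")
  if (any(Matrix::diag(W) != 0)) stop("weight matrix must have a zero diagonal")
  if (length(W@x) && min(W@x) < 0) stop("edge weights must be non-negative")
  structure(list(W = W, degree = Matrix::rowSums(W), coords = coords,
                 dims = dims, n = nrow(W)),
            class = "pixel_graph")
}

#' @export
print.pixel_graph <- function(x, ...) {
  cat(sprintf("<pixel_graph: %d vertices, %d edges>\n", x$n,
              length(x$W@x) / 2))
  invisible(x)
}

#' Build the pixel similarity graph of an image
#'
#' Edge weights follow the intensity-times-proximity Gaussian form
#' \deqn{w(u,v) = \exp(-\|F(u)-F(v)\|^2/\sigma_i^2)\,
#'               \exp(-\|X(u)-X(v)\|^2/\sigma_x^2)}
#' for \eqn{\|X(u)-X(v)\| < radius} and 0 otherwise, where \eqn{F} is the
#' RGB colour on `[0, 1]` and \eqn{X} the pixel coordinate. A degenerate
#' (constant-colour) image is allowed: weights become purely spatial.
#'
#' @param img a [raster_image].
#' @param sigma_i colour bandwidth (default 0.1 on the `[0, 1]` RGB scale).
#' @param sigma_x spatial bandwidth in pixels (default 4).
#' @param radius connection radius in pixels (default 5, strict inequality).
#' @param smooth_sigma optional Gaussian pre-smoothing (in pixels) of the
#'   colours used for the *affinities only* — fine texture is averaged into
#'   its local mean colour so textured areas stay internally coherent while
#'   colour boundaries remain sharp. 0 (default) disables it; features are
#'   always computed on the unsmoothed pixels.
#' @return A [pixel_graph]; errors with "empty graph" if no pair of pixels
#'   is within `radius`.
#' @export
build_pixel_graph <- function(img, sigma_i = 0.1, sigma_x = 4.0, radius = 5.0,
                              smooth_sigma = 0) {
  stopifnot(inherits(img, "raster_image"))
  if (radius < 1) stop("radius must be >= 1")
  if (smooth_sigma > 0) {
    px <- img$pixels
    for (ch in 1:3) px[, , ch] <- gauss_blur(px[, , ch], smooth_sigma)
    img <- raster_image(pmin(pmax(px, 0), 1), img$id)
  }
  d <- dim(img$pixels)
  H <- d[1]; W <- d[2]; n <- H * W
  rmax <- ceiling(radius - 1e-9)
  offs <- expand.grid(dr = 0:rmax, dc = -rmax:rmax)
  offs <- offs[offs$dr > 0 | offs$dc > 0, , drop = FALSE]       # half-plane
  offs <- offs[offs$dr^2 + offs$dc^2 < radius^2, , drop = FALSE] # strict
  if (!nrow(offs)) stop("empty graph: no pixel pair within the radius")
  R <- img$pixels[, , 1]; G <- img$pixels[, , 2]; B <- img$pixels[, , 3]
  ii <- jj <- xx <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    if (dr >= H || abs(dc) >= W) next
    r1 <- seq_len(H - dr)
    c1 <- if (dc >= 0) seq_len(W - dc) else (1 - dc):W
    r2 <- r1 + dr;         c2 <- c1 + dc
    v1 <- as.vector(outer(r1, (c1 - 1L) * H, "+"))
    v2 <- as.vector(outer(r2, (c2 - 1L) * H, "+"))
    df2 <- (R[v1] - R[v2])^2 + (G[v1] - G[v2])^2 + (B[v1] - B[v2])^2
    w <- exp(-df2 / sigma_i^2) * exp(-(dr^2 + dc^2) / sigma_x^2)
    ii[[k]] <- v1; jj[[k]] <- v2; xx[[k]] <- w
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  if (!length(i)) stop("empty graph: no pixel pair within the radius")
  Wm <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
                             dims = c(n, n))
  pixel_graph(Wm, coords = cbind(row = rep(seq_len(H), W),
                                 col = rep(seq_len(W), each = H)),
              dims = c(H, W))
}

#' Normalized Cut value of a bipartition
#'
#' \deqn{Ncut(A,B) = \frac{cut(A,B)}{assoc(A,V)} + \frac{cut(A,B)}{assoc(B,V)}}
#' where \eqn{cut(A,B)} is the total weight crossing the partition and
#' \eqn{assoc(S,V)} the total weight incident to side \eqn{S}. Symmetric in
#' the two sides and bounded in `[0, 2]`.
#'
#' @param g a [pixel_graph].
#' @param in_a logical vector: `TRUE` for vertices in side A.
#' @return The Ncut value.
#' @export
ncut_value <- function(g, in_a) {
  stopifnot(inherits(g, "pixel_graph"), length(in_a) == g$n)
  in_a <- as.logical(in_a)
  if (!any(in_a) || all(in_a)) stop("both sides of the cut must be non-empty")
  assoc_a <- sum(g$degree[in_a]); assoc_b <- sum(g$degree[!in_a])
  if (assoc_a <= 0 || assoc_b <= 0)
    stop("Ncut undefined: a side has zero association")
  cut <- sum(g$W[in_a, !in_a, drop = FALSE])
  cut / assoc_a + cut / assoc_b
}

# second-smallest generalized eigenvector of (D - W) y = lambda D y,
# computed as the second-largest eigenvector of I + D^{-1/2} W D^{-1/2}
# (equivalently 2I - L_sym, for which Lanczos iteration converges quickly),
# mapped back through y = D^{-1/2} z. Deterministic start vector.
fiedler_vector <- function(g) {
  n <- g$n
  dg <- pmax(g$degree, 1e-12)
  s <- 1 / sqrt(dg)
  if (n <= 600) {
    Ls <- Matrix::Diagonal(n) - Matrix::Diagonal(x = s) %*% g$W %*%
      Matrix::Diagonal(x = s)
    e <- eigen(as.matrix(Matrix::forceSymmetric(Ls)), symmetric = TRUE)
    z <- e$vectors[, n - 1L]
  } else {
    Wm <- g$W
    # the top eigenpair of I + S W S is known exactly on a connected graph
    # (eigenvalue 2, eigenvector D^{1/2} 1); deflating it makes the wanted
    # second eigenvector the dominant one, which Lanczos finds quickly even
    # when the graph is nearly disconnected.
    z1 <- sqrt(dg); z1 <- z1 / sqrt(sum(z1^2))
    fun <- function(v, extra) {
      u <- v + s * (Wm %*% (s * v))
      as.numeric(u - 2 * sum(z1 * v) * z1)
    }
    start <- sin(seq_len(n)) # fixed, reproducible
    res <- tryCatch(
      igraph::arpack(fun, sym = TRUE,
                     options = list(n = n, nev = 1, ncv = 30, which = "LA",
                                    maxiter = 10000, start = start)),
      error = function(e) stop("eigensolver failed on ", n,
                               " vertices: ", conditionMessage(e)))
    z <- res$vectors
    z <- z - sum(z1 * z) * z1 # numerical hygiene: stay orthogonal to z1
  }
  s * z
}

#' Optimal two-way Normalized Cut of a graph
#'
#' Solves the relaxed problem through the generalized eigensystem
#' \eqn{(D - W) y = \lambda D y}, takes the eigenvector of the
#' second-smallest eigenvalue and sweeps splitting thresholds over its
#' entries, returning the threshold cut with the smallest [ncut_value()].
#' Disconnected graphs are split along components (Ncut exactly 0).
#'
#' @param g a [pixel_graph] with at least 2 vertices.
#' @param max_thresholds use all distinct eigenvector values when the graph
#'   has at most 5000 vertices, otherwise this many evenly spaced quantiles.
#' @return list with `in_a` (logical side indicator) and `value` (the Ncut).
#' @export
bipartition <- function(g, max_thresholds = 50L) {
  stopifnot(inherits(g, "pixel_graph"))
  n <- g$n
  if (n < 2L) stop("bipartition needs at least 2 vertices")
  comp <- graph_components(g)
  if (max(comp) > 1L) {
    in_a <- comp == 1L
    return(list(in_a = in_a, value = 0))
  }
  y <- fiedler_vector(g)
  sweep_threshold(g, y, max_thresholds)
}

# exact incremental threshold sweep over an ordering score y:
# vertices enter side A in increasing y; cut and assoc maintained in O(nnz).
sweep_threshold <- function(g, y, max_thresholds = 50L) {
  n <- g$n
  ord <- order(y)
  ys <- y[ord]
  # candidate prefix ends: positions where a threshold between distinct
  # values can fall (groups of tied values move together)
  ends <- which(diff(ys) > 1e-15)
  if (!length(ends)) ends <- seq_len(n - 1L) # all tied: allow any prefix
  if (n > 5000L && length(ends) > max_thresholds) {
    qs <- unique(round(seq(1, length(ends), length.out = max_thresholds)))
    ends <- ends[qs]
  }
  Wp <- g$W@p; Wi <- g$W@i; Wx <- g$W@x
  in_a <- logical(n)
  cut <- 0; assoc_a <- 0
  total <- sum(g$degree)
  best <- Inf; best_end <- NA_integer_
  eptr <- 1L
  for (k in seq_len(n - 1L)) {
    v <- ord[k]
    idx <- if (Wp[v] < Wp[v + 1L]) (Wp[v] + 1L):Wp[v + 1L] else integer()
    w_to_a <- if (length(idx)) sum(Wx[idx][in_a[Wi[idx] + 1L]]) else 0
    cut <- cut + g$degree[v] - 2 * w_to_a
    assoc_a <- assoc_a + g$degree[v]
    in_a[v] <- TRUE
    if (eptr <= length(ends) && k == ends[eptr]) {
      eptr <- eptr + 1L
      assoc_b <- total - assoc_a
      if (assoc_a > 0 && assoc_b > 0) {
        val <- cut / assoc_a + cut / assoc_b
        if (val < best) { best <- val; best_end <- k }
      }
    }
  }
  if (!is.finite(best)) stop("no valid threshold cut found")
  in_a <- logical(n); in_a[ord[seq_len(best_end)]] <- TRUE
  list(in_a = in_a, value = best)
}

# connected components of the weight pattern (BFS on sparse columns)
graph_components <- function(g) {
  n <- g$n
  Wp <- g$W@p; Wi <- g$W@i
  comp <- integer(n)
  cur <- 0L
  for (seed in seq_len(n)) {
    if (comp[seed]) next
    cur <- cur + 1L
    frontier <- seed
    comp[seed] <- cur
    while (length(frontier)) {
      nbr <- unlist(lapply(frontier, function(v)
        if (Wp[v] < Wp[v + 1L]) Wi[(Wp[v] + 1L):Wp[v + 1L]] + 1L else integer()))
      nbr <- unique(nbr[comp[nbr] == 0L])
      comp[nbr] <- cur
      frontier <- nbr
    }
  }
  comp
}

induced_subgraph_pg <- function(g, idx) {
  pixel_graph(g$W[idx, idx, drop = FALSE],
              coords = if (!is.null(g$coords)) g$coords[idx, , drop = FALSE],
              dims = g$dims)
}

#' Segmented regions
#'
#' A `region` is one NCut-generated connected pixel set of an image,
#' packaged — as the feature extractor expects — as its axis-aligned
#' minimum covering rectangle with the non-region pixels padded black, plus
#' a mask distinguishing original pixels from padding.
#'
#' @param image_id id of the source image.
#' @param pixels integer N x 2 matrix of (row, col) positions.
#' @param rect,mask,offset optional: filled by [min_covering_rect()].
#' @return A `region` object.
#' @export
region <- function(image_id, pixels, rect = NULL, mask = NULL, offset = NULL) {
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels) < 1L) stop("a region needs at least one pixel")
  structure(list(image_id = as.character(image_id), pixels = pixels,
                 rect = rect, mask = mask, offset = offset),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region of '%s': %d px%s>\n", x$image_id, nrow(x$pixels),
              if (!is.null(x$rect))
                sprintf(", rect %d x %d", dim(x$rect)[1], dim(x$rect)[2])
              else ""))
  invisible(x)
}

#' Minimum covering rectangle of a region
#'
#' Crops the tight axis-aligned bounding box of the region's pixel set out
#' of the source image, sets every pixel outside the region to black
#' `(0,0,0)`, and records a binary mask marking the original pixels.
#' Rectangle edges are parallel to the image edges.
#'
#' @param reg a [region] with a non-empty pixel set.
#' @param img the source [raster_image].
#' @return The region with `rect`, `mask` and `offset` populated.
#' @export
min_covering_rect <- function(reg, img) {
  stopifnot(inherits(reg, "region"), inherits(img, "raster_image"))
  r0 <- min(reg$pixels[, 1L]); r1 <- max(reg$pixels[, 1L])
  c0 <- min(reg$pixels[, 2L]); c1 <- max(reg$pixels[, 2L])
  h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
  mask <- matrix(0L, h, w)
  mask[cbind(reg$pixels[, 1L] - r0 + 1L, reg$pixels[, 2L] - c0 + 1L)] <- 1L
  rect <- img$pixels[r0:r1, c0:c1, , drop = FALSE]
  for (ch in 1:3) rect[, , ch][mask == 0L] <- 0
  reg$rect <- rect; reg$mask <- mask; reg$offset <- c(r0, c0)
  reg
}

#' Segment an image into p regions by recursive Normalized Cut
#'
#' Builds the pixel graph, then repeatedly applies [bipartition()] to the
#' current segment whose best split has the lowest Ncut value until `p`
#' segments exist (greedy recursive two-way cutting). Spectral cuts can
#' return spatially disconnected pieces, so a repair pass splits segments
#' into 4-connected components and merges the smallest components into the
#' spatial neighbour sharing the longest boundary until exactly `p`
#' connected regions remain. The result always partitions the image.
#'
#' @param img a [raster_image].
#' @param p number of regions (>= 1, at most the pixel count).
#' @param sigma_i,sigma_x,radius,smooth_sigma graph parameters, see
#'   [build_pixel_graph()].
#' @return list of `p` [region]s with rectangles and masks populated.
#' @export
segment_image <- function(img, p, sigma_i = 0.1, sigma_x = 4.0, radius = 5.0,
                          smooth_sigma = 0) {
  segment_image_multi(img, p, sigma_i = sigma_i, sigma_x = sigma_x,
                      radius = radius, smooth_sigma = smooth_sigma)[[1L]]
}

#' Segment an image at several granularities in one pass
#'
#' Greedy recursive cutting is nested: the segmentation at a larger `p`
#' refines the one at a smaller `p`. This routine runs the cut sequence once
#' up to `max(p_values)` and snapshots every requested granularity, which is
#' what the ensemble protocol (models at p = 8, 10, 12) uses.
#'
#' @param img a [raster_image].
#' @param p_values integer vector of region counts.
#' @inheritParams segment_image
#' @return named list, one entry per `p`, each a list of `p` [region]s.
#' @export
segment_image_multi <- function(img, p_values, sigma_i = 0.1, sigma_x = 4.0,
                                radius = 5.0, smooth_sigma = 0) {
  stopifnot(inherits(img, "raster_image"))
  p_values <- sort(unique(as.integer(p_values)))
  d <- dim(img$pixels); n <- d[1] * d[2]
  if (min(p_values) < 1L) stop("p must be >= 1")
  if (max(p_values) > n) stop("p exceeds the pixel count")
  g <- build_pixel_graph(img, sigma_i = sigma_i, sigma_x = sigma_x,
                         radius = radius, smooth_sigma = smooth_sigma)
  segments <- list(seq_len(n))     # pixel indices (column-major)
  splits <- list(if (n >= 2L) bipartition(induced_subgraph_pg(g, segments[[1L]]))
                 else NULL)
  out <- vector("list", length(p_values))
  names(out) <- paste0("p", p_values)
  repeat {
    k <- length(segments)
    if (k %in% p_values)
      out[[paste0("p", k)]] <- finalize_regions(img, segments, k)
    if (k >= max(p_values)) break
    vals <- vapply(seq_len(k), function(i)
      if (is.null(splits[[i]])) Inf else splits[[i]]$value, numeric(1))
    best <- which.min(vals)
    if (!is.finite(vals[best]))
      stop("p exceeds achievable segments: no segment can be split further")
    idx <- segments[[best]]
    in_a <- splits[[best]]$in_a
    a <- idx[in_a]; b <- idx[!in_a]
    segments[[best]] <- a
    segments[[k + 1L]] <- b
    splits[[best]] <- if (length(a) >= 2L)
      bipartition(induced_subgraph_pg(g, a)) else NULL
    splits[[k + 1L]] <- if (length(b) >= 2L)
      bipartition(induced_subgraph_pg(g, b)) else NULL
  }
  out
}

# turn segment pixel-index sets into exactly p connected regions
finalize_regions <- function(img, segments, p) {
  d <- dim(img$pixels); H <- d[1]; W <- d[2]
  lab <- integer(H * W)
  for (i in seq_along(segments)) lab[segments[[i]]] <- i
  lab <- matrix(lab, H, W)
  comp <- label_components(lab)          # 4-connected within each segment
  comp <- merge_small_components(comp, p)
  ids <- sort(unique(as.vector(comp)))
  regs <- lapply(ids, function(i) {
    px <- which(comp == i, arr.ind = TRUE)
    min_covering_rect(region(img$id, px), img)
  })
  regs
}

# 4-connected component labelling of a label matrix (components cannot
# straddle different segment labels)
label_components <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  comp <- matrix(0L, H, W)
  cur <- 0L
  for (start in seq_len(H * W)) {
    if (comp[start]) next
    cur <- cur + 1L
    seg <- lab[start]
    frontier <- start
    comp[start] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% H + 1L
      c <- (frontier - 1L) %/% H + 1L
      nbr <- c(frontier[r > 1L] - 1L, frontier[r < H] + 1L,
               frontier[c > 1L] - H, frontier[c < W] + H)
      nbr <- unique(nbr[comp[nbr] == 0L & lab[nbr] == seg])
      comp[nbr] <- cur
      frontier <- nbr
    }
  }
  comp
}

# merge components until exactly p connected regions remain; smallest first
# (sub-0.5%-of-image fragments are by construction the first victims), each
# absorbed by the 4-neighbour component sharing the longest boundary
merge_small_components <- function(comp, p) {
  repeat {
    ids <- sort(unique(as.vector(comp)))
    if (length(ids) <= p) break
    sizes <- vapply(ids, function(i) sum(comp == i), numeric(1))
    victim <- ids[which.min(sizes)]
    nb <- boundary_neighbours(comp, victim)
    if (!length(nb)) break # isolated component (cannot occur on a grid)
    target <- as.integer(names(nb)[which.max(nb)])
    comp[comp == victim] <- target
  }
  # relabel 1..k
  matrix(match(as.vector(comp), sort(unique(as.vector(comp)))),
         nrow(comp), ncol(comp))
}

# shared 4-boundary lengths between component `id` and its neighbours
boundary_neighbours <- function(comp, id) {
  H <- nrow(comp); W <- ncol(comp)
  m <- comp == id
  nb <- integer(0)
  if (H > 1L) {
    up <- m[-1L, ] & !m[-H, ];  nb <- c(nb, comp[-H, ][up])
    dn <- m[-H, ] & !m[-1L, ];  nb <- c(nb, comp[-1L, ][dn])
  }
  if (W > 1L) {
    lf <- m[, -1L] & !m[, -W];  nb <- c(nb, comp[, -W][lf])
    rt <- m[, -W] & !m[, -1L];  nb <- c(nb, comp[, -1L][rt])
  }
  nb <- nb[nb != id]
  if (!length(nb)) return(integer(0))
  table(nb)
}

#' Label matrix of a segmentation
#'
#' @param regions list of [region]s covering one image.
#' @param dims c(H, W) image dimensions.
#' @return Integer H x W matrix; entry = region index.
#' @export
segmentation_labels <- function(regions, dims) {
  lab <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(regions)) lab[regions[[i]]$pixels] <- i
  lab
}
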