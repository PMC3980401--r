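#' Bags of region feature vectors
#'
#' Under the multi-instance view an image is a *bag* whose *instances* are
#' the feature vectors of its segmented regions. A bag is positive for a
#' term iff at least one of its regions carries that term; only the
#' bag-level label is observed.
#'
#' @param instances numeric matrix, one row per instance (region), or a
#'   numeric vector for a single instance.
#' @param image_id character id of the source image.
#' @param scheme feature scheme tag, e.g. `"DWT9"` or `"SIFT128"`.
#' @return A `bag` object.
#' @export
bag <- function(instances, image_id = "img", scheme = "DWT9") {
  if (is.null(dim(instances))) instances <- matrix(instances, nrow = 1L)
  instances <- as.matrix(instances)
  if (nrow(instances) < 1L) stop("a bag needs at least one instance")
  if (!all(is.finite(instances))) stop("bag instances must be finite")
  structure(list(image_id = as.character(image_id),
                 scheme = as.character(scheme),
                 instances = unname(instances)),
            class = "bag")
}

#' @export
print.bag <- function(x, ...) {
  cat(sprintf("<bag '%s': %d instances x %d features (%s)>\n",
              x$image_id, nrow(x$instances), ncol(x$instances), x$scheme))
  invisible(x)
}

#' Assemble a bag from segmented regions
#'
#' Extracts one feature vector per region (in region order) and stacks them
#' into a bag.
#'
#' @param regions non-empty list of [region] objects from one image.
#' @param scheme `"DWT9"` or `"SIFT128"`.
#' @param m block size for the DWT features (default 4).
#' @return A [bag] with one instance per region.
#' @export
make_bag <- function(regions, scheme = c("DWT9", "SIFT128"), m = 4L) {
  scheme <- match.arg(scheme)
  if (length(regions) < 1L) stop("make_bag needs at least one region")
  feats <- lapply(regions, function(r) {
    fv <- if (scheme == "DWT9") extract_dwt9(r, m = m) else extract_sift(r)
    fv$values
  })
  bag(do.call(rbind, feats), image_id = regions[[1L]]$image_id, scheme = scheme)
}

#' Bag datasets
#'
#' A labelled collection of bags: the MIL training/testing unit. The
#' annotation matrix (if present) has one row per bag, in bag order.
#'
#' @param bags list of [bag] objects.
#' @param terms character vector of term names.
#' @param annotation optional [annotation_matrix] aligned with `bags`.
#' @param meta optional named list of provenance (scheme, p, feature params,
#'   standardization statistics).
#' @return A `bag_dataset`.
#' @export
bag_dataset <- function(bags, terms = character(), annotation = NULL,
                        meta = list()) {
  stopifnot(is.list(bags), all(vapply(bags, inherits, TRUE, "bag")))
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "annotation_matrix"))
    if (nrow(annotation) != length(bags))
      stop("annotation must have one row per bag")
    if (!length(terms)) terms <- colnames(annotation)
  }
  structure(list(bags = bags, terms = terms, annotation = annotation,
                 meta = meta),
            class = "bag_dataset")
}

#' @export
print.bag_dataset <- function(x, ...) {
  cat(sprintf("<bag_dataset: %d bags, %d terms%s>\n", length(x$bags),
              length(x$terms),
              if (is.null(x$annotation)) ", unlabelled" else ""))
  invisible(x)
}

#' @export
length.bag_dataset <- function(x) length(x$bags)

subset_dataset <- function(dataset, idx) {
  ann <- dataset$annotation
  if (!is.null(ann))
    ann <- annotation_matrix(unclass(ann)[idx, , drop = FALSE],
                             rownames(ann)[idx], colnames(ann))
  bag_dataset(dataset$bags[idx], terms = dataset$terms, annotation = ann,
              meta = dataset$meta)
}

#' Average Hausdorff distance between two bags
#'
#' The symmetric bag distance used by Citation-KNN and the locality matrix:
#' every instance is matched to its nearest instance in the other bag and
#' the matched distances are averaged,
#' \deqn{AHD(A,B) = \frac{\sum_{a \in A}\min_{b \in B} d(a,b) +
#'   \sum_{b \in B}\min_{a \in A} d(a,b)}{|A| + |B|},}
#' with \eqn{d} the Euclidean distance in instance space. AHD is symmetric,
#' non-negative, zero on identical bags, and invariant to instance order;
#' it is not a metric (no triangle inequality) and nothing here assumes one.
#'
#' @param a,b [bag] objects with equal instance dimension.
#' @return A single non-negative number.
#' @export
ahd <- function(a, b) {
  A <- if (inherits(a, "bag")) a$instances else as.matrix(a)
  B <- if (inherits(b, "bag")) b$instances else as.matrix(b)
  if (ncol(A) != ncol(B))
    stop("instance dimension mismatch: ", ncol(A), " vs ", ncol(B))
  .milanno_env$ahd_calls <- .milanno_env$ahd_calls + 1L
  D <- cross_dist(A, B)
  (sum(apply(D, 1L, min)) + sum(apply(D, 2L, min))) / (nrow(A) + nrow(B))
}

.milanno_env <- new.env(parent = emptyenv())
.milanno_env$ahd_calls <- 0L

#' Count AHD evaluations
#'
#' A diagnostic counter of how many bag-distance evaluations have run, used
#' to verify the advertised pruning/caching cost bounds.
#'
#' @param reset if `TRUE`, zero the counter after reading it.
#' @return The number of [ahd()] calls since the last reset.
#' @export
ahd_call_count <- function(reset = FALSE) {
  n <- .milanno_env$ahd_calls
  if (reset) .milanno_env$ahd_calls <- 0L
  n
}

# Euclidean cross-distance matrix, rows of A x rows of B. Squared distances
# below the floating-point resolution of the Gram expansion are snapped to
# zero so identical instances are at distance exactly 0.
cross_dist <- function(A, B) {
  sa <- rowSums(A^2); sb <- rowSums(B^2)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(A, B)
  tiny <- d2 < 64 * .Machine$double.eps * pmax(outer(sa, sb, "+"), 1)
  d2[tiny | d2 < 0] <- 0
  sqrt(d2)
}

#' Pairwise AHD matrix for a list of bags
#'
#' @param bags list of [bag]s (or a [bag_dataset]).
#' @param bags2 optional second list; if given, the (possibly rectangular)
#'   cross-distance matrix is returned.
#' @return A numeric distance matrix.
#' @export
ahd_matrix <- function(bags, bags2 = NULL) {
  if (inherits(bags, "bag_dataset")) bags <- bags$bags
  if (is.null(bags2)) {
    n <- length(bags)
    D <- matrix(0, n, n)
    if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- ahd(bags[[i]], bags[[j]])
    }
    D
  } else {
    if (inherits(bags2, "bag_dataset")) bags2 <- bags2$bags
    outer(seq_along(bags), seq_along(bags2),
          Vectorize(function(i, j) ahd(bags[[i]], bags2[[j]])))
  }
}

#' Standardize bag features
#'
#' Per-dimension z-scoring fitted on a training dataset and applied to any
#' dataset. Recommended for DWT9 features whose dimensions live on
#' incommensurate scales; the fitted statistics are carried in `meta` so a
#' model can replay them on test bags.
#'
#' @param dataset a [bag_dataset] to standardize.
#' @param stats optional list with `center` and `scale`; if `NULL` they are
#'   fitted on `dataset`'s pooled instances.
#' @return The standardized [bag_dataset]; fitted statistics in
#'   `meta$standardize`.
#' @export
standardize_bags <- function(dataset, stats = NULL) {
  stopifnot(inherits(dataset, "bag_dataset"))
  X <- do.call(rbind, lapply(dataset$bags, `[[`, "instances"))
  if (is.null(stats)) {
    s <- apply(X, 2L, stats::sd)
    s[s < 1e-12] <- 1
    stats <- list(center = colMeans(X), scale = s)
  }
  bags <- lapply(dataset$bags, function(b) {
    b$instances <- sweep(sweep(b$instances, 2L, stats$center), 2L,
                         stats$scale, "/")
    b
  })
  meta <- dataset$meta
  meta$standardize <- stats
  bag_dataset(bags, terms = dataset$terms, annotation = dataset$annotation,
              meta = meta)
}
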