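#' Fit a Citation-KNN term model
#'
#' Citation-KNN is memory-based: fitting stores the training bags and their
#' binary labels for one annotation term; no optimisation is run. The
#' pairwise training AHD matrix is computed once here (n(n-1)/2 distance
#' evaluations) and reused by prediction, citer ranking and the locality
#' matrix, so the advertised one-off O(n^2) distance cost holds.
#'
#' At prediction time the label is decided by a vote of *references* (the R
#' training bags nearest to the test bag under the average Hausdorff
#' distance) and *citers* (the training bags that rank the test bag within
#' their own C nearest neighbours).
#'
#' @param bags list of training [bag]s (or a [bag_dataset]).
#' @param labels binary 0/1 vector aligned with `bags`.
#' @param R number of references (>= 1, at most n - 1).
#' @param C citer rank (>= R; default R + 2).
#' @param term optional term name carried for bookkeeping.
#' @return A `citation_model`.
#' @export
fit_citation <- function(bags, labels, R = 3L, C = R + 2L, term = "") {
  if (inherits(bags, "bag_dataset")) bags <- bags$bags
  labels <- as.integer(labels)
  n <- length(bags)
  stopifnot(length(labels) == n, all(labels %in% 0:1))
  if (R < 1L) stop("R must be >= 1")
  if (R > n - 1L) stop("R must be at most n - 1 = ", n - 1L)
  if (C < R) stop("C must be >= R")
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; the vote is degenerate")
  structure(list(bags = bags, labels = labels, R = as.integer(R),
                 C = as.integer(C), term = term, D = ahd_matrix(bags),
                 locality = NULL),
            class = "citation_model")
}

#' @export
print.citation_model <- function(x, ...) {
  cat(sprintf("<citation_model%s: %d bags, R = %d, C = %d%s>\n",
              if (nzchar(x$term)) paste0(" '", x$term, "'") else "",
              length(x$bags), x$R, x$C,
              if (!is.null(x$locality))
                sprintf(", locality %d x %d", nrow(x$locality$rows),
                        ncol(x$locality$rows)) else ""))
  invisible(x)
}

# reference + citer vote over a candidate subset of training-bag indices.
# d_test[k] is the AHD from the test bag to candidate cand[k]; training-
# training distances come from the cached matrix.
citation_vote <- function(model, cand, d_test) {
  refs <- cand[order(d_test)[seq_len(min(model$R, length(cand)))]]
  citers <- integer(0)
  for (k in seq_along(cand)) {
    i <- cand[k]
    others <- cand[cand != i]
    # rank of the test bag among {candidates \ i} U {test}, seen from i
    rank_test <- sum(model$D[i, others] < d_test[k]) + 1L
    if (rank_test <= model$C) citers <- c(citers, i)
  }
  voters <- c(refs, citers)
  pos <- sum(model$labels[voters] == 1L)
  as.integer(pos > length(voters) - pos) # ties break negative
}

#' Predict a term with Citation-KNN
#'
#' References are the `R` training bags nearest to the test bag by AHD;
#' citers are the training bags whose `C`-nearest-neighbour list over the
#' training set plus the test bag contains the test bag. The predicted bit
#' is 1 iff positive votes strictly outnumber negative votes (ties go to 0,
#' favouring annotation precision).
#'
#' @param model a [fit_citation()] model.
#' @param test a [bag].
#' @return 0 or 1.
#' @export
predict_citation <- function(model, test) {
  stopifnot(inherits(model, "citation_model"), inherits(test, "bag"))
  cand <- seq_along(model$bags)
  d_test <- vapply(cand, function(i) ahd(model$bags[[i]], test), numeric(1))
  citation_vote(model, cand, d_test)
}

#' Build the locality matrix of a Citation-KNN model
#'
#' The training bags are clustered into `s` groups by k-medoids (PAM) on the
#' cached AHD dissimilarity — medoids must be actual bags because AHD needs
#' instances; no mean bag exists. Row i of the s x K matrix lists the K
#' training bags nearest to medoid i, sorted by AHD. The matrix is built
#' once; at test time only the rows of nearby medoids are consulted, pruning
#' most distance computations.
#'
#' @param model a [citation_model].
#' @param s number of clusters (default `ceiling(sqrt(n))`).
#' @param K neighbours kept per medoid (default `min(25, n)`).
#' @param seed integer seed making the clustering reproducible.
#' @return The model with a `locality` field: `medoids` (bag indices) and
#'   `rows` (s x K index matrix).
#' @export
build_locality_matrix <- function(model, s = NULL, K = NULL, seed = 1L) {
  stopifnot(inherits(model, "citation_model"))
  n <- length(model$bags)
  if (is.null(s)) s <- ceiling(sqrt(n))
  if (is.null(K)) K <- min(25L, n)
  if (s < 1L || s > n) stop("s must lie in [1, n]")
  if (K < 1L || K > n) stop("K must lie in [1, n]")
  medoids <- if (s == n) seq_len(n) else {
    set.seed(seed)
    cluster::pam(stats::as.dist(model$D), k = s, diss = TRUE)$id.med
  }
  rows <- t(vapply(medoids, function(m) order(model$D[m, ])[seq_len(K)],
                   integer(K)))
  model$locality <- list(medoids = as.integer(medoids),
                         rows = matrix(as.integer(rows), nrow = length(medoids)),
                         s = as.integer(s), K = as.integer(K))
  model
}

#' Predict with locality-matrix pruning
#'
#' AHD is computed from the test bag to the `s` medoids only; the far
#' medoids are discarded, keeping the `ceiling(q * s)` nearest. The
#' candidate training set is the union of the kept medoids' locality rows,
#' and the reference+citer vote runs restricted to those candidates. With
#' `q = 1` and `K = n` this reproduces [predict_citation()] exactly.
#'
#' @param model a [citation_model] with a locality matrix.
#' @param test a [bag].
#' @param q fraction of medoids kept, in (0, 1].
#' @return 0 or 1.
#' @export
predict_citation_pruned <- function(model, test, q = 0.5) {
  stopifnot(inherits(model, "citation_model"))
  if (is.null(model$locality))
    stop("no locality matrix; call build_locality_matrix() first")
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  loc <- model$locality
  d_med <- vapply(loc$medoids, function(i) ahd(model$bags[[i]], test),
                  numeric(1))
  keep <- order(d_med)[seq_len(ceiling(q * loc$s))]
  cand <- sort(unique(as.vector(loc$rows[keep, , drop = FALSE])))
  d_test <- vapply(cand, function(i) {
    m <- match(i, loc$medoids)
    if (!is.na(m)) d_med[m] else ahd(model$bags[[i]], test)
  }, numeric(1))
  citation_vote(model, cand, d_test)
}

#' Predict every bag of a dataset with a Citation-KNN model
#'
#' @param object a [citation_model].
#' @param newdata a [bag_dataset] or list of [bag]s.
#' @param pruned use the locality matrix (requires one to be built).
#' @param q pruning fraction for the locality path.
#' @param ... unused.
#' @return A tibble with columns `image_id` and `pred` (0/1).
#' @export
predict.citation_model <- function(object, newdata, pruned = FALSE, q = 0.5,
                                   ...) {
  bags <- if (inherits(newdata, "bag_dataset")) newdata$bags else newdata
  pred <- vapply(bags, function(b)
    if (pruned) predict_citation_pruned(object, b, q = q)
    else predict_citation(object, b), integer(1))
  tibble::tibble(image_id = vapply(bags, `[[`, "", "image_id"), pred = pred)
}
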