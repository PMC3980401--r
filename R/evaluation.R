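#' Zero-one precision of one term
#'
#' The fraction of images whose predicted bit for a single term equals the
#' truth (the complement of the per-term zero-one loss).
#'
#' @param pred,truth equal-length binary 0/1 vectors.
#' @return A number in `[0, 1]`.
#' @export
zero_one_precision <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ: ", length(pred), " vs ", length(truth))
  mean(as.integer(pred) == as.integer(truth))
}

#' Hamming loss of a multi-term annotation
#'
#' The fraction of image-term pairs annotated incorrectly across the whole
#' n x m prediction matrix; 0 is perfect, 1 is total misprediction. Equal to
#' the mean over terms of (1 - zero-one precision).
#'
#' @param pred,truth equal-shape binary matrices (images x terms).
#' @return A number in `[0, 1]`.
#' @export
hamming_loss <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ")
  mean(abs(as.integer(pred) - as.integer(truth)))
}

#' False positive / false negative rates
#'
#' For imbalance studies plain accuracy misleads (a degenerate all-positive
#' predictor scores the positive prevalence), so rates are normalized per
#' class: fp = FP / negatives, fn = FN / positives.
#'
#' @param pred,truth equal-length binary 0/1 vectors; `truth` must contain
#'   both classes.
#' @return Named numeric c(fp_rate, fn_rate).
#' @export
fp_fn_rates <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  pred <- as.integer(pred); truth <- as.integer(truth)
  npos <- sum(truth == 1L); nneg <- sum(truth == 0L)
  if (npos == 0L || nneg == 0L)
    stop("truth contains a single class; fp/fn rates undefined")
  c(fp_rate = sum(pred == 1L & truth == 0L) / nneg,
    fn_rate = sum(pred == 0L & truth == 1L) / npos)
}

#' Random train/test split of a bag dataset
#'
#' `round(ratio * n)` bags go to training, the rest to testing; disjoint,
#' exhaustive and reproducible from the seed. The annotation protocol uses
#' ratio 0.3 (a 3:7 train:test division).
#'
#' @param dataset a [bag_dataset] with at least 2 bags.
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` [bag_dataset]s and the index vectors.
#' @export
split_train_test <- function(dataset, ratio = 0.3, seed = 1L) {
  stopifnot(inherits(dataset, "bag_dataset"))
  n <- length(dataset$bags)
  if (n < 2L) stop("need at least 2 bags to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  set.seed(seed)
  n_train <- max(1L, min(n - 1L, round(ratio * n)))
  tr <- sort(sample.int(n, n_train))
  te <- setdiff(seq_len(n), tr)
  list(train = subset_dataset(dataset, tr), test = subset_dataset(dataset, te),
       train_idx = tr, test_idx = te)
}

#' Majority-vote ensemble of binary prediction matrices
#'
#' One prediction matrix per segmentation granularity p; the final bit for
#' each image-term pair is the majority of the voters. The voter count must
#' be odd so no tie rule is needed.
#'
#' @param preds list of equal-shape binary matrices.
#' @return A binary matrix of the same shape.
#' @export
ensemble_vote <- function(preds) {
  stopifnot(is.list(preds), length(preds) >= 1L)
  if (length(preds) %% 2L == 0L)
    stop("even number of voters; use an odd count to avoid ties")
  dims <- lapply(preds, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("voter matrices must have identical shapes")
  acc <- Reduce(`+`, lapply(preds, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "integer"; m
  }))
  out <- (acc > length(preds) / 2) + 0L
  dimnames(out) <- dimnames(as.matrix(preds[[1L]]))
  out
}

#' Build an imbalanced single-term subset
#'
#' Draws `round(N * r)` images annotated with `term` and `round(N * (1-r))`
#' images not annotated with it, reproducibly; used to study how class
#' imbalance drives false positive / false negative rates.
#'
#' @param dataset a labelled [bag_dataset].
#' @param term term name (must be a column of the annotation matrix).
#' @param N subset size.
#' @param r positive fraction in (0, 1).
#' @param seed integer seed.
#' @return A [bag_dataset] of exactly `round(N*r) + round(N*(1-r))` bags.
#' @export
build_imbalanced_subset <- function(dataset, term, N, r, seed = 1L) {
  stopifnot(inherits(dataset, "bag_dataset"), !is.null(dataset$annotation))
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  y <- unclass(dataset$annotation)[, term]
  n_pos <- round(N * r); n_neg <- round(N * (1 - r))
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (length(pos) < n_pos || length(neg) < n_neg)
    stop(sprintf(
      "insufficient class counts for term '%s': need %d+/%d-, have %d+/%d-",
      term, n_pos, n_neg, length(pos), length(neg)))
  set.seed(seed)
  idx <- sort(c(sample(pos, n_pos), sample(neg, n_neg)))
  subset_dataset(dataset, idx)
}

# fit one term with one learner on a training set; return a 0/1 vector for
# the test bags. Degenerate single-class training predicts that class.
fit_predict_term <- function(train, test, y_train, learner, params) {
  if (length(unique(y_train)) < 2L)
    return(rep(y_train[1L], length(test$bags)))
  if (learner == "cknn") {
    mod <- fit_citation(train$bags, y_train,
                        R = params$R %||% 3L,
                        C = params$C %||% ((params$R %||% 3L) + 2L))
    predict(mod, test)$pred
  } else {
    mod <- fit_gpmil(train$bags, y_train,
                     alpha = params$alpha %||% 10,
                     lengthscale = params$lengthscale,
                     variance = params$variance %||% 1)
    predict(mod, test)$pred
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full annotation evaluation protocol
#'
#' For each of `n_trials` random 3:7 train/test splits: per-term models are
#' fitted independently at every segmentation granularity p, the per-p
#' binary predictions are combined by majority vote, and zero-one precision,
#' Hamming loss and fp/fn rates are measured on the test images. Reported
#' values are averages over trials; everything is reproducible from the
#' master seed.
#'
#' @param bag_sets named list of aligned labelled [bag_dataset]s, one per
#'   segmentation granularity (e.g. `list(p8 = ..., p10 = ..., p12 = ...)`);
#'   bags must be in the same image order in every set. Use an odd number of
#'   granularities.
#' @param learner `"cknn"` or `"gpmil"`.
#' @param n_trials number of random splits (default 10).
#' @param ratio training fraction (default 0.3).
#' @param seed master seed; trial t uses `seed + t`.
#' @param standardize z-score features on the training bags of each trial
#'   (recommended for DWT9).
#' @param params named list of learner parameters (R, C, alpha, ...).
#' @return An `eval_report`.
#' @export
run_protocol <- function(bag_sets, learner = c("cknn", "gpmil"),
                         n_trials = 10L, ratio = 0.3, seed = 1L,
                         standardize = TRUE, params = list()) {
  learner <- match.arg(learner)
  if (inherits(bag_sets, "bag_dataset")) bag_sets <- list(p = bag_sets)
  stopifnot(all(vapply(bag_sets, inherits, TRUE, "bag_dataset")))
  ann <- bag_sets[[1L]]$annotation
  if (is.null(ann)) stop("bag datasets must carry an annotation matrix")
  terms <- colnames(ann)
  n <- nrow(ann)
  trial_rows <- list(); trial_hl <- numeric(0)
  seeds <- seed + seq_len(n_trials)
  for (t in seq_len(n_trials)) {
    sp <- split_train_test(bag_sets[[1L]], ratio = ratio, seed = seeds[t])
    truth <- unclass(ann)[sp$test_idx, , drop = FALSE]
    preds_by_p <- lapply(bag_sets, function(ds) {
      tr <- subset_dataset(ds, sp$train_idx)
      te <- subset_dataset(ds, sp$test_idx)
      if (standardize) {
        tr <- standardize_bags(tr)
        te <- standardize_bags(te, stats = tr$meta$standardize)
      }
      y <- unclass(ds$annotation)[sp$train_idx, , drop = FALSE]
      m <- vapply(terms, function(tm)
        as.integer(fit_predict_term(tr, te, y[, tm], learner, params)),
        integer(length(sp$test_idx)))
      matrix(m, ncol = length(terms), dimnames = list(NULL, terms))
    })
    pred <- if (length(preds_by_p) > 1L) ensemble_vote(preds_by_p)
            else as.matrix(preds_by_p[[1L]])
    for (tm in terms) {
      rates <- tryCatch(fp_fn_rates(pred[, tm], truth[, tm]),
                        error = function(e) c(fp_rate = NA_real_,
                                              fn_rate = NA_real_))
      trial_rows[[length(trial_rows) + 1L]] <- tibble::tibble(
        trial = t, term = tm,
        precision = zero_one_precision(pred[, tm], truth[, tm]),
        fp_rate = rates[["fp_rate"]], fn_rate = rates[["fn_rate"]])
    }
    trial_hl <- c(trial_hl, hamming_loss(pred, truth))
  }
  trials <- do.call(rbind, trial_rows)
  per_term <- do.call(rbind, lapply(split(trials, trials$term), function(d)
    tibble::tibble(term = d$term[1L], precision = mean(d$precision),
                   fp_rate = mean(d$fp_rate, na.rm = TRUE),
                   fn_rate = mean(d$fn_rate, na.rm = TRUE))))
  per_term <- per_term[match(terms, per_term$term), ]
  structure(list(per_term = per_term, hamming_loss = mean(trial_hl),
                 trial_hamming = trial_hl, trials = trials,
                 n_trials = n_trials, seeds = seeds, learner = learner,
                 p_names = names(bag_sets)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s over %d trials (%s)>\n", x$learner,
              x$n_trials, paste(x$p_names, collapse = ", ")))
  cat(sprintf("  Hamming loss: %.4f\n", x$hamming_loss))
  cat(sprintf("  mean per-term precision: %.4f\n", mean(x$per_term$precision)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report: one row per term
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return A tibble with term, precision, fp_rate, fn_rate.
#' @export
tidy.eval_report <- function(x, ...) x$per_term

#' One-row summary of an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return A one-row tibble: learner, n_trials, hamming_loss, mean/min
#'   per-term precision.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(learner = x$learner, n_trials = x$n_trials,
                 hamming_loss = x$hamming_loss,
                 mean_precision = mean(x$per_term$precision),
                 min_precision = min(x$per_term$precision))
}

#' Plot per-term precision of an evaluation report
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return A ggplot bar chart of per-term zero-one precision.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- object$per_term
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$precision)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$hamming_loss, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "annotation term", y = "zero-one precision",
                  caption = "dashed line: Hamming loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Plot a segmentation as a coloured label raster
#'
#' @param regions list of [region]s from [segment_image()].
#' @param dims c(H, W) image dimensions.
#' @return A ggplot raster of region labels.
#' @export
plot_segmentation <- function(regions, dims) {
  lab <- segmentation_labels(regions, dims)
  d <- data.frame(row = as.vector(row(lab)), col = as.vector(col(lab)),
                  region = factor(as.vector(lab)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
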