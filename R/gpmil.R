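#' Softmax bag likelihood
#'
#' Under the MIL assumption a bag is positive iff its best instance is, so
#' the bag-level success probability is \eqn{\max_j g(x_j)} with
#' \eqn{g \in (0,1)} the per-instance latent score. For differentiability
#' the max is replaced by its softmax relaxation
#' \deqn{s = \frac{1}{\alpha}\log\Big(\frac{1}{|B|}\sum_j
#'       e^{\alpha g_j}\Big),}
#' clipped to `[0, 1]`. As \eqn{\alpha \to \infty} this converges to
#' \eqn{\max_j g_j}; it is monotone non-decreasing in every \eqn{g_j} and
#' bounded by \eqn{[\max g - \log|B|/\alpha,\ \max g]} before clipping.
#'
#' @param g numeric vector of instance scores in (0, 1).
#' @param alpha softmax sharpness, > 0.
#' @return The bag probability in `[0, 1]`.
#' @export
bag_likelihood <- function(g, alpha = 10) {
  if (!length(g)) stop("empty bag")
  stopifnot(alpha > 0, all(g > 0 & g < 1))
  s <- log_mean_exp(alpha * g) / alpha
  min(max(s, 0), 1)
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

logistic <- function(f) 1 / (1 + exp(-f))

#' Joint log-likelihood of bag labels given instance latents
#'
#' The per-bag likelihoods multiply across bags (bags are conditionally
#' independent given the latents): a positive bag contributes
#' \eqn{\log s_B}, a negative bag \eqn{\log(1 - s_B)} (Bernoulli), with the
#' softmax bag probability \eqn{s_B} of [bag_likelihood()].
#'
#' @param f numeric vector of latent values, one per training instance.
#' @param bag_index integer vector assigning each instance to its bag.
#' @param labels 0/1 vector, one per bag.
#' @param alpha softmax sharpness.
#' @return The joint log-likelihood (finite; probabilities are guarded away
#'   from 0 and 1 by a small epsilon before the log).
#' @export
joint_log_likelihood <- function(f, bag_index, labels, alpha = 10) {
  stopifnot(length(f) == length(bag_index), max(bag_index) <= length(labels))
  g <- logistic(f)
  eps <- 1e-9
  sum(vapply(seq_along(labels), function(b) {
    s <- bag_likelihood(g[bag_index == b], alpha)
    s <- min(max(s, eps), 1 - eps)
    if (labels[b] == 1L) log(s) else log1p(-s)
  }, numeric(1)))
}

# gradient and (negated) Hessian blocks of the log-likelihood w.r.t. f.
# With e_j = exp(alpha * g_j), w_j = e_j / sum(e), s = logmeanexp/alpha:
#   ds/df_j      = w_j g'_j
#   d2s/df_j df_k = alpha (delta_jk w_j - w_j w_k) g'_j g'_k
#                   + delta_jk w_j g''_j
# and for log s (positive bag): H = (1/s) d2s - (1/s^2) ds ds^T; for
# log(1-s): H = -(1/(1-s)) d2s - (1/(1-s)^2) ds ds^T.
loglik_grad_hess <- function(f, bag_index, labels, alpha) {
  n <- length(f)
  g <- logistic(f)
  gp <- g * (1 - g)
  gpp <- gp * (1 - 2 * g)
  grad <- numeric(n)
  W <- matrix(0, n, n) # negated Hessian of the log-likelihood
  eps <- 1e-9
  for (b in seq_along(labels)) {
    idx <- which(bag_index == b)
    e <- exp(alpha * (g[idx] - max(g[idx])))
    w <- e / sum(e)
    s <- min(max(log_mean_exp(alpha * g[idx]) / alpha, eps), 1 - eps)
    ds <- w * gp[idx]
    d2s <- alpha * (diag(w, length(idx)) - tcrossprod(w)) *
      tcrossprod(gp[idx]) + diag(w * gpp[idx], length(idx))
    if (labels[b] == 1L) {
      grad[idx] <- ds / s
      Hb <- d2s / s - tcrossprod(ds) / s^2
    } else {
      grad[idx] <- -ds / (1 - s)
      Hb <- -d2s / (1 - s) - tcrossprod(ds) / (1 - s)^2
    }
    W[idx, idx] <- -Hb
  }
  list(grad = grad, W = W)
}

rbf_kernel <- function(X, Y = NULL, lengthscale, variance = 1) {
  if (is.null(Y)) Y <- X
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  variance * exp(-d2 / (2 * lengthscale^2))
}

median_heuristic <- function(X) {
  n <- nrow(X)
  idx <- if (n > 300L) sample.int(n, 300L) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Fit a GPMIL term model by Laplace approximation
#'
#' Places a zero-mean Gaussian-process prior with an RBF kernel on the
#' per-instance latent function f (squashed to scores g = logistic(f)), and
#' links latents to bag labels through the softmax bag likelihood. The
#' posterior over the stacked training latents is approximated by a
#' Gaussian centred at the mode (damped Newton ascent of the log posterior,
#' with step halving whenever a step fails to increase it) with covariance
#' from the local curvature. The likelihood is not log-concave, so the
#' curvature term is diagonally regularized just enough to keep the
#' approximation positive definite.
#'
#' @param bags list of training [bag]s (or a [bag_dataset]).
#' @param labels 0/1 vector, one per bag; both classes must be present.
#' @param lengthscale RBF lengthscale; `NULL` (default) uses the median
#'   heuristic on pooled training-instance distances.
#' @param variance RBF signal variance (default 1).
#' @param alpha softmax sharpness (default 10).
#' @param jitter diagonal jitter added to the Gram matrix (default 1e-6).
#' @param max_newton maximum Newton iterations (default 100).
#' @param tol convergence threshold on the gradient infinity norm.
#' @param term optional term name.
#' @return A `gpmil_model` with the posterior mode `f_hat`, its Laplace
#'   covariance, and everything needed for prediction.
#' @export
fit_gpmil <- function(bags, labels, lengthscale = NULL, variance = 1,
                      alpha = 10, jitter = 1e-6, max_newton = 100L,
                      tol = 1e-4, term = "") {
  if (inherits(bags, "bag_dataset")) bags <- bags$bags
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(bags), all(labels %in% 0:1))
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class")
  X <- do.call(rbind, lapply(bags, `[[`, "instances"))
  bag_index <- rep(seq_along(bags),
                   vapply(bags, function(b) nrow(b$instances), integer(1)))
  if (is.null(lengthscale)) lengthscale <- median_heuristic(X)
  n <- nrow(X)
  K <- rbf_kernel(X, lengthscale = lengthscale, variance = variance) +
    diag(jitter, n)
  Kc <- tryCatch(chol(K), error = function(e)
    stop("kernel Gram matrix is not positive definite after jitter: ",
         conditionMessage(e)))
  Kinv <- chol2inv(Kc)

  psi <- function(f) joint_log_likelihood(f, bag_index, labels, alpha) -
    0.5 * sum(f * (Kinv %*% f))
  f <- numeric(n)
  val <- psi(f)
  converged <- FALSE
  for (it in seq_len(max_newton)) {
    gh <- loglik_grad_hess(f, bag_index, labels, alpha)
    grad <- gh$grad - as.numeric(Kinv %*% f)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    A <- Kinv + psd_boost(gh$W)
    step <- tryCatch(solve(A, grad), error = function(e) grad)
    t_step <- 1
    repeat {
      f_new <- f + t_step * step
      val_new <- psi(f_new)
      if (is.finite(val_new) && val_new > val - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-8) { f_new <- f; val_new <- val; break }
    }
    if (max(abs(f_new - f)) < 1e-12) { f <- f_new; val <- val_new; break }
    f <- f_new; val <- val_new
  }
  if (!converged) {
    gh <- loglik_grad_hess(f, bag_index, labels, alpha)
    grad <- gh$grad - as.numeric(Kinv %*% f)
    if (max(abs(grad)) < tol) converged <- TRUE
    else warning("GPMIL Newton ascent stopped before reaching tol (grad ",
                 signif(max(abs(grad)), 3), ")")
  }
  Wt <- psd_boost(loglik_grad_hess(f, bag_index, labels, alpha)$W)
  Sigma <- solve(Kinv + Wt)
  structure(list(term = term, X = X, bag_index = bag_index, labels = labels,
                 kernel = list(lengthscale = lengthscale, variance = variance),
                 alpha = alpha, jitter = jitter, f_hat = f, Sigma = Sigma,
                 Kinv = Kinv, converged = converged),
            class = "gpmil_model")
}

# smallest diagonal boost making a symmetric matrix positive semidefinite
psd_boost <- function(W) {
  W <- (W + t(W)) / 2
  ev <- min(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8) W <- W + diag(1e-8 - ev, nrow(W))
  W
}

#' @export
print.gpmil_model <- function(x, ...) {
  cat(sprintf(
    "<gpmil_model%s: %d instances / %d bags, lengthscale %.3g, alpha %g%s>\n",
    if (nzchar(x$term)) paste0(" '", x$term, "'") else "",
    nrow(x$X), length(x$labels), x$kernel$lengthscale, x$alpha,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix)
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L) / 2)
  J[cbind(1:(n - 1L), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(sqrt(pi) * e$vectors[1L, ]^2))
}

#' Predict the probability of a term for a test bag
#'
#' Conditions the GP on the Laplace posterior to get the predictive mean
#' and variance of each test-instance latent, then pushes the softmax bag
#' likelihood through the uncertainty of the top-scoring instance's latent
#' by Gauss-Hermite quadrature (32 nodes); the remaining instances are held
#' at their predictive means. The returned probability r lies in `[0, 1]`
#' and the binary decision is `b = 1` iff `r > 0.5` (the sign of r - 0.5).
#'
#' @param model a [fit_gpmil()] model.
#' @param test a [bag] with the training feature dimension.
#' @param n_quad number of Gauss-Hermite nodes.
#' @return A one-row tibble: `image_id`, `prob`, `pred`.
#' @export
predict_gpmil <- function(model, test, n_quad = 32L) {
  stopifnot(inherits(model, "gpmil_model"), inherits(test, "bag"))
  Xs <- test$instances
  if (ncol(Xs) != ncol(model$X))
    stop("feature dimension mismatch: ", ncol(Xs), " vs ", ncol(model$X))
  Ks <- rbf_kernel(model$X, Xs, lengthscale = model$kernel$lengthscale,
                   variance = model$kernel$variance)
  Q <- model$Kinv %*% Ks                       # n_train x n_test
  mu <- as.numeric(crossprod(Ks, model$Kinv %*% model$f_hat))
  var_red <- colSums(Ks * Q) - colSums(Q * (model$Sigma %*% Q))
  s2 <- pmax(model$kernel$variance + model$jitter - var_red, 1e-10)
  j <- which.max(mu)
  gh <- gauss_hermite(n_quad)
  fj <- mu[j] + sqrt(2 * s2[j]) * gh$nodes
  wts <- gh$weights / sqrt(pi)
  r <- sum(wts * vapply(fj, function(fv) {
    f_all <- mu; f_all[j] <- fv
    bag_likelihood(squash_open(logistic(f_all)), model$alpha)
  }, numeric(1)))
  r <- min(max(r, 0), 1)
  tibble::tibble(image_id = test$image_id, prob = r,
                 pred = as.integer(r > 0.5))
}

# keep scores strictly inside (0, 1) for the likelihood's open-interval domain
squash_open <- function(g, eps = 1e-12) pmin(pmax(g, eps), 1 - eps)

#' Predict every bag of a dataset with a GPMIL model
#'
#' @param object a [gpmil_model].
#' @param newdata a [bag_dataset] or list of [bag]s.
#' @param ... passed to [predict_gpmil()].
#' @return A tibble with `image_id`, `prob`, `pred` per bag.
#' @export
predict.gpmil_model <- function(object, newdata, ...) {
  bags <- if (inherits(newdata, "bag_dataset")) newdata$bags else newdata
  do.call(rbind, lapply(bags, function(b) predict_gpmil(object, b, ...)))
}
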