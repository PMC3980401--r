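test_that("the softmax bag likelihood matches direct log-mean-exp arithmetic", {
  # identical instances: exactly the common value
  expect_equal(bag_likelihood(rep(0.3, 5), alpha = 10), 0.3)
  # alpha -> infinity limit approaches the max
  expect_equal(bag_likelihood(c(0.2, 0.9), alpha = 50), 0.9, tolerance = 0.02)
  # direct arithmetic oracle at alpha = 1
  g <- c(0.2, 0.9)
  expect_equal(bag_likelihood(g, alpha = 1), log(mean(exp(g))))
  expect_error(bag_likelihood(numeric(0)), "empty bag")
})

test_that("bag likelihood is monotone, bounded and stable under witness duplication", {
  set.seed(20)
  for (k in 1:25) {
    g <- runif(sample(2:8, 1), 0.02, 0.98)
    alpha <- runif(1, 0.5, 50)
    s <- bag_likelihood(g, alpha)
    expect_gte(s, max(0, min(g) - log(length(g)) / alpha))
    expect_lte(s, max(g))
    # monotone non-decreasing in every coordinate
    j <- sample(length(g), 1)
    g2 <- g; g2[j] <- min(g2[j] + 0.01, 0.99)
    expect_gte(bag_likelihood(g2, alpha), s - 1e-12)
    # duplicating the best instance shifts by at most log(2)/alpha
    gd <- c(g, max(g))
    expect_gte(bag_likelihood(gd, alpha), s - log(2) / alpha)
  }
  # at alpha = 1000 a two-instance softmax equals the max within 1e-3 for
  # gaps >= 0.1 (the deviation of the log-mean-exp form is log(n)/alpha)
  expect_equal(bag_likelihood(c(0.3, 0.8), alpha = 1e3), 0.8,
               tolerance = 1e-3)
  expect_equal(bag_likelihood(c(0.2, 0.5, 0.8), alpha = 1e3),
               0.8 - log(3) / 1e3, tolerance = 1e-6)
})

test_that("the joint log-likelihood is a sum of Bernoulli bag terms", {
  # single positive bag at s = 0.5: log 0.5
  f <- rep(0, 3) # logistic(0) = 0.5 for every instance -> s = 0.5
  expect_equal(joint_log_likelihood(f, rep(1L, 3), 1L, alpha = 7), log(0.5))
  # two independent bags: the sum of their terms
  f2 <- c(0.4, -0.2, 1.1, 0.3)
  idx <- c(1L, 1L, 2L, 2L)
  both <- joint_log_likelihood(f2, idx, c(1L, 0L), alpha = 5)
  one <- joint_log_likelihood(f2[1:2], c(1L, 1L), 1L, alpha = 5)
  two <- joint_log_likelihood(f2[3:4], c(1L, 1L), 0L, alpha = 5)
  expect_equal(both, one + two)
  # three-bag toy set against term-by-term hand computation
  f3 <- c(2, -1, 0.5, -2, 1)
  idx3 <- c(1L, 1L, 2L, 3L, 3L)
  g3 <- 1 / (1 + exp(-f3))
  s1 <- log(mean(exp(3 * g3[1:2]))) / 3
  s2 <- log(mean(exp(3 * g3[3]))) / 3
  s3 <- log(mean(exp(3 * g3[4:5]))) / 3
  expect_equal(joint_log_likelihood(f3, idx3, c(1L, 0L, 1L), alpha = 3),
               log(s1) + log(1 - s2) + log(s3))
})

test_that("the Newton mode satisfies its own stationarity and is deterministic", {
  d <- generate_bags(8, 8, dim = 3, separation = 4, seed = 90)
  y <- unclass(d$annotation)[, 1]
  m <- fit_gpmil(d$bags, y, alpha = 2, tol = 1e-6)
  expect_true(m$converged)
  # near-linear likelihood at small alpha: gradient at the mode ~ 0
  m2 <- fit_gpmil(d$bags, y, alpha = 2, tol = 1e-6)
  expect_identical(m$f_hat, m2$f_hat)
  expect_error(fit_gpmil(d$bags, rep(0L, 16)), "single class")
})

test_that("well-separated training bags are refit with confident positives", {
  d <- generate_bags(12, 12, dim = 4, separation = 5, witness_rate = 0.5,
                     seed = 91)
  y <- unclass(d$annotation)[, 1]
  m <- suppressWarnings(fit_gpmil(d$bags, y, alpha = 10))
  pr <- predict(m, d)
  expect_gte(mean(pr$prob[y == 1] >= 0.5), 0.95)
})

test_that("predictions revert to indifference far from the training data", {
  d <- generate_bags(6, 6, dim = 3, separation = 4, seed = 92)
  y <- unclass(d$annotation)[, 1]
  m <- suppressWarnings(fit_gpmil(d$bags, y, alpha = 10))
  far <- bag(matrix(500, 4, 3))
  r <- predict_gpmil(m, far)$prob
  expect_gte(r, 0.4); expect_lte(r, 0.6)
  # a duplicate of a confidently positive training bag predicts positive
  conf <- predict(m, d)
  best <- which.max(conf$prob * (y == 1))
  expect_gt(predict_gpmil(m, d$bags[[best]])$prob, 0.5)
  expect_error(predict_gpmil(m, bag(matrix(0, 1, 5))), "dimension mismatch")
})

test_that("the quadrature prediction matches a dense adaptive-integration oracle", {
  # independent oracle: the same predictive Gaussian on the top instance's
  # latent, but integrated with stats::integrate instead of Gauss-Hermite
  oracle_prob <- function(m, test) {
    Xs <- test$instances
    ell <- m$kernel$lengthscale
    Ks <- m$kernel$variance *
      exp(-(outer(rowSums(m$X^2), rowSums(Xs^2), "+") -
              2 * tcrossprod(m$X, Xs)) / (2 * ell^2))
    Q <- m$Kinv %*% Ks
    mu <- as.numeric(crossprod(Ks, m$Kinv %*% m$f_hat))
    s2 <- pmax(m$kernel$variance + m$jitter -
                 (colSums(Ks * Q) - colSums(Q * (m$Sigma %*% Q))), 1e-10)
    j <- which.max(mu)
    integrand <- function(fj) {
      vapply(fj, function(fv) {
        f_all <- mu; f_all[j] <- fv
        g <- pmin(pmax(1 / (1 + exp(-f_all)), 1e-12), 1 - 1e-12)
        s <- log(mean(exp(m$alpha * g))) / m$alpha
        min(max(s, 0), 1) * dnorm(fv, mu[j], sqrt(s2[j]))
      }, numeric(1))
    }
    stats::integrate(integrand, mu[j] - 8 * sqrt(s2[j]),
                     mu[j] + 8 * sqrt(s2[j]))$value
  }
  d <- generate_bags(3, 3, dim = 2, separation = 3, seed = 93,
                     instances_range = c(2L, 3L))
  y <- unclass(d$annotation)[, 1]
  m <- suppressWarnings(fit_gpmil(d$bags, y, alpha = 5))
  for (i in seq_along(d$bags)) {
    r32 <- predict_gpmil(m, d$bags[[i]], n_quad = 32L)$prob
    expect_equal(r32, oracle_prob(m, d$bags[[i]]), tolerance = 0.01)
    expect_gte(r32, 0); expect_lte(r32, 1)
  }
})
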