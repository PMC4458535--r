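test_that("symmetric one-dimensional problem puts the boundary at zero", {
  set.seed(20)
  n <- 20000
  X <- cbind(f = c(rnorm(n / 2, -1), rnorm(n / 2, 1)))
  y <- rep(0:1, each = n / 2)
  m <- fit_lda(X, y)
  # decision boundary: L1 = L2 at x = 0 (up to sampling error)
  boundary <- -(m$alpha[1] - m$beta[1]) / (m$alpha[2] - m$beta[2])
  expect_equal(unname(boundary), 0, tolerance = 0.05)
  cl <- score_and_classify(m, cbind(f = c(-3, 3)))
  expect_equal(as.character(cl$assigned), c("0", "1"))
})

test_that("identical class means give all-0.5 posteriors and the tie rule", {
  set.seed(21)
  X <- cbind(f = rnorm(40))
  y <- rep(0:1, 20)
  m <- fit_lda(X, y)
  m$alpha <- m$beta        # force exact degeneracy
  cl <- score_and_classify(m, X)
  expect_true(all(abs(cl$posteriors[, 1] - 0.5) < 1e-12))
  # ties resolve to the less severe class (class 1)
  expect_true(all(cl$assigned == m$class_labels[1]))
})

test_that("fitted weights approach the analytic discriminant parameters", {
  set.seed(22)
  Sigma <- matrix(c(1, 0.4, 0.4, 2), 2, 2)
  mu0 <- c(0, 0); mu1 <- c(1.5, 0.5)
  g <- gaussian_pair(25000, 25000, mu0, mu1, Sigma)
  m <- fit_lda(g$X, g$y)
  w_true0 <- solve(Sigma, mu0); w_true1 <- solve(Sigma, mu1)
  expect_equal(unname(m$beta[-1]), unname(w_true1), tolerance = 0.02)
  expect_equal(unname(m$beta[1]), -0.5 * sum(mu1 * w_true1), tolerance = 0.02)
  expect_equal(unname(m$alpha[-1]), unname(w_true0), tolerance = 0.05)
})

test_that("posteriors sum to one and softmax is shift-invariant", {
  set.seed(23)
  for (i in 1:50) {
    p <- sample(1:4, 1)
    S <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
    g <- gaussian_pair(30, 30, rnorm(p), rnorm(p, 1), S)
    m <- fit_lda(g$X, g$y)
    cl <- score_and_classify(m, g$X)
    expect_true(all(abs(rowSums(cl$posteriors) - 1) < 1e-12))
    # adding a constant to both discriminants leaves posteriors unchanged
    m2 <- m
    m2$alpha[1] <- m2$alpha[1] + 37.5
    m2$beta[1] <- m2$beta[1] + 37.5
    cl2 <- score_and_classify(m2, g$X)
    expect_equal(cl2$posteriors, cl$posteriors, tolerance = 1e-12)
  }
})

test_that("equal-prior assignment is nearest class mean in Mahalanobis distance", {
  set.seed(24)
  for (i in 1:200) {
    p <- sample(1:3, 1)
    S <- crossprod(matrix(rnorm(p * p), p)) + 0.5 * diag(p)
    g <- gaussian_pair(20, 25, rnorm(p), rnorm(p, 0.5), S)
    m <- fit_lda(g$X, g$y)
    cl <- score_and_classify(m, g$X)
    Sp <- m$cov
    d0 <- mahalanobis(g$X, m$means["class1", ], Sp)
    d1 <- mahalanobis(g$X, m$means["class2", ], Sp)
    nearest <- ifelse(d1 < d0, "1", "0")
    strict <- abs(d1 - d0) > 1e-9
    expect_identical(as.character(cl$assigned)[strict], nearest[strict])
  }
})

test_that("posteriors agree with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(25)
  for (i in 1:20) {
    p <- sample(2:4, 1)
    S <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
    g <- gaussian_pair(40, 35, rnorm(p), rnorm(p, 0.8), S)
    m <- fit_lda(g$X, g$y)
    cl <- score_and_classify(m, g$X)
    ref <- MASS::lda(g$X, grouping = g$y, prior = c(0.5, 0.5))
    rp <- predict(ref, g$X)$posterior
    expect_equal(unname(cl$posteriors[, 1]), unname(rp[, "0"]),
                 tolerance = 1e-8)
  }
})

test_that("posteriors are invariant to affine feature rescaling", {
  set.seed(26)
  g <- gaussian_pair(50, 50, c(0, 0), c(1, 1), diag(2))
  m1 <- fit_lda(g$X, g$y)
  p1 <- score_and_classify(m1, g$X)$posteriors
  Xs <- g$X
  Xs[, 1] <- 100 * Xs[, 1] - 7
  Xs[, 2] <- -0.01 * Xs[, 2] + 3
  m2 <- fit_lda(Xs, g$y)
  p2 <- score_and_classify(m2, Xs)$posteriors
  expect_equal(p2, p1, tolerance = 1e-8)
})

test_that("empirical priors shift the linear scores by their logs", {
  set.seed(27)
  g <- gaussian_pair(125, 55, c(0, 0), c(1, 0.5), diag(2))
  m_eq <- fit_lda(g$X, g$y, class_labels = c("CN", "AD"))
  m_emp <- fit_lda(g$X, g$y, prior = c(125 / 180, 55 / 180),
                   class_labels = c("CN", "AD"))
  s_eq <- score_and_classify(m_eq, g$X)
  s_emp <- score_and_classify(m_emp, g$X)
  expect_equal(s_emp$linear_scores[, "L1"] - s_eq$linear_scores[, "L1"],
               rep(log(125 / 180) - log(0.5), nrow(g$X)), ignore_attr = TRUE)
  expect_equal(s_emp$linear_scores[, "L2"] - s_eq$linear_scores[, "L2"],
               rep(log(55 / 180) - log(0.5), nrow(g$X)), ignore_attr = TRUE)
  # a subject with equal discriminant values goes to the majority class CN
  d_equal <- which.min(abs(s_eq$linear_scores[, 1] - s_eq$linear_scores[, 2]))
  expect_equal(as.character(s_emp$assigned[d_equal]), "CN")
})

test_that("degenerate inputs are rejected with informative errors", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(fit_lda(X, rep(0, 10)), "both classes")
  expect_error(fit_lda(X, rep(0:1, 5)), "zero-variance feature.*b")
  m <- fit_lda(cbind(a = rnorm(10)), rep(0:1, 5))
  expect_error(score_and_classify(m, cbind(z = rnorm(3))), "lacks model feature")
  expect_error(score_and_classify(m, cbind(a = c(1, NA))), "non-finite")
})

test_that("held-out accuracy approaches the analytic Bayes rate", {
  # Mahalanobis separation 2 -> Bayes accuracy pnorm(1) ~ 0.841
  set.seed(28)
  tr <- gaussian_pair(5000, 5000, c(0, 0), c(2, 0), diag(2))
  te <- gaussian_pair(10000, 10000, c(0, 0), c(2, 0), diag(2))
  m <- fit_lda(tr$X, tr$y)
  acc <- mean(as.integer(as.character(score_and_classify(m, te$X)$assigned)) == te$y)
  expect_equal(acc, pnorm(1), tolerance = 0.01)
})
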