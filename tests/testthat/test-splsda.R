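test_that("encode_response produces sorted, column-centered dummies", {
  Y <- encode_response(c("Pos", "Pos", "Neg", "Neg"))
  expect_identical(attr(Y, "class_levels"), c("Neg", "Pos"))
  expect_equal(dim(Y), c(4L, 2L))
  expect_equal(unname(colSums(Y)), c(0, 0))
  expect_equal(abs(as.numeric(Y)), rep(0.5, 8))

  Y3 <- encode_response(rep(c("a", "b", "c"), each = 2))
  expect_equal(ncol(Y3), 3)
  expect_equal(unname(colSums(Y3)), rep(0, 3), tolerance = 1e-12)

  expect_error(encode_response(rep("only", 4)), "at least 2 classes")
  expect_error(encode_response(c("a", "a", "b")), "fewer than 2")
})

test_that("worked 4-sample example: thresholding, scores, support", {
  inst <- toy_pls_instance()
  m <- fit_splsda(inst$X, encode_response(inst$labels), eta = 0.5, K = 1)
  expect_equal(unname(m$weights[, 1]), c(1, 0, 0))
  expect_equal(unname(m$scores[, 1]), c(2, 1, -1, -2))
  expect_identical(m$support, "f1")

  # eta = 0 keeps the full z = (6, 2, 0) direction
  m0 <- fit_splsda(inst$X, encode_response(inst$labels), eta = 0, K = 1)
  expect_equal(unname(m0$weights[, 1]),
               c(6, 2, 0) / sqrt(40), tolerance = 1e-12)
  expect_identical(m0$support, c("f1", "f2"))

  # perfect separation on the training data
  expect_identical(unname(predict_classes(m, inst$X)), inst$labels)

  # excessive sparsity on a degenerate direction errors helpfully
  Xdeg <- matrix(rnorm(20), 5, 4,
                 dimnames = list(sprintf("s%d", 1:5), sprintf("f%d", 1:4)))
  expect_error(fit_splsda(Xdeg * 0, encode_response(c("a", "a", "a", "b", "b")),
                          eta = 0.5, K = 1),
               "degenerate")
  expect_error(fit_splsda(inst$X, encode_response(inst$labels),
                          eta = 1, K = 1), "eta")
  expect_error(fit_splsda(inst$X, encode_response(inst$labels),
                          eta = 0, K = 3), "n >= K")
})

test_that("eta = 0 reproduces dense PLS2 NIPALS within 1e-8", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- 20; p <- 8
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%d", 1:n), sprintf("f%d", 1:p)))
    labels <- rep(c("A", "B"), each = n / 2)
    Y <- encode_response(labels)
    K <- 2
    fit <- fit_splsda(X, Y, eta = 0, K = K)
    oracle <- pls2_nipals_oracle(X, Y, K)
    expect_equal(unname(fit$scores), unname(oracle$scores),
                 tolerance = 1e-8)
    expect_equal(unname(fit$weights), unname(oracle$weights),
                 tolerance = 1e-8)
  }
})

test_that("score orthogonality and sparsity monotonicity hold on random instances", {
  for (seed in seq_len(50)) {
    set.seed(seed)
    n <- sample(12:24, 1)
    p <- sample(5:40, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%02d", 1:n),
                                sprintf("f%02d", 1:p)))
    labels <- sample(rep(c("A", "B"), length.out = n))
    if (min(table(labels)) < 2) next
    K <- sample(1:3, 1)
    eta <- stats::runif(1, 0, 0.9)
    fit <- fit_splsda(X, encode_response(labels), eta = eta, K = K)
    TT <- crossprod(fit$scores)
    expect_lt(max(abs(TT - diag(diag(TT), ncol(TT)))), 1e-8)

    # |support| non-increasing in eta, single component
    sizes <- vapply(c(0, 0.3, 0.6, 0.9), function(e)
      length(fit_splsda(X, encode_response(labels),
                        eta = e, K = 1)$support), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("fit is invariant to sample order", {
  set.seed(99)
  n <- 16; p <- 10
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  labels <- rep(c("A", "B"), each = 8)
  fit <- fit_splsda(X, encode_response(labels), eta = 0.4, K = 2)
  perm <- sample(n)
  fit_p <- fit_splsda(X[perm, ], encode_response(labels[perm]),
                      eta = 0.4, K = 2)
  expect_equal(fit_p$weights, fit$weights, tolerance = 1e-10)
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_equal(unname(fit_p$scores), unname(fit$scores[perm, ]),
               tolerance = 1e-10)

  # predictions are a row-wise operation
  pred <- predict_classes(fit, X)
  expect_identical(unname(predict_classes(fit, X[perm, ])),
                   unname(pred[perm]))
})

test_that("prediction ties go to the lexicographically first class", {
  inst <- toy_pls_instance()
  m <- fit_splsda(inst$X, encode_response(inst$labels), eta = 0.5, K = 1)
  centroid <- matrix(m$feature_means, 1,
                     dimnames = list("mid", colnames(inst$X)))
  expect_identical(unname(predict_classes(m, centroid)), "Neg")

  expect_error(predict_classes(m, inst$X[, 2:3]), "lacks model features")
  # extra columns are dropped silently
  Xextra <- cbind(inst$X, junk = rnorm(4))
  expect_identical(predict_classes(m, Xextra), predict_classes(m, inst$X))
})

test_that("cross_validate finds separable structure and is deterministic", {
  set.seed(5)
  n <- 24
  X <- matrix(rnorm(n * 6, sd = 0.2), n, 6,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:6)))
  labels <- rep(c("A", "B"), each = n / 2)
  X[labels == "B", 1] <- X[labels == "B", 1] + 5   # one separating feature
  tun <- cross_validate(X, labels, eta_grid = c(0, 0.5, 0.9),
                        K_grid = 1:2, folds = 4, seed = 3)
  expect_true(min(tun$grid$error, na.rm = TRUE) == 0)
  expect_true(all(tun$grid$error >= 0 & tun$grid$error <= 1,
                  na.rm = TRUE))
  # ties resolved toward smaller K then larger eta
  zero <- tun$grid[!is.na(tun$grid$error) & tun$grid$error == 0, ]
  expect_equal(tun$best_K, min(zero$K))
  expect_equal(tun$best_eta,
               max(zero$eta[zero$K == tun$best_K]))

  tun2 <- cross_validate(X, labels, eta_grid = c(0, 0.5, 0.9),
                         K_grid = 1:2, folds = 4, seed = 3)
  expect_identical(tun$grid, tun2$grid)
  expect_identical(tun$fold_assignment, tun2$fold_assignment)

  expect_error(cross_validate(X, labels, eta_grid = numeric(0),
                              K_grid = 1, seed = 1), "grid is empty")
  expect_warning(
    cross_validate(X[1:10, ], rep(c("A", "B"), c(7, 3)),
                   eta_grid = 0, K_grid = 1, folds = 5, seed = 1),
    "reducing folds")
})

test_that("CV error on label-independent data sits near chance", {
  # Monte-Carlo oracle: pure-noise X, balanced labels, fixed seeds.
  errs <- vapply(1:8, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(40 * 12), 40, 12,
                dimnames = list(sprintf("s%02d", 1:40),
                                sprintf("f%02d", 1:12)))
    labels <- rep(c("A", "B"), each = 20)
    tun <- cross_validate(X, labels, eta_grid = 0, K_grid = 1,
                          folds = 5, seed = s)
    tun$grid$error[1]
  }, numeric(1))
  se <- stats::sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs) - 0.5), 3 * se + 1e-9)
})

test_that("models survive a plain-text round trip", {
  inst <- toy_pls_instance()
  m <- fit_splsda(inst$X, encode_response(inst$labels), eta = 0.3, K = 2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_splsda_model(m, f)
  back <- read_splsda_model(f)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_identical(back$support, m$support)
  expect_identical(unname(predict_classes(back, inst$X)),
                   unname(predict_classes(m, inst$X)))
})
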