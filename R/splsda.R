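#' Dummy-code class labels as a centered response matrix
#'
#' Standard PLS-DA coding: one indicator column per class (levels sorted
#' lexicographically), then column-centered so each column sums to zero.
#'
#' @param labels character vector of per-sample class labels (may be
#'   named by sample id).
#' @return A `response_matrix`: n-by-G numeric matrix with attribute
#'   `class_levels`.
#' @examples
#' encode_response(c("Pos", "Pos", "Neg", "Neg"))
#' @export
encode_response <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) {
    clrda_error("labels contain missing values; drop those samples first",
                "clrda_input_error")
  }
  levels <- sort(unique(labels))
  if (length(levels) < 2) {
    clrda_error("need at least 2 classes", "clrda_input_error")
  }
  tab <- table(labels)
  if (any(tab < 2)) {
    clrda_error(sprintf("class '%s' has fewer than 2 samples",
                        names(tab)[tab < 2][1]), "clrda_input_error")
  }
  Y <- vapply(levels, function(l) as.numeric(labels == l),
              numeric(length(labels)))
  Y <- scale(Y, center = TRUE, scale = FALSE)
  attr(Y, "scaled:center") <- NULL
  dimnames(Y) <- list(names(labels), levels)
  structure(Y, class = c("response_matrix", "matrix", "array"),
            class_levels = levels)
}

#' Fit a sparse PLS-DA model
#'
#' Sparse Partial Least Squares against a dummy-coded class response,
#' fit by a NIPALS-style sequence of `K` latent components. For each
#' component the candidate direction `z` is the leading left singular
#' vector of `X_k' Y_k` (for a binary response this is proportional to
#' `X_k' y`); sparsity comes from soft-thresholding,
#' `w_j = sign(z_j) max(|z_j| - eta * max_i |z_i|, 0)`, normalized to
#' unit length. Scores are `t = X_k w`; X- and Y-loadings are the
#' regressions of `X_k` and `Y_k` on `t`; both matrices are deflated by
#' the rank-one fit (PLS2 regression mode), which makes the coefficient
#' matrix `B = W (P'W)^{-1} Q'` well defined. After thresholding the
#' direction is used as-is (no least-squares refit on the support).
#'
#' `X` is column-centered internally; the training means are stored so
#' new samples are centered identically at prediction time.
#'
#' @param X samples-by-feature numeric matrix (typically a `clr_matrix`).
#' @param Y a `response_matrix` from [encode_response()], or any centered
#'   numeric response matrix/vector.
#' @param eta sparsity in `[0, 1)`; 0 gives ordinary dense PLS2.
#' @param K number of latent components (`n >= K + 2`).
#' @param scale_features if `TRUE`, features are also scaled to unit
#'   training variance (default `FALSE`: centering only).
#' @return An object of class `splsda_model`: list with `eta`, `K`,
#'   `weights` (p x K), `x_loadings` (p x K), `y_loadings` (G x K),
#'   `scores` (n x K), `coefficients` (p x G), `support` (feature ids
#'   with any nonzero weight), `feature_means`, `feature_scales`,
#'   `class_levels`.
#' @export
fit_splsda <- function(X, Y, eta = 0, K = 1, scale_features = FALSE) {
  if (!is.matrix(X) || !is.numeric(X)) {
    clrda_error("`X` must be a numeric matrix", "clrda_input_error")
  }
  if (!is.numeric(eta) || length(eta) != 1 || eta < 0 || eta >= 1) {
    clrda_error("`eta` must be a single number in [0, 1)",
                "clrda_input_error")
  }
  if (!is_whole(K) || K < 1) {
    clrda_error("`K` must be a positive integer", "clrda_input_error")
  }
  if (nrow(X) < K + 2) {
    clrda_error(sprintf("need n >= K + 2 samples (n = %d, K = %d)",
                        nrow(X), K), "clrda_input_error")
  }
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  if (nrow(Y) != nrow(X)) {
    clrda_error("X and Y have different sample counts", "clrda_input_error")
  }
  class_levels <- attr(Y, "class_levels")
  p <- ncol(X); G <- ncol(Y); n <- nrow(X)

  feature_means <- colMeans(X)
  Xk <- sweep(X, 2L, feature_means)
  feature_scales <- rep(1, p)
  if (scale_features) {
    feature_scales <- apply(Xk, 2L, stats::sd)
    feature_scales[feature_scales == 0] <- 1
    Xk <- sweep(Xk, 2L, feature_scales, "/")
  }
  Yk <- as.matrix(Y)

  W <- matrix(0, p, K, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, K, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, G, K, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, K, dimnames = list(rownames(X), NULL))

  for (k in seq_len(K)) {
    M <- crossprod(Xk, Yk)                      # p x G
    if (max(abs(M)) < 1e-12) {
      clrda_error(sprintf(
        "component %d: X'Y direction is numerically zero (degenerate data)",
        k), "clrda_fit_error")
    }
    z <- if (ncol(M) == 1) M[, 1] else svd(M, nu = 1, nv = 0)$u[, 1]
    zmax <- max(abs(z))
    if (zmax < 1e-12) {
      clrda_error(sprintf(
        "component %d: X'Y direction is numerically zero (degenerate data)",
        k), "clrda_fit_error")
    }
    jmax <- which.max(abs(z))                   # deterministic sign fix
    if (z[jmax] < 0) z <- -z
    w <- sign(z) * pmax(abs(z) - eta * zmax, 0)
    if (all(w == 0)) {
      clrda_error(sprintf(
        "component %d: soft threshold eta = %g removed every feature; use a smaller eta",
        k, eta), "clrda_fit_error")
    }
    w <- w / sqrt(sum(w^2))
    t_k <- drop(Xk %*% w)
    tt <- sum(t_k^2)
    if (tt < 1e-12) {
      clrda_error(sprintf("component %d: zero-variance score", k),
                  "clrda_fit_error")
    }
    W[, k] <- w
    Tm[, k] <- t_k
    P[, k] <- crossprod(Xk, t_k) / tt
    Q[, k] <- crossprod(Yk, t_k) / tt
    Xk <- Xk - tcrossprod(t_k, P[, k])
    Yk <- Yk - tcrossprod(t_k, Q[, k])
  }

  PtW <- crossprod(P, W)
  Binner <- tryCatch(solve(PtW), error = function(e) {
    clrda_error("P'W is singular; coefficients are not identifiable",
                "clrda_fit_error")
  })
  B <- W %*% Binner %*% t(Q)
  B <- B / feature_scales                       # back to input scale
  dimnames(B) <- list(colnames(X), colnames(Y))
  support <- colnames(X)[rowSums(W != 0) > 0]
  if (is.null(support)) support <- which(rowSums(W != 0) > 0)

  structure(list(eta = eta, K = K, weights = W, x_loadings = P,
                 y_loadings = Q, scores = Tm, coefficients = B,
                 support = support, feature_means = feature_means,
                 feature_scales = feature_scales,
                 class_levels = class_levels),
            class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("<splsda_model> K = %d, eta = %g, support %d/%d features\n",
              x$K, x$eta, length(x$support), nrow(x$weights)))
  invisible(x)
}

#' Predict class labels from a fitted sPLS-DA model
#'
#' New samples are centered with the training feature means, projected
#' through the coefficient matrix, and assigned to the class whose
#' response column is largest. Ties go to the lexicographically smallest
#' class level. Extra columns in `Xnew` are dropped; missing model
#' features are an error.
#'
#' @param model an `splsda_model`.
#' @param Xnew samples-by-feature matrix with (at least) the model's
#'   feature columns.
#' @return Character vector of predicted class levels, named by sample.
#' @export
predict_classes <- function(model, Xnew) {
  stopifnot(inherits(model, "splsda_model"))
  feats <- rownames(model$coefficients)
  missing <- setdiff(feats, colnames(Xnew))
  if (length(missing) > 0) {
    clrda_error(sprintf("Xnew lacks model features: %s",
                        paste(missing, collapse = ", ")),
                "clrda_input_error")
  }
  Xc <- sweep(Xnew[, feats, drop = FALSE], 2L, model$feature_means)
  scores <- Xc %*% model$coefficients
  levels <- colnames(model$coefficients)
  if (is.null(levels)) levels <- as.character(seq_len(ncol(scores)))
  # which.max takes the first maximum; columns are already sorted
  # lexicographically by encode_response, giving the stated tie rule
  idx <- apply(scores, 1L, which.max)
  stats::setNames(levels[idx], rownames(Xnew))
}

#' Tune sparsity and component count by stratified cross-validation
#'
#' Samples are assigned to `folds` folds stratified by class,
#' deterministically from `seed`. For every grid point `(eta, K)` each
#' held-out fold is predicted by a model fit on the remaining folds
#' (fold-train centering only, so no information leaks from the test
#' fold), and the misclassification rate is averaged across folds. The
#' chosen pair minimizes mean error; ties are broken by smaller `K`,
#' then larger `eta` (prefer the sparser, simpler model).
#'
#' @param X samples-by-feature matrix.
#' @param labels per-sample class labels.
#' @param eta_grid candidate sparsity values (default 0, 0.1, ..., 0.9).
#' @param K_grid candidate component counts (default 1:3).
#' @param folds number of CV folds (default 5). If a class has fewer
#'   members than `folds`, the fold count is reduced (floor 2) with a
#'   warning.
#' @param seed integer seed for the fold assignment.
#' @param scale_features passed to [fit_splsda()].
#' @return A `tuning_result`: list with `grid` (data.frame of eta, K,
#'   error, se), `best_eta`, `best_K`, `folds`, `seed`,
#'   `fold_assignment`.
#' @export
cross_validate <- function(X, labels, eta_grid = seq(0, 0.9, by = 0.1),
                           K_grid = 1:3, folds = 5, seed = 1,
                           scale_features = FALSE) {
  labels <- as.character(labels)
  if (length(eta_grid) == 0 || length(K_grid) == 0) {
    clrda_error("tuning grid is empty", "clrda_input_error")
  }
  if (!is_whole(folds) || folds < 2) {
    clrda_error("`folds` must be an integer >= 2", "clrda_input_error")
  }
  min_class <- min(table(labels))
  if (min_class < folds) {
    folds_new <- max(2L, min_class)
    warning(sprintf(
      "smallest class has %d samples; reducing folds from %d to %d",
      min_class, folds, folds_new))
    folds <- folds_new
  }
  n <- nrow(X)
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })

  grid <- expand.grid(eta = eta_grid, K = K_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$error <- NA_real_
  grid$se <- NA_real_
  for (g in seq_len(nrow(grid))) {
    errs <- rep(NA_real_, folds)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      fit <- tryCatch({
        m <- fit_splsda(X[tr, , drop = FALSE],
                        encode_response(labels[tr]),
                        eta = grid$eta[g], K = grid$K[g],
                        scale_features = scale_features)
        pred <- predict_classes(m, X[!tr, , drop = FALSE])
        mean(pred != labels[!tr])
      }, clrda_error = function(e) NA_real_)
      errs[f] <- fit
    }
    if (!anyNA(errs)) {
      grid$error[g] <- mean(errs)
      grid$se[g] <- stats::sd(errs) / sqrt(folds)
    }
  }
  ok <- which(!is.na(grid$error))
  if (length(ok) == 0) {
    clrda_error("every grid point failed to fit", "clrda_fit_error")
  }
  # minimize error; ties -> smaller K, then larger eta
  cand <- grid[ok, ]
  cand <- cand[order(cand$error, cand$K, -cand$eta), ]
  structure(list(grid = grid, best_eta = cand$eta[1], best_K = cand$K[1],
                 folds = folds, seed = seed, fold_assignment = fold_of),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf(
    "<tuning_result> chosen eta = %g, K = %d (%d-fold CV, seed %d)\n",
    x$best_eta, x$best_K, x$folds, x$seed))
  best <- x$grid[x$grid$eta == x$best_eta & x$grid$K == x$best_K, ]
  cat(sprintf("  CV error %.3f (SE %.3f)\n", best$error, best$se))
  invisible(x)
}

#' Persist / restore a fitted model as plain text
#'
#' Key-value + matrix dump; no binary serialization, so a stored model
#' is diffable and survives R version changes.
#'
#' @param model an `splsda_model`.
#' @param path file path.
#' @return `path` (writer) or the restored `splsda_model` (reader).
#' @export
write_splsda_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  put <- function(...) writeLines(sprintf(...), con)
  put("#clrda_splsda_model\teta=%.17g\tK=%d", model$eta, model$K)
  put("#class_levels\t%s", paste(model$class_levels, collapse = "\t"))
  put("#support\t%s", paste(model$support, collapse = "\t"))
  dump_mat <- function(name, m) {
    put("#matrix\t%s\t%d\t%d", name, nrow(m), ncol(m))
    utils::write.table(format(m, digits = 17, trim = TRUE), con,
                       sep = "\t", quote = FALSE, col.names = FALSE)
  }
  dump_mat("weights", model$weights)
  dump_mat("x_loadings", model$x_loadings)
  dump_mat("y_loadings", model$y_loadings)
  dump_mat("scores", model$scores)
  dump_mat("coefficients", model$coefficients)
  dump_mat("feature_means", cbind(model$feature_means))
  dump_mat("feature_scales", cbind(model$feature_scales))
  invisible(path)
}

#' @rdname write_splsda_model
#' @export
read_splsda_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "#clrda_splsda_model") {
    clrda_error(sprintf("%s: not a clrda model file", path),
                "clrda_input_error")
  }
  eta <- as.numeric(sub("eta=", "", hdr[2]))
  K <- as.integer(sub("K=", "", hdr[3]))
  levels <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  support <- strsplit(lines[3], "\t", fixed = TRUE)[[1]][-1]
  mats <- list()
  i <- 4L
  while (i <= length(lines)) {
    meta <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    nr <- as.integer(meta[3])
    block <- strsplit(lines[i + seq_len(nr)], "\t", fixed = TRUE)
    m <- do.call(rbind, lapply(block, function(f) as.numeric(f[-1])))
    rownames(m) <- vapply(block, `[[`, "", 1L)
    mats[[meta[2]]] <- m
    i <- i + nr + 1L
  }
  colnames(mats$coefficients) <- levels
  structure(list(eta = eta, K = K, weights = mats$weights,
                 x_loadings = mats$x_loadings,
                 y_loadings = mats$y_loadings, scores = mats$scores,
                 coefficients = mats$coefficients, support = support,
                 feature_means = stats::setNames(
                   mats$feature_means[, 1], rownames(mats$feature_means)),
                 feature_scales = mats$feature_scales[, 1],
                 class_levels = levels),
            class = "splsda_model")
}
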