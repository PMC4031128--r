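#' Bootstrap distribution of sPLS-DA coefficients
#'
#' Refits the model on `B` class-stratified bootstrap resamples (drawn
#' with replacement within each class, so a class can never vanish in a
#' 70/30 cohort) at the tuned `(eta, K)`, recording the positive-class
#' column of the coefficient matrix each time. Resamples whose refit is
#' degenerate are redrawn, capped at `10 * B` total attempts.
#'
#' @param X samples-by-feature matrix (typically filtered clr values).
#' @param labels per-sample class labels.
#' @param eta,K tuned sparsity and component count (from
#'   [cross_validate()]).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param positive class level whose coefficient column is tracked;
#'   default is the lexicographically last level (e.g. `"Pos"` for
#'   Pos/Neg coding).
#' @param scale_features passed to [fit_splsda()].
#' @param .resampler internal hook used by the test suite to force a
#'   specific resample; must map `n` to an index vector.
#' @return A `resampling_distribution`: list with `kind = "bootstrap"`,
#'   `draws` (B x p matrix, columns in X's feature order), `seed`,
#'   `eta`, `K`, `positive`, `failures` (redraw count).
#' @export
bootstrap_coefficients <- function(X, labels, eta, K, B = 1000, seed = 1,
                                   positive = NULL,
                                   scale_features = FALSE,
                                   .resampler = NULL) {
  labels <- as.character(labels)
  if (!is_whole(B) || B < 1) {
    clrda_error("`B` must be a positive integer", "clrda_input_error")
  }
  if (is.null(positive)) positive <- sort(unique(labels))[
    length(unique(labels))]
  class_idx <- split(seq_along(labels), labels)
  default_resampler <- function(n) {
    unlist(lapply(class_idx, function(idx)
      idx[sample.int(length(idx), length(idx), replace = TRUE)]),
      use.names = FALSE)
  }
  resampler <- if (is.null(.resampler)) default_resampler else .resampler
  draws <- matrix(NA_real_, B, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  failures <- 0L
  with_seed(seed, {
    b <- 1L
    attempts <- 0L
    while (b <= B) {
      attempts <- attempts + 1L
      if (attempts > 10L * B) {
        clrda_error(sprintf(
          "bootstrap exceeded %d attempts for %d resamples (degenerate class sizes)",
          10L * B, B), "clrda_fit_error")
      }
      idx <- resampler(length(labels))
      coef <- tryCatch({
        m <- fit_splsda(X[idx, , drop = FALSE],
                        encode_response(labels[idx]), eta = eta, K = K,
                        scale_features = scale_features)
        m$coefficients[, positive]
      }, clrda_error = function(e) NULL)
      if (is.null(coef)) {
        failures <- failures + 1L
        next
      }
      draws[b, ] <- coef
      b <- b + 1L
    }
  })
  structure(list(kind = "bootstrap", draws = draws, seed = seed,
                 eta = eta, K = K, positive = positive,
                 failures = failures),
            class = "resampling_distribution")
}

#' Permutation-null distribution of sPLS-DA coefficients
#'
#' Refits the model `P` times with the class labels uniformly permuted
#' (labels only, keeping X intact and class counts fixed), recording
#' the positive-class coefficient column. This is the reference
#' distribution against which bootstrap coefficients are judged.
#'
#' @inheritParams bootstrap_coefficients
#' @param P number of permutations (default 1000).
#' @return A `resampling_distribution` with `kind = "permutation_null"`.
#' @export
permutation_null <- function(X, labels, eta, K, P = 1000, seed = 1,
                             positive = NULL, scale_features = FALSE) {
  labels <- as.character(labels)
  if (!is_whole(P) || P < 1) {
    clrda_error("`P` must be a positive integer", "clrda_input_error")
  }
  if (is.null(positive)) positive <- sort(unique(labels))[
    length(unique(labels))]
  draws <- matrix(NA_real_, P, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  failures <- 0L
  with_seed(seed, {
    r <- 1L
    attempts <- 0L
    while (r <= P) {
      attempts <- attempts + 1L
      if (attempts > 10L * P) {
        clrda_error("permutation null exceeded the attempt cap",
                    "clrda_fit_error")
      }
      perm <- labels[sample.int(length(labels))]
      coef <- tryCatch({
        m <- fit_splsda(X, encode_response(perm), eta = eta, K = K,
                        scale_features = scale_features)
        m$coefficients[, positive]
      }, clrda_error = function(e) NULL)
      if (is.null(coef)) {
        failures <- failures + 1L
        next
      }
      draws[r, ] <- coef
      r <- r + 1L
    }
  })
  structure(list(kind = "permutation_null", draws = draws, seed = seed,
                 eta = eta, K = K, positive = positive,
                 failures = failures),
            class = "resampling_distribution")
}

#' Pseudo p-values from bootstrap vs permutation-null coefficients
#'
#' For each OTU the permutation-null draws define two-sided tail
#' thresholds (the `alpha/2` and `1 - alpha/2` empirical quantiles,
#' computed per OTU since clr scales are heterogeneous). The
#' significance strength `s` is the fraction of bootstrap draws beyond
#' those tails, and `pseudo_p = 1 - s`: an OTU whose bootstrap mass lies
#' entirely beyond the null tails gets pseudo_p = 0 (maximally
#' significant). Selection is `pseudo_p <= alpha`.
#'
#' With `tail_rule = "strict"` (default) "beyond" means strictly outside
#' the closed interval \[lower, upper\]. The non-strict reading
#' (`"inclusive"`, draws `<=` lower or `>=` upper) is provided for
#' comparison, but degenerates when a sparse fit leaves an OTU's null
#' draws all exactly zero: the thresholds collapse to (0, 0) and every
#' all-zero bootstrap column would count as significant.
#' `p_is_fraction = TRUE` switches to the complementary convention in
#' which the reported p IS the tail fraction `s` itself.
#'
#' @param boot bootstrap `resampling_distribution`.
#' @param null permutation-null `resampling_distribution`.
#' @param alpha significance level in (0, 1), default 0.05.
#' @param tail_rule `"strict"` or `"inclusive"` (see Details).
#' @param p_is_fraction report `s` instead of `1 - s` as the p-value.
#' @param taxonomy optional named lineage strings merged into the report.
#' @return A `significance_report`: data.frame with one row per OTU
#'   (otu_id, taxonomy, boot_median, boot_lo, boot_hi, null_lo, null_hi,
#'   tail_fraction, pseudo_p, selected) and attribute `alpha`.
#' @export
pseudo_pvalues <- function(boot, null, alpha = 0.05,
                           tail_rule = c("strict", "inclusive"),
                           p_is_fraction = FALSE, taxonomy = NULL) {
  tail_rule <- match.arg(tail_rule)
  stopifnot(inherits(boot, "resampling_distribution"),
            inherits(null, "resampling_distribution"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    clrda_error("`alpha` must be in (0, 1)", "clrda_input_error")
  }
  if (!identical(colnames(boot$draws), colnames(null$draws))) {
    clrda_error("bootstrap and null OTU sets/orders differ",
                "clrda_input_error")
  }
  otus <- colnames(boot$draws)
  null_lo <- apply(null$draws, 2L, stats::quantile, probs = alpha / 2,
                   names = FALSE)
  null_hi <- apply(null$draws, 2L, stats::quantile,
                   probs = 1 - alpha / 2, names = FALSE)
  beyond <- if (tail_rule == "strict") {
    sweep(boot$draws, 2L, null_lo, "<") | sweep(boot$draws, 2L, null_hi, ">")
  } else {
    sweep(boot$draws, 2L, null_lo, "<=") |
      sweep(boot$draws, 2L, null_hi, ">=")
  }
  s <- colMeans(beyond)
  pseudo_p <- if (p_is_fraction) s else 1 - s
  report <- data.frame(
    otu_id = otus,
    taxonomy = if (is.null(taxonomy)) NA_character_ else
      unname(taxonomy[otus]),
    boot_median = apply(boot$draws, 2L, stats::median),
    boot_lo = apply(boot$draws, 2L, stats::quantile, probs = 0.025,
                    names = FALSE),
    boot_hi = apply(boot$draws, 2L, stats::quantile, probs = 0.975,
                    names = FALSE),
    null_lo = null_lo,
    null_hi = null_hi,
    tail_fraction = s,
    pseudo_p = pseudo_p,
    selected = pseudo_p <= alpha,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(report, alpha = alpha,
            class = c("significance_report", "data.frame"))
}

#' Sample and variable coordinates for a biplot
#'
#' Samples are placed at their scores on the first two latent
#' components; loading arrows are drawn only for the selected
#' (significant) OTUs, using their weights on those components. With a
#' one-component model the second coordinate is identically zero and
#' the result is flagged.
#'
#' @param model an `splsda_model`.
#' @param report a `significance_report`; OTUs with `selected = TRUE`
#'   get arrows.
#' @param labels optional per-sample class labels carried along for
#'   plotting.
#' @return A `biplot_data`: list with `scores` (n x 2), `arrows`
#'   (selected x 2), `labels`, `axis2_degenerate` flag.
#' @export
biplot_coordinates <- function(model, report, labels = NULL) {
  stopifnot(inherits(model, "splsda_model"))
  k1 <- model$K < 2
  scores <- cbind(comp1 = model$scores[, 1],
                  comp2 = if (k1) 0 else model$scores[, 2])
  rownames(scores) <- rownames(model$scores)
  sel <- report$otu_id[report$selected]
  sel <- intersect(sel, rownames(model$weights))
  arrows <- cbind(comp1 = model$weights[sel, 1],
                  comp2 = if (k1) rep(0, length(sel)) else
                    model$weights[sel, 2])
  rownames(arrows) <- sel
  structure(list(scores = scores, arrows = arrows, labels = labels,
                 axis2_degenerate = k1),
            class = "biplot_data")
}

#' Write a significance report / biplot data as TSV
#'
#' @param report a `significance_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_significance_report <- function(report, path) {
  out <- report
  out$selected <- ifelse(out$selected, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_significance_report
#' @param biplot a `biplot_data`.
#' @param prefix path prefix; writes `<prefix>_samples.tsv` and
#'   `<prefix>_arrows.tsv`.
#' @export
write_biplot_data <- function(biplot, prefix) {
  s <- data.frame(sample_id = rownames(biplot$scores),
                  comp1 = biplot$scores[, 1],
                  comp2 = biplot$scores[, 2],
                  label = if (is.null(biplot$labels)) NA_character_ else
                    as.character(biplot$labels))
  utils::write.table(s, paste0(prefix, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  a <- data.frame(otu_id = rownames(biplot$arrows),
                  comp1 = biplot$arrows[, 1],
                  comp2 = biplot$arrows[, 2])
  utils::write.table(a, paste0(prefix, "_arrows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
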