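#' Full compositional feature-selection pipeline
#'
#' Runs the whole method on a count table + metadata pair: align
#' samples, drop samples with missing class labels, close to
#' compositions with a pseudocount, clr-transform, keep the `top_n`
#' most variable OTUs, tune `(eta, K)` by stratified cross-validation,
#' fit the final sparse PLS-DA model, draw bootstrap and
#' permutation-null coefficient distributions, convert them to pseudo
#' p-values, and assemble biplot coordinates.
#'
#' @param table a [count_table].
#' @param meta a [sample_metadata].
#' @param class_col metadata column holding the binary phenotype.
#' @param positive class level treated as "positive" for coefficient
#'   reporting; default the lexicographically last level.
#' @param pseudocount passed to [close_composition()].
#' @param top_n passed to [filter_variable_features()].
#' @param eta_grid,K_grid,folds passed to [cross_validate()].
#' @param B,P bootstrap / permutation resample counts.
#' @param alpha selection level.
#' @param seed master seed; stage seeds are derived from it.
#' @param tail_rule,p_is_fraction passed to [pseudo_pvalues()].
#' @param scale_features passed to [fit_splsda()].
#' @return A `selection_result`: list with `clr` (filtered matrix),
#'   `labels`, `tuning`, `model`, `boot`, `null`, `report`, `biplot`,
#'   `dropped_na` (samples lost to missing labels), `seeds`.
#' @export
select_features <- function(table, meta, class_col = "Helminth",
                            positive = NULL, pseudocount = 0.5,
                            top_n = 300,
                            eta_grid = seq(0, 0.9, by = 0.1),
                            K_grid = 1:3, folds = 5, B = 1000,
                            P = 1000, alpha = 0.05, seed = 1,
                            tail_rule = "strict",
                            p_is_fraction = FALSE,
                            scale_features = FALSE) {
  aligned <- align_samples(table, meta)
  labels <- metadata_column(aligned$meta, class_col)
  keep <- !is.na(labels)
  dropped_na <- sum(!keep)
  if (dropped_na > 0) {
    ids <- sample_ids(aligned$table)[keep]
    aligned$table <- count_table(
      aligned$table$counts[ids, , drop = FALSE], aligned$table$taxonomy)
    labels <- labels[ids]
  }
  comp <- close_composition(aligned$table, pseudocount)
  clr <- clr_transform(comp)
  clr <- filter_variable_features(clr, top_n)
  seeds <- derive_seeds(seed, 3)
  tuning <- cross_validate(clr, labels, eta_grid = eta_grid,
                           K_grid = K_grid, folds = folds,
                           seed = seeds[1],
                           scale_features = scale_features)
  model <- fit_splsda(clr, encode_response(labels),
                      eta = tuning$best_eta, K = tuning$best_K,
                      scale_features = scale_features)
  boot <- bootstrap_coefficients(clr, labels, eta = tuning$best_eta,
                                 K = tuning$best_K, B = B,
                                 seed = seeds[2], positive = positive,
                                 scale_features = scale_features)
  null <- permutation_null(clr, labels, eta = tuning$best_eta,
                           K = tuning$best_K, P = P, seed = seeds[3],
                           positive = positive,
                           scale_features = scale_features)
  report <- pseudo_pvalues(boot, null, alpha = alpha,
                           tail_rule = tail_rule,
                           p_is_fraction = p_is_fraction,
                           taxonomy = aligned$table$taxonomy)
  biplot <- biplot_coordinates(model, report, labels = labels)
  structure(list(clr = clr, labels = labels, tuning = tuning,
                 model = model, boot = boot, null = null,
                 report = report, biplot = biplot,
                 dropped_na = dropped_na, seeds = seeds),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> eta = %g, K = %d; %d/%d OTUs selected at alpha = %g\n",
    x$tuning$best_eta, x$tuning$best_K, sum(x$report$selected),
    nrow(x$report), attr(x$report, "alpha")))
  invisible(x)
}
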