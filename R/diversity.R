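#' Alpha-diversity metrics for one sample
#'
#' `shannon` is the base-2 entropy of the within-sample relative
#' abundances, `-sum(p_j log2 p_j)` over nonzero `p_j` (the QIIME
#' convention; natural log available via `base`); `observed_otus` is
#' the number of taxa with nonzero count.
#'
#' @param counts non-negative integer vector, total > 0.
#' @param metric `"shannon"` or `"observed_otus"`.
#' @param base logarithm base for Shannon (default 2).
#' @return A single number.
#' @examples
#' alpha_metrics(c(5, 5, 5, 5), "shannon")   # 2
#' alpha_metrics(c(10, 0, 0), "observed_otus")  # 1
#' @export
alpha_metrics <- function(counts, metric = c("shannon", "observed_otus"),
                          base = 2) {
  metric <- match.arg(metric)
  if (any(counts < 0) || any(!is_whole(counts))) {
    clrda_error("counts must be non-negative integers",
                "clrda_input_error")
  }
  total <- sum(counts)
  if (total == 0) {
    clrda_error("all-zero count vector has no diversity",
                "clrda_input_error")
  }
  if (metric == "observed_otus") return(sum(counts > 0))
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Rarefy a count vector to a fixed depth
#'
#' Subsampling without replacement (a multivariate hypergeometric
#' draw): exactly `depth` reads are drawn from the pool of reads the
#' sample actually contains, matching the subsampling semantics of
#' standard 16S pipelines.
#'
#' @param counts non-negative integer vector.
#' @param depth number of reads to draw; must not exceed `sum(counts)`.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return Integer vector of the same length summing to `depth`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  if (any(counts < 0) || any(!is_whole(counts))) {
    clrda_error("counts must be non-negative integers",
                "clrda_input_error")
  }
  total <- sum(counts)
  if (!is_whole(depth) || depth < 0) {
    clrda_error("`depth` must be a non-negative integer",
                "clrda_input_error")
  }
  if (depth > total) {
    clrda_error(sprintf("depth %d exceeds sample total %d",
                        depth, total), "clrda_input_error")
  }
  if (depth == 0) {
    return(stats::setNames(integer(length(counts)), names(counts)))
  }
  if (depth == total) {
    return(stats::setNames(as.integer(counts), names(counts)))
  }
  out <- with_seed(seed, {
    pool <- rep.int(seq_along(counts), counts)
    drawn <- pool[sample.int(length(pool), depth)]
    tabulate(drawn, nbins = length(counts))
  })
  names(out) <- names(counts)
  out
}

#' Rarefaction curves over a grid of depths
#'
#' For every sample and depth, the chosen alpha metric is averaged over
#' `iterations` independent rarefactions; the per-point standard
#' deviation quantifies subsampling noise. Deterministic under `seed`.
#'
#' @param table a [count_table].
#' @param depths non-empty increasing vector of depths; each must be
#'   attainable by every sample.
#' @param iterations rarefactions per (sample, depth), default 10.
#' @param metric passed to [alpha_metrics()].
#' @param seed integer seed.
#' @return A `rarefaction_curve`: data.frame (sample_id, depth, mean,
#'   sd) with attributes `metric`, `iterations`, `seed`.
#' @export
rarefaction_curve <- function(table, depths, iterations = 10,
                              metric = "shannon", seed = 1) {
  stopifnot(inherits(table, "count_table"))
  if (length(depths) == 0) {
    clrda_error("`depths` must be non-empty", "clrda_input_error")
  }
  if (!is_whole(iterations) || iterations < 1) {
    clrda_error("`iterations` must be a positive integer",
                "clrda_input_error")
  }
  totals <- rowSums(table$counts)
  for (s in seq_along(totals)) {
    if (any(depths > totals[s])) {
      clrda_error(sprintf(
        "depth %d exceeds total count %d of sample '%s'",
        max(depths), totals[s], rownames(table$counts)[s]),
        "clrda_input_error")
    }
  }
  rows <- vector("list", n_samples(table) * length(depths))
  i <- 0L
  with_seed(seed, {
    for (s in rownames(table$counts)) {
      x <- table$counts[s, ]
      for (d in depths) {
        vals <- vapply(seq_len(iterations), function(it)
          alpha_metrics(rarefy(x, d), metric), numeric(1))
        i <- i + 1L
        rows[[i]] <- data.frame(sample_id = s, depth = d,
                                mean = mean(vals),
                                sd = stats::sd(vals))
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, metric = metric, iterations = iterations, seed = seed,
            class = c("rarefaction_curve", "data.frame"))
}

#' Classical two-sample t-test
#'
#' Pooled-variance two-sample t with `n_a + n_b - 2` degrees of
#' freedom, as used for between-group alpha-diversity comparisons;
#' Welch's unequal-variance form is available via `pooled = FALSE`.
#' Two identical constant groups return `t = 0, p = 1`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance statistic (default `TRUE`).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
group_ttest <- function(values_a, values_b, pooled = TRUE) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) {
    clrda_error("each group needs at least 2 values", "clrda_input_error")
  }
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (ma == mb) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(ma - mb) * Inf, df = df, p = 0))
  }
  t <- (ma - mb) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Bray-Curtis dissimilarity matrix on counts
#'
#' `d(a, b) = 1 - 2 sum_j min(x_aj, x_bj) / (sum x_a + sum x_b)`.
#' Identical samples get 0, samples with disjoint taxa get 1. Used here
#' as the tree-free stand-in distance for community comparisons.
#'
#' @param table a [count_table].
#' @return A `distance_matrix` (samples x samples).
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "count_table"))
  x <- table$counts
  n <- nrow(x)
  totals <- rowSums(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      shared <- sum(pmin(x[a, ], x[b, ]))
      d[a, b] <- d[b, a] <- 1 - 2 * shared / (totals[a] + totals[b])
    }
  }
  distance_matrix(d)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group distances
#' exceed within-group distances. With mid-ranks `r` of the
#' `M = n (n - 1) / 2` pairwise distances,
#' `R = (mean r_between - mean r_within) / (M / 2)`, in \[-1, 1\].
#' The p-value uses the add-one permutation rule,
#' `p = (1 + #\{perm R >= observed\}) / (permutations + 1)`, so it is
#' never exactly zero.
#'
#' @param D a `distance_matrix`.
#' @param labels per-sample group labels (>= 2 groups, each >= 2
#'   samples).
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return List with `R`, `p`, `permutations`, `perm_R` (the permuted
#'   statistics).
#' @export
anosim <- function(D, labels, permutations = 999, seed = 1) {
  if (!is.matrix(D)) clrda_error("`D` must be a matrix",
                                 "clrda_input_error")
  labels <- as.character(labels)
  if (length(labels) != nrow(D)) {
    clrda_error("labels length does not match distance matrix",
                "clrda_input_error")
  }
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    clrda_error("need >= 2 groups with >= 2 samples each",
                "clrda_input_error")
  }
  if (!is_whole(permutations) || permutations < 1) {
    clrda_error("`permutations` must be a positive integer",
                "clrda_input_error")
  }
  lower <- lower.tri(D)
  r <- rank(D[lower])          # mid-ranks for ties
  M <- length(r)
  pair_rows <- row(D)[lower]
  pair_cols <- col(D)[lower]
  stat <- function(lab) {
    within <- lab[pair_rows] == lab[pair_cols]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R <- stat(labels)
  perm_R <- with_seed(seed, {
    vapply(seq_len(permutations), function(i)
      stat(labels[sample.int(length(labels))]), numeric(1))
  })
  p <- (1 + sum(perm_R >= R)) / (permutations + 1)
  list(R = R, p = p, permutations = permutations, perm_R = perm_R)
}

#' Binomial prevalence with a Wald 95% confidence interval
#'
#' `percent = 100 x / n`; the normal-approximation interval
#' `percent +/- 1.96 * 100 * sqrt((x/n)(1 - x/n)/n)` is clipped to
#' \[0, 100\] and everything is reported rounded to one decimal, the
#' precision prevalence tables are printed at.
#'
#' @param x number of positives (0 <= x <= n).
#' @param n cohort size (>= 1).
#' @return A `prevalence_estimate`: list with `x`, `n`, `percent`,
#'   `ci_low`, `ci_high` (percent scale, one decimal).
#' @examples
#' prevalence_ci(36, 51)  # 70.6% of the cohort
#' @export
prevalence_ci <- function(x, n) {
  if (!is_whole(n) || n < 1) clrda_error("`n` must be a positive integer",
                                         "clrda_input_error")
  if (!is_whole(x) || x < 0 || x > n) {
    clrda_error("`x` must be an integer in [0, n]", "clrda_input_error")
  }
  p <- x / n
  half <- 1.96 * 100 * sqrt(p * (1 - p) / n)
  structure(list(x = as.integer(x), n = as.integer(n),
                 percent = round(100 * p, 1),
                 ci_low = round(max(0, 100 * p - half), 1),
                 ci_high = round(min(100, 100 * p + half), 1)),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (95%% CI %.1f-%.1f)\n",
              x$x, x$n, x$percent, x$ci_low, x$ci_high))
  invisible(x)
}
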