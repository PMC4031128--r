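#' Close counts to strictly positive relative abundances
#'
#' Adds a constant pseudocount to every cell, then divides each sample
#' row by its total so rows sum to 1. Read counts only carry relative
#' information (sequencing depth is arbitrary), so all downstream
#' analysis works on these compositions. The centered log-ratio
#' transform is undefined at zero, hence the pseudocount; the default
#' 0.5 is deterministic and preserves within-sample rank order.
#'
#' @param table a [count_table].
#' @param pseudocount non-negative constant added to every count;
#'   0 is only allowed when the table has no zero cells.
#' @return A `composition_matrix`: numeric samples-by-OTU matrix whose
#'   rows sum to 1, all entries strictly positive.
#' @examples
#' ct <- count_table(matrix(c(1L, 1L, 2L), 1,
#'                   dimnames = list("S1", c("a", "b", "c"))))
#' close_composition(ct, pseudocount = 0)  # 0.25 0.25 0.50
#' @export
close_composition <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount < 0) {
    clrda_error("`pseudocount` must be a single non-negative number",
                "clrda_input_error")
  }
  if (pseudocount == 0 && any(table$counts == 0)) {
    clrda_error(paste0(
      "zero counts present with pseudocount 0: the clr transform is ",
      "undefined at zero; use a positive pseudocount"),
      "clrda_input_error")
  }
  x <- table$counts + pseudocount
  v <- x / rowSums(x)
  structure(v, class = c("composition_matrix", class(v)))
}

#' Centered log-ratio transform
#'
#' Maps each composition row into Euclidean coordinates by dividing each
#' component by the geometric mean of the row and taking logs:
#' `clr[i, j] = ln v[i, j] - mean_j(ln v[i, j])`. Full-feature clr rows
#' sum to zero and are invariant to per-sample rescaling of the raw
#' abundances.
#'
#' @param comp a `composition_matrix` (or any strictly positive matrix
#'   with dimnames).
#' @return A `clr_matrix`: real samples-by-OTU matrix, rows summing to 0.
#' @export
clr_transform <- function(comp) {
  if (!is.matrix(comp) || !is.numeric(comp)) {
    clrda_error("`comp` must be a numeric matrix", "clrda_input_error")
  }
  if (any(comp <= 0)) {
    bad <- which(comp <= 0, arr.ind = TRUE)[1, ]
    clrda_error(sprintf(
      "non-positive entry at row %d, column %d: clr requires strictly positive compositions",
      bad[1], bad[2]), "clrda_input_error")
  }
  lg <- log(comp)
  out <- lg - rowMeans(lg)
  structure(out, class = c("clr_matrix", "matrix", "array"),
            filtered = FALSE)
}

#' Keep the most variable OTUs of a clr matrix
#'
#' Retains the `top_n` OTUs with the largest sample variance of clr
#' values (denominator n - 1), the usual pre-selection step before
#' fitting a sparse discriminant model to a wide table. Ties are broken
#' lexicographically by OTU id; `top_n >= p` returns the input.
#' After filtering, rows no longer sum to zero.
#'
#' @param clr a `clr_matrix`.
#' @param top_n number of OTUs to keep (>= 1).
#' @return A `clr_matrix` with at most `top_n` columns, original column
#'   order preserved; attribute `filtered` set to `TRUE` when columns
#'   were dropped.
#' @export
filter_variable_features <- function(clr, top_n = 300) {
  if (!is.matrix(clr)) clrda_error("`clr` must be a matrix",
                                   "clrda_input_error")
  if (!is_whole(top_n) || top_n < 1) {
    clrda_error("`top_n` must be a positive integer", "clrda_input_error")
  }
  if (top_n >= ncol(clr)) return(clr)
  v <- apply(clr, 2L, stats::var)
  ord <- order(-v, colnames(clr))
  keep <- sort(ord[seq_len(top_n)])
  out <- clr[, keep, drop = FALSE]
  structure(out, class = c("clr_matrix", "matrix", "array"),
            filtered = TRUE)
}

#' Write a clr matrix as TSV (samples as rows)
#'
#' @param clr a `clr_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clr_matrix <- function(clr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#SampleID", colnames(clr)), collapse = "\t"), con)
  utils::write.table(format(clr, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
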