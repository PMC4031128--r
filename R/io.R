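#' Construct a validated OTU count table
#'
#' A `count_table` stores a samples-by-OTU matrix of non-negative integer
#' read counts, with optional taxonomy lineage strings per OTU. It is the
#' entry object for every downstream analysis.
#'
#' @param counts numeric matrix, samples as rows, OTUs as columns, with
#'   rownames (sample ids) and colnames (OTU ids). All entries must be
#'   non-negative integers and every sample must have total count > 0.
#' @param taxonomy optional named character vector mapping OTU id to a
#'   lineage string; names must be a subset of the OTU ids.
#' @return An object of class `count_table`: a list with elements
#'   `counts` (integer matrix) and `taxonomy` (named character or `NULL`).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 2,
#'             dimnames = list(c("S1", "S2"), c("O1", "O2", "O3")))
#' ct <- count_table(m)
#' n_samples(ct)
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    clrda_error("`counts` must be a numeric matrix", "clrda_input_error")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    clrda_error("`counts` must carry sample rownames and OTU colnames",
                "clrda_input_error")
  }
  bad <- which(!is_whole(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    clrda_error(sprintf(
      "count for sample '%s', OTU '%s' is not a non-negative integer (%s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])), "clrda_input_error")
  }
  if (anyDuplicated(rownames(counts))) {
    clrda_error(sprintf("duplicate sample id '%s'",
                        rownames(counts)[duplicated(rownames(counts))][1]),
                "clrda_input_error")
  }
  if (anyDuplicated(colnames(counts))) {
    clrda_error(sprintf("duplicate OTU id '%s'",
                        colnames(counts)[duplicated(colnames(counts))][1]),
                "clrda_input_error")
  }
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    clrda_error(sprintf("sample '%s' has total count 0",
                        rownames(counts)[zero][1]), "clrda_input_error")
  }
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) ||
        !all(names(taxonomy) %in% colnames(counts))) {
      clrda_error("taxonomy names must be OTU ids of the table",
                  "clrda_input_error")
    }
    taxonomy <- taxonomy[intersect(colnames(counts), names(taxonomy))]
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "count_table")
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname count_table
#' @export
n_otus <- function(x) ncol(x$counts)

#' @rdname count_table
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.count_table <- function(x) rownames(x$counts)

#' @export
sample_ids.sample_metadata <- function(x) x$data[["SampleID"]]

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d OTUs%s\n",
              n_samples(x), n_otus(x),
              if (is.null(x$taxonomy)) "" else ", taxonomy present"))
  invisible(x)
}

#' Construct validated sample metadata
#'
#' Wraps a data frame of per-sample annotations keyed by a `SampleID`
#' column. Missing values are stored as `NA` (the on-disk token is the
#' literal string `"NA"` or an empty cell).
#'
#' @param data data.frame whose first column is `SampleID` (unique
#'   character ids); remaining columns are categorical/string values.
#' @return An object of class `sample_metadata`.
#' @export
sample_metadata <- function(data) {
  if (!is.data.frame(data) || names(data)[1] != "SampleID") {
    clrda_error("metadata must be a data.frame with first column 'SampleID'",
                "clrda_input_error")
  }
  data[] <- lapply(data, as.character)
  if (anyDuplicated(data$SampleID)) {
    clrda_error(sprintf("duplicate sample id '%s' in metadata",
                        data$SampleID[duplicated(data$SampleID)][1]),
                "clrda_input_error")
  }
  rownames(data) <- NULL
  structure(list(data = data), class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("<sample_metadata> %d samples, columns: %s\n",
              nrow(x$data), paste(names(x$data)[-1], collapse = ", ")))
  invisible(x)
}

#' Extract one metadata column as a named character vector
#'
#' @param meta a `sample_metadata`.
#' @param column column name.
#' @return Named character vector (names = sample ids), `NA` for missing.
#' @export
metadata_column <- function(meta, column) {
  if (!column %in% names(meta$data)) {
    clrda_error(sprintf("metadata column '%s' not found (have: %s)",
                        column,
                        paste(names(meta$data)[-1], collapse = ", ")),
                "clrda_input_error")
  }
  stats::setNames(meta$data[[column]], meta$data$SampleID)
}

#' Read a QIIME classic tab-delimited OTU table
#'
#' Parses the "classic" dialect: a header line starting with `#OTU ID`,
#' OTUs as rows, samples as columns, and an optional final `taxonomy`
#' column (case-insensitive). Lines before the header that start with `#`
#' (e.g. "# Constructed from biom file") are ignored. The returned table
#' is transposed to the samples-by-OTU orientation used internally.
#'
#' @param path file path.
#' @param dialect table dialect; only `"qiime_classic_tsv"` is supported.
#' @return A [count_table].
#' @export
read_otu_table <- function(path, dialect = "qiime_classic_tsv") {
  dialect <- match.arg(dialect, "qiime_classic_tsv")
  if (!file.exists(path)) {
    clrda_error(sprintf("file not found: %s", path), "clrda_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr_i <- which(startsWith(lines, "#OTU ID"))[1]
  if (is.na(hdr_i)) {
    clrda_error(sprintf("%s: malformed header (no line starting '#OTU ID')",
                        path), "clrda_input_error")
  }
  header <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_i)]
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    clrda_error(sprintf("%s: row %d has %d fields, expected %d",
                        path, which(nf != length(header))[1],
                        nf[nf != length(header)][1], length(header)),
                "clrda_input_error")
  }
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  samp_cols <- seq(2L, length(header) - as.integer(has_tax))
  if (length(samp_cols) < 1) {
    clrda_error(sprintf("%s: no sample columns in header", path),
                "clrda_input_error")
  }
  otu_ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(otu_ids)) {
    clrda_error(sprintf("%s: duplicate OTU id '%s'", path,
                        otu_ids[duplicated(otu_ids)][1]),
                "clrda_input_error")
  }
  raw <- vapply(fields, function(f) f[samp_cols],
                character(length(samp_cols)))
  raw <- matrix(raw, nrow = length(samp_cols))  # samples x OTUs
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) {
    bad <- which(is.na(matrix(num, nrow = nrow(raw))), arr.ind = TRUE)[1, ]
    clrda_error(sprintf(
      "%s: non-numeric count '%s' at OTU '%s', sample '%s'",
      path, raw[bad[1], bad[2]], otu_ids[bad[2]],
      header[samp_cols][bad[1]]), "clrda_input_error")
  }
  counts <- matrix(num, nrow = length(samp_cols),
                   dimnames = list(header[samp_cols], otu_ids))
  taxonomy <- NULL
  if (has_tax) {
    taxonomy <- stats::setNames(
      vapply(fields, function(f) f[[length(header)]], ""), otu_ids)
  }
  count_table(counts, taxonomy)
}

#' Write a count table in QIIME classic dialect
#'
#' @param table a [count_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  m <- t(table$counts)  # OTUs as rows
  header <- paste(c("#OTU ID", rownames(table$counts),
                    if (!is.null(table$taxonomy)) "taxonomy"),
                  collapse = "\t")
  rows <- apply(cbind(rownames(m), m), 1L, paste, collapse = "\t")
  if (!is.null(table$taxonomy)) {
    tax <- table$taxonomy[rownames(m)]
    tax[is.na(tax)] <- ""
    rows <- paste(rows, tax, sep = "\t")
  }
  writeLines(c(header, unname(rows)), path)
  invisible(path)
}

#' Read a QIIME mapping (metadata) file
#'
#' Tab-delimited, first header field `#SampleID`. File order is
#' preserved; empty cells and the literal token `"NA"` become `NA`.
#'
#' @param path file path.
#' @return A [sample_metadata].
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) {
    clrda_error(sprintf("file not found: %s", path), "clrda_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2 || !startsWith(lines[1], "#SampleID")) {
    clrda_error(sprintf("%s: mapping header must start with '#SampleID'",
                        path), "clrda_input_error")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  header[1] <- "SampleID"
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty cells are dropped by strsplit; pad, but reject short+long
  if (any(nf > length(header))) {
    clrda_error(sprintf("%s: row %d has %d fields, expected %d (ragged)",
                        path, which(nf > length(header))[1],
                        max(nf), length(header)), "clrda_input_error")
  }
  rows <- lapply(fields, function(f) {
    f <- c(f, rep("", length(header) - length(f)))
    f[f == "" | f == "NA"] <- NA_character_
    f
  })
  data <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(data) <- header
  if (anyNA(data$SampleID)) {
    clrda_error(sprintf("%s: missing sample id", path), "clrda_input_error")
  }
  sample_metadata(data)
}

#' Write a mapping file
#'
#' @param meta a [sample_metadata].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(meta, path) {
  stopifnot(inherits(meta, "sample_metadata"))
  d <- meta$data
  d[is.na(d)] <- "NA"
  header <- paste(c("#SampleID", names(d)[-1]), collapse = "\t")
  rows <- apply(d, 1L, paste, collapse = "\t")
  writeLines(c(header, unname(rows)), path)
  invisible(path)
}

#' Restrict a count table and metadata to their shared samples
#'
#' Both objects are subset to the intersection of their sample ids, in
#' the OTU table's order (the table is the sample-order authority so
#' downstream fold assignment is deterministic). The numbers of dropped
#' ids are attached as attribute `dropped` = c(table = ..., meta = ...).
#'
#' @param table a [count_table].
#' @param meta a [sample_metadata].
#' @return List with elements `table` and `meta`, aligned; attribute
#'   `dropped` records how many ids each side lost.
#' @export
align_samples <- function(table, meta) {
  common <- intersect(sample_ids(table), sample_ids(meta))
  if (length(common) == 0) {
    clrda_error("no samples shared between OTU table and metadata",
                "clrda_input_error")
  }
  keep <- sample_ids(table)[sample_ids(table) %in% common]
  out_table <- count_table(table$counts[keep, , drop = FALSE],
                           table$taxonomy)
  out_meta <- sample_metadata(
    meta$data[match(keep, meta$data$SampleID), , drop = FALSE])
  structure(list(table = out_table, meta = out_meta),
            dropped = c(table = n_samples(table) - length(keep),
                        meta = nrow(meta$data) - length(keep)))
}

#' Read / write a square distance matrix TSV
#'
#' Square tab-delimited layout with identical header and row ids, so a
#' distance matrix produced elsewhere (e.g. UniFrac) can be fed to
#' [anosim()].
#'
#' @param path file path.
#' @return For the reader, a `distance_matrix` (symmetric numeric matrix
#'   with zero diagonal and matching dimnames).
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) {
    clrda_error(sprintf("file not found: %s", path), "clrda_input_error")
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(d)
  if (!identical(rownames(m), colnames(m))) {
    clrda_error(sprintf("%s: row and column ids differ", path),
                "clrda_input_error")
  }
  distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param D a `distance_matrix`.
#' @export
write_distance_matrix <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(D)), collapse = "\t"), con)
  utils::write.table(D, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Validate a symmetric distance matrix
#'
#' @param m symmetric non-negative numeric matrix with zero diagonal and
#'   sample ids as dimnames.
#' @return The matrix with class `distance_matrix`.
#' @export
distance_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    clrda_error("distance matrix must be square", "clrda_input_error")
  }
  if (max(abs(m - t(m))) > 1e-12) {
    clrda_error("distance matrix not symmetric within 1e-12",
                "clrda_input_error")
  }
  if (any(diag(m) != 0)) {
    clrda_error("distance matrix diagonal must be exactly 0",
                "clrda_input_error")
  }
  if (any(m < 0)) {
    clrda_error("distances must be non-negative", "clrda_input_error")
  }
  class(m) <- c("distance_matrix", class(m))
  m
}
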