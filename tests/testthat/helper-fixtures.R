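# In-code fixtures; nothing is read from disk except what a test writes.

toy_count_table <- function() {
  m <- matrix(c(5L, 0L, 3L,
                2L, 1L, 4L), nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("O1", "O2", "O3")))
  count_table(m, taxonomy = c(
    O1 = "k__Bacteria; p__Firmicutes",
    O2 = "k__Bacteria; p__Bacteroidetes",
    O3 = "k__Bacteria; p__Proteobacteria"))
}

toy_metadata <- function() {
  sample_metadata(data.frame(
    SampleID = c("S1", "S2", "S3"),
    Helminth = c("Pos", "Neg", "Pos"),
    stringsAsFactors = FALSE))
}

# The hand-derived 4-sample instance: X is column-centered already and
# feature 1 perfectly orders the classes.
toy_pls_instance <- function() {
  X <- matrix(c(2, 0, 1,
                1, 1, -1,
                -1, -1, 1,
                -2, 0, -1), nrow = 4, byrow = TRUE,
              dimnames = list(sprintf("s%d", 1:4), c("f1", "f2", "f3")))
  list(X = X, labels = c("Pos", "Pos", "Neg", "Neg"))
}

write_classic_table <- function(path,
                                lines = c(
    "#OTU ID\tS1\tS2\ttaxonomy",
    "O1\t5\t2\tk__Bacteria; p__Firmicutes",
    "O2\t0\t1\tk__Bacteria; p__Bacteroidetes",
    "O3\t3\t4\tk__Bacteria; p__Proteobacteria")) {
  writeLines(lines, path)
  path
}
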