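#' Generate a two-class synthetic microbiome cohort with known truth
#'
#' Emulates a case-control 16S cohort on the scale the method operates
#' at. Per-OTU baseline log-abundances `mu_j ~ Normal(0, 2)` give the
#' long-tailed dominance structure of real stool communities (a few
#' abundant taxa, many rare ones). For sample `i` of class
#' `c_i in {0, 1}`, log-abundance is
#' `lambda_ij = mu_j + delta_j c_i + eps_ij`, `eps ~ Normal(0, sigma^2)`,
#' where `delta_j = +/- effect` (balanced signs) on `n_disc` randomly
#' chosen discriminative OTUs and 0 elsewhere, so effects are planted
#' directly on the (approximate) clr scale the selection method sees.
#' Counts are multinomial given a lognormal library size with mean
#' `depth_mean` and coefficient of variation `depth_cv`. Class-1
#' samples additionally receive `richness_bonus` rare OTUs (count 2
#' each, drawn from a dedicated bonus pool of `2 * richness_bonus`
#' OTUs), reproducing a class-linked richness increase.
#'
#' Defaults mirror a 51-subject cohort with 36 infected (positive) and
#' 15 uninfected samples and a mean library size of ~19,000 reads with
#' SD/mean of about one third; tests use smaller depths for speed.
#'
#' @param n_pos,n_neg samples per class (defaults 36 / 15).
#' @param p number of body OTUs (default 200).
#' @param n_disc number of discriminative OTUs (default 10,
#'   `n_disc <= p`).
#' @param effect absolute clr-scale effect size (default 1.5).
#' @param sigma per-sample log-abundance noise SD (default 1).
#' @param depth_mean mean library size (default 19000).
#' @param depth_cv coefficient of variation of library size
#'   (default 0.34).
#' @param richness_bonus rare OTUs added to each class-1 sample
#'   (default 20; 0 disables).
#' @param seed integer seed; the whole cohort is a deterministic
#'   function of it.
#' @param taxonomy attach synthetic lineage strings (default `TRUE`).
#' @return List with `table` ([count_table]), `meta`
#'   ([sample_metadata] with columns Helminth/Trichuris/Ascaris/
#'   Hookworm), and `truth` (a `synthetic_truth`: named effect vector
#'   over discriminative OTUs, per-sample classes, generator
#'   parameters, seed).
#' @export
generate_cohort <- function(n_pos = 36, n_neg = 15, p = 200,
                            n_disc = 10, effect = 1.5, sigma = 1,
                            depth_mean = 19000, depth_cv = 0.34,
                            richness_bonus = 20, seed = 1,
                            taxonomy = TRUE) {
  if (!is_whole(n_pos) || !is_whole(n_neg) || n_pos < 2 || n_neg < 2) {
    clrda_error("need at least 2 samples per class", "clrda_input_error")
  }
  if (!is_whole(p) || p < 2 || !is_whole(n_disc) || n_disc < 0 ||
      n_disc > p) {
    clrda_error("need 0 <= n_disc <= p and p >= 2", "clrda_input_error")
  }
  if (sigma <= 0 || depth_mean <= 0 || depth_cv < 0 || effect < 0 ||
      !is_whole(richness_bonus) || richness_bonus < 0) {
    clrda_error("invalid generator parameter", "clrda_input_error")
  }
  n <- n_pos + n_neg
  classes <- c(rep(1L, n_pos), rep(0L, n_neg))
  ids <- sprintf("S%03d", seq_len(n))
  otu_ids <- sprintf("OTU_%04d", seq_len(p))
  bonus_ids <- if (richness_bonus > 0) {
    sprintf("OTUB_%03d", seq_len(2L * richness_bonus))
  } else character(0)

  out <- with_seed(seed, {
    mu <- stats::rnorm(p, 0, 2)
    delta <- numeric(p)
    # plant effects on the more abundant half of the baseline so every
    # discriminative OTU is actually observable at realistic depths and
    # truth-recovery (and the planted-sign invariant) is well-posed
    eligible <- which(mu >= stats::median(mu))
    if (length(eligible) < n_disc) eligible <- seq_len(p)
    disc <- sort(sample(eligible, n_disc))
    if (n_disc > 0) {
      delta[disc] <- rep_len(c(1, -1), n_disc) * effect
    }
    sdlog <- sqrt(log(1 + depth_cv^2))
    meanlog <- log(depth_mean) - sdlog^2 / 2
    depths <- pmax(1L, as.integer(round(
      stats::rlnorm(n, meanlog, sdlog))))

    counts <- matrix(0L, n, p + length(bonus_ids),
                     dimnames = list(ids, c(otu_ids, bonus_ids)))
    for (i in seq_len(n)) {
      lambda <- mu + delta * classes[i] + stats::rnorm(p, 0, sigma)
      prob <- exp(lambda - max(lambda))
      counts[i, seq_len(p)] <- as.integer(
        stats::rmultinom(1, depths[i], prob / sum(prob)))
      if (richness_bonus > 0 && classes[i] == 1L) {
        pick <- sample.int(length(bonus_ids), richness_bonus)
        counts[i, p + pick] <- 2L
      }
    }
    # sub-infection columns among positives, at field-realistic rates
    status <- function(rate) {
      s <- rep("Neg", n)
      s[classes == 1L] <- ifelse(stats::runif(n_pos) < rate, "Pos", "Neg")
      s
    }
    list(counts = counts, disc = disc, delta = delta,
         trich = status(28 / 36), asc = status(21 / 36),
         hook = status(5 / 36))
  })

  tax <- NULL
  if (taxonomy) {
    phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
               "Actinobacteria", "Tenericutes")
    all_ids <- colnames(out$counts)
    tax <- stats::setNames(sprintf(
      "k__Bacteria; p__%s; g__Genus%03d",
      phyla[(seq_along(all_ids) - 1L) %% length(phyla) + 1L],
      seq_along(all_ids)), all_ids)
  }
  table <- count_table(out$counts, tax)
  meta <- sample_metadata(data.frame(
    SampleID = ids,
    Helminth = ifelse(classes == 1L, "Pos", "Neg"),
    Trichuris = out$trich, Ascaris = out$asc, Hookworm = out$hook,
    stringsAsFactors = FALSE))
  params <- list(n_pos = n_pos, n_neg = n_neg, p = p, n_disc = n_disc,
                 effect = effect, sigma = sigma,
                 depth_mean = depth_mean, depth_cv = depth_cv,
                 richness_bonus = richness_bonus, seed = seed)
  truth <- structure(list(
    discriminative = stats::setNames(out$delta[out$disc],
                                     otu_ids[out$disc]),
    classes = stats::setNames(classes, ids),
    params = params, seed = seed),
    class = "synthetic_truth")
  list(table = table, meta = meta, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d discriminative OTUs, effect %g, %d+/%d- samples\n",
    length(x$discriminative), x$params$effect,
    sum(x$classes == 1), sum(x$classes == 0)))
  invisible(x)
}

#' Sensitivity and false-discovery proportion against planted truth
#'
#' `sensitivity = |selected intersect truth| / |truth|`;
#' `FDP = |selected \ truth| / max(1, |selected|)` (so an empty
#' selection has FDP 0).
#'
#' @param report a `significance_report` (or character vector of
#'   selected OTU ids).
#' @param truth a `synthetic_truth`.
#' @return List with `sensitivity` and `fdp`.
#' @export
truth_recovery_metrics <- function(report, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  selected <- if (is.character(report)) report else
    report$otu_id[report$selected]
  disc <- names(truth$discriminative)
  sensitivity <- if (length(disc) == 0) NA_real_ else
    length(intersect(selected, disc)) / length(disc)
  fdp <- length(setdiff(selected, disc)) / max(1L, length(selected))
  list(sensitivity = sensitivity, fdp = fdp)
}

#' Write a synthetic truth record as TSV
#'
#' Two sections in one file: a parameter echo (lines starting
#' `#param`) and the per-OTU planted effects.
#'
#' @param truth a `synthetic_truth`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(truth$params)) {
    writeLines(sprintf("#param\t%s\t%s", nm,
                       format(truth$params[[nm]], digits = 15)), con)
  }
  writeLines("otu_id\teffect", con)
  writeLines(sprintf("%s\t%s", names(truth$discriminative),
                     format(truth$discriminative, digits = 15,
                            trim = TRUE)), con)
  invisible(path)
}
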