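test_that("alpha metrics match closed forms", {
  expect_equal(alpha_metrics(c(5, 5, 5, 5), "shannon"), 2)
  expect_equal(alpha_metrics(c(10, 0, 0), "shannon"), 0)
  expect_equal(alpha_metrics(c(10, 0, 0), "observed_otus"), 1)
  expect_equal(alpha_metrics(c(75, 25), "shannon"),
               -0.75 * log2(0.75) - 0.25 * log2(0.25))
  # natural-log flag
  expect_equal(alpha_metrics(c(1, 1), "shannon", base = exp(1)), log(2))
  expect_error(alpha_metrics(c(0, 0)), "all-zero")

  # uniform composition maximizes Shannon at fixed richness
  set.seed(2)
  for (i in 1:10) {
    x <- rmultinom(1, 500, prob = runif(6))[, 1]
    if (any(x == 0)) next
    expect_lte(alpha_metrics(x, "shannon"),
               alpha_metrics(rep(100, 6), "shannon") + 1e-12)
  }
})

test_that("rarefy is an exact hypergeometric subsample", {
  x <- c(a = 6L, b = 3L, c = 1L)
  expect_identical(rarefy(x, 10), x)          # full depth: identity
  expect_identical(unname(rarefy(x, 0)), rep(0L, 3))
  expect_error(rarefy(x, 11), "exceeds")

  draws <- rarefy(x, 5, seed = 1)
  expect_equal(sum(draws), 5)
  expect_true(all(draws <= x))
  expect_identical(rarefy(x, 5, seed = 9), rarefy(x, 5, seed = 9))

  # Monte-Carlo mean richness vs the exact hypergeometric oracle
  exact <- expected_richness_hypergeom(x, 5)
  iters <- 4000
  obs <- with(list(), {
    set.seed(123)
    vapply(seq_len(iters), function(i)
      sum(rarefy(x, 5) > 0), numeric(1))
  })
  se <- stats::sd(obs) / sqrt(iters)
  expect_lt(abs(mean(obs) - exact), 3 * se)
})

test_that("rarefaction curves are deterministic and sensible", {
  ct <- toy_count_table()  # totals: S1 = 8, S2 = 7
  crv <- rarefaction_curve(ct, depths = c(5, 7), iterations = 1,
                           metric = "shannon", seed = 1)
  # S2's depth-7 point is the exhaustive draw, so it equals the plain
  # full-sample metric
  expect_equal(crv$mean[crv$sample_id == "S2" & crv$depth == 7],
               alpha_metrics(ct$counts["S2", ], "shannon"))

  crv2 <- rarefaction_curve(ct, depths = c(5, 7), iterations = 1,
                            metric = "shannon", seed = 1)
  expect_identical(crv, crv2)

  expect_error(rarefaction_curve(ct, depths = 9, seed = 1), "S1")
  expect_error(rarefaction_curve(ct, depths = integer(0)), "non-empty")

  # mean observed richness is non-decreasing in depth for every sample
  set.seed(8)
  m <- matrix(rpois(40, 20) + 1L, 4, 10,
              dimnames = list(sprintf("s%d", 1:4), sprintf("o%d", 1:10)))
  big <- count_table(m)
  depths <- round(seq(10, min(rowSums(m)), length.out = 4))
  crv3 <- rarefaction_curve(big, depths, iterations = 30,
                            metric = "observed_otus", seed = 4)
  for (s in unique(crv3$sample_id)) {
    means <- crv3$mean[crv3$sample_id == s][order(depths)]
    expect_true(all(diff(means) >= -0.5))  # within Monte-Carlo slack
  }
})

test_that("pooled t-test matches stats::t.test and its edge cases", {
  expect_equal(group_ttest(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  expect_equal(group_ttest(c(2, 2), c(2, 2)), list(t = 0, df = 2, p = 1))

  set.seed(14)
  a <- rnorm(8); b <- rnorm(11, mean = 1)
  ours <- group_ttest(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # Welch flag
  ours_w <- group_ttest(a, b, pooled = FALSE)
  ref_w <- stats::t.test(a, b)
  expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-12)

  # antisymmetry
  flip <- group_ttest(b, a)
  expect_equal(flip$t, -ours$t)
  expect_equal(flip$p, ours$p)

  jit <- group_ttest(c(0, 0, 0, 0) + rnorm(4, sd = 1e-6),
                     c(1, 1, 1, 1) + rnorm(4, sd = 1e-6))
  expect_lt(jit$p, 0.01)
  expect_error(group_ttest(1, c(1, 2)), "at least 2")
})

test_that("Bray-Curtis matches the formula and vegan", {
  m <- matrix(c(2L, 2L,
                2L, 0L), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("x", "y")))
  D <- bray_curtis(count_table(m))
  expect_equal(D["A", "B"], 1 / 3)
  expect_equal(diag(D), c(A = 0, B = 0))

  ident <- matrix(c(3L, 1L, 3L, 1L), 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(bray_curtis(count_table(ident))["A", "B"], 0)

  disj <- matrix(c(3L, 0L, 0L, 5L), 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(bray_curtis(count_table(disj))["A", "B"], 1)

  skip_if_not_installed("vegan")
  set.seed(31)
  counts <- matrix(rpois(60, 12) + 1L, 6, 10,
                   dimnames = list(sprintf("s%d", 1:6),
                                   sprintf("o%d", 1:10)))
  ours <- bray_curtis(count_table(counts))
  ref <- as.matrix(vegan::vegdist(counts, method = "bray"))
  expect_equal(unclass(ours), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(ours >= 0 & ours <= 1))
})

test_that("ANOSIM separates what should separate and matches vegan", {
  # two tight, far-apart clusters: all between > all within -> R = 1
  set.seed(41)
  pts <- rbind(matrix(rnorm(8, 0, 0.05), 4),
               matrix(rnorm(8, 10, 0.05), 4))
  rownames(pts) <- sprintf("s%d", 1:8)
  d <- as.matrix(dist(pts))
  labels <- rep(c("A", "B"), each = 4)
  res <- anosim(distance_matrix(d), labels, permutations = 999, seed = 2)
  expect_equal(res$R, 1)
  ties <- sum(res$perm_R >= 1)
  expect_lte(res$p, (1 + ties) / 1000)

  # permutation-distribution mean near 0 under random labels
  expect_lt(abs(mean(res$perm_R)), 3 * stats::sd(res$perm_R) /
              sqrt(length(res$perm_R)))
  expect_true(all(res$perm_R >= -1 & res$perm_R <= 1))

  skip_if_not_installed("vegan")
  set.seed(55)
  pts2 <- matrix(rnorm(24), 12, 2,
                 dimnames = list(sprintf("s%02d", 1:12), NULL))
  labels2 <- rep(c("A", "B", "C"), each = 4)
  d2 <- as.matrix(dist(pts2))
  ours <- anosim(distance_matrix(d2), labels2, permutations = 99,
                 seed = 1)
  ref <- vegan::anosim(stats::as.dist(d2), grouping = labels2,
                       permutations = 9)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)

  expect_error(anosim(distance_matrix(d2), rep("A", 12)), ">= 2 groups")
})

test_that("prevalence estimates reproduce the Wald-consistent cohort rows", {
  rows <- list(list(30, 51, 58.8, 45.3, 72.3),
               list(21, 51, 41.2, 27.7, 54.7),
               list(24, 51, 47.1, 33.4, 60.8),
               list(27, 51, 52.9, 39.2, 66.6),
               list(11, 51, 21.6, 10.3, 32.9))
  for (r in rows) {
    est <- prevalence_ci(r[[1]], r[[2]])
    expect_equal(est$percent, r[[3]])
    expect_equal(est$ci_low, r[[4]])
    expect_equal(est$ci_high, r[[5]])
  }
  degenerate <- prevalence_ci(0, 51)
  expect_equal(degenerate$percent, 0)
  expect_equal(degenerate$ci_low, 0)
  expect_equal(degenerate$ci_high, 0)
  full <- prevalence_ci(51, 51)
  expect_equal(full$ci_high, 100)
  expect_error(prevalence_ci(5, 4), "in \\[0, n\\]")
  # ordering invariant
  est <- prevalence_ci(17, 51)
  expect_true(est$ci_low <= est$percent && est$percent <= est$ci_high)
})
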