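test_that("genus-table filters apply depth, prevalence and abundance rules", {
  counts <- matrix(0L, nrow = 5, ncol = 4,
                   dimnames = list(sprintf("s%d", 1:5),
                                   c("gA", "gB", "gC", "gD")))
  counts[, "gA"] <- c(9000L, 40000L, 40000L, 40000L, 40000L)
  counts[, "gB"] <- c(999L, 0L, 5L, 7L, 0L)          # 2 samples after s1 drop
  counts[, "gC"] <- c(0L, 10L, 2L, 3L, 2L)           # ~0.011% mean abundance
  counts[, "gD"] <- c(0L, 3L, 3L, 3L, 2L)            # ~0.009% mean abundance
  f <- filter_genus_table(counts)
  # sample s1 has 9999 reads in total: dropped first
  expect_false("s1" %in% rownames(f))
  expect_false("gB" %in% colnames(f))                # detected in two samples
  expect_false("gD" %in% colnames(f))                # below 0.01% mean
  expect_true("gC" %in% colnames(f))                 # above 0.01% mean
  log <- attr(f, "filter_log")
  expect_setequal(log$item, c("s1", "gB", "gD"))
  expect_error(filter_genus_table(matrix(1L, 2, 2)), "empty|filter")
})

test_that("exact Wilcoxon matches full enumeration for all n1, n2 <= 6", {
  enum_p <- function(x, y) {
    pooled <- c(x, y); n1 <- length(x)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    combos <- combn(length(pooled), n1)
    w_all <- apply(combos, 2, function(idx) sum(r[idx]))
    min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  }
  withr::with_seed(31, {
    for (n1 in 1:6) for (n2 in 1:6) {
      x <- rnorm(n1); y <- rnorm(n2)
      expect_equal(wilcoxon_rank_sum(x, y)$p, enum_p(x, y),
                   tolerance = 1e-12)
    }
  })
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 4, 6), c(2, 4, 6))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("normal-approximation Wilcoxon tracks the exact test", {
  withr::with_seed(33, {
    diffs <- replicate(50, {
      x <- rnorm(10); y <- rnorm(10, 0.5)
      exact <- wilcox.test(x, y, exact = TRUE)$p.value
      approx <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
      abs(exact - approx)
    })
  })
  expect_lt(median(diffs), 0.005)
})

test_that("BH q values match the hand-computed step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  withr::with_seed(35, p <- runif(40)^2)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))      # monotone in p order
})

test_that("Spearman correlation handles ties via the permutation null", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "n >= 3")
  # tie-laden n = 7 against a brute-force permutation oracle
  x <- c(1, 2, 2, 3, 4, 4, 5); y <- c(2, 1, 3, 3, 5, 4, 6)
  res <- spearman_cor(x, y)
  perms <- strainspec:::all_permutations(7)
  rx <- rank(x); ry <- rank(y)
  rho_all <- apply(perms, 1, function(i) suppressWarnings(cor(rx, ry[i])))
  p_oracle <- mean(abs(rho_all) >= abs(cor(rx, ry)) - 1e-12)
  expect_equal(res$p, p_oracle)
})

test_that("Bray-Curtis follows the formula and stays in [0, 1]", {
  x <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  expect_equal(as.numeric(bray_curtis(x)), 0.5)
  same <- rbind(a = c(2, 3), b = c(2, 3))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disj <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  withr::with_seed(37, m <- matrix(rpois(60, 5), 6, 10))
  d <- as.numeric(bray_curtis(m))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 2))), "negative")
  expect_warning(dz <- bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 1))),
                 "all-zero")
  expect_equal(as.matrix(dz)[1, 2], 0)
})

test_that("within-group distances separate tight and diffuse groups", {
  withr::with_seed(39, {
    tight <- matrix(rnorm(20 * 3, 0, 0.05), 20, 3)
    diffuse <- matrix(rnorm(20 * 3, 0, 1), 20, 3)
  })
  d <- stats::dist(rbind(tight, diffuse))
  groups <- rep(c("tight", "diffuse"), each = 20)
  res <- within_group_distance_test(d, groups, reference = "tight")
  expect_lt(res[group == "diffuse", p], 1e-6)
  expect_gt(res[group == "diffuse", median_distance],
            res[group == "tight", median_distance])
  expect_error(within_group_distance_test(d, c("x", rep("y", 39)), "y"),
               "singleton")
})

test_that("PCoA reconstructs Euclidean configurations", {
  # three collinear points: one positive eigenvalue carries all variance
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  p3 <- pcoa_ordination(d3)
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-10]
  expect_length(pos, 1)
  expect_equal(p3$proportion_explained[1], 1)
  # Euclidean distances are reproduced by the embedding
  withr::with_seed(41, x <- matrix(rnorm(8 * 4), 8, 4))
  d <- stats::dist(x)
  p <- pcoa_ordination(d)
  expect_lt(max(abs(stats::dist(p$coordinates) - d)), 1e-9)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # identical samples embed at a single point
  dd <- matrix(0, 4, 4)
  expect_true(all(abs(pcoa_ordination(dd)$coordinates) < 1e-12))
})

test_that("PERMANOVA separates clusters and respects its permutation floor", {
  withr::with_seed(43, {
    a <- matrix(rnorm(10 * 4, 0, 0.1), 10, 4)
    b <- matrix(rnorm(10 * 4, 5, 0.1), 10, 4)
  })
  d <- stats::dist(rbind(a, b))
  res <- permanova(d, rep(c("g1", "g2"), each = 10),
                   n_permutations = 999, seed = 3)
  expect_equal(res$p, 1 / 1000)
  expect_true(res$R2 > 0 && res$R2 <= 1)
  expect_error(permanova(d, rep(c("g1", "g2"), each = 10),
                         n_permutations = 0), "permutations")
  expect_error(permanova(d, rep("g1", 20)), "groups")
  # seeded: reproducible p
  res2 <- permanova(d, rep(c("g1", "g2"), each = 10),
                    n_permutations = 999, seed = 3)
  expect_identical(res, res2)
})

test_that("Shannon diversity matches closed-form values", {
  expect_equal(shannon_index(c(1, 1, 1, 1)), 2)
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("CLR Monte-Carlo flags planted effects and not the null", {
  # all-equal compositions: nothing to flag
  eq <- matrix(100L, nrow = 8, ncol = 6,
               dimnames = list(sprintf("s%d", 1:8), sprintf("g%d", 1:6)))
  res_eq <- clr_mc_differential_abundance(eq, rep(c("a", "b"), each = 4),
                                          reference = "a", seed = 2)
  expect_true(all(res_eq$p > 0.5))
  # a planted 3-fold genus is flagged
  g <- simulate_genus_table(planted_effects = c(g5 = 3), seed = 77)
  res <- clr_mc_differential_abundance(g$counts, g$metadata$group,
                                       reference = "healthy", seed = 3)
  expect_lt(res[feature == "g5", p], 0.05)
  expect_gt(res[feature == "g5", log2fc], 0)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(clr_mc_differential_abundance(
    rbind(eq, s9 = 0L), c(rep(c("a", "b"), each = 4), "b"),
    reference = "a"), "all-zero")
})

test_that("planted genus effects are detected in most seeded tables", {
  hits <- vapply(1:60, function(s) {
    g <- simulate_genus_table(planted_effects = c(g5 = 3), seed = 1000 + s)
    res <- clr_mc_differential_abundance(g$counts, g$metadata$group,
                                         reference = "healthy",
                                         seed = 1000 + s)
    res[feature == "g5", p] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ortholog DA report is antisymmetric and flags planted signal", {
  withr::with_seed(45, {
    og <- cbind(OGa = c(rgamma(10, 40), rgamma(8, 10)),
                OGb = rgamma(18, 20))
    rownames(og) <- sprintf("s%d", 1:18)
  })
  groups <- rep(c("healthy", "case"), c(10, 8))
  rep1 <- ortholog_da_report(og, groups, reference = "healthy")
  expect_lt(rep1$results[og_id == "OGa", p], 0.01)
  expect_true(rep1$results[og_id == "OGa", significant])
  # swapping group labels negates the fold changes
  rep2 <- ortholog_da_report(og, ifelse(groups == "healthy", "case",
                                        "healthy"), reference = "healthy")
  expect_equal(rep1$results$log2fc, -rep2$results$log2fc)
  expect_equal(rep1$results$p, rep2$results$p)
  # requested orthologs missing from the table are listed untested
  rep3 <- ortholog_da_report(og, groups, reference = "healthy",
                             og_subset = c("OGa", "OGmissing"))
  expect_equal(rep3$untested, "OGmissing")
  # identical groups: nothing beyond the nominal rate
  withr::with_seed(46, null_og <- matrix(rgamma(18 * 20, 10), 18, 20,
                                         dimnames = list(NULL,
                                                         sprintf("o%d", 1:20))))
  repn <- ortholog_da_report(null_og, groups, reference = "healthy")
  expect_lte(sum(repn$results$significant), 3)
})

test_that("alternation ratio scans entry triples", {
  expect_equal(alternation_ratio(c("A", "B", "C", "A", "B", "C"))$ratio, 1)
  expect_equal(alternation_ratio(c("A", "B", "A", "B"))$ratio, 0)
  expect_equal(alternation_ratio(c("A", "B", "C"))$ratio, 1)
  expect_error(alternation_ratio(c("A", "B")), "at least 3")
  expect_error(alternation_ratio(c("A", "A", "B")), "duplicate")
  # property: ratio always in [0, 1] for valid sequences
  withr::with_seed(47, {
    for (i in 1:200) {
      n <- sample(3:40, 1)
      seq <- character(n); seq[1] <- sample(c("A", "B", "C"), 1)
      for (j in 2:n)
        seq[j] <- sample(setdiff(c("A", "B", "C"), seq[j - 1]), 1)
      r <- alternation_ratio(seq)$ratio
      expect_true(r >= 0 && r <= 1)
    }
  })
})
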