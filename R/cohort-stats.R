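#' Filter a genus-level count table
#'
#' In order: (1) samples with fewer than `min_sample_reads` total reads are
#' removed; (2) genera detected in two or fewer of the remaining samples are
#' removed; (3) genera with mean relative abundance below
#' `min_mean_rel_abund` are removed.  Every removal is logged.
#'
#' @param counts samples x genera matrix of counts.
#' @param min_sample_reads minimum per-sample total (default 10,000).
#' @param min_prevalence minimum number of samples a genus must appear in
#'   (default 3, i.e. genera in only one or two samples are dropped).
#' @param min_mean_rel_abund minimum mean relative abundance
#'   (default 1e-4, i.e. 0.01%).
#' @return filtered matrix with attribute `filter_log` (data.table of
#'   removals: step, item, reason).
#' @export
filter_genus_table <- function(counts, min_sample_reads = 10000,
                               min_prevalence = 3,
                               min_mean_rel_abund = 1e-4) {
  log <- list()
  tot <- rowSums(counts)
  drop_s <- tot < min_sample_reads
  if (any(drop_s))
    log[[length(log) + 1]] <- data.table::data.table(
      step = "sample_depth", item = rownames(counts)[drop_s],
      reason = sprintf("total reads %d < %d", as.integer(tot[drop_s]),
                       as.integer(min_sample_reads)))
  m <- counts[!drop_s, , drop = FALSE]
  prev <- colSums(m > 0)
  drop_p <- prev < min_prevalence
  if (any(drop_p))
    log[[length(log) + 1]] <- data.table::data.table(
      step = "prevalence", item = colnames(m)[drop_p],
      reason = sprintf("detected in %d sample(s)", as.integer(prev[drop_p])))
  m <- m[, !drop_p, drop = FALSE]
  rel <- m / rowSums(m)
  mra <- colMeans(rel)
  drop_a <- mra < min_mean_rel_abund
  if (any(drop_a))
    log[[length(log) + 1]] <- data.table::data.table(
      step = "mean_abundance", item = colnames(m)[drop_a],
      reason = sprintf("mean relative abundance %.3g", mra[drop_a]))
  m <- m[, !drop_a, drop = FALSE]
  if (nrow(m) == 0 || ncol(m) == 0)
    stopf("table is empty after filtering")
  attr(m, "filter_log") <- if (length(log)) data.table::rbindlist(log)
  else data.table::data.table(step = character(0), item = character(0),
                              reason = character(0))
  m
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when both samples have at most `exact_max`
#' observations and there are no ties; normal approximation with tie and
#' continuity corrections otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max exact-test size limit (default 25).
#' @return list with `p` and `statistic` (the rank-sum U of `x`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25L) {
  if (length(x) == 0 || length(y) == 0) stopf("empty input")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  res <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                      alternative = "two.sided"))
  list(p = res$p.value, statistic = unname(res$statistic))
}

#' Benjamini-Hochberg q values
#' @param p vector of p values in `[0,1]`.
#' @return vector of q values (order-preserving).
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p values must be in [0,1]")
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Average ranks for ties; exact permutation p for n <= 9 without ties,
#' t approximation otherwise.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch")
  if (length(x) < 3) stopf("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("rho undefined for a constant vector")
  n <- length(x)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9) {
    # exact permutation null (handles ties via average ranks)
    rx <- rank(x); ry <- rank(y)
    rho_obs <- suppressWarnings(stats::cor(rx, ry))
    a <- rx - mean(rx); b <- ry - mean(ry)
    denom <- sqrt(sum(a^2) * sum(b^2))
    perms <- all_permutations(n)
    rho_perm <- (matrix(b[perms], nrow(perms), n) %*% a)[, 1] / denom
    p <- mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
    return(list(rho = rho_obs, p = p))
  }
  res <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(res$estimate), p = res$p.value)
}

# all permutations of 1..n (n! x n matrix); recursive construction
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1))
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Bray-Curtis distance matrix
#'
#' `d(u, v) = sum |u - v| / sum (u + v)`, in `[0, 1]` for non-negative
#' rows.  A pair of all-zero samples gets distance 0 with a warning.
#'
#' @param x samples x features non-negative matrix.
#' @return object of class `dist`.
#' @export
bray_curtis <- function(x) {
  if (any(x < 0)) stopf("negative entries")
  zero <- rowSums(x) == 0
  d <- if (any(zero)) suppressWarnings(vegan::vegdist(x, method = "bray"))
  else vegan::vegdist(x, method = "bray")
  if (sum(zero) >= 2) {
    warnf("distance between all-zero samples defined as 0")
    m <- as.matrix(d)
    m[zero, zero] <- 0
    d <- stats::as.dist(m)
  }
  d
}

#' Compare within-group distances against a reference group
#'
#' Collects all within-group pairwise distances per group and compares each
#' group's set to the reference group's by two-sided Wilcoxon rank-sum.
#'
#' @param d `dist` or square matrix.
#' @param groups group labels (length = number of samples).
#' @param reference reference group label.
#' @return data.table (group, n_pairs, median_distance, p; reference row
#'   has NA p).
#' @export
within_group_distance_test <- function(d, groups, reference) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  if (!reference %in% groups) stopf("unknown reference group")
  sets <- lapply(split(seq_along(groups), groups), function(idx) {
    if (length(idx) < 2) stopf("singleton group")
    mm <- m[idx, idx]
    mm[upper.tri(mm)]
  })
  ref <- sets[[reference]]
  out <- lapply(names(sets), function(gname) {
    p <- if (gname == reference) NA_real_
    else wilcoxon_rank_sum(sets[[gname]], ref)$p
    data.table::data.table(group = gname, n_pairs = length(sets[[gname]]),
                           median_distance = median(sets[[gname]]), p = p)
  })
  data.table::rbindlist(out)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2/2` and eigendecomposition; coordinates
#' are eigenvectors scaled by the square root of the (positive)
#' eigenvalues.  Negative eigenvalues are reported, not corrected.
#'
#' @param d `dist` or square symmetric zero-diagonal matrix.
#' @return list with `coordinates`, `eigenvalues`, `proportion_explained`
#'   (over positive eigenvalues) and `negative_eigenvalues` flag.
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stopf("distance matrix must be symmetric")
  n <- nrow(m)
  fit <- suppressWarnings(cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > 1e-8 * max(abs(eig), 1)
  coords <- fit$points
  if (!is.null(coords) && ncol(coords) > 0)
    coords <- coords[, seq_len(min(ncol(coords), sum(pos))), drop = FALSE]
  prop <- ifelse(eig > 0, eig / sum(eig[eig > 0]), 0)
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop[pos][seq_len(min(sum(pos), ncol(coords)))],
       negative_eigenvalues = any(eig < -1e-8 * max(abs(eig), 1)))
}

#' PERMANOVA on a distance matrix
#'
#' Distance-based variance partitioning between groups with a seeded
#' permutation test (wraps vegan's adonis2).
#'
#' @param d `dist` or square matrix.
#' @param groups group labels.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @return list with `F`, `R2` and `p`.
#' @export
permanova <- function(d, groups, n_permutations = 9999, seed = 1L) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("each group needs n >= 2")
  dd <- stats::as.dist(as.matrix(d))
  df <- data.frame(group = factor(groups))
  res <- withr::with_seed(as.integer(seed),
    vegan::adonis2(dd ~ group, data = df, permutations = n_permutations))
  list(F = res$F[1], R2 = res$R2[1], p = res$`Pr(>F)`[1])
}

#' Shannon-Wiener alpha diversity
#' @param x count/abundance vector or samples x features matrix.
#' @param base logarithm base (default 2).
#' @return numeric index (per sample).
#' @export
shannon_index <- function(x, base = 2) {
  if (is.matrix(x)) {
    if (any(rowSums(x) == 0)) stopf("all-zero sample")
    return(vegan::diversity(x, index = "shannon", base = base))
  }
  if (sum(x) == 0) stopf("all-zero sample")
  vegan::diversity(rbind(x), index = "shannon", base = base)[[1]]
}

# half of the smallest positive value: pseudo-abundance for zero medians
half_min_positive <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0) return(NA_real_)
  min(pos) / 2
}

#' Dirichlet-CLR Monte-Carlo differential abundance
#'
#' Compositional two-group test: for each of `n_instances` Monte-Carlo
#' instances, per-sample compositions are drawn from Dirichlet(counts +
#' 0.5), CLR-transformed (log ratio to the geometric mean), and each
#' feature is tested by a two-sided Wilcoxon rank-sum test; the reported p
#' is the mean over instances ("expected p"), with BH q values over
#' features.  The log2 fold change is the log2 ratio of case over reference
#' median relative abundance (half-minimum pseudo-abundance for zero
#' medians).
#'
#' @param counts samples x features count matrix.
#' @param groups two-group labels (length = samples).
#' @param reference reference (e.g. healthy) group label; the other group
#'   is the case group.
#' @param n_instances Monte-Carlo instances (default 128).
#' @param seed RNG seed.
#' @return data.table (feature, median_ref, median_case, log2fc, p, q).
#' @export
clr_mc_differential_abundance <- function(counts, groups,
                                          reference = NULL,
                                          n_instances = 128L, seed = 1L) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stopf("need exactly two groups")
  reference <- reference %||% lv[1]
  case <- setdiff(lv, reference)
  n1 <- sum(groups == reference); n2 <- sum(groups == case)
  if (n1 < 3 || n2 < 3) stopf("each group needs n >= 3")
  if (any(rowSums(counts) == 0)) stopf("group with all-zero sample")
  nf <- ncol(counts); ns <- nrow(counts)
  idx_case <- which(groups == case)

  pm <- withr::with_seed(as.integer(seed), {
    psum <- numeric(nf)
    for (b in seq_len(n_instances)) {
      g <- matrix(rgamma(ns * nf, shape = t(counts) + 0.5), nf, ns)
      p <- sweep(g, 2, colSums(g), "/")          # features x samples
      clr <- log(p) - rep(colMeans(log(p)), each = nf)
      psum <- psum + wilcox_p_matrix(clr, idx_case)
    }
    psum / n_instances
  })

  rel <- counts / rowSums(counts)
  med_ref <- apply(rel[groups == reference, , drop = FALSE], 2, median)
  med_case <- apply(rel[idx_case, , drop = FALSE], 2, median)
  pseudo <- half_min_positive(rel)
  lfc <- log2(ifelse(med_case > 0, med_case, pseudo) /
                ifelse(med_ref > 0, med_ref, pseudo))
  data.table::data.table(feature = colnames(counts) %||%
                           sprintf("f%d", seq_len(nf)),
                         median_ref = med_ref, median_case = med_case,
                         log2fc = lfc, p = pm, q = bh_fdr(pm))
}

# vectorised exact two-sided Wilcoxon p per row of a features x samples
# matrix (continuous data: no ties expected; falls back per-feature on ties)
wilcox_p_matrix <- function(clr, idx_case) {
  nf <- nrow(clr); ns <- ncol(clr)
  n2 <- length(idx_case); n1 <- ns - n2
  ranks <- t(apply(clr, 1, rank))
  U <- rowSums(ranks[, -idx_case, drop = FALSE]) - n1 * (n1 + 1) / 2
  if (n1 <= 25 && n2 <= 25) {
    lo <- U <= n1 * n2 / 2
    p <- ifelse(lo, 2 * pwilcox(U, n1, n2),
                2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    p <- pmin(1, p)
    tied <- apply(clr, 1, function(r) anyDuplicated(r) > 0)
    if (any(tied)) {
      ref <- clr[tied, -idx_case, drop = FALSE]
      cs <- clr[tied, idx_case, drop = FALSE]
      p[tied] <- vapply(seq_len(sum(tied)), function(i)
        wilcoxon_rank_sum(ref[i, ], cs[i, ])$p, numeric(1))
    }
    p
  } else {
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 * (ns + 1) / 12)
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    pmin(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Ortholog-level differential abundance report
#'
#' Per ortholog: two-sided Wilcoxon rank-sum between groups, BH q over the
#' tested orthologs, log2 fold change of case over reference median
#' abundance (half-minimum pseudo-value for zero medians), overall median
#' abundance, and a significance flag at p < 0.05 — the volcano-plot table.
#'
#' @param og_table samples x ortholog abundance matrix.
#' @param groups two-group labels.
#' @param reference reference group label.
#' @param og_subset orthologs to test (default: all columns); requested
#'   orthologs absent from the table are listed as untested.
#' @param alpha significance level for the flag.
#' @return list with `results` (data.table og_id, median_ref, median_case,
#'   median_all, log2fc, p, q, significant) and `untested`.
#' @export
ortholog_da_report <- function(og_table, groups, reference = NULL,
                               og_subset = NULL, alpha = 0.05) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stopf("need exactly two groups")
  reference <- reference %||% lv[1]
  case <- setdiff(lv, reference)
  want <- og_subset %||% colnames(og_table)
  untested <- setdiff(want, colnames(og_table))
  test <- intersect(want, colnames(og_table))
  if (length(test) == 0) stopf("no orthologs to test")
  ref_rows <- groups == reference
  res <- lapply(test, function(ogid) {
    x <- og_table[ref_rows, ogid]; y <- og_table[!ref_rows, ogid]
    data.table::data.table(og_id = ogid,
                           median_ref = median(x), median_case = median(y),
                           median_all = median(og_table[, ogid]),
                           p = wilcoxon_rank_sum(x, y)$p)
  })
  res <- data.table::rbindlist(res)
  pseudo <- half_min_positive(og_table)
  res[, log2fc := log2(ifelse(median_case > 0, median_case, pseudo) /
                         ifelse(median_ref > 0, median_ref, pseudo))]
  res[, q := bh_fdr(p)]
  res[, significant := p < alpha]
  list(results = res[], untested = untested)
}

#' Y-maze alternation ratio
#'
#' Alternations are consecutive entry triples visiting three distinct arms;
#' the ratio is alternations over (total entries - 2).
#'
#' @param entries character vector of arm entries (no consecutive
#'   duplicates; re-entry into the same arm is not an entry).
#' @return list with `total_entries`, `alternations` and `ratio`.
#' @export
alternation_ratio <- function(entries) {
  n <- length(entries)
  if (n < 3) stopf("need at least 3 entries")
  if (any(entries[-1] == entries[-n]))
    stopf("consecutive duplicate entries are not valid arm entries")
  triples <- vapply(seq_len(n - 2), function(i)
    length(unique(entries[i:(i + 2)])) == 3L, logical(1))
  alt <- sum(triples)
  list(total_entries = n, alternations = alt, ratio = alt / (n - 2))
}
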