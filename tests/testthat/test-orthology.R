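mk_sets <- function(...) {
  args <- list(...)
  lapply(seq_along(args), function(i) {
    genes <- args[[i]]
    strain_gene_set(sprintf("S%02d", i), data.table::data.table(
      gene_index = seq_along(genes),
      gene_id = sprintf("S%02d_g%d", i, seq_along(genes)),
      nt = vapply(genes, function(g) paste(rep("ACG", nchar(g)),
                                           collapse = ""), character(1)),
      aa = genes))
  })
}

test_that("similarity edges report identity and coverage correctly", {
  withr::with_seed(1, {
    p <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                      TRUE), collapse = "")
  })
  half <- substring(p, 1, 60)
  gs <- mk_sets(c(p), c(p, half))
  e <- pairwise_similarity(gs, seq_type = "protein")
  full <- e[subject_gene == "S02_g1"]
  expect_equal(full$identity, 100)
  expect_equal(full$query_coverage, 100)
  expect_equal(full$subject_coverage, 100)
  haga <- e[subject_gene == "S02_g2" | query_gene == "S02_g2"]
  expect_equal(nrow(haga), 1)
  # the half-length protein is fully covered; the full one half covered
  covs <- sort(c(haga$query_coverage, haga$subject_coverage))
  expect_equal(covs, c(50, 100))
  expect_equal(haga$identity, 100)
})

test_that("alignment scores match a plain dynamic-programming oracle", {
  withr::with_seed(1, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    p1 <- paste(sample(aas, 100, TRUE), collapse = "")
    p2 <- paste(sample(aas, 100, TRUE), collapse = "")
  })
  gs <- mk_sets(c(p1), c(p2))
  e <- pairwise_similarity(gs, seq_type = "protein", kmer_size = 2,
                           min_shared_kmers = 1)
  expect_equal(nrow(e), 1)
  expect_equal(e$score, sw_oracle(p1, p2))
  # unrelated proteins never satisfy the combined similarity thresholds
  expect_false(strainspec:::ko_thresholds_pass(e$identity, e$score,
                                               min(e$query_coverage,
                                                   e$subject_coverage)))
  expect_lt(e$score, 70)
  expect_lt(min(e$query_coverage, e$subject_coverage), 80)
  # related pair: score equals the oracle too
  p3 <- paste0(substring(p1, 1, 80), substring(p2, 1, 20))
  gs2 <- mk_sets(c(p1), c(p3))
  e2 <- pairwise_similarity(gs2, seq_type = "protein")
  expect_equal(e2$score, sw_oracle(p1, p3))
})

test_that("both clustering methods group identical copies and split cliques", {
  withr::with_seed(2, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    a <- paste(sample(aas, 90, TRUE), collapse = "")
    b <- paste(sample(aas, 90, TRUE), collapse = "")
  })
  gs <- mk_sets(c(a, b), c(a, b), c(a, b))
  e <- pairwise_similarity(gs, seq_type = "protein")
  for (m in c("A", "B")) {
    cl <- cluster_orthologs(e, gs, m)
    sig <- partition_signature(cl$groups)
    expect_length(sig, 2)      # two disjoint cliques -> two groups
    sizes <- vapply(strsplit(sig, "\\|"), length, integer(1))
    expect_equal(sizes, c(3L, 3L))
  }
  expect_error(cluster_orthologs(e, gs, "Z"), "method")
})

test_that("single-linkage merges chains that best-hit components keep apart", {
  # hand-traced graph over strains S01={a}, S02={b}, S03={c,d,e}:
  #   a-b id 97 score 100; b-c id 97 score 40; a-c id 60 score 50;
  #   a-d id 60 score 55; b-e id 60 score 58
  # method A (threshold 95): a-b and b-c pass -> {a,b,c}; d, e singletons
  # method B: reciprocal bests are a-b, a-d (55 > 50) and b-e (58 > 40);
  #   c is nobody's reciprocal best -> {a,b,d,e} and {c}
  gs <- mk_sets("AAAA", c("AAAB"), c("AABB", "AAAC", "AADD"))
  edges <- data.table::data.table(
    query_strain  = c("S01", "S02", "S01", "S01", "S02"),
    query_gene    = c("S01_g1", "S02_g1", "S01_g1", "S01_g1", "S02_g1"),
    subject_strain = c("S02", "S03", "S03", "S03", "S03"),
    subject_gene  = c("S02_g1", "S03_g1", "S03_g1", "S03_g2", "S03_g3"),
    identity = c(97, 97, 60, 60, 60),
    score = c(100, 40, 50, 55, 58),
    query_coverage = 100, subject_coverage = 100)
  sig_a <- partition_signature(
    cluster_orthologs(edges, gs, "A", identity_threshold = 95)$groups)
  expect_true("S01:S01_g1|S02:S02_g1|S03:S03_g1" %in% sig_a)
  expect_true(all(c("S03:S03_g2", "S03:S03_g3") %in% sig_a))
  sig_b <- partition_signature(cluster_orthologs(edges, gs, "B")$groups)
  expect_true("S01:S01_g1|S02:S02_g1|S03:S03_g2|S03:S03_g3" %in% sig_b)
  expect_true("S03:S03_g1" %in% sig_b)
})

test_that("clustering partitions the gene universe and ignores strain order", {
  pg <- tiny_pangenome()
  e <- pairwise_similarity(pg$gene_sets)
  n_genes <- sum(vapply(pg$gene_sets, function(g) nrow(g$genes), integer(1)))
  for (m in c("A", "B")) {
    cl <- cluster_orthologs(e, pg$gene_sets, m)
    expect_equal(nrow(cl$groups), n_genes)
    expect_equal(anyDuplicated(cl$groups[, .(strain, gene_id)]), 0L)
  }
  # permuting strain input order leaves the partition unchanged
  rev_sets <- rev(pg$gene_sets)
  e2 <- pairwise_similarity(rev_sets)
  for (m in c("A", "B")) {
    s1 <- partition_signature(cluster_orthologs(e, pg$gene_sets, m)$groups)
    s2 <- partition_signature(cluster_orthologs(e2, rev_sets, m)$groups)
    expect_identical(s1, s2)
  }
})

test_that("near-identical pan-genome copies are recovered exactly", {
  pg <- tiny_pangenome(mutation_rate = 0.01)
  e <- pairwise_similarity(pg$gene_sets)
  truth_sig <- partition_signature(pg$truth$og_membership)
  for (m in c("A", "B"))
    expect_identical(partition_signature(
      cluster_orthologs(e, pg$gene_sets, m)$groups), truth_sig)
  # at 2% per-copy divergence pairwise identity sits near 96%, so method A
  # needs a threshold below that band; method B has no absolute threshold
  pg2 <- tiny_pangenome(mutation_rate = 0.02)
  e2 <- pairwise_similarity(pg2$gene_sets)
  truth2 <- partition_signature(pg2$truth$og_membership)
  expect_identical(partition_signature(
    cluster_orthologs(e2, pg2$gene_sets, "A",
                      identity_threshold = 90)$groups), truth2)
  expect_identical(partition_signature(
    cluster_orthologs(e2, pg2$gene_sets, "B")$groups), truth2)
})

test_that("KO assignment enforces all three thresholds strictly", {
  pass <- strainspec:::ko_thresholds_pass
  expect_true(pass(45, 80, 90))
  expect_false(pass(40, 80, 90))    # identity exactly 40: strict >
  expect_false(pass(45, 70, 90))    # score exactly 70
  expect_false(pass(45, 80, 80))    # coverage exactly 80
  expect_true(pass(40.1, 70.1, 80.1))

  pg <- tiny_pangenome()
  ann <- assign_ko(pg$gene_sets, pg$ko_reference)
  truth <- pg$truth$ko_truth
  got <- ann[!is.na(ko), .(strain, gene_id, ko)]
  merged <- merge(truth, got, by = c("strain", "gene_id"),
                  suffixes = c("_true", "_got"))
  # every truth-labeled gene recovered with the right label
  expect_equal(nrow(merged), nrow(truth))
  expect_true(all(merged$ko_true == merged$ko_got))
  # no spurious labels on unlabeled genes
  expect_equal(nrow(got), nrow(truth))
  expect_error(assign_ko(pg$gene_sets, pg$ko_reference[0]), "non-empty")
})

test_that("localization calls follow the hydropathy window rule", {
  # 19 leucines embedded in a charged context
  tm <- paste0(paste(rep("K", 15), collapse = ""),
               paste(rep("L", 19), collapse = ""),
               paste(rep("E", 15), collapse = ""))
  expect_equal(classify_localization(tm)$call, "transmembrane")
  expect_equal(classify_localization(tm)$n_helices, 1L)
  # all-lysine: no helix, no signal
  kk <- paste(rep("K", 60), collapse = "")
  expect_equal(classify_localization(kk)$call, "intracellular")
  # hydrophobic N-terminal stretch, too short for a helix
  sig <- paste0(paste(rep("I", 10), collapse = ""),
                paste(rep("K", 60), collapse = ""))
  expect_equal(classify_localization(sig)$call, "extracellular")
  expect_error(classify_localization("MKLZ"), "non-amino-acid")

  # window-mean oracle on a random protein
  withr::with_seed(9, {
    aas <- names(strainspec:::.kd_scale)
    p <- paste(sample(aas, 200, TRUE, prob = rep(1, 20)), collapse = "")
  })
  res <- classify_localization(p, window = 19, cutoff = 1.6)
  h <- strainspec:::.kd_scale[strsplit(p, "")[[1]]]
  wm <- vapply(1:(200 - 18), function(i) mean(h[i:(i + 18)]), numeric(1))
  cov <- rep(FALSE, 200)
  for (i in which(wm > 1.6)) cov[i:(i + 18)] <- TRUE
  r <- rle(cov)
  expect_equal(res$n_helices, sum(r$values))
})
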