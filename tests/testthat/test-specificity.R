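# hand-built clustering helper
mk_clustering <- function(df, method = "A") {
  structure(list(method = method,
                 groups = data.table::as.data.table(df)),
            class = "ortholog_clustering")
}

test_that("presence/absence matrix counts members exactly", {
  cl <- mk_clustering(data.frame(
    og_id = c("OG1", "OG1", "OG1", "OG2", "OG3", "OG3"),
    strain = c("S01", "S02", "S03", "S02", "S01", "S01"),
    gene_id = c("a", "b", "c", "d", "e", "f")))
  m <- presence_absence(cl, c("S01", "S02", "S03"))
  expect_equal(unname(m["OG1", ]), c(1L, 1L, 1L))
  expect_equal(unname(m["OG2", ]), c(0L, 1L, 0L))     # singleton group
  expect_equal(unname(m["OG3", ]), c(2L, 0L, 0L))     # within-strain paralogs
  expect_equal(unname(rowSums(m)), c(3L, 1L, 2L))
  expect_equal(unname(colSums(m)),
               as.integer(table(cl$groups$strain)[c("S01", "S02", "S03")]))
  expect_error(presence_absence(cl, c("S01", "S02")), "absent")
})

test_that("presence and KO rules call specific orthologs", {
  strains <- sprintf("S%02d", 1:4)
  cl <- mk_clustering(data.frame(
    og_id = c("OGpair", "OGpair",                   # exactly in S01+S02
              "OGcore", "OGcore", "OGcore", "OGcore",  # everywhere
              "OGwide", "OGwide", "OGwide"),        # S01,S02,S03
    strain = c("S01", "S02", "S01", "S02", "S03", "S04", "S01", "S02", "S03"),
    gene_id = paste0("g", 1:9)))
  # KO K_x occurs genome-wide only in S01's gene of the core group
  ko <- data.frame(strain = "S01", gene_id = "g3", ko = "K00099")

  calls <- call_specific_orthologs(cl, c("S01", "S02"), strains, ko)
  expect_equal(calls$calls$og_id, "OGpair")
  expect_equal(calls$calls$rule, "presence_only")

  # core group called through its exclusive KO when targeting S01 alone
  calls1 <- call_specific_orthologs(cl, "S01", strains, ko)
  expect_true("OGcore" %in% calls1$calls$og_id)
  expect_equal(calls1$calls[og_id == "OGcore", rule], "ko_only")
  expect_equal(calls1$calls[og_id == "OGcore", kos], "K00099")
  # OGwide covers S03 too: not called for {S01,S02}
  expect_false("OGwide" %in% calls$calls$og_id)
  expect_error(call_specific_orthologs(cl, "S99", strains), "unknown")
  expect_error(call_specific_orthologs(cl, character(0), strains),
               "non-empty")
})

test_that("require_all_targets toggles the partial-presence reading", {
  strains <- c("S01", "S02", "S03")
  cl <- mk_clustering(data.frame(og_id = "OGsolo", strain = "S01",
                                 gene_id = "g1"))
  strict <- call_specific_orthologs(cl, c("S01", "S02"), strains)
  expect_equal(nrow(strict$calls), 0)
  loose <- call_specific_orthologs(cl, c("S01", "S02"), strains,
                                   require_all_targets = FALSE)
  expect_equal(loose$calls$og_id, "OGsolo")
})

test_that("presence calls never have members outside the target set", {
  pg <- tiny_pangenome()
  strains <- vapply(pg$gene_sets, `[[`, character(1), "strain_id")
  e <- pairwise_similarity(pg$gene_sets)
  cl <- cluster_orthologs(e, pg$gene_sets, "A")
  calls <- call_specific_orthologs(cl, c("S01", "S02"), strains)
  m <- presence_absence(cl, strains)
  for (ogid in calls$calls[rule != "ko_only", og_id])
    expect_equal(sum(m[ogid, setdiff(strains, c("S01", "S02"))]), 0)
})

test_that("consensus pairs identical partitions and flags split groups", {
  strains <- c("S01", "S02", "S03")
  cl_a <- mk_clustering(data.frame(
    og_id = c("A1", "A1", "A2", "A2"),
    strain = c("S01", "S02", "S01", "S02"),
    gene_id = c("g1", "g2", "g3", "g4")), "A")
  ca <- call_specific_orthologs(cl_a, c("S01", "S02"), strains)
  cb <- call_specific_orthologs(
    mk_clustering(cl_a$groups, "B"), c("S01", "S02"), strains)
  cons <- consensus_calls(ca, cb)
  expect_equal(nrow(cons$consensus), 2)
  expect_equal(cons$consensus$jaccard, c(1, 1))
  expect_equal(nrow(cons$exclusive), 0)

  # method B splits A1 across two groups, neither of which is called
  # (each half also contains an S03 gene): A1 becomes method-exclusive
  cl_b <- mk_clustering(data.frame(
    og_id = c("B1", "B1", "B2", "B2", "B3", "B3"),
    strain = c("S01", "S03", "S02", "S03", "S01", "S02"),
    gene_id = c("g1", "x1", "g2", "x2", "g3", "g4")), "B")
  cb2 <- call_specific_orthologs(cl_b, c("S01", "S02"), strains)
  expect_equal(cb2$calls$og_id, "B3")
  cons2 <- consensus_calls(ca, cb2)
  expect_equal(cons2$consensus$og_a, "A2")
  expect_true("A1" %in% cons2$exclusive[method == "A", og_id])

  # mismatched target sets are rejected
  cb3 <- call_specific_orthologs(cl_b, "S01", strains)
  expect_error(consensus_calls(ca, cb3), "target")
})

test_that("consensus recovers exactly the planted groups on clean input", {
  pg <- tiny_pangenome()
  strains <- vapply(pg$gene_sets, `[[`, character(1), "strain_id")
  e <- pairwise_similarity(pg$gene_sets)
  ca <- call_specific_orthologs(cluster_orthologs(e, pg$gene_sets, "A"),
                                c("S01", "S02"), strains)
  cb <- call_specific_orthologs(cluster_orthologs(e, pg$gene_sets, "B"),
                                c("S01", "S02"), strains)
  cons <- consensus_calls(ca, cb)
  expect_equal(nrow(cons$consensus), 4)
  expect_equal(nrow(cons$exclusive), 0)
  # member sets equal the planted truth
  truth_mem <- pg$truth$og_membership[
    og_id %in% pg$truth$planted_specific_ids]
  called_sig <- partition_signature(
    ca$members[og_id %in% cons$consensus$og_a])
  expect_identical(called_sig, partition_signature(truth_mem))
})

test_that("adjacency blocks are maximal runs of consecutive gene indices", {
  # one strain whose called genes sit at the positions reported for the
  # trehalose (753-757) and pilus (767-778) regions, plus two isolated calls
  idx <- c(753:757, 767:778, 1, 3)
  gs <- list(strain_gene_set("S01", data.table::data.table(
    gene_index = sort(c(idx, 900:910)),
    gene_id = sprintf("g%04d", sort(c(idx, 900:910))),
    nt = "ACGT", aa = "MK")))
  calls <- list(members = data.table::data.table(
    og_id = sprintf("OG%04d", idx), strain = "S01",
    gene_id = sprintf("g%04d", idx)))
  blocks <- find_adjacent_blocks(calls, gs)
  expect_equal(nrow(blocks), 4)
  b5 <- blocks[start == 753]
  expect_equal(b5$end, 757); expect_equal(b5$n_genes, 5L)
  b12 <- blocks[start == 767]
  expect_equal(b12$end, 778); expect_equal(b12$n_genes, 12L)
  expect_equal(blocks[start == 1, n_genes], 1L)
  expect_equal(blocks[start == 3, n_genes], 1L)
})
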