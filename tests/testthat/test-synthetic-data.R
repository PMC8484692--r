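test_that("pan-genome construction plants blocks with recorded truth", {
  pg <- tiny_pangenome()
  truth <- pg$truth
  # planted groups live exactly in strains S01+S02
  expect_length(truth$planted_specific_ids, 4)
  mem <- truth$og_membership[og_id %in% truth$planted_specific_ids]
  expect_setequal(unique(mem$strain), c("S01", "S02"))
  for (ogid in truth$planted_specific_ids)
    expect_setequal(mem[og_id == ogid, strain], c("S01", "S02"))
  # block is a consecutive run in both member strains
  blk <- truth$adjacency_blocks
  expect_equal(blk$end - blk$start + 1L, rep(4L, nrow(blk)))
  # every gene belongs to exactly one truth group
  expect_equal(anyDuplicated(truth$og_membership[, .(strain, gene_id)]), 0L)
  n_genes <- sum(vapply(pg$gene_sets, function(g) nrow(g$genes), integer(1)))
  expect_equal(nrow(truth$og_membership), n_genes)
})

test_that("zero mutation rate yields identical copies within groups", {
  pg <- tiny_pangenome(mutation_rate = 0)
  seqs <- data.table::rbindlist(lapply(pg$gene_sets, function(g)
    data.table::data.table(strain = g$strain_id, gene_id = g$genes$gene_id,
                           nt = g$genes$nt)))
  m <- pg$truth$og_membership[seqs, on = c("strain", "gene_id")]
  n_variants <- m[, length(unique(nt)), by = og_id]$V1
  expect_true(all(n_variants == 1))
})

test_that("generator is deterministic under a fixed seed", {
  a <- tiny_pangenome(seed = 42)
  b <- tiny_pangenome(seed = 42)
  expect_identical(lapply(a$gene_sets, `[[`, "genes"),
                   lapply(b$gene_sets, `[[`, "genes"))
  expect_identical(a$truth$og_membership, b$truth$og_membership)
  cs <- cohort_sim_spec(group_sizes = c(healthy = 2, case = 2),
                        reads_per_sample = 500, seed = 5)
  r1 <- simulate_metagenome_cohort(a$gene_sets, cs)
  r2 <- simulate_metagenome_cohort(a$gene_sets, cs)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
})

test_that("planted blocks exceeding accessory capacity are rejected", {
  spec <- pan_genome_spec(n_strains = 2, core_size = 1, accessory_size = 0,
                          planted_specific = list(
                            list(strains = 1, len = 1),
                            list(strains = 1, len = 1),
                            list(strains = 1, len = 1)),
                          seed = 1)
  expect_error(simulate_pangenome(spec), "capacity")
})

test_that("invalid pan-genome specs are rejected", {
  expect_error(pan_genome_spec(1, 10), "n_strains")
  expect_error(pan_genome_spec(3, 10, mutation_rate = 0.5), "mutation_rate")
  expect_error(pan_genome_spec(3, 10,
                               planted_specific = list(list(strains = c(),
                                                            len = 2))),
               "non-empty")
  expect_error(pan_genome_spec(3, 10,
                               planted_specific = list(list(strains = 4,
                                                            len = 2))),
               "subset")
})

test_that("cohort reads are exact gene substrings when contaminant-free", {
  pg <- tiny_pangenome(mutation_rate = 0)
  cs <- cohort_sim_spec(group_sizes = c(healthy = 1, case = 1),
                        reads_per_sample = 400, seed = 2)
  co <- simulate_metagenome_cohort(pg$gene_sets, cs)
  genes <- unlist(lapply(pg$gene_sets, function(g) g$genes$nt))
  haystack <- paste(c(genes, revcomp(genes)), collapse = "#")
  for (dt in co$reads) {
    hit <- vapply(dt$seq, function(s) grepl(s, haystack, fixed = TRUE),
                  logical(1))
    expect_true(all(hit))
  }
})

test_that("contaminant injection matches the binomial expectation", {
  pg <- tiny_pangenome()
  cs <- cohort_sim_spec(group_sizes = c(healthy = 1, case = 1),
                        reads_per_sample = 10000,
                        contaminant_fractions = c(phix = 0.05),
                        seed = 31)
  co <- simulate_metagenome_cohort(pg$gene_sets, cs, keep_reads = TRUE)
  n_phix <- co$truth[[1]]$contaminants[["phix"]]
  sd3 <- 3 * sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(n_phix - 500), sd3)
  # conservation: gene-origin counts + contaminants = reads_per_sample
  for (tr in co$truth)
    expect_equal(sum(tr$gene_counts) + sum(tr$contaminants), 10000)
})

test_that("reads_per_sample must be a positive even count", {
  expect_error(cohort_sim_spec(reads_per_sample = 0), "even")
  expect_error(cohort_sim_spec(reads_per_sample = 101), "even")
  expect_error(cohort_sim_spec(contaminant_fractions = c(phix = 0.6,
                                                         host = 0.5)),
               "sum")
})

test_that("gene sets round-trip through FASTA + TSV", {
  pg <- tiny_pangenome()
  dir <- withr::local_tempdir()
  write_gene_sets(pg$gene_sets, dir)
  back <- read_gene_sets(dir)
  expect_equal(lapply(back, `[[`, "strain_id"),
               lapply(pg$gene_sets, `[[`, "strain_id"))
  for (i in seq_along(back))
    expect_equal(back[[i]]$genes[, .(gene_index, gene_id, nt, aa)],
                 pg$gene_sets[[i]]$genes[, .(gene_index, gene_id, nt, aa)])
})

test_that("genus tables carry the planted fold change and score link", {
  # planted effect recovered in the latent means over repeated tables
  lfc <- replicate(30, {
    g <- simulate_genus_table(planted_effects = c(g5 = 3),
                              seed = sample.int(1e6, 1))
    rel <- g$counts / rowSums(g$counts)
    case <- g$metadata$group == "case"
    log2(mean(rel[case, "g5"]) / mean(rel[!case, "g5"]))
  })
  expect_gt(mean(lfc), 0.8)    # compositional closure dampens log2(3)=1.58
  expect_lt(mean(lfc), 1.8)
  expect_error(simulate_genus_table(planted_effects = c(g2 = -1)),
               "fold-changes")
  # no planted effects: no systematic group difference
  lfc0 <- replicate(30, {
    g <- simulate_genus_table(seed = sample.int(1e6, 1))
    rel <- g$counts / rowSums(g$counts)
    case <- g$metadata$group == "case"
    log2(mean(rel[case, "g1"]) / mean(rel[!case, "g1"]))
  })
  expect_lt(abs(mean(lfc0)), 0.25)
  # score link: mean realized Spearman near the target
  rhos <- replicate(40, {
    g <- simulate_genus_table(score_link = list(genus = 7, rho = 0.6),
                              seed = sample.int(1e6, 1))
    suppressWarnings(cor(g$counts[, "g7"], g$metadata$score,
                         method = "spearman"))
  })
  expect_lt(abs(mean(rhos) - 0.6), 0.15)
})
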