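#!/usr/bin/env Rscript
# Generate the synthetic study inputs with planted truth: the 12-strain
# pan-genome, the two-cohort shotgun metagenome, the genus count table with
# a cognitive-score covariate, and a 16S-like alignment of the isolates.
source("analysis/00_config.R")

message("-- pan-genome --")
pg <- simulate_pangenome(PANGENOME_SPEC())
n_genes <- sum(vapply(pg$gene_sets, function(g) nrow(g$genes), integer(1)))
message(sprintf("12 strains, %d genes, %d planted specific groups",
                n_genes, length(pg$truth$planted_specific_ids)))
gdir <- file.path(DATA, "pangenome")
write_gene_sets(pg$gene_sets, gdir)
fwrite(pg$truth$og_membership, file.path(gdir, "truth_og_membership.tsv"),
       sep = "\t")
fwrite(pg$truth$adjacency_blocks, file.path(gdir, "truth_blocks.tsv"),
       sep = "\t")
fwrite(pg$ko_reference, file.path(gdir, "ko_reference.tsv"), sep = "\t")
jsonlite::write_json(
  list(planted_specific_ids = pg$truth$planted_specific_ids,
       planted_by_directive = pg$truth$planted_by_directive),
  file.path(gdir, "truth_planted.json"))

message("-- cohort metagenome --")
co <- simulate_metagenome_cohort(pg$gene_sets, COHORT_SPEC(),
                                 out_dir = file.path(DATA, "cohort"),
                                 keep_reads = FALSE)
truth_counts <- as.data.table(t(vapply(co$truth, function(x) x$gene_counts,
                                       numeric(nrow(co$genes)))),
                              keep.rownames = "sample")
fwrite(truth_counts, file.path(DATA, "cohort", "truth_gene_counts.tsv"),
       sep = "\t")
message(sprintf("%d samples x %d reads written", nrow(co$metadata),
                COHORT_SPEC()$reads_per_sample))

message("-- genus table --")
gt <- simulate_genus_table(n_per_group = c(healthy = 20L, case = 15L),
                           n_genera = 60,
                           planted_effects = c(g5 = 1 / 3, g9 = 1 / 2,
                                               g12 = 2),
                           score_link = list(genus = 5, rho = 0.6),
                           seed = SEED + 2L)
fwrite(as.data.table(gt$counts, keep.rownames = "sample"),
       file.path(DATA, "genus_counts.tsv"), sep = "\t")
fwrite(gt$metadata, file.path(DATA, "genus_metadata.tsv"), sep = "\t")
message("60 genera; planted case/healthy fold changes 1/3, 1/2 and 2")

message("-- 16S-like alignment --")
withr::with_seed(SEED + 3L, {
  L <- 1400
  anc <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  mut <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(L) < rate)
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  # two clades (S01/S02 near the healthy-derived isolates) plus drift
  cladeA <- mut(anc, 0.02); cladeB <- mut(anc, 0.02)
  aln <- c(
    setNames(lapply(1:6, function(i) mut(cladeA, 0.008)),
             sprintf("S%02d", 1:6)),
    setNames(lapply(7:12, function(i) mut(cladeB, 0.008)),
             sprintf("S%02d", 7:12)))
  aln <- unlist(aln)
})
writeLines(paste0(">", names(aln), "\n", aln),
           file.path(DATA, "isolates_16S_synthetic.fasta"))
message("wrote ", file.path(DATA, "isolates_16S_synthetic.fasta"))
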