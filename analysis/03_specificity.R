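#!/usr/bin/env Rscript
# Call strain-specific ortholog groups for the effective-strain pair and for
# each effective strain alone; build the two-method consensus and the
# chromosomal adjacency blocks.
source("analysis/00_config.R")

gdir <- file.path(DATA, "pangenome")
gene_sets <- read_gene_sets(gdir)
strains <- vapply(gene_sets, `[[`, character(1), "strain_id")
cl_a <- structure(list(method = "A",
                       groups = fread(file.path(OUT, "clustering_A.tsv"))),
                  class = "ortholog_clustering")
cl_b <- structure(list(method = "B",
                       groups = fread(file.path(OUT, "clustering_B.tsv"))),
                  class = "ortholog_clustering")
ko <- fread(file.path(OUT, "ko_annotation.tsv"))

run_target <- function(target, label) {
  ca <- call_specific_orthologs(cl_a, target, strains, ko)
  cb <- call_specific_orthologs(cl_b, target, strains, ko)
  cons <- consensus_calls(ca, cb)
  blocks <- find_adjacent_blocks(ca, gene_sets)
  message(sprintf(
    "%s: %d calls (A), %d calls (B), %d consensus, %d method-exclusive",
    label, nrow(ca$calls), nrow(cb$calls), nrow(cons$consensus),
    nrow(cons$exclusive)))
  runs <- blocks[n_genes > 1]
  if (nrow(runs))
    message(sprintf("  adjacent runs: %s",
                    paste(sprintf("%s:%d-%d (%d)", runs$strain, runs$start,
                                  runs$end, runs$n_genes), collapse = "; ")))
  fwrite(ca$calls, file.path(OUT, sprintf("calls_%s_A.tsv", label)),
         sep = "\t")
  fwrite(cons$consensus, file.path(OUT, sprintf("consensus_%s.tsv", label)),
         sep = "\t")
  fwrite(blocks, file.path(OUT, sprintf("blocks_%s.tsv", label)), sep = "\t")
  list(calls = ca, consensus = cons, blocks = blocks)
}

shared <- run_target(TARGET_PAIR, "sharedS01S02")
solo14 <- run_target("S01", "soloS01")
solo360 <- run_target("S02", "soloS02")

summary <- list(
  n_shared_pair = nrow(shared$consensus$consensus),
  n_solo_S01 = nrow(solo14$consensus$consensus),
  n_solo_S02 = nrow(solo360$consensus$consensus),
  shared_block_lengths = shared$blocks[strain %in% TARGET_PAIR, n_genes])
jsonlite::write_json(summary, file.path(OUT, "specificity_summary.json"),
                     auto_unbox = TRUE)
message(sprintf("summary: %d shared-pair, %d solo-S01, %d solo-S02 groups",
                summary$n_shared_pair, summary$n_solo_S01,
                summary$n_solo_S02))
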