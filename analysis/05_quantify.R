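#!/usr/bin/env Rscript
# Assign QC-passed reads to genes by k-mer plurality voting, normalise to
# TPM, and aggregate to ortholog-group abundance under both clusterings.
source("analysis/00_config.R")

gene_sets <- read_gene_sets(file.path(DATA, "pangenome"))
meta <- fread(file.path(DATA, "cohort", "metadata.tsv"))
idx <- build_gene_index(gene_sets, k = 31)

clean <- lapply(meta$sample, function(s) {
  r1 <- read_fastq(file.path(DATA, "clean", paste0(s, "_1.fastq.gz")))
  r2 <- read_fastq(file.path(DATA, "clean", paste0(s, "_2.fastq.gz")))
  c(r1$seq, r2$seq)
})
names(clean) <- meta$sample

for (m in c("A", "B")) {
  cl <- structure(list(method = m, groups = fread(
    file.path(OUT, sprintf("clustering_%s.tsv", m)))),
    class = "ortholog_clustering")
  quant <- quantify_cohort(clean, idx, cl)
  message(sprintf(
    "method %s: TPM sums in [%.6f, %.6f] x 1e6; %d ortholog groups",
    m, min(rowSums(quant$tpm)) / 1e6, max(rowSums(quant$tpm)) / 1e6,
    ncol(quant$og_abundance)))
  fwrite(as.data.table(quant$og_abundance, keep.rownames = "sample"),
         file.path(OUT, sprintf("og_abundance_%s.tsv", m)), sep = "\t")
  if (m == "A")
    fwrite(as.data.table(quant$tpm, keep.rownames = "sample"),
           file.path(OUT, "gene_tpm.tsv"), sep = "\t")
}
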