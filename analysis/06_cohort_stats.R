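#!/usr/bin/env Rscript
# The statistical layer: genus-level community analysis (filters, CLR
# Monte-Carlo differential abundance, Bray-Curtis/PCoA/PERMANOVA,
# within-group distances, Shannon, score correlation) and ortholog-level
# differential abundance for the called specific orthologs under both
# clusterings; plus the Y-maze alternation-ratio demonstration.
source("analysis/00_config.R")

message("-- genus arm --")
counts <- as.matrix(fread(file.path(DATA, "genus_counts.tsv")),
                    rownames = "sample")
meta <- fread(file.path(DATA, "genus_metadata.tsv"))
f <- filter_genus_table(counts)
message(sprintf("%d of %d genera retained after filtering", ncol(f),
                ncol(counts)))

da <- clr_mc_differential_abundance(f, meta$group, reference = "healthy",
                                    seed = SEED + 5L)
fwrite(da, file.path(OUT, "genus_da.tsv"), sep = "\t")
sig <- da[p < 0.05][order(p)]
message(sprintf("%d genera differential at p < 0.05: %s", nrow(sig),
                paste(sprintf("%s (log2FC %.2f, p %.3g)", sig$feature,
                              sig$log2fc, sig$p), collapse = "; ")))

d <- bray_curtis(f)
fwrite(as.data.table(as.matrix(d), keep.rownames = "sample"),
       file.path(OUT, "bray_curtis.tsv"), sep = "\t")
pc <- pcoa_ordination(d)
ord <- data.table(sample = rownames(as.matrix(d)),
                  group = meta$group,
                  PC1 = pc$coordinates[, 1], PC2 = pc$coordinates[, 2])
fwrite(ord, file.path(OUT, "pcoa.tsv"), sep = "\t")
pm <- permanova(d, meta$group, n_permutations = 9999, seed = SEED + 6L)
message(sprintf("PERMANOVA: R2 = %.4f, p = %.4f (PC1 %.1f%%, PC2 %.1f%%)",
                pm$R2, pm$p, 100 * pc$proportion_explained[1],
                100 * pc$proportion_explained[2]))
wg <- within_group_distance_test(d, meta$group, reference = "healthy")
message(sprintf("within-group distance, case vs healthy: p = %.4g",
                wg[group == "case", p]))

alpha <- shannon_index(f, base = 2)
sh_p <- wilcoxon_rank_sum(alpha[meta$group == "healthy"],
                          alpha[meta$group == "case"])$p
message(sprintf("Shannon index healthy vs case: p = %.3f", sh_p))

sc <- spearman_cor(f[, "g5"] / rowSums(f), meta$score)
message(sprintf("score vs linked genus g5: Spearman rho = %.3f, p = %.3g",
                sc$rho, sc$p))
jsonlite::write_json(list(permanova = pm,
                          within_group_p = wg[group == "case", p],
                          shannon_p = sh_p,
                          score_rho = sc$rho, score_p = sc$p),
                     file.path(OUT, "community_stats.json"),
                     auto_unbox = TRUE, digits = NA)

message("-- ortholog arm --")
cohort_meta <- fread(file.path(DATA, "cohort", "metadata.tsv"))
for (m in c("A", "B")) {
  og <- as.matrix(fread(file.path(OUT, sprintf("og_abundance_%s.tsv", m))),
                  rownames = "sample")
  cons <- fread(file.path(OUT, "consensus_sharedS01S02.tsv"))
  solo1 <- fread(file.path(OUT, "consensus_soloS01.tsv"))
  solo2 <- fread(file.path(OUT, "consensus_soloS02.tsv"))
  key <- if (m == "A") "og_a" else "og_b"
  wanted <- c(cons[[key]], solo1[[key]], solo2[[key]])
  rep <- ortholog_da_report(og, cohort_meta$group, reference = "healthy",
                            og_subset = wanted)
  fwrite(rep$results, file.path(OUT, sprintf("ortholog_da_%s.tsv", m)),
         sep = "\t")
  message(sprintf(
    "method %s: %d of %d specific orthologs higher in healthy at p < 0.05",
    m, sum(rep$results$significant & rep$results$log2fc < 0),
    nrow(rep$results)))
}

message("-- alternation ratio demonstration --")
withr::with_seed(SEED + 7L, {
  # an alternating-prone walker vs a perseverating one
  walk <- function(p_alt, n = 25) {
    s <- character(n); s[1:2] <- sample(c("A", "B", "C"), 2)
    for (j in 3:n) {
      third <- setdiff(c("A", "B", "C"), s[c(j - 2, j - 1)])
      nxt <- if (runif(1) < p_alt) third else s[j - 2]
      s[j] <- nxt
    }
    s
  }
  good <- replicate(12, alternation_ratio(walk(0.75))$ratio)
  poor <- replicate(12, alternation_ratio(walk(0.45))$ratio)
})
message(sprintf(
  "alternation ratio: intact group %.2f +/- %.2f, impaired group %.2f +/- %.2f (Wilcoxon p = %.3g)",
  mean(good), sd(good), mean(poor), sd(poor),
  wilcoxon_rank_sum(good, poor)$p))
fwrite(data.table(group = rep(c("intact", "impaired"), each = 12),
                  ratio = c(good, poor)),
       file.path(OUT, "alternation_ratios.tsv"), sep = "\t")
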