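# strainspec

Comparative-genomics and cohort-metagenomics toolkit for finding
**strain-specific ortholog groups** in a bacterial pan-genome and testing
whether they differ in abundance between human cohorts measured by shotgun
metagenome sequencing. It was built for the setting where a few isolates of
a species (here, *Faecalibacterium prausnitzii*-like strains relevant to
cognitive health) show an effect their conspecifics lack, and the candidate
explanation is gene content: which ortholog groups do only the effective
strains carry, and are those groups enriched in healthy-donor microbiomes?

Intended users are microbial genomics / microbiome researchers who want the
full chain — pan-genome ortholog clustering, specificity calling, read QC,
quantification, cohort statistics, isolate phylogeny — as plain, tested R
functions over data frames and matrices, with synthetic-data generators
that plant a recorded ground truth so every stage can be validated.

## The core definitions

**Specific ortholog.** For a target strain set *T* inside a pan-genome of
strains *S*, an ortholog group *g* is specific to *T* iff

- (presence rule) strains(*g*) = *T* — its members occur in every strain of
  *T* and nowhere else; or
- (KO rule) *g* contains a gene whose KO label occurs, over all genes of
  all strains, only in genes of strains in *T* (covering all of *T*).

Groups are called independently under two clusterings — single-linkage
components at identity ≥ 95% / coverage ≥ 80% (method A), and
bidirectional-best-hit components (method B) — and reconciled by member-set
Jaccard ≥ 0.5 into consensus and method-exclusive calls. Runs of called
groups at consecutive gene indices are reported as adjacency blocks.

**Cohort verification.** Reads pass a seven-step QC cascade (N filter,
PhiX-like decoy, adapter + Q17 tail trimming, length ≥ 50, mean quality
> 25, host-like decoy, orphan removal), are assigned to genes by canonical
31-mer plurality voting, normalised to TPM
(`TPM_i = 10^6 (c_i/l_i) / Σ_j (c_j/l_j)`), summed per ortholog group, and
tested healthy-vs-case with the two-sided Wilcoxon rank-sum test and BH
FDR. Genus-level community analysis (Dirichlet–CLR Monte-Carlo
differential abundance, Bray-Curtis / PCoA / PERMANOVA, Shannon index,
Spearman score correlations), K2P + neighbor-joining phylogeny with
bootstrap supports, and the Y-maze alternation ratio round out the study's
statistical layer.

## Worked example

One call runs the whole synthetic pipeline — pan-genome with planted
strain-specific blocks, two-cohort metagenome, QC, quantification,
differential abundance:

```r
library(strainspec)
res <- run_all(list(
  pangenome = list(n_strains = 6, core_size = 20, accessory_size = 10),
  cohort    = list(group_sizes = c(healthy = 8, case = 6),
                   reads_per_sample = 4000)),
  seed = 7)

res$summary$n_consensus
#> [1] 4
res$blocks[res$blocks$n_genes > 1]
#>    strain start   end n_genes                     og_ids
#> 1:    S01    22    24       3 OG000022,OG000023,OG000024
#> 2:    S02     9    11       3 OG000022,OG000023,OG000024
res$da$results
#>       og_id median_ref median_case    log2fc            p           q significant
#> 1: OG000008   5856.511   2188.9720 -1.419788 0.0046620047 0.006216006        TRUE
#> 2: OG000022   8651.844   1608.8036 -2.427019 0.0006660007 0.001332001        TRUE
#> 3: OG000023   6417.133    916.3153 -2.808013 0.0117284785 0.011728479        TRUE
#> 4: OG000024   8152.819   1553.0647 -2.392181 0.0006660007 0.001332001        TRUE
```

The generator planted four ortholog groups shared exclusively by strains
S01 and S02 (three of them adjacent — visible as the 3-gene blocks in both
strains) and made those strains four-fold more abundant in the healthy
group. Both clustering methods recover the four groups (consensus = 4, no
method-exclusive calls), and all four are significantly higher in the
healthy cohort: `median_ref`/`median_case` are median TPM-derived
abundances in the healthy and case groups, `log2fc` ≈ −2 is the case/healthy
median log-ratio (1/4, the planted effect), and `p`/`q` are Wilcoxon and BH
values. QC accounting for the same run: 56,000 input reads, 49,432
surviving the cascade, with per-filter tallies in `res$qc`.

The `analysis/` scripts run the same stages at isolate scale (12 strains;
4 + 150 + 214 planted specific groups; 35 samples) as a narrative
workflow, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # pan-genome, cohort FASTQs, genus table, 16S
Rscript analysis/02_orthology.R     # edges, clusterings A/B, KO, localization
Rscript analysis/03_specificity.R   # calls, consensus, adjacency blocks
Rscript analysis/04_qc.R            # QC cascade + accounting report
Rscript analysis/05_quantify.R      # TPM and ortholog abundance
Rscript analysis/06_cohort_stats.R  # genus + ortholog statistics
Rscript analysis/07_phylogeny.R     # K2P + NJ + bootstrap
```

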