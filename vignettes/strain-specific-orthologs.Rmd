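---
title: "Strain-specific orthologs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-specific orthologs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(strainspec)
```

## The problem

When a few isolates of a bacterial species show an effect that their
conspecifics lack — here, cognitive-improvement activity of particular
*Faecalibacterium prausnitzii*-like strains in a dementia model — a natural
genomic explanation is gene content: ortholog groups carried only by the
effective strains. Two questions follow. First, which ortholog groups are
exclusive to a designated strain set within the species pan-genome? Second,
do those groups actually differ in abundance between human cohorts (healthy
versus mild cognitive impairment) when measured from shotgun metagenome
reads? `strainspec` implements both arms, the supporting community
statistics, an isolate phylogeny, and synthetic-data generators with
planted, machine-readable truth so that every stage can be validated end to
end without external data.

## Specific orthologs

An ortholog group is called *specific* to a target strain set if either

* **presence rule** — its member genes occur only in target strains and
  (by default, `require_all_targets = TRUE`) in *every* target strain, so
  the group's strain set equals the target set exactly; or
* **KO rule** — it contains a gene whose KO (KEGG Ortholog-style
  functional label) occurs, across all genes of all strains, only in genes
  of target strains (again covering every target strain).

The strict reading of the presence rule reflects the intended semantics of
"shared only by" a pair of strains: present in both, absent everywhere
else. The looser reading (members merely confined to the target set) is
available behind the flag because genuinely partial presence can be of
interest when screening candidate strain sets.

Calls are made independently under two clustering strategies and then
reconciled: a consensus item pairs a call from each method whose member
gene sets (restricted to target strains) overlap by Jaccard at least 0.5
(`jaccard_min`, exposed because no principled value exists — group
identity across clusterers is a matching problem, and 0.5 requires a
majority overlap while tolerating boundary genes). Calls with no partner
are reported as method-exclusive rather than dropped: a group significant
under one clusterer but not recoverable under the other is exactly the
kind of fragile finding a reader needs to see labeled.

Chromosomal context matters because strain-specific genes arrive by
horizontal transfer in islands: `find_adjacent_blocks()` reports maximal
runs of called groups whose member gene indices are consecutive in a
strain's annotation order (length-1 blocks included). Wraparound on
circular chromosomes is deliberately not treated as adjacency; annotation
order is linear and the generator plants linear runs.

## Ortholog clustering

Two transparent, independent strategies play the role that a pair of
established ortholog-finding tools plays in practice, because the scientific
contribution gated by them is the consensus/specificity logic, not the
clusterer internals:

* **Method A** — single-linkage components over similarity edges with
  identity ≥ 95% and both coverages ≥ 80%.
* **Method B** — connected components of the bidirectional-best-hit (BBH)
  graph: per ordered strain pair, an edge survives only if each gene is
  the other's best-scoring hit in that strain (ties broken toward the
  lexicographically smaller gene id, making results deterministic).
  Coverage is filtered first; no absolute identity threshold applies.

Similarity edges come from Smith–Waterman local alignment
(`Biostrings::pairwiseAlignment`) under unit scores (match +1, mismatch
−1, gap −2) after a shared-k-mer prefilter (15-mers for nucleotides,
5-mers for proteins; at least 3 and 2 distinct shared k-mers
respectively). The prefilter thresholds are set so that unrelated uniform
random sequences essentially never reach the aligner, while homologs
diverged by ≤ 10% always do.

Two properties of local alignment deserve explicit mention:

* **Identity is a per-alignment quantity.** The percent identity of the
  maximal-scoring local alignment of two *unrelated* proteins is high —
  typically a handful of perfectly matching residues — while its score and
  coverage are negligible. Identity alone therefore never gates anything
  in this package; every rule combines it with score and coverage.
* **Clustering runs on nucleotide sequences by default** (`seq_type`).
  At a per-copy substitution rate *r*, two copies of a gene diverge at
  ≈ 2*r* of nucleotide sites but ≈ 6*r*·0.76 of codons at the protein
  level, so a 95% identity threshold that comfortably separates orthologs
  from noise on nucleotides would sit inside the ortholog divergence band
  on proteins. Protein mode remains available and is what KO assignment
  uses.

KO labels are assigned from the best-scoring reference hit if and only if
that hit exceeds identity 40, score 70 and coverage 80 — all three
strictly ("greater than", not "at least"). Coverage is the minimum of
query and subject coverage: the conservative choice, recorded in the
output attributes, since a one-sided convention would let a short gene
fully covered by a fragment of a long reference pass.

Protein localization uses a hydropathy-window heuristic standing in for an
HMM predictor: predicted helices are maximal regions covered by 19-residue
windows whose mean Kyte–Doolittle hydropathy exceeds 1.6; one or more
helices ⇒ transmembrane; otherwise a run of ≥ 8 hydrophobic residues
within the first 30 ⇒ extracellular; otherwise intracellular. The window
of 19 matches a membrane-spanning helix; the cutoff 1.6 is the
conventional threshold for candidate transmembrane segments on that
scale. Calls on real proteins will not reproduce a trained predictor and
are labeled heuristic wherever they surface.

## The QC cascade

Shotgun reads pass seven filters, in this order: (1) any read containing
`N` is discarded; (2) reads matching the PhiX-like decoy are discarded;
(3) each mate is trimmed — 3′-anchored adapter removal (its own adapter
per mate, minimum overlap 32 nt, ≤ 10% mismatches in the overlap), then
removal of the maximal 3′ suffix whose Phred values are all ≤ 17; (4)
reads shorter than 50 bp are discarded; (5) reads with mean quality ≤ 25
are discarded ("25 or less", so exactly 25 fails); (6) reads matching the
host-like decoy are discarded; (7) reads whose mate was lost at any step
are discarded. Order is load-bearing and tested: a read whose raw mean
quality is below 25 only because of a bad tail is *kept*, because
trimming precedes the mean-quality test.

Decoy "mapping" is k-mer containment rather than alignment: a read
matches when at least ⌈(L−k+1)/2⌉ of its distinct canonical k-mers
(k = 21) occur in the decoy — deterministic, self-contained, and adequate
for planted contaminants, which are verbatim decoy substrings. The
packaged decoys are synthetic sequences (labeled as such in their
filenames), not the real PhiX or human genomes.

The accounting report preserves the conventions of sequencing-center
reports: base-pair totals for fixed-length stages are reads × nominal
read length, and per-sample averages are totals divided by sample count,
rounded half away from zero for display. Conservation (input = surviving
+ sum of per-filter discards) is asserted per sample and in aggregate.

## Quantification

Reads are assigned to genes by k-mer plurality voting against a canonical
31-mer index: each read votes for the gene(s) hit by the most of its
k-mers; exact ties split the read fractionally in equal parts; zero-hit
reads stay unassigned. There is no expectation-maximisation step — for
synthetic genes with low inter-gene similarity the plurality vote is
already unambiguous at the ortholog-group level (copies of the same group
may tie, but their shares aggregate back together). Paired mates are
assigned independently and each counts one.

Gene abundance is TPM: `rate = count / length`, `TPM = 1e6 · rate /
sum(rate)`, with effective length equal to the full gene length (no
fragment-length model is simulated, so none is corrected for). Ortholog
abundance is the *sum* of member-gene TPM (a mean option exists behind
`agg = "mean"`); summing keeps the per-sample mass interpretable — each
sample's ortholog row sums to the TPM assigned to clustered genes — and
matches the view of a group as one pangene measured through its copies.

For large simulation studies an in-memory fast path avoids materialising
read strings: because error-free reads are exact windows of indexed
genes, the voting outcome is a deterministic function of (gene, start),
and `position_assignment_map()` precomputes it once per genome with the
same C++ kernel (canonical k-mers make the outcome strand-invariant).
Tests assert count-level equality between the string, positional and
mapped paths.

## Statistics

* **Wilcoxon rank-sum** (two-sided) uses the exact null distribution when
  both groups have ≤ 25 observations and no ties, and the normal
  approximation with tie and continuity corrections otherwise; the exact
  branch is verified against full enumeration for all sizes up to 6 per
  group.
* **BH q values** via the standard step-up rule; monotonicity and `q ≥ p`
  are property-tested.
* **Spearman correlation** uses average ranks; for n ≤ 9 the p value is
  an exact permutation probability (which remains valid under ties),
  otherwise the t approximation.
* **Compositional differential abundance** re-implements the
  Dirichlet–CLR Monte-Carlo scheme: 128 instances (the conventional
  default for this family of methods) of per-sample compositions drawn
  from Dirichlet(counts + 0.5), CLR transform against the per-sample
  geometric mean, per-feature two-sided Wilcoxon per instance, and the
  *expected p* (mean over instances) reported, with BH q over features.
  Fold changes are log2 of case over reference median relative abundance,
  with half the smallest positive value as pseudo-abundance when a median
  is zero (the table gives no information below that scale).
  The expected-p aggregation is measurably conservative under the null:
  in the packaged calibration study (125 null tables of 40 genera,
  n = 20 vs 15, depth 30,000) the fraction of feature-tests below 0.05 is
  ≈ 0.04 rather than 0.05, with the deficit concentrated in low-count
  genera, whose Dirichlet jitter (relative scale ≈ 1/√count) smooths
  borderline p values upward. This mirrors the documented behaviour of
  the method family; the unsmoothed Wilcoxon on the same tables is
  calibrated (≈ 0.052), which the test suite also computes.
* **Community structure**: Bray–Curtis dissimilarity, PCoA by Gower
  double-centering (negative eigenvalues reported, never corrected
  silently), PERMANOVA with seeded label permutations (default 9,999;
  the null-uniformity study uses 999 per run, enough resolution for a
  Kolmogorov–Smirnov check over 500 runs), within-group distance
  comparisons by Wilcoxon, and Shannon–Wiener diversity in bits
  (base 2, the common amplicon-pipeline convention; `base` is a
  parameter).
* **Alternation ratio** for Y-maze sequences: consecutive triples
  visiting three distinct arms, divided by (entries − 2).

Significance is flagged at two-sided p < 0.05 throughout, with BH q
reported alongside rather than substituted.

## Phylogeny

Kimura 2-parameter distances with pairwise deletion of gap/`N` sites
(complete deletion would discard whole columns for a single ragged taxon);
saturation (1−2P−Q ≤ 0 or 1−2Q ≤ 0) raises an error rather than returning
a number. Neighbor-joining (via `ape::nj`) is exact on additive matrices —
property-tested on random trees — and negative branch estimates are
clamped to zero with a warning, the common convention. Bootstrap support
resamples alignment columns (default 1,000 replicates, seeded); replicates
whose resampled distances saturate are skipped and counted, and support is
the percentage of successful replicates containing each original split.

## The generators

`simulate_pangenome()` draws one ancestral gene per ortholog group —
codons sampled uniformly from the 61 sense codons, so translations are
valid proteins; lengths uniform over a configurable range, rounded to
codons — and copies it into every member strain with independent per-site
substitutions (substitutions that would create a premature stop are
reverted). Uniform sequences are deliberate: they make exact-matching
quantification and clustering analysable, at the cost of realism discussed
below. Three structural guarantees keep the planted truth identifiable:
accessory strain subsets that would coincide with a planted directive's
subset are redrawn; each planted block is laid out as a contiguous run;
and distinct planted units are separated by at least one non-planted gene
(violations of capacity raise an error instead of silently merging
blocks).

`simulate_metagenome_cohort()` draws paired 150-bp reads (the emulated
platform configuration) from a per-group strain mixture; by default the
target strains' weights differ by `effect_size` between groups (the study
condition is effect size 4 with cohorts of 20 and 15). Contaminants are
injected per read: decoy (PhiX-like/host-like) substrings, adapter
read-through (fragment shorter than the read, adapter running to the 3′
end), `N`-containing reads, and low-quality 3′ tails (a run of 10–60
bases at Phred ≤ 17). Base qualities come from a truncated normal (mean
35, sd 3, clipped to [2, 40]). Per-sample, per-gene read-origin counts and
contaminant counts are recorded; their sum is the read count by
construction.

`simulate_genus_table()` is a compositional model: per-genus log-normal
baselines (sd 1.5, giving the realistic skew of genus tables), per-sample
log-normal noise (sd 0.6), closure to proportions and multinomial
sampling at depth 30,000. Planted effects multiply a genus' latent mean
in the case group. The score covariate is coupled to one genus' latent
abundance at a target Spearman correlation via the bivariate-normal
identity r = 2 sin(πρ/6); count sampling attenuates the realized
correlation slightly, which the tests measure as a mean over seeds.

### What the synthetic data does not emulate

No sequencing errors (substitutions, indels, quality-dependent error
rates), no real genome structure (GC content, codon bias, repeats,
paralogs, operons, rearrangements, plasmids), no realistic evolutionary
process (uniform substitutions, no selection, star-shaped gene
genealogies), no fragment-length distribution, and no taxonomic
cross-mapping from non-target community members. Passing tests therefore
demonstrate that the *logic* of every stage is correct and that effect
sizes propagate end to end at the stated cohort sizes and depths — not
that thresholds tuned here transfer to real data, where clustering
identity bands, decoy thresholds and localization calls would all need
re-examination against the field's standard tools.

## Problem sizes used in the validation studies

The packaged studies run at: isolate scale — 12 strains, 120 core and 60
accessory groups plus 154 planted (4 shared by two strains, 3 of them
adjacent; 150 private to one strain as runs of 5 and 12 plus 133 isolated
genes), genes 300–600 nt, substitution rate 0.01; cohort scale — 20
healthy vs 15 case samples, 50,000 reads per sample, effect size 4, 200
seeded repetitions for the power study (a compact 12-strain backdrop keeps
the repeated runs economical; sample sizes, depth and effect size are the
study conditions and are never scaled); QC — 1,000 engineered reads
covering every filter branch, checked read-by-read against an independent
straight-line re-implementation of the seven rules; statistics — 5,000
null feature-tests for type-I calibration and 500 runs for PERMANOVA null
uniformity; phylogeny — 100 random additive matrices up to 8 taxa.

## Known limitations

The clusterers are stand-ins with transparent semantics, not
re-implementations of any published tool; k-mer decoy matching is not
alignment; the localization heuristic is not a trained HMM; quantification
has no multi-mapping EM; and the compositional test's expected-p
aggregation is conservative under the null, as quantified above. Each of
these is a deliberate trade for determinism and analysability and is
flagged in the relevant outputs.
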