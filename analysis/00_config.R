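# Shared settings for the analysis scripts.  Run the scripts in order from
# the repository root:  Rscript analysis/01_simulate.R  etc.
suppressMessages({
  library(strainspec)
  library(data.table)
})

SEED <- 2026L
OUT <- "results"
DATA <- file.path(OUT, "data")

# isolate-scale pan-genome: 12 strains; the two "effective" strains are
# S01 (Fp14-like: 150 private groups, runs of 5 and 12 among them) and
# S02 (Fp360-like: 214 private groups) sharing a further 4 groups (3
# adjacent); KO labels on the shared block allow the KO rule to fire
PANGENOME_SPEC <- function() pan_genome_spec(
  n_strains = 12, core_size = 120, accessory_size = 60,
  planted_specific = c(
    list(list(strains = c(1, 2), len = 3, ko_policy = "exclusive"),
         list(strains = c(1, 2), len = 1, ko_policy = "exclusive"),
         list(strains = 1, len = 5), list(strains = 1, len = 12)),
    rep(list(list(strains = 1, len = 1)), 133),          # rest of the 150
    rep(list(list(strains = 2, len = 5)), 30),           # 214 = 30x5 + 64
    rep(list(list(strains = 2, len = 1)), 64)),
  gene_length_range = c(300, 600), mutation_rate = 0.01, seed = SEED)

# two cohorts of paired 150-bp shotgun samples; the effective strains are
# four-fold enriched in the healthy group; every contaminant class injected
COHORT_SPEC <- function() cohort_sim_spec(
  group_sizes = c(healthy = 20L, case = 15L),
  reads_per_sample = 10000L, read_length = 150L,
  target_strains = c(1L, 2L), effect_size = 4,
  contaminant_fractions = c(phix = 0.02, host = 0.02, adapter = 0.02,
                            ncont = 0.02, lowq = 0.02),
  seed = SEED + 1L)

TARGET_PAIR <- c("S01", "S02")

dir.create(DATA, showWarnings = FALSE, recursive = TRUE)
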