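default_run_config <- function() {
  list(
    pangenome = list(n_strains = 12L, core_size = 30L, accessory_size = 40L,
                     mutation_rate = 0.01, gene_length_range = c(300, 900),
                     planted = list(
                       list(strains = c(1L, 2L), len = 3L,
                            ko_policy = "exclusive"),
                       list(strains = c(1L, 2L), len = 1L,
                            ko_policy = "exclusive"))),
    cohort = list(group_sizes = c(healthy = 10L, case = 8L),
                  reads_per_sample = 4000L, read_length = 150L,
                  target_strains = c(1L, 2L), effect_size = 4,
                  contaminant_fractions = c(phix = 0.02, host = 0.02,
                                            adapter = 0.02, ncont = 0.02,
                                            lowq = 0.02)),
    orthology = list(identity_threshold = 95, min_coverage = 80),
    qc = list(tail_quality_cutoff = 17L, min_length = 50L,
              min_mean_quality = 25, adapter_min_overlap = 32L),
    quantify = list(k = 31L),
    stats = list(alpha = 0.05),
    consensus = list(jaccard_min = 0.5)
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and out-of-range values, and
#' returns the normalised configuration (idempotent) with a content hash.
#'
#' @param config a nested list, or a path to a YAML file.
#' @return normalised configuration list with attribute `hash`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  def <- default_run_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stopf("unknown config section(s): %s",
                         paste(bad, collapse = ", "))
  errs <- character(0)
  out <- def
  for (sec in names(config)) {
    unknown <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(unknown))
      errs <- c(errs, sprintf("unknown key(s) in %s: %s", sec,
                              paste(unknown, collapse = ", ")))
    out[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  if (out$qc$tail_quality_cutoff < 0)
    errs <- c(errs, "qc$tail_quality_cutoff must be >= 0")
  if (out$qc$min_length < 1) errs <- c(errs, "qc$min_length must be >= 1")
  if (out$pangenome$n_strains < 2)
    errs <- c(errs, "pangenome$n_strains must be >= 2")
  if (out$cohort$effect_size <= 0)
    errs <- c(errs, "cohort$effect_size must be > 0")
  if (out$quantify$k < 1 || out$quantify$k > 31)
    errs <- c(errs, "quantify$k must be in 1..31")
  if (length(errs)) stopf("invalid configuration:\n  %s",
                          paste(errs, collapse = "\n  "))
  # canonical key order for a stable hash
  out <- out[sort(names(out))]
  out <- lapply(out, function(s) s[sort(names(s))])
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), tf)
  attr(out, "hash") <- unname(tools::md5sum(tf))
  out
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate a pan-genome with planted strain-specific blocks; cluster
#' orthologs with both methods; call specific orthologs and their
#' consensus; simulate the two-cohort metagenome; run QC; quantify gene TPM
#' and aggregate to ortholog abundance; test the called orthologs for
#' differential abundance between groups.
#'
#' @param config configuration (see [validate_config()]).
#' @param seed global seed; per-stage seeds are derived as `seed + stage
#'   counter` (documented scheme: pangenome +1, cohort +2, statistics +3).
#' @param out_dir optional directory for stage outputs (TSV/JSON).
#' @return list with stage results and a `summary` list.
#' @export
run_all <- function(config = list(), seed = 1L, out_dir = NULL) {
  cfg <- validate_config(config)
  seed <- as.integer(seed)
  pg_cfg <- cfg$pangenome
  spec <- pan_genome_spec(n_strains = pg_cfg$n_strains,
                          core_size = pg_cfg$core_size,
                          accessory_size = pg_cfg$accessory_size,
                          planted_specific = pg_cfg$planted,
                          gene_length_range = pg_cfg$gene_length_range,
                          mutation_rate = pg_cfg$mutation_rate,
                          seed = seed + 1L)
  pg <- simulate_pangenome(spec)
  strains <- vapply(pg$gene_sets, function(g) g$strain_id, character(1))
  target <- strains[cfg$cohort$target_strains]

  edges <- pairwise_similarity(pg$gene_sets)
  cl_a <- cluster_orthologs(edges, pg$gene_sets, "A",
                            cfg$orthology$identity_threshold,
                            cfg$orthology$min_coverage)
  cl_b <- cluster_orthologs(edges, pg$gene_sets, "B",
                            min_coverage = cfg$orthology$min_coverage)
  ko <- assign_ko(pg$gene_sets, pg$ko_reference)
  calls_a <- call_specific_orthologs(cl_a, target, strains, ko)
  calls_b <- call_specific_orthologs(cl_b, target, strains, ko)
  cons <- consensus_calls(calls_a, calls_b, cfg$consensus$jaccard_min)
  blocks <- find_adjacent_blocks(calls_a, pg$gene_sets)

  co_cfg <- cfg$cohort
  cspec <- cohort_sim_spec(group_sizes = co_cfg$group_sizes,
                           reads_per_sample = co_cfg$reads_per_sample,
                           read_length = co_cfg$read_length,
                           target_strains = co_cfg$target_strains,
                           effect_size = co_cfg$effect_size,
                           contaminant_fractions =
                             co_cfg$contaminant_fractions,
                           seed = seed + 2L)
  cohort <- simulate_metagenome_cohort(pg$gene_sets, cspec)

  qcfg <- filter_config(tail_quality_cutoff = cfg$qc$tail_quality_cutoff,
                        min_length = cfg$qc$min_length,
                        min_mean_quality = cfg$qc$min_mean_quality,
                        adapter_min_overlap = cfg$qc$adapter_min_overlap)
  qc_res <- lapply(cohort$reads, function(dt)
    qc_pipeline(dt[mate == 1L, .(id, seq, qual)],
                dt[mate == 2L, .(id, seq, qual)], qcfg))
  tallies <- data.table::rbindlist(lapply(qc_res, `[[`, "tally"))
  tallies[, sample := names(qc_res)]
  qc_summary <- qc_report_summary(tallies, co_cfg$read_length)

  index <- build_gene_index(pg$gene_sets, cfg$quantify$k)
  clean_reads <- lapply(qc_res, function(r)
    c(r$pairs$r1$seq, r$pairs$r2$seq))
  quant <- quantify_cohort(clean_reads, index, cl_a)

  called_a <- calls_a$calls$og_id
  da <- ortholog_da_report(quant$og_abundance, cohort$metadata$group,
                           reference = "healthy", og_subset = called_a,
                           alpha = cfg$stats$alpha)

  summary <- list(
    config_hash = attr(cfg, "hash"), seed = seed,
    n_strains = length(strains), target_set = target,
    n_calls_a = nrow(calls_a$calls), n_calls_b = nrow(calls_b$calls),
    n_consensus = nrow(cons$consensus),
    n_method_exclusive = nrow(cons$exclusive),
    adjacency_blocks = blocks,
    qc_totals = qc_summary$totals,
    n_significant = sum(da$results$significant))

  res <- list(pangenome = pg, clustering = list(A = cl_a, B = cl_b),
              ko = ko, calls = list(A = calls_a, B = calls_b),
              consensus = cons, blocks = blocks, cohort = cohort,
              qc = list(per_sample = qc_res, summary = qc_summary),
              quant = quant, da = da, summary = summary, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(calls_a$calls, file.path(out_dir, "calls_A.tsv"),
                       sep = "\t")
    data.table::fwrite(calls_b$calls, file.path(out_dir, "calls_B.tsv"),
                       sep = "\t")
    data.table::fwrite(cons$consensus, file.path(out_dir, "consensus.tsv"),
                       sep = "\t")
    data.table::fwrite(blocks, file.path(out_dir, "adjacency_blocks.tsv"),
                       sep = "\t")
    data.table::fwrite(da$results, file.path(out_dir, "ortholog_da.tsv"),
                       sep = "\t")
    data.table::fwrite(tallies, file.path(out_dir, "qc_tallies.tsv"),
                       sep = "\t")
    jsonlite::write_json(summary[setdiff(names(summary),
                                         "adjacency_blocks")],
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
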