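#' Pan-genome simulation specification
#'
#' Describes a synthetic pan-genome: a set of strains sharing a core gene
#' repertoire, a variably-present accessory ("shell") repertoire, and planted
#' strain-exclusive gene blocks whose identity is recorded as ground truth.
#'
#' @param n_strains number of strains (>= 2).
#' @param core_size number of ortholog groups present in every strain.
#' @param accessory_size number of non-planted accessory ortholog groups,
#'   each present in a random proper subset (>= 2 strains).  Subsets that
#'   would coincide with a planted directive's strain subset are redrawn so
#'   the planted truth stays identifiable.
#' @param planted_specific list of directives, each a list with elements
#'   `strains` (integer indices of the member strains), `len` (number of
#'   consecutive genes in the block) and optional `ko_policy`
#'   (`"exclusive"`: each planted group receives its own KO label;
#'   `"none"`: no KO).
#' @param gene_length_range nucleotide length bounds; lengths are drawn
#'   uniformly and rounded to codon multiples.
#' @param mutation_rate per-site substitution probability applied
#'   independently to each strain's copy of a group's ancestral gene
#'   (in `[0, 0.2]`).  Substitutions that would create a premature stop
#'   codon are reverted so translations stay valid.
#' @param core_ko_fraction fraction of core groups given a (shared) KO label.
#' @param seed RNG seed.
#' @return object of class `pan_genome_spec`.
#' @export
pan_genome_spec <- function(n_strains, core_size, accessory_size = 0,
                            planted_specific = list(),
                            gene_length_range = c(300, 900),
                            mutation_rate = 0.01,
                            core_ko_fraction = 0.5,
                            seed = 1L) {
  if (n_strains < 2) stopf("n_strains must be >= 2")
  if (core_size < 0 || accessory_size < 0) stopf("sizes must be non-negative")
  if (mutation_rate < 0 || mutation_rate > 0.2)
    stopf("mutation_rate must be in [0, 0.2]")
  if (gene_length_range[1] < 60 || gene_length_range[2] < gene_length_range[1])
    stopf("invalid gene_length_range")
  for (d in planted_specific) {
    if (is.null(d$strains) || length(d$strains) == 0)
      stopf("every planted directive needs a non-empty strain subset")
    if (any(d$strains < 1 | d$strains > n_strains))
      stopf("planted strain subset outside 1..n_strains")
    if (is.null(d$len) || d$len < 1) stopf("planted block length must be >= 1")
  }
  structure(list(n_strains = n_strains, core_size = core_size,
                 accessory_size = accessory_size,
                 planted_specific = planted_specific,
                 gene_length_range = gene_length_range,
                 mutation_rate = mutation_rate,
                 core_ko_fraction = core_ko_fraction,
                 seed = as.integer(seed)),
            class = "pan_genome_spec")
}

#' One strain's ordered gene set
#'
#' @param strain_id strain identifier.
#' @param genes data.table with columns `gene_index` (1-based chromosomal
#'   order, strictly increasing), `gene_id`, `nt` (nucleotide sequence) and
#'   `aa` (protein sequence).
#' @return object of class `strain_gene_set`.
#' @export
strain_gene_set <- function(strain_id, genes) {
  genes <- data.table::as.data.table(genes)
  req <- c("gene_index", "gene_id", "nt", "aa")
  if (!all(req %in% names(genes))) stopf("genes must have columns %s",
                                         paste(req, collapse = ", "))
  if (is.unsorted(genes$gene_index, strictly = TRUE))
    stopf("gene_index must be strictly increasing")
  if (any(!nzchar(genes$nt)) || any(!nzchar(genes$aa)))
    stopf("sequences must be non-empty")
  structure(list(strain_id = strain_id, genes = genes),
            class = "strain_gene_set")
}

#' @export
print.strain_gene_set <- function(x, ...) {
  cat(sprintf("<strain_gene_set> %s: %d genes\n", x$strain_id,
              nrow(x$genes)))
  invisible(x)
}

random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# mutate a CDS at per-site rate; substitutions creating stops are reverted
mutate_cds <- function(nt, rate) {
  if (rate <= 0) return(nt)
  n <- nchar(nt)
  hits <- which(runif(n) < rate)
  if (length(hits) == 0) return(nt)
  chars <- strsplit(nt, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hits) {
    old <- chars[i]
    chars[i] <- sample_one(setdiff(bases, old))
    cstart <- 3L * ((i - 1L) %/% 3L) + 1L
    codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
    if (is_stop_codon(codon)) chars[i] <- old
  }
  paste(chars, collapse = "")
}

#' Simulate a pan-genome with planted strain-specific blocks
#'
#' Generates one ancestral gene per ortholog group, copies it (with
#' independent per-strain substitutions) into every member strain, and lays
#' the genes out on each strain's chromosome so that every planted block is
#' a run of consecutive genes separated from other planted material by at
#' least one non-planted gene.
#'
#' @param spec a [pan_genome_spec()].
#' @return list with elements
#'   `gene_sets` (list of [strain_gene_set()]),
#'   `truth` (list: `og_membership` data.table (og_id, strain, gene_id,
#'   gene_index), `planted_specific_ids`, `planted_by_directive`,
#'   `ko_truth` (strain, gene_id, ko), `adjacency_blocks` (strain, start,
#'   end, og_ids)), and
#'   `ko_reference` (data.table ko, protein: one ancestral protein per KO).
#' @export
simulate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "pan_genome_spec"))
  withr::with_seed(spec$seed, simulate_pangenome_impl(spec))
}

simulate_pangenome_impl <- function(spec) {
  ns <- spec$n_strains
  strains <- sprintf("S%02d", seq_len(ns))
  lr <- spec$gene_length_range

  directive_sets <- lapply(spec$planted_specific,
                           function(d) sort(unique(d$strains)))

  og <- list()   # per OG: list(og_id, members (strain idx), planted, directive, ko)
  next_ko <- 1L
  add_og <- function(members, planted, directive = NA_integer_, ko = NA_character_) {
    og[[length(og) + 1L]] <<- list(members = members, planted = planted,
                                   directive = directive, ko = ko)
  }
  for (i in seq_len(spec$core_size)) {
    ko <- NA_character_
    if (runif(1) < spec$core_ko_fraction) {
      ko <- sprintf("K%05d", next_ko); next_ko <- next_ko + 1L
    }
    add_og(seq_len(ns), planted = FALSE, ko = ko)
  }
  for (i in seq_len(spec$accessory_size)) {
    repeat {
      m <- sample.int(ns - 1L, 1L) + 1L            # 2 .. n_strains
      members <- sort(sample.int(ns, min(m, ns)))
      clash <- any(vapply(directive_sets, function(s) identical(s, members),
                          logical(1)))
      if (!clash) break
    }
    add_og(members, planted = FALSE)
  }
  for (di in seq_along(spec$planted_specific)) {
    d <- spec$planted_specific[[di]]
    pol <- d$ko_policy %||% "none"
    for (j in seq_len(d$len)) {
      ko <- NA_character_
      if (identical(pol, "exclusive")) {
        ko <- sprintf("K%05d", next_ko); next_ko <- next_ko + 1L
      }
      add_og(sort(unique(d$strains)), planted = TRUE, directive = di, ko = ko)
    }
  }

  n_og <- length(og)
  og_ids <- sprintf("TOG%05d", seq_len(n_og))
  n_codons <- pmax(20L, round(runif(n_og, lr[1], lr[2]) / 3))
  ancestral_nt <- vapply(n_codons, random_cds, character(1))
  ancestral_aa <- translate_cds(ancestral_nt)

  # per-strain unit layout: planted blocks stay contiguous, separated by
  # non-planted genes
  planted_by_dir <- split(seq_len(n_og),
                          vapply(og, function(o) o$directive, integer(1)))
  planted_by_dir[["NA"]] <- NULL

  gene_sets <- vector("list", ns)
  membership <- vector("list", ns)
  for (si in seq_len(ns)) {
    non_planted <- which(vapply(og, function(o) !o$planted && si %in% o$members,
                                logical(1)))
    blocks <- Filter(function(idx) si %in% og[[idx[1]]]$members,
                     planted_by_dir)
    nb <- length(blocks)
    if (nb > 0 && length(non_planted) < nb - 1L)
      stopf(paste("planted blocks exceed accessory capacity: strain %s has",
                  "%d planted blocks but only %d non-planted genes to",
                  "separate them"), strains[si], nb, length(non_planted))
    sep <- sample(non_planted)
    units <- list()
    if (nb == 0) {
      units <- as.list(sep)
    } else {
      # separators between blocks; remaining non-planted genes appended
      blocks <- blocks[sample.int(nb)]
      filler <- if (length(sep) > nb - 1L) sep[nb:length(sep)] else integer(0)
      # distribute filler genes into the nb+1 outer/inner gaps at random
      gap_of <- if (length(filler)) sample.int(nb + 1L, length(filler),
                                               replace = TRUE) else integer(0)
      for (g in seq_len(nb + 1L)) {
        units <- c(units, as.list(filler[gap_of == g]))
        if (g <= nb) {
          if (g > 1L) units <- c(units, as.list(sep[g - 1L]))  # guaranteed separator
          units <- c(units, list(unlist(blocks[[g]])))
        }
      }
    }
    ord <- unlist(units)
    n_genes <- length(ord)
    gene_ids <- sprintf("%s_g%04d", strains[si], seq_len(n_genes))
    nt <- vapply(ord, function(oi)
      mutate_cds(ancestral_nt[oi], spec$mutation_rate), character(1))
    aa <- translate_cds(nt)
    genes <- data.table::data.table(gene_index = seq_len(n_genes),
                                    gene_id = gene_ids, nt = nt, aa = aa)
    gene_sets[[si]] <- strain_gene_set(strains[si], genes)
    membership[[si]] <- data.table::data.table(
      og_id = og_ids[ord], strain = strains[si], gene_id = gene_ids,
      gene_index = seq_len(n_genes))
  }
  og_membership <- data.table::rbindlist(membership)

  planted_idx <- which(vapply(og, function(o) o$planted, logical(1)))
  planted_ids <- og_ids[planted_idx]
  planted_by_directive <- lapply(planted_by_dir, function(idx) og_ids[idx])

  ko_of_og <- vapply(og, function(o) o$ko, character(1))
  ko_truth <- og_membership[
    data.table::data.table(og_id = og_ids, ko = ko_of_og), on = "og_id"
  ][!is.na(ko), .(strain, gene_id, ko)]

  # adjacency blocks: per strain, each planted directive block's index run
  blk <- og_membership[og_id %in% planted_ids]
  blk[, directive := vapply(og[match(og_id, og_ids)],
                            function(o) o$directive, integer(1))]
  adjacency_blocks <- blk[, .(start = min(gene_index), end = max(gene_index),
                              og_ids = paste(og_id[order(gene_index)],
                                             collapse = ",")),
                          by = .(strain, directive)]

  ko_ref <- data.table::data.table(ko = ko_of_og, protein = ancestral_aa)
  ko_ref <- ko_ref[!is.na(ko)]

  list(gene_sets = gene_sets,
       truth = list(og_membership = og_membership,
                    planted_specific_ids = planted_ids,
                    planted_by_directive = planted_by_directive,
                    ko_truth = ko_truth,
                    adjacency_blocks = adjacency_blocks),
       ko_reference = ko_ref)
}

#' Read strain gene sets written by [write_gene_sets()]
#'
#' @param dir directory holding `<strain>_nt.fasta`, `<strain>_aa.fasta`
#'   and `<strain>_genes.tsv` per strain.
#' @return list of [strain_gene_set()].
#' @export
read_gene_sets <- function(dir) {
  tsvs <- sort(list.files(dir, pattern = "_genes\\.tsv$", full.names = TRUE))
  if (length(tsvs) == 0) stopf("no gene tables found in %s", dir)
  lapply(tsvs, function(f) {
    strain <- sub("_genes\\.tsv$", "", basename(f))
    tab <- data.table::fread(f)
    nt <- Biostrings::readDNAStringSet(file.path(dir, paste0(strain,
                                                             "_nt.fasta")))
    aa <- Biostrings::readAAStringSet(file.path(dir, paste0(strain,
                                                            "_aa.fasta")))
    tab[, nt := as.character(nt[gene_id])]
    tab[, aa := as.character(aa[gene_id])]
    strain_gene_set(strain, tab)
  })
}

#' Write strain gene sets to FASTA + gene-table TSV
#'
#' One nucleotide FASTA, one protein FASTA and one gene-order TSV per strain.
#'
#' @param gene_sets list of [strain_gene_set()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_gene_sets <- function(gene_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gs in gene_sets) {
    nt <- Biostrings::DNAStringSet(setNames(gs$genes$nt, gs$genes$gene_id))
    aa <- Biostrings::AAStringSet(setNames(gs$genes$aa, gs$genes$gene_id))
    Biostrings::writeXStringSet(nt, file.path(dir, paste0(gs$strain_id, "_nt.fasta")))
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(gs$strain_id, "_aa.fasta")))
    data.table::fwrite(gs$genes[, .(gene_index, gene_id)],
                       file.path(dir, paste0(gs$strain_id, "_genes.tsv")),
                       sep = "\t")
  }
  invisible(dir)
}
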