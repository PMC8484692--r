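#' Cohort metagenome simulation specification
#'
#' Two cohorts of paired-end shotgun samples drawn from a strain mixture
#' that differs between groups, plus injected contaminant reads exercising
#' every branch of the QC cascade.
#'
#' @param group_sizes named integer vector `c(healthy = ..., case = ...)`.
#' @param reads_per_sample total reads per sample (both mates counted; even).
#' @param read_length read length in bases (default 150, the platform
#'   configuration emulated here).
#' @param target_strains indices of the strains whose mixture weight differs
#'   between groups (used when `strain_mixtures` is not given).
#' @param effect_size ratio of each target strain's mixture weight in the
#'   healthy group over the case group.
#' @param strain_mixtures optional list with elements `healthy` and `case`,
#'   each a probability vector over strains (sums to 1).  Overrides
#'   `target_strains`/`effect_size`.
#' @param contaminant_fractions named vector with entries `phix`, `host`,
#'   `adapter`, `ncont`, `lowq`, each in `[0,1]`, summing to < 1: the
#'   per-read probabilities of being a PhiX-like decoy read, a host-like
#'   decoy read, an adapter read-through, an N-containing read, or a read
#'   with a low-quality 3' tail.
#' @param quality_mean,quality_sd per-base Phred model: values are drawn
#'   from a normal truncated to `[2, 40]`.
#' @param seed RNG seed.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(group_sizes = c(healthy = 20L, case = 15L),
                            reads_per_sample = 10000L,
                            read_length = 150L,
                            target_strains = c(1L, 2L),
                            effect_size = 4,
                            strain_mixtures = NULL,
                            contaminant_fractions = c(phix = 0, host = 0,
                                                      adapter = 0, ncont = 0,
                                                      lowq = 0),
                            quality_mean = 35, quality_sd = 3,
                            seed = 1L) {
  if (any(group_sizes < 1)) stopf("group sizes must be positive")
  if (reads_per_sample < 2 || reads_per_sample %% 2L != 0L)
    stopf("reads_per_sample must be a positive even count")
  if (read_length < 50) stopf("read_length must be >= 50")
  cf <- c(phix = 0, host = 0, adapter = 0, ncont = 0, lowq = 0)
  cf[names(contaminant_fractions)] <- contaminant_fractions
  if (any(cf < 0) || any(cf > 1) || sum(cf) >= 1)
    stopf("contaminant fractions must lie in [0,1] and sum to < 1")
  if (!is.null(strain_mixtures)) {
    for (m in strain_mixtures)
      if (abs(sum(m) - 1) > 1e-8) stopf("each strain mixture must sum to 1")
  }
  structure(list(group_sizes = group_sizes,
                 reads_per_sample = as.integer(reads_per_sample),
                 read_length = as.integer(read_length),
                 target_strains = target_strains,
                 effect_size = effect_size,
                 strain_mixtures = strain_mixtures,
                 contaminant_fractions = cf,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# healthy/case mixtures from target strains and effect size
default_mixtures <- function(n_strains, target, effect_size) {
  nt <- length(target)
  stopifnot(nt >= 1, nt < n_strains)
  # case weight w for targets, healthy weight effect_size * w; the remaining
  # strains share the rest uniformly within each group
  w_case <- 0.25 / (nt * effect_size)   # targets get 25% of healthy mass
  w_healthy <- effect_size * w_case
  mk <- function(wt) {
    m <- rep((1 - nt * wt) / (n_strains - nt), n_strains)
    m[target] <- wt
    m
  }
  list(healthy = mk(w_healthy), case = mk(w_case))
}

# packaged synthetic decoy sequences (not real PhiX / human)
#' Load the packaged synthetic decoy sequences
#' @param which `"phix"` or `"host"`.
#' @return character scalar (the decoy sequence).
#' @export
decoy_sequence <- function(which = c("phix", "host")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("synthetic_%s_decoy.fasta", which),
                   package = "strainspec", mustWork = TRUE)
  as.character(Biostrings::readDNAStringSet(f))[[1]]
}

truncnorm_phred <- function(n, mean, sd) {
  pmin(40L, pmax(2L, as.integer(round(rnorm(n, mean, sd)))))
}

# build n quality strings of length len in one pass
quality_strings <- function(n, len, mean, sd) {
  q <- truncnorm_phred(n * len, mean, sd)
  all <- rawToChar(as.raw(q + 33L))
  substring(all, (seq_len(n) - 1L) * len + 1L, seq_len(n) * len)
}

#' Simulate a two-cohort paired-end shotgun metagenome
#'
#' Clean reads are exact substrings of the strains' gene sequences, drawn
#' according to the sample's group mixture; contaminant reads are injected
#' at the configured fractions.  Per-sample, per-gene read-origin counts are
#' recorded as ground truth.
#'
#' @param gene_sets list of [strain_gene_set()].
#' @param spec a [cohort_sim_spec()].
#' @param out_dir if non-NULL, gzipped FASTQ pairs
#'   (`<sample>_1.fastq.gz`, `<sample>_2.fastq.gz`) and a metadata TSV are
#'   written there; reads are always also returned in memory unless
#'   `keep_reads = FALSE`.
#' @param keep_reads return per-sample read tables (id, seq, qual, mate).
#' @return list with `metadata` (sample, group), `truth` (list per sample:
#'   `gene_counts` named vector, `contaminants` named vector), `reads`
#'   (per-sample data.tables, if kept) and `files` (if written).
#' @export
simulate_metagenome_cohort <- function(gene_sets, spec, out_dir = NULL,
                                       keep_reads = TRUE) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (length(gene_sets) == 0) stopf("gene_sets must be non-empty")
  withr::with_seed(spec$seed,
                   simulate_cohort_impl(gene_sets, spec, out_dir, keep_reads))
}

simulate_cohort_impl <- function(gene_sets, spec, out_dir, keep_reads) {
  ns <- length(gene_sets)
  mix <- spec$strain_mixtures %||%
    default_mixtures(ns, spec$target_strains, spec$effect_size)
  if (length(mix$healthy) != ns || length(mix$case) != ns)
    stopf("mixture length must equal number of strains")
  rl <- spec$read_length

  # flatten genes; only genes long enough to yield a full-length read are
  # eligible read sources
  genes <- data.table::rbindlist(lapply(gene_sets, function(gs)
    data.table::data.table(strain = gs$strain_id, gene_id = gs$genes$gene_id,
                           nt = gs$genes$nt, len = nchar(gs$genes$nt))))
  genes[, eligible := len >= rl]
  if (!any(genes$eligible)) stopf("no gene is long enough to source reads")
  strain_ids <- vapply(gene_sets, function(g) g$strain_id, character(1))

  # per-strain gene sampling weights (uniform coverage: weight by the number
  # of admissible start positions)
  gw <- lapply(seq_len(ns), function(si) {
    idx <- which(genes$strain == strain_ids[si] & genes$eligible)
    w <- genes$len[idx] - rl + 1
    list(idx = idx, w = w / sum(w))
  })

  cf <- spec$contaminant_fractions
  phix <- decoy_sequence("phix"); host <- decoy_sequence("host")
  adapter_fwd <- qc_default_adapters()[["fwd"]]
  adapter_rev <- qc_default_adapters()[["rev"]]

  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  samples <- sprintf("%s%02d", ifelse(groups == names(spec$group_sizes)[1],
                                      "H", "C"),
                     unlist(lapply(spec$group_sizes, seq_len)))
  metadata <- data.table::data.table(sample = samples, group = groups)

  n_reads <- spec$reads_per_sample
  npairs <- n_reads %/% 2L
  truth <- vector("list", length(samples))
  reads_out <- if (keep_reads) vector("list", length(samples)) else NULL
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
  }

  cat_levels <- c("clean", "phix", "host", "adapter", "ncont", "lowq")
  probs <- c(1 - sum(cf), cf["phix"], cf["host"], cf["adapter"],
             cf["ncont"], cf["lowq"])

  for (k in seq_along(samples)) {
    m <- mix[[groups[k]]]
    # pair origin: strain then gene (both mates from the same gene)
    strain_of_pair <- sample.int(ns, npairs, replace = TRUE, prob = m)
    gene_of_pair <- integer(npairs)
    for (si in unique(strain_of_pair)) {
      sel <- strain_of_pair == si
      gene_of_pair[sel] <- gw[[si]]$idx[
        sample.int(length(gw[[si]]$idx), sum(sel), replace = TRUE,
                   prob = gw[[si]]$w)]
    }
    gidx <- rep(gene_of_pair, each = 2L)           # mate-level gene origin
    mate <- rep(c(1L, 2L), npairs)
    category <- sample(cat_levels, n_reads, replace = TRUE, prob = probs)

    glen <- genes$len[gidx]
    start <- 1L + floor(runif(n_reads) * (glen - rl + 1))
    seqs <- substring(genes$nt[gidx], start, start + rl - 1L)
    # mate 1 on a random strand, mate 2 on the opposite strand
    flip1 <- rep(runif(npairs) < 0.5, each = 2L) == (mate == 1L)
    seqs[flip1] <- revcomp(seqs[flip1])

    quals <- quality_strings(n_reads, rl, spec$quality_mean, spec$quality_sd)

    is_phix <- category == "phix"; is_host <- category == "host"
    for (dd in list(list(is_phix, phix), list(is_host, host))) {
      sel <- dd[[1]]
      if (!any(sel)) next
      dl <- nchar(dd[[2]])
      st <- 1L + floor(runif(sum(sel)) * (dl - rl + 1))
      ds <- substring(dd[[2]], st, st + rl - 1L)
      rc <- runif(sum(sel)) < 0.5
      ds[rc] <- revcomp(ds[rc])
      seqs[sel] <- ds
    }
    sel <- category == "adapter"
    if (any(sel)) {
      # read-through: fragment shorter than the read, adapter runs to the end
      ad <- ifelse(mate[sel] == 1L, adapter_fwd, adapter_rev)
      frag_choices <- seq(rl - nchar(adapter_fwd), rl - 32L)
      frag <- frag_choices[sample.int(length(frag_choices), sum(sel),
                                      replace = TRUE)]
      seqs[sel] <- paste0(substring(seqs[sel], 1L, frag),
                          substring(ad, 1L, rl - frag))
    }
    sel <- which(category == "ncont")
    if (length(sel)) {
      nn <- sample.int(3L, length(sel), replace = TRUE)
      for (i in seq_along(sel)) {
        pos <- sample.int(rl, nn[i])
        s <- seqs[sel[i]]
        for (p in pos) substr(s, p, p) <- "N"
        seqs[sel[i]] <- s
      }
    }
    sel <- which(category == "lowq")
    if (length(sel)) {
      tl <- sample(10:60, length(sel), replace = TRUE)
      for (i in seq_along(sel)) {
        q <- string_to_phred(quals[sel[i]])
        tail_idx <- (rl - tl[i] + 1L):rl
        q[tail_idx] <- sample(2:17, tl[i], replace = TRUE)
        quals[sel[i]] <- phred_to_string(q)
      }
    }

    ids <- sprintf("%s_p%06d", samples[k], rep(seq_len(npairs), each = 2L))
    # truth: gene-origin counts for gene-derived reads, decoys separately
    gene_derived <- !(is_phix | is_host)
    gc <- tabulate(gidx[gene_derived], nbins = nrow(genes))
    names(gc) <- genes$gene_id
    truth[[k]] <- list(gene_counts = gc,
                       contaminants = c(phix = sum(is_phix),
                                        host = sum(is_host)))

    dt <- data.table::data.table(id = ids, mate = mate, seq = seqs,
                                 qual = quals, category = category)
    if (keep_reads) reads_out[[k]] <- dt
    if (!is.null(out_dir)) {
      f1 <- file.path(out_dir, paste0(samples[k], "_1.fastq.gz"))
      f2 <- file.path(out_dir, paste0(samples[k], "_2.fastq.gz"))
      write_fastq(dt[mate == 1L], f1, mate = 1L)
      write_fastq(dt[mate == 2L], f2, mate = 2L)
      files[[samples[k]]] <- c(f1, f2)
    }
  }
  names(truth) <- samples
  if (keep_reads) names(reads_out) <- samples
  if (!is.null(out_dir))
    data.table::fwrite(metadata, file.path(out_dir, "metadata.tsv"), sep = "\t")

  list(metadata = metadata, truth = truth, reads = reads_out, files = files,
       mixtures = mix, genes = genes[, .(strain, gene_id, len)])
}

#' Draw read positions only (contaminant-free fast path)
#'
#' For large simulation studies: returns, per sample, the (gene, start)
#' origin of every read instead of materialised sequences.  Only valid when
#' all contaminant fractions are zero; reads are exact gene substrings, so
#' the positional representation carries the same information.
#'
#' @inheritParams simulate_metagenome_cohort
#' @return list with `metadata`, `genes` (flattened gene table) and
#'   `positions` (per sample: data.table gene (row index into `genes`),
#'   start).
#' @export
simulate_cohort_positions <- function(gene_sets, spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (sum(spec$contaminant_fractions) > 0)
    stopf("positional simulation requires all contaminant fractions zero")
  withr::with_seed(spec$seed, {
    ns <- length(gene_sets)
    mix <- spec$strain_mixtures %||%
      default_mixtures(ns, spec$target_strains, spec$effect_size)
    rl <- spec$read_length
    genes <- data.table::rbindlist(lapply(gene_sets, function(gs)
      data.table::data.table(strain = gs$strain_id,
                             gene_id = gs$genes$gene_id,
                             len = nchar(gs$genes$nt))))
    strain_ids <- vapply(gene_sets, function(g) g$strain_id, character(1))
    gw <- lapply(seq_len(ns), function(si) {
      idx <- which(genes$strain == strain_ids[si] & genes$len >= rl)
      w <- genes$len[idx] - rl + 1
      list(idx = idx, w = w / sum(w))
    })
    groups <- rep(names(spec$group_sizes), spec$group_sizes)
    samples <- sprintf("%s%02d",
                       ifelse(groups == names(spec$group_sizes)[1], "H", "C"),
                       unlist(lapply(spec$group_sizes, seq_len)))
    n_reads <- spec$reads_per_sample
    positions <- vector("list", length(samples))
    for (k in seq_along(samples)) {
      m <- mix[[groups[k]]]
      strain_of <- sample.int(ns, n_reads, replace = TRUE, prob = m)
      gidx <- integer(n_reads)
      for (si in unique(strain_of)) {
        sel <- strain_of == si
        gidx[sel] <- gw[[si]]$idx[
          sample.int(length(gw[[si]]$idx), sum(sel), replace = TRUE,
                     prob = gw[[si]]$w)]
      }
      start <- 1L + floor(runif(n_reads) * (genes$len[gidx] - rl + 1))
      positions[[k]] <- data.table::data.table(gene = gidx,
                                               start = as.integer(start))
    }
    names(positions) <- samples
    list(metadata = data.table::data.table(sample = samples, group = groups),
         genes = genes, positions = positions, mixtures = mix)
  })
}

#' Write a read table as gzipped FASTQ (Phred+33)
#' @param reads data.table with columns id, seq, qual.
#' @param path output path (`.gz`).
#' @param mate mate number appended to ids as `/1` or `/2` (NULL: none).
#' @export
write_fastq <- function(reads, path, mate = NULL) {
  suffix <- if (is.null(mate)) "" else paste0("/", mate)
  rec <- paste0("@", reads$id, suffix, "\n", reads$seq, "\n+\n", reads$qual)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Read a FASTQ file into a data.table
#' @param path FASTQ path (possibly gzipped).
#' @return data.table with columns id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(x))
  ids <- sub("/[12]$", "", ids)
  data.table::data.table(id = ids,
                         seq = as.character(x),
                         qual = as.character(Biostrings::quality(x)))
}
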