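#' Default adapter sequences for the QC cascade
#'
#' The forward/reverse adapter-and-primer sequences trimmed from shotgun
#' reads (3'-anchored, minimum overlap 32).
#'
#' @return named character vector `c(fwd = ..., rev = ...)`.
#' @export
qc_default_adapters <- function() {
  c(fwd = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    rev = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")
}

#' QC filter configuration
#'
#' Parameters of the seven-step shotgun-read quality-control cascade:
#' (1) discard reads containing `N`; (2) discard reads matching the
#' PhiX-like decoy; (3) trim adapters (3'-anchored, minimum overlap 32) and
#' cut 3' tails of consecutive quality <= 17; (4) discard reads shorter
#' than 50 bp; (5) discard reads with mean quality <= 25; (6) discard reads
#' matching the host-like decoy; (7) discard reads whose mate was discarded.
#'
#' @param adapter_fwd,adapter_rev adapters for mate 1 / mate 2.
#' @param adapter_min_overlap minimum 3' overlap (both mates; default 32).
#' @param adapter_max_mismatch_frac mismatch tolerance in the overlap.
#' @param tail_quality_cutoff Phred cutoff for 3' tail cutting (<= 17).
#' @param min_length minimum post-trim read length (reads < 50 discarded).
#' @param min_mean_quality reads with mean quality <= this are discarded.
#' @param decoy_phix,decoy_host decoy sequences (character vectors) or paths
#'   to FASTA files; NULL loads the packaged synthetic decoys.
#' @param decoy_k k-mer length for decoy matching.
#' @param decoy_min_frac a read matches a decoy when its distinct k-mer hits
#'   reach `ceiling(decoy_min_frac * n_kmers)` (default half).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(adapter_fwd = qc_default_adapters()[["fwd"]],
                          adapter_rev = qc_default_adapters()[["rev"]],
                          adapter_min_overlap = 32L,
                          adapter_max_mismatch_frac = 0.1,
                          tail_quality_cutoff = 17L,
                          min_length = 50L,
                          min_mean_quality = 25,
                          decoy_phix = NULL, decoy_host = NULL,
                          decoy_k = 21L, decoy_min_frac = 0.5) {
  if (tail_quality_cutoff < 0 || min_length < 1 || min_mean_quality < 0 ||
      adapter_min_overlap < 1 || decoy_k < 1)
    stopf("cutoffs must be positive")
  load_decoy <- function(x, which) {
    if (is.null(x)) return(decoy_sequence(which))
    if (length(x) == 1 && file.exists(x))
      return(as.character(Biostrings::readDNAStringSet(x)))
    x
  }
  structure(list(adapter_fwd = adapter_fwd, adapter_rev = adapter_rev,
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_mismatch_frac = adapter_max_mismatch_frac,
                 tail_quality_cutoff = as.integer(tail_quality_cutoff),
                 min_length = as.integer(min_length),
                 min_mean_quality = min_mean_quality,
                 decoy_phix = load_decoy(decoy_phix, "phix"),
                 decoy_host = load_decoy(decoy_host, "host"),
                 decoy_k = as.integer(decoy_k),
                 decoy_min_frac = decoy_min_frac),
            class = "filter_config")
}

#' Trim one or more reads at the 3' end
#'
#' Adapter removal (longest 3'-anchored overlap of at least `min_overlap`
#' with at most 10% mismatches) followed by cutting the maximal 3' suffix
#' whose quality values are all <= `q_cutoff`.  Idempotent.
#'
#' @param seq,qual character vectors (sequences and Phred+33 qualities).
#' @param adapter adapter sequence.
#' @param min_overlap minimum overlap.
#' @param q_cutoff tail quality cutoff.
#' @param max_mismatch_frac allowed mismatch fraction in the overlap.
#' @return list with `seq`, `qual` (trimmed) and `mean_q`.
#' @export
trim_read_3prime <- function(seq, qual, adapter, min_overlap = 32L,
                             q_cutoff = 17L, max_mismatch_frac = 0.1) {
  if (q_cutoff < 0) stopf("q_cutoff must be >= 0")
  ts <- qc_trim_stats(seq, qual, adapter, as.integer(min_overlap),
                      max_mismatch_frac, as.integer(q_cutoff), 33L)
  list(seq = substring(seq, 1L, ts$trim_len),
       qual = substring(qual, 1L, ts$trim_len),
       mean_q = ts$mean_q)
}

#' Match reads against a decoy sequence set by k-mer containment
#'
#' A stand-in for alignment-based decoy mapping: a read matches when at
#' least `T` of its distinct k-mers (either strand) occur in the decoy,
#' with `T = ceiling(min_frac * n_kmers)` by default.
#'
#' @param reads character vector of read sequences.
#' @param decoy decoy sequence(s).
#' @param k k-mer length.
#' @param min_frac fraction of the read's k-mers required to hit.
#' @return logical vector.
#' @export
decoy_match <- function(reads, decoy, k = 21L, min_frac = 0.5) {
  short <- nchar(reads) < k
  if (any(short))
    warnf("%d read(s) shorter than k=%d treated as non-matching",
          sum(short), k)
  idx <- kmer_index_build(decoy, as.integer(k))
  hits <- kmer_distinct_hits(idx, reads)
  n_kmers <- pmax(0L, nchar(reads) - as.integer(k) + 1L)
  need <- ceiling(min_frac * n_kmers)
  !short & n_kmers > 0L & hits >= need
}

# per-mate cascade bookkeeping: returns data.table with fate and trim info
qc_run_mate <- function(dt, adapter, config, phix_idx, host_idx) {
  n <- nrow(dt)
  bad <- nchar(dt$seq) != nchar(dt$qual)
  if (any(bad))
    stopf("sequence/quality length mismatch for read(s): %s",
          paste(head(dt$id[bad], 3), collapse = ", "))
  fate <- rep("pass", n)
  alive <- rep(TRUE, n)

  mark <- function(sel, label) {
    sel <- alive & sel
    fate[sel] <<- label
    alive[sel] <<- FALSE
  }
  # 1. N bases
  mark(grepl("N", dt$seq, fixed = TRUE), "n_base")
  # 2. PhiX-like decoy
  hits <- kmer_distinct_hits(phix_idx, dt$seq)
  nk <- pmax(0L, nchar(dt$seq) - config$decoy_k + 1L)
  mark(nk > 0L & hits >= ceiling(config$decoy_min_frac * nk), "phix")
  # 3. adapter + quality-tail trim (on surviving reads; others keep raw seq)
  seq2 <- dt$seq; qual2 <- dt$qual; meanq <- rep(NA_real_, n)
  if (any(alive)) {
    tr <- trim_read_3prime(dt$seq[alive], dt$qual[alive], adapter,
                           config$adapter_min_overlap,
                           config$tail_quality_cutoff,
                           config$adapter_max_mismatch_frac)
    seq2[alive] <- tr$seq; qual2[alive] <- tr$qual; meanq[alive] <- tr$mean_q
  }
  # 4. length
  mark(nchar(seq2) < config$min_length, "short")
  # 5. mean quality ("25 or less")
  mark(!is.na(meanq) & meanq <= config$min_mean_quality, "low_meanq")
  # 6. host-like decoy
  if (any(alive)) {
    hh <- kmer_distinct_hits(host_idx, seq2)
    nk2 <- pmax(0L, nchar(seq2) - config$decoy_k + 1L)
    mark(nk2 > 0L & hh >= ceiling(config$decoy_min_frac * nk2), "host")
  }
  data.table::data.table(id = dt$id, fate = fate, seq = seq2, qual = qual2)
}

#' Run the seven-step QC cascade on paired reads
#'
#' @param r1,r2 FASTQ paths or data.tables with columns `id`, `seq`, `qual`
#'   (mate 1 and mate 2; ids without mate suffix).
#' @param config a [filter_config()].
#' @return list with `pairs` (list `r1`, `r2`: surviving trimmed reads),
#'   `fates` (per-mate read fate tables) and `tally` (one-row data.table of
#'   per-stage counts: input/discarded/surviving reads and base pairs).
#' @export
qc_pipeline <- function(r1, r2, config = filter_config()) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  r1 <- data.table::as.data.table(r1); r2 <- data.table::as.data.table(r2)
  phix_idx <- kmer_index_build(config$decoy_phix, config$decoy_k)
  host_idx <- kmer_index_build(config$decoy_host, config$decoy_k)

  f1 <- qc_run_mate(r1, config$adapter_fwd, config, phix_idx, host_idx)
  f2 <- qc_run_mate(r2, config$adapter_rev, config, phix_idx, host_idx)

  # 7. orphan removal
  ok1 <- f1$id[f1$fate == "pass"]; ok2 <- f2$id[f2$fate == "pass"]
  keep <- intersect(ok1, ok2)
  f1[fate == "pass" & !(id %in% keep), fate := "orphan"]
  f2[fate == "pass" & !(id %in% keep), fate := "orphan"]

  s1 <- f1[fate == "pass"]; s2 <- f2[fate == "pass"]
  # mate files keep identical id sets in identical order
  data.table::setkey(s1, NULL); data.table::setkey(s2, NULL)
  s2 <- s2[match(s1$id, s2$id)]

  count_fates <- function(f) table(factor(
    f$fate, levels = c("n_base", "phix", "short", "low_meanq", "host",
                       "orphan", "pass")))
  cf <- count_fates(f1) + count_fates(f2)
  tally <- data.table::data.table(
    input_reads = nrow(r1) + nrow(r2),
    input_bp = sum(nchar(r1$seq)) + sum(nchar(r2$seq)),
    discard_n = as.integer(cf[["n_base"]]),
    discard_phix = as.integer(cf[["phix"]]),
    discard_short = as.integer(cf[["short"]]),
    discard_meanq = as.integer(cf[["low_meanq"]]),
    discard_host = as.integer(cf[["host"]]),
    discard_orphan = as.integer(cf[["orphan"]]),
    surviving_reads = nrow(s1) + nrow(s2),
    surviving_bp = sum(nchar(s1$seq)) + sum(nchar(s2$seq)))
  list(pairs = list(r1 = s1[, .(id, seq, qual)], r2 = s2[, .(id, seq, qual)]),
       fates = list(r1 = f1, r2 = f2), tally = tally,
       config = config)
}

#' Aggregate report totals from printed-scale inputs
#'
#' Report arithmetic for fixed-length read sets: base pairs are reads times
#' the nominal read length, and per-sample averages are totals over the
#' number of samples, rounded half away from zero for display.
#'
#' @param total_reads total read count over all samples.
#' @param n_samples number of samples.
#' @param read_length nominal read length (bp).
#' @return list with `bp_total`, `reads_avg`, `bp_avg`.
#' @export
report_totals <- function(total_reads, n_samples, read_length = 150) {
  bp_total <- total_reads * read_length
  list(bp_total = bp_total,
       reads_avg = round_half_up(total_reads / n_samples),
       bp_avg = round_half_up(bp_total / n_samples))
}

#' Summarise per-sample QC tallies into an aggregate report
#'
#' @param tallies data.table of per-sample tallies (rows as produced by
#'   [qc_pipeline()], plus a `sample` column).
#' @param read_length nominal read length for fixed-length accounting.
#' @return list with `per_sample`, `totals` (all tally columns summed),
#'   `averages` (per-sample means, rounded half away from zero) and a
#'   `conservation` flag (input = surviving + sum of discards everywhere).
#' @export
qc_report_summary <- function(tallies, read_length = 150) {
  t <- data.table::as.data.table(tallies)
  num_cols <- setdiff(names(t), "sample")
  totals <- t[, lapply(.SD, sum), .SDcols = num_cols]
  n <- nrow(t)
  averages <- lapply(totals, function(x) round_half_up(x / n))
  discard_cols <- grep("^discard_", num_cols, value = TRUE)
  conserved <- all(t$input_reads ==
                     t$surviving_reads + rowSums(t[, ..discard_cols]))
  list(per_sample = t, totals = as.list(totals), averages = averages,
       n_samples = n, conservation = conserved,
       nominal = list(
         input_bp_nominal = totals$input_reads * read_length,
         surviving_bp_nominal = totals$surviving_reads * read_length))
}
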