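#' Build a canonical k-mer index over strain gene sets
#'
#' Indexes every gene's canonical (strand-minimal) k-mers for read
#' assignment.  Genes shorter than `k` are skipped with a warning.
#'
#' @param gene_sets list of [strain_gene_set()].
#' @param k k-mer length (default 31; must be <= 31).
#' @return object of class `gene_index`: list with `ptr` (external pointer
#'   to the C++ index), `genes` (data.table strain, gene_id, length) and `k`.
#' @export
build_gene_index <- function(gene_sets, k = 31L) {
  genes <- data.table::rbindlist(lapply(gene_sets, function(gs)
    data.table::data.table(strain = gs$strain_id, gene_id = gs$genes$gene_id,
                           nt = gs$genes$nt)))
  genes[, length := nchar(nt)]
  short <- genes$length < k
  if (any(short))
    warnf("%d gene(s) shorter than k=%d skipped from the index",
          sum(short), k)
  genes <- genes[!short]
  ptr <- kmer_index_build(genes$nt, as.integer(k))
  structure(list(ptr = ptr, genes = genes[, .(strain, gene_id, length)],
                 k = as.integer(k)),
            class = "gene_index")
}

#' Assign reads to genes by k-mer plurality voting
#'
#' Each read votes for the gene(s) hit by the plurality of its canonical
#' k-mers; ties are split fractionally in equal parts; reads with no hits
#' are unassigned.  Counts may therefore be fractional.
#'
#' @param reads character vector of read sequences (or a data.table with a
#'   `seq` column).
#' @param index a [build_gene_index()] result.
#' @param detail return per-read assignments instead of summed counts.
#' @return named numeric vector of per-gene counts (names = gene ids) with
#'   attribute `n_assigned`; or, with `detail = TRUE`, a data.table
#'   (read, gene_id, weight).
#' @export
assign_reads <- function(reads, index, detail = FALSE) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (detail) {
    d <- kmer_assign_detail(index$ptr, reads)
    return(data.table::data.table(read = d$read,
                                  gene_id = index$genes$gene_id[d$gene],
                                  weight = d$weight))
  }
  counts <- kmer_count_reads(index$ptr, reads)
  out <- setNames(as.numeric(counts), index$genes$gene_id)
  attr(out, "n_assigned") <- attr(counts, "n_assigned")
  out
}

#' Positional fast path of [assign_reads()]
#'
#' For reads known to be exact windows of indexed genes (as produced by
#' [simulate_cohort_positions()]): replays the identical voting kernel on
#' the stored gene sequence instead of a materialised read string.
#'
#' @param positions data.table with columns `gene` (row index into
#'   `index$genes`) and `start` (1-based).
#' @param index a [build_gene_index()] result.
#' @param read_length read length.
#' @param map optional precomputed [position_assignment_map()] (same
#'   outcome, constant time per read).
#' @return named numeric vector of per-gene counts, as [assign_reads()].
#' @export
assign_reads_positions <- function(positions, index, read_length = 150L,
                                   map = NULL) {
  counts <- if (is.null(map)) {
    kmer_count_positions(index$ptr, positions$gene, positions$start,
                         as.integer(read_length))
  } else {
    kmer_count_mapped(map, positions$gene, positions$start)
  }
  out <- setNames(as.numeric(counts), index$genes$gene_id)
  attr(out, "n_assigned") <- attr(counts, "n_assigned")
  out
}

#' Precompute per-position read assignments
#'
#' For exact-window reads every admissible (gene, start) position has a
#' fixed voting outcome; this computes it once (with the same kernel as
#' [assign_reads()]) so that large simulation studies can count sampled
#' positions in constant time per read.
#'
#' @param index a [build_gene_index()] result.
#' @param read_length read length.
#' @return opaque position map for [assign_reads_positions()].
#' @export
position_assignment_map <- function(index, read_length = 150L) {
  m <- kmer_position_map(index$ptr, as.integer(read_length))
  m$gene_ids <- index$genes$gene_id
  m
}

#' Transcripts-per-million from counts and lengths
#'
#' `rate_i = count_i / length_i`; `TPM_i = 1e6 * rate_i / sum(rate)`.
#' All-zero counts yield an all-zero vector.
#'
#' @param counts non-negative numeric vector.
#' @param lengths positive gene lengths (same order).
#' @return numeric TPM vector.
#' @export
compute_tpm <- function(counts, lengths) {
  if (any(counts < 0)) stopf("negative counts")
  if (any(lengths <= 0)) stopf("lengths must be positive")
  if (length(counts) != length(lengths)) stopf("length mismatch")
  rate <- counts / lengths
  s <- sum(rate)
  if (s == 0) return(rep(0, length(counts)))
  1e6 * rate / s
}

#' Aggregate gene-level TPM to ortholog groups
#'
#' Ortholog abundance is the sum of member-gene TPM (a mean option is
#' provided); genes absent from the clustering are reported separately,
#' never silently dropped.
#'
#' @param tpm samples x genes numeric matrix (column names = gene ids).
#' @param clustering an [cluster_orthologs()] result.
#' @param agg `"sum"` (default) or `"mean"`.
#' @return samples x og matrix with attributes `unassigned` (gene ids not
#'   in the clustering) and `method` (clustering method tag).
#' @export
aggregate_orthologs <- function(tpm, clustering, agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  g <- clustering$groups
  map <- setNames(g$og_id, g$gene_id)
  gene_ids <- colnames(tpm)
  og <- map[gene_ids]
  unassigned <- gene_ids[is.na(og)]
  keep <- !is.na(og)
  m <- tpm[, keep, drop = FALSE]
  fo <- factor(og[keep])
  out <- t(rowsum(t(m), fo))
  if (agg == "mean")
    out <- sweep(out, 2, as.numeric(table(fo)), "/")
  attr(out, "unassigned") <- unassigned
  attr(out, "method") <- clustering$method
  out
}

#' Quantify a cohort: reads to gene TPM to ortholog abundance
#'
#' @param sample_reads named list of per-sample read tables or character
#'   vectors (e.g. surviving reads from [qc_pipeline()]).
#' @param index a [build_gene_index()] result.
#' @param clustering an [cluster_orthologs()] result (optional).
#' @return list with `counts` and `tpm` (samples x genes matrices) and, if
#'   a clustering was given, `og_abundance`.
#' @export
quantify_cohort <- function(sample_reads, index, clustering = NULL) {
  lens <- index$genes$length
  counts <- t(vapply(sample_reads, function(r) assign_reads(r, index),
                     numeric(nrow(index$genes))))
  tpm <- t(apply(counts, 1, compute_tpm, lengths = lens))
  dimnames(tpm) <- dimnames(counts)
  out <- list(counts = counts, tpm = tpm)
  if (!is.null(clustering))
    out$og_abundance <- aggregate_orthologs(tpm, clustering)
  out
}
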