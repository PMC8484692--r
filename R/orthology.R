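#' All-vs-all cross-strain sequence similarity
#'
#' Computes local-alignment similarity edges between genes of different
#' strains.  A shared-k-mer prefilter restricts the quadratic all-vs-all
#' comparison to plausible homolog pairs; surviving pairs are aligned
#' locally (Smith-Waterman via Biostrings) under a unit scoring scheme
#' (match +1, mismatch -1, gap -2 by default).
#'
#' @param gene_sets list of [strain_gene_set()] (>= 2 strains).
#' @param seq_type `"nucleotide"` (default; used for ortholog clustering) or
#'   `"protein"`.
#' @param kmer_size prefilter k-mer length (default 15 nt / 5 aa).
#' @param min_shared_kmers minimum number of distinct shared k-mers for a
#'   pair to be aligned (default 3 nt / 2 aa).
#' @param match,mismatch,gap alignment scores (gap is per gapped position).
#' @return data.table of similarity edges: strain/gene ids of both members,
#'   `identity` (percent, over aligned columns), `score` (alignment score),
#'   `query_coverage`, `subject_coverage` (percent of each full sequence
#'   covered by the local alignment).  One row per unordered cross-strain
#'   pair; "query" is the lexicographically smaller strain.
#' @export
pairwise_similarity <- function(gene_sets,
                                seq_type = c("nucleotide", "protein"),
                                kmer_size = NULL, min_shared_kmers = NULL,
                                match = 1, mismatch = -1, gap = 2) {
  seq_type <- match.arg(seq_type)
  if (length(gene_sets) < 2) stopf("need at least 2 strains")
  for (gs in gene_sets)
    if (nrow(gs$genes) == 0) stopf("empty gene set: %s", gs$strain_id)
  kmer_size <- kmer_size %||% if (seq_type == "nucleotide") 15L else 5L
  min_shared_kmers <- min_shared_kmers %||%
    if (seq_type == "nucleotide") 3L else 2L

  seqs <- data.table::rbindlist(lapply(gene_sets, function(gs)
    data.table::data.table(
      strain = gs$strain_id, gene_id = gs$genes$gene_id,
      seq = if (seq_type == "nucleotide") gs$genes$nt else gs$genes$aa)))

  cand <- shared_kmer_pairs(seqs$seq, kmer_size, min_shared_kmers,
                            cross_only_groups = seqs$strain)
  if (nrow(cand) == 0) return(empty_edge_table())

  align_pairs(seqs, cand, match, mismatch, gap)
}

# distinct-k-mer sharing counts between sequences; returns pairs (i, j, n)
# with i < j, n >= min_shared, and (if given) different groups
shared_kmer_pairs <- function(seqs, k, min_shared, cross_only_groups = NULL) {
  n <- length(seqs)
  lens <- nchar(seqs)
  km <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    L <- lens[i]
    if (L < k) return(NULL)
    data.table::data.table(
      kmer = unique(substring(seqs[i], 1:(L - k + 1), k:L)), id = i)
  }))
  if (nrow(km) == 0)
    return(data.table::data.table(i = integer(0), j = integer(0)))
  pairs <- km[km, on = "kmer", allow.cartesian = TRUE][id < i.id]
  pairs <- pairs[, .(n_shared = .N), by = .(i = id, j = i.id)]
  pairs <- pairs[n_shared >= min_shared]
  if (!is.null(cross_only_groups))
    pairs <- pairs[cross_only_groups[i] != cross_only_groups[j]]
  pairs
}

empty_edge_table <- function() {
  data.table::data.table(query_strain = character(0),
                         query_gene = character(0),
                         subject_strain = character(0),
                         subject_gene = character(0),
                         identity = numeric(0), score = numeric(0),
                         query_coverage = numeric(0),
                         subject_coverage = numeric(0))
}

unit_submat <- function(letters, match, mismatch) {
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

align_pairs <- function(seqs, cand, match, mismatch, gap) {
  letters <- sort(unique(unlist(strsplit(seqs$seq[unique(c(cand$i, cand$j))],
                                         ""))))
  submat <- unit_submat(letters, match, mismatch)
  # batch all pairs sharing a subject into one pairwiseAlignment call
  out <- vector("list", length(unique(cand$j)))
  b <- 0L
  for (j in unique(cand$j)) {
    is <- cand$i[cand$j == j]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::BStringSet(seqs$seq[is]), Biostrings::BString(seqs$seq[j]),
      type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = gap)
    pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
    b <- b + 1L
    out[[b]] <- data.table::data.table(
      query_strain = seqs$strain[is], query_gene = seqs$gene_id[is],
      subject_strain = seqs$strain[j], subject_gene = seqs$gene_id[j],
      identity = Biostrings::pid(aln, type = "PID1"),
      score = Biostrings::score(aln),
      query_coverage = 100 *
        (Biostrings::end(pat) - Biostrings::start(pat) + 1) /
        nchar(seqs$seq[is]),
      subject_coverage = 100 *
        (Biostrings::end(sub) - Biostrings::start(sub) + 1) /
        nchar(seqs$seq[j]))
  }
  e <- data.table::rbindlist(out)
  # orient so the query is the lexicographically smaller strain
  swap <- e$query_strain > e$subject_strain
  if (any(swap)) {
    qs <- e$query_strain[swap]; qg <- e$query_gene[swap]
    qc <- e$query_coverage[swap]
    e[swap, `:=`(query_strain = subject_strain, query_gene = subject_gene,
                 query_coverage = subject_coverage)]
    e[swap, `:=`(subject_strain = qs, subject_gene = qg,
                 subject_coverage = qc)]
  }
  e
}

#' Cluster genes into ortholog groups
#'
#' Two independent strategies over the similarity edges:
#' * method `"A"`: single-linkage connected components of the graph of
#'   edges with `identity >= identity_threshold` and both coverages
#'   `>= min_coverage`;
#' * method `"B"`: connected components of the bidirectional-best-hit (BBH)
#'   graph — for each ordered strain pair an edge survives only if each
#'   gene is the other's best-scoring hit in that strain (coverage-filtered
#'   first; score ties broken towards the lexicographically smaller gene id).
#'
#' Genes untouched by any surviving edge form singleton groups, so the
#' result always partitions the gene universe.
#'
#' @param edges edge table from [pairwise_similarity()].
#' @param gene_sets list of [strain_gene_set()] (the gene universe).
#' @param method `"A"` or `"B"`.
#' @param identity_threshold percent identity cut for method A (default 95).
#' @param min_coverage minimum percent coverage (both sides, both methods).
#' @return object of class `ortholog_clustering`: list with `method` and
#'   `groups` (data.table og_id, strain, gene_id).  Group ids are assigned
#'   in order of each group's smallest (strain, gene_id), so they are stable
#'   for a fixed input ordering.
#' @export
cluster_orthologs <- function(edges, gene_sets, method = c("A", "B"),
                              identity_threshold = 95, min_coverage = 80) {
  if (!is.character(method) || !all(method %in% c("A", "B")))
    stopf("unknown clustering method: %s", paste(method, collapse = ","))
  method <- match.arg(method)
  universe <- data.table::rbindlist(lapply(gene_sets, function(gs)
    data.table::data.table(strain = gs$strain_id, gene_id = gs$genes$gene_id)))
  universe[, key := paste(strain, gene_id, sep = ":")]

  e <- data.table::as.data.table(edges)
  e <- e[query_coverage >= min_coverage & subject_coverage >= min_coverage]
  if (method == "A") {
    e <- e[identity >= identity_threshold]
    keep <- e
  } else {
    # bidirectional best hits per strain pair
    both <- data.table::rbindlist(list(
      e[, .(from_strain = query_strain, from_gene = query_gene,
            to_strain = subject_strain, to_gene = subject_gene, score)],
      e[, .(from_strain = subject_strain, from_gene = subject_gene,
            to_strain = query_strain, to_gene = query_gene, score)]))
    data.table::setorder(both, from_strain, from_gene, to_strain,
                         -score, to_gene)
    best <- both[, .SD[1], by = .(from_strain, from_gene, to_strain)]
    fwd <- best[, .(a = paste(from_strain, from_gene, sep = ":"),
                    b = paste(to_strain, to_gene, sep = ":"))]
    keep_keys <- fwd[fwd, on = c(a = "b", b = "a"), nomatch = NULL]
    keep <- unique(keep_keys[a < b])
    keep <- data.table::data.table(qkey = keep$a, skey = keep$b)
  }

  if (method == "A") {
    qk <- paste(keep$query_strain, keep$query_gene, sep = ":")
    sk <- paste(keep$subject_strain, keep$subject_gene, sep = ":")
  } else {
    qk <- keep$qkey; sk <- keep$skey
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = qk, to = sk),
    directed = FALSE, vertices = data.frame(name = universe$key))
  comp <- igraph::components(g)$membership
  universe[, comp := comp[key]]
  data.table::setorder(universe, strain, gene_id)
  first_of <- universe[, .(first = paste(strain[1], gene_id[1], sep = ":")),
                       by = comp]
  data.table::setorder(first_of, first)
  first_of[, og_id := sprintf("OG%06d", .I)]
  universe <- universe[first_of, on = "comp"]
  groups <- universe[order(og_id, strain, gene_id),
                     .(og_id, strain, gene_id)]
  structure(list(method = method, groups = groups,
                 params = list(identity_threshold = identity_threshold,
                               min_coverage = min_coverage)),
            class = "ortholog_clustering")
}

#' @export
print.ortholog_clustering <- function(x, ...) {
  cat(sprintf("<ortholog_clustering> method %s: %d groups over %d genes\n",
              x$method, length(unique(x$groups$og_id)), nrow(x$groups)))
  invisible(x)
}

#' Assign KO functional labels by best reference hit
#'
#' Each gene's protein is compared against a labeled reference protein set;
#' the KO of the best-scoring hit is assigned if and only if that hit
#' exceeds all three thresholds strictly (identity > 40, score > 70,
#' coverage > 80, where coverage is the minimum of query and subject
#' coverage — the conservative reading, recorded in the output attributes).
#'
#' @param gene_sets list of [strain_gene_set()].
#' @param ko_reference data.table/data.frame with columns `ko`, `protein`.
#' @param identity_min,score_min,coverage_min strict thresholds.
#' @param kmer_size,min_shared_kmers prefilter (protein k-mers).
#' @return data.table (strain, gene_id, ko, identity, score, coverage);
#'   `ko` is NA where no hit passed.
#' @export
assign_ko <- function(gene_sets, ko_reference,
                      identity_min = 40, score_min = 70, coverage_min = 80,
                      kmer_size = 5L, min_shared_kmers = 2L) {
  ko_reference <- data.table::as.data.table(ko_reference)
  if (nrow(ko_reference) == 0) stopf("ko_reference must be non-empty")
  genes <- data.table::rbindlist(lapply(gene_sets, function(gs)
    data.table::data.table(strain = gs$strain_id, gene_id = gs$genes$gene_id,
                           seq = gs$genes$aa)))
  all_seqs <- c(genes$seq, ko_reference$protein)
  grp <- c(rep("gene", nrow(genes)), rep("ref", nrow(ko_reference)))
  cand <- shared_kmer_pairs(all_seqs, kmer_size, min_shared_kmers,
                            cross_only_groups = grp)
  ann <- genes[, .(strain, gene_id)]
  ann[, `:=`(ko = NA_character_, identity = NA_real_, score = NA_real_,
             coverage = NA_real_)]
  if (nrow(cand) > 0) {
    # orient as (gene, ref)
    gi <- ifelse(grp[cand$i] == "gene", cand$i, cand$j)
    ri <- ifelse(grp[cand$i] == "gene", cand$j, cand$i) - nrow(genes)
    submat <- unit_submat(
      sort(unique(unlist(strsplit(all_seqs[unique(c(cand$i, cand$j))], "")))),
      1, -1)
    for (r0 in unique(ri)) {
      gs_idx <- gi[ri == r0]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::BStringSet(genes$seq[gs_idx]),
        Biostrings::BString(ko_reference$protein[r0]),
        type = "local", substitutionMatrix = submat,
        gapOpening = 0, gapExtension = 2)
      sc <- Biostrings::score(aln)
      pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
      qcov <- 100 * (Biostrings::end(pat) - Biostrings::start(pat) + 1) /
        nchar(genes$seq[gs_idx])
      scov <- 100 * (Biostrings::end(sub) - Biostrings::start(sub) + 1) /
        nchar(ko_reference$protein[r0])
      ident <- Biostrings::pid(aln, type = "PID1")
      for (t in seq_along(gs_idx)) {
        cur <- ann$score[gs_idx[t]]
        if (!is.na(cur) && cur >= sc[t]) next
        data.table::set(ann, gs_idx[t],
                        c("ko", "identity", "score", "coverage"),
                        list(ko_reference$ko[r0], ident[t], sc[t],
                             min(qcov[t], scov[t])))
      }
    }
  }
  # enforce the strict thresholds on the recorded best hit
  fail <- !is.na(ann$score) &
    !ko_thresholds_pass(ann$identity, ann$score, ann$coverage,
                        identity_min, score_min, coverage_min)
  ann[fail, ko := NA_character_]
  data.table::setattr(ann, "thresholds",
                      c(identity = identity_min, score = score_min,
                        coverage = coverage_min))
  data.table::setattr(ann, "coverage_rule", "min(query, subject)")
  ann[]
}

# the KO assignment rule: all three thresholds must be exceeded STRICTLY
ko_thresholds_pass <- function(identity, score, coverage,
                               identity_min = 40, score_min = 70,
                               coverage_min = 80) {
  identity > identity_min & score > score_min & coverage > coverage_min
}

# Kyte-Doolittle hydropathy scale
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Classify protein localization by hydropathy windows
#'
#' A transparent stand-in for HMM-based transmembrane prediction: predicted
#' helices are maximal regions covered by windows of length `window` whose
#' mean Kyte-Doolittle hydropathy exceeds `cutoff`.  At least one helix
#' makes the protein transmembrane; otherwise a signal-like hydrophobic
#' stretch (a run of >= `signal_min_run` residues, each above `cutoff`,
#' contained in the first `signal_region` residues) marks it extracellular;
#' otherwise it is intracellular.  Calls on real proteins will not match a
#' trained predictor and should be labeled as heuristic in reports.
#'
#' @param protein amino-acid sequence (single string).
#' @param window sliding-window length (default 19, a typical helix span).
#' @param cutoff mean-hydropathy threshold (default 1.6).
#' @param signal_min_run,signal_region N-terminal signal rule parameters.
#' @return list with `call` (one of `"transmembrane"`, `"extracellular"`,
#'   `"intracellular"`) and `n_helices`.
#' @export
classify_localization <- function(protein, window = 19L, cutoff = 1.6,
                                  signal_min_run = 8L, signal_region = 30L) {
  if (!nzchar(protein)) stopf("protein must be non-empty")
  aa <- strsplit(toupper(protein), "")[[1]]
  h <- .kd_scale[aa]
  if (anyNA(h)) stopf("non-amino-acid characters in protein: %s",
                      paste(unique(aa[is.na(h)]), collapse = ","))
  n <- length(h)
  n_helices <- 0L
  covered <- logical(n)
  if (n >= window) {
    cs <- cumsum(c(0, h))
    wmean <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
    pass <- which(wmean > cutoff)
    for (s in pass) covered[s:(s + window - 1L)] <- TRUE
    r <- rle(covered)
    n_helices <- sum(r$values)
  }
  if (n_helices >= 1L)
    return(list(call = "transmembrane", n_helices = n_helices))
  # N-terminal hydrophobic stretch
  region <- h[seq_len(min(signal_region, n))]
  r <- rle(region > cutoff)
  has_signal <- any(r$values & r$lengths >= signal_min_run)
  list(call = if (has_signal) "extracellular" else "intracellular",
       n_helices = 0L)
}

#' Vectorised localization calls for gene sets
#' @param gene_sets list of [strain_gene_set()].
#' @inheritParams classify_localization
#' @return data.table (strain, gene_id, call, n_helices).
#' @export
classify_localization_all <- function(gene_sets, window = 19L, cutoff = 1.6) {
  data.table::rbindlist(lapply(gene_sets, function(gs) {
    res <- lapply(gs$genes$aa, function(p) {
      # generator proteins may carry X for reverted/unknown codons
      cl <- classify_localization(gsub("X", "A", p), window, cutoff)
      data.table::data.table(call = cl$call, n_helices = cl$n_helices)
    })
    cbind(data.table::data.table(strain = gs$strain_id,
                                 gene_id = gs$genes$gene_id),
          data.table::rbindlist(res))
  }))
}
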