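#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites with a gap (`-`) or `N` in either sequence are excluded (pairwise
#' deletion).  With transition proportion `P` and transversion proportion
#' `Q` over the retained sites,
#' `d = -(1/2) * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param seq1,seq2 aligned sequences (equal-length strings over
#'   `A/C/G/T/-/N`).
#' @return non-negative distance.  Saturated pairs (log argument <= 0)
#'   raise an error.
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) stopf("sequences must be aligned (equal length)")
  ok_chars <- c("A", "C", "G", "T", "-", "N")
  badc <- setdiff(unique(c(a, b)), ok_chars)
  if (length(badc))
    stopf("unsupported characters in alignment: %s",
          paste(badc, collapse = ","))
  keep <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) stopf("no comparable sites after pairwise deletion")
  diff <- a != b
  purine <- function(x) x %in% c("A", "G")
  transition <- diff & (purine(a) == purine(b))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stopf("saturated distance: 1-2P-Q = %.4g, 1-2Q = %.4g", w1, w2)
  max(0, -0.5 * log(w1 * sqrt(w2)))
}

#' K2P distance matrix for a multiple alignment
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (>= 3 taxa).
#' @return symmetric `dist`-compatible matrix.
#' @export
k2p_distance_matrix <- function(alignment) {
  n <- length(alignment)
  if (n < 3) stopf("need >= 3 taxa")
  if (length(unique(nchar(alignment))) != 1)
    stopf("alignment rows must have equal length")
  ids <- names(alignment) %||% sprintf("t%d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- k2p_distance(alignment[[i]], alignment[[j]])
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ (via ape); on additive matrices the generating topology and
#' branch lengths are recovered exactly.  Negative branch-length estimates
#' are clamped to zero with a warning.
#'
#' @param d square symmetric zero-diagonal matrix (n >= 3).
#' @return `phylo` tree (unrooted).
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8))
    stopf("distance matrix must be square and symmetric")
  if (any(abs(diag(m)) > 1e-12)) stopf("diagonal must be zero")
  if (nrow(m) < 3) stopf("need >= 3 taxa")
  tr <- ape::nj(m)
  if (any(tr$edge.length < 0)) {
    warnf("%d negative NJ branch length(s) clamped to 0",
          sum(tr$edge.length < 0))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for an NJ tree from an alignment
#'
#' Sites are resampled with replacement `n_replicates` times; each
#' replicate is re-analysed (K2P + NJ) and the support of each original
#' internal split is the percentage of successful replicates containing
#' it.  Replicates whose distance matrix saturates are skipped and counted.
#'
#' @param alignment named character vector of aligned sequences.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `tree` (the original NJ tree with node labels set to
#'   the support percentages), `support` (per internal node),
#'   `n_replicates`, `n_skipped`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L) {
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  L <- unique(nchar(alignment))
  if (length(L) != 1) stopf("alignment rows must have equal length")
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  tree <- nj_tree(k2p_distance_matrix(alignment))
  boot <- withr::with_seed(as.integer(seed), {
    out <- vector("list", n_replicates)
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      names(rep_aln) <- names(alignment)
      out[[b]] <- tryCatch(
        suppressWarnings(nj_tree(k2p_distance_matrix(rep_aln))),
        error = function(e) NULL)
    }
    out
  })
  ok <- !vapply(boot, is.null, logical(1))
  n_ok <- sum(ok)
  if (n_ok == 0) stopf("all bootstrap replicates saturated")
  counts <- suppressWarnings(ape::prop.clades(tree, boot[ok], rooted = FALSE))
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_ok
  tree$node.label <- formatC(support, format = "f", digits = 1)
  list(tree = tree, support = support,
       n_replicates = n_replicates, n_skipped = n_replicates - n_ok)
}

#' Write a tree as Newick text
#' @param tree `phylo` object (node labels carry supports, if any).
#' @param path optional output file; otherwise the text is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#' @param text Newick string or file path.
#' @return `phylo` object.
#' @export
read_newick <- function(text) {
  if (file.exists(text)) ape::read.tree(text) else ape::read.tree(text = text)
}
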