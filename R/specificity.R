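#' Ortholog presence/absence matrix
#'
#' Exact member-gene counts of every ortholog group in every strain; no
#' thresholding.
#'
#' @param clustering an [cluster_orthologs()] result.
#' @param strains character vector of all strain ids.
#' @return integer matrix (og_id x strain).
#' @export
presence_absence <- function(clustering, strains) {
  g <- clustering$groups
  extra <- setdiff(unique(g$strain), strains)
  if (length(extra))
    stopf("clustering contains strain(s) absent from strain list: %s",
          paste(extra, collapse = ","))
  tab <- table(factor(g$og_id), factor(g$strain, levels = strains))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Call strain-specific ortholog groups
#'
#' A group is specific to `target_set` if
#' * (presence rule) its member genes occur only in target-set strains and
#'   — with `require_all_targets = TRUE` (default) — in every strain of the
#'   target set; or
#' * (KO rule) it contains a gene whose KO label occurs, across all genes
#'   of all strains, only in genes of target-set strains (and, with
#'   `require_all_targets`, in every target strain).
#'
#' @param clustering an [cluster_orthologs()] result.
#' @param target_set character vector of target strain ids.
#' @param strains all strain ids (the known universe).
#' @param ko optional KO annotation from [assign_ko()] (or any table with
#'   strain, gene_id, ko).  Without it only the presence rule applies.
#' @param require_all_targets require occurrence in every target strain
#'   (the strict reading of "shared only by" the target strains).
#' @return object of class `specific_ortholog_calls`: list with `calls`
#'   (data.table og_id, rule, kos) and `members` (data.table og_id, strain,
#'   gene_id for called groups); attribute `target_set`.
#' @export
call_specific_orthologs <- function(clustering, target_set, strains,
                                    ko = NULL, require_all_targets = TRUE) {
  if (length(target_set) == 0) stopf("target_set must be non-empty")
  if (!all(target_set %in% strains))
    stopf("target_set contains unknown strain(s): %s",
          paste(setdiff(target_set, strains), collapse = ","))
  g <- clustering$groups
  strain_sets <- g[, .(set = list(sort(unique(strain)))), by = og_id]
  target <- sort(unique(target_set))
  ok_set <- function(s) {
    if (require_all_targets) identical(s, target)
    else length(setdiff(s, target)) == 0
  }
  presence_ok <- vapply(strain_sets$set, ok_set, logical(1))
  presence_ids <- strain_sets$og_id[presence_ok]

  ko_ids <- character(0)
  ko_of_group <- list()
  if (!is.null(ko)) {
    ko <- data.table::as.data.table(ko)[!is.na(ko)]
    if (nrow(ko)) {
      ko_strains <- ko[, .(set = list(sort(unique(strain)))), by = ko]
      specific_kos <- ko_strains$ko[vapply(ko_strains$set, ok_set, logical(1))]
      if (length(specific_kos)) {
        gk <- g[ko, on = c("strain", "gene_id"), nomatch = NULL]
        gk <- gk[ko %in% specific_kos]
        ko_of_group <- lapply(split(gk$ko, gk$og_id), unique)
        ko_ids <- names(ko_of_group)
      }
    }
  }

  called <- union(presence_ids, ko_ids)
  if (length(called) == 0) {
    calls <- data.table::data.table(og_id = character(0), rule = character(0),
                                    kos = character(0))
  } else {
    rule <- ifelse(called %in% presence_ids & called %in% ko_ids, "both",
                   ifelse(called %in% presence_ids, "presence_only",
                          "ko_only"))
    kos <- vapply(called, function(id)
      paste(ko_of_group[[id]] %||% character(0), collapse = ","), character(1))
    calls <- data.table::data.table(og_id = called, rule = rule, kos = kos)
    data.table::setorder(calls, og_id)
  }
  members <- g[og_id %in% called]
  structure(list(calls = calls, members = members),
            class = "specific_ortholog_calls",
            target_set = target)
}

#' Consensus between two methods' specific-ortholog calls
#'
#' Pairs calls from two clusterings when their member gene sets (restricted
#' to target-set strains) overlap by Jaccard at least `jaccard_min`;
#' unpaired calls are reported as method-exclusive.
#'
#' @param calls_a,calls_b [call_specific_orthologs()] results for the same
#'   target set under the two clusterings.
#' @param jaccard_min minimum member-gene Jaccard index (default 0.5).
#' @return list with `consensus` (data.table og_a, og_b, jaccard) and
#'   `exclusive` (data.table method, og_id); attribute `target_set`.
#' @export
consensus_calls <- function(calls_a, calls_b, jaccard_min = 0.5) {
  ta <- attr(calls_a, "target_set"); tb <- attr(calls_b, "target_set")
  if (!identical(ta, tb)) stopf("call sets target different strain sets")
  mem_keys <- function(calls) {
    m <- calls$members[strain %in% ta]
    split(paste(m$strain, m$gene_id, sep = ":"), m$og_id)
  }
  ka <- mem_keys(calls_a); kb <- mem_keys(calls_b)
  cand <- data.table::CJ(a = names(ka), b = names(kb))
  if (nrow(cand)) {
    cand[, jaccard := mapply(function(x, y) {
      length(intersect(ka[[x]], kb[[y]])) / length(union(ka[[x]], kb[[y]]))
    }, a, b)]
    cand <- cand[jaccard >= jaccard_min]
    data.table::setorder(cand, -jaccard, a, b)
    used_a <- character(0); used_b <- character(0)
    pick <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (cand$a[r] %in% used_a || cand$b[r] %in% used_b) next
      pick[r] <- TRUE
      used_a <- c(used_a, cand$a[r]); used_b <- c(used_b, cand$b[r])
    }
    consensus <- cand[pick, .(og_a = a, og_b = b, jaccard)]
  } else {
    consensus <- data.table::data.table(og_a = character(0),
                                        og_b = character(0),
                                        jaccard = numeric(0))
  }
  exclusive <- data.table::rbindlist(list(
    data.table::data.table(method = "A",
                           og_id = setdiff(names(ka), consensus$og_a)),
    data.table::data.table(method = "B",
                           og_id = setdiff(names(kb), consensus$og_b))))
  structure(list(consensus = consensus, exclusive = exclusive),
            target_set = ta)
}

#' Find runs of chromosomally adjacent specific orthologs
#'
#' For each strain, maximal runs of called groups whose member gene indices
#' are consecutive integers; single-group blocks are reported too.
#'
#' @param calls a [call_specific_orthologs()] result.
#' @param gene_sets list of [strain_gene_set()] (for gene positions).
#' @return data.table (strain, start, end, n_genes, og_ids) where `og_ids`
#'   lists the groups in chromosomal order.
#' @export
find_adjacent_blocks <- function(calls, gene_sets) {
  pos <- data.table::rbindlist(lapply(gene_sets, function(gs)
    data.table::data.table(strain = gs$strain_id, gene_id = gs$genes$gene_id,
                           gene_index = gs$genes$gene_index)))
  m <- calls$members[pos, on = c("strain", "gene_id"), nomatch = NULL]
  if (nrow(m) == 0)
    return(data.table::data.table(strain = character(0), start = integer(0),
                                  end = integer(0), n_genes = integer(0),
                                  og_ids = character(0)))
  data.table::setorder(m, strain, gene_index)
  m[, run := cumsum(c(1L, diff(gene_index) != 1L)), by = strain]
  out <- m[, .(start = min(gene_index), end = max(gene_index),
               n_genes = .N,
               og_ids = paste(unique(og_id[order(gene_index)]),
                              collapse = ",")),
           by = .(strain, run)]
  out[, run := NULL]
  data.table::setorder(out, strain, start)
  out[]
}
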