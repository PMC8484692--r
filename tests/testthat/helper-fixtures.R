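# shared fixture builders and independent oracles

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# a tiny pan-genome used across tests: 3 strains, one planted pair-block
tiny_pangenome <- function(seed = 7, mutation_rate = 0.01) {
  simulate_pangenome(pan_genome_spec(
    n_strains = 3, core_size = 10, accessory_size = 4,
    planted_specific = list(list(strains = c(1, 2), len = 4,
                                 ko_policy = "exclusive")),
    mutation_rate = mutation_rate, seed = seed))
}

# canonical partition signature: strain:gene member sets, sorted
partition_signature <- function(groups) {
  s <- split(paste(groups$strain, groups$gene_id, sep = ":"), groups$og_id)
  unname(sort(vapply(s, function(x) paste(sort(x), collapse = "|"),
                     character(1))))
}

# ---- independent straight-line QC oracle -----------------------------------
# Scalar re-implementation of the seven filter rules, written without the
# package's cascade machinery.

oracle_kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  kms <- substring(seq, 1:(L - k + 1), k:L)
  rc <- strainspec::revcomp(kms)
  unique(pmin(kms, rc))   # canonical form
}

oracle_decoy <- function(seq, decoy_kmers, k, min_frac = 0.5) {
  kms <- oracle_kmer_set(seq, k)
  nk <- max(0L, nchar(seq) - k + 1L)
  if (nk == 0) return(FALSE)
  hits <- sum(kms %in% decoy_kmers)
  hits >= ceiling(min_frac * nk)
}

oracle_trim <- function(seq, qual, adapter, min_overlap = 32,
                        q_cutoff = 17, max_mm = 0.1) {
  len <- nchar(seq)
  keep <- len
  lmax <- min(len, nchar(adapter))
  for (l in if (lmax >= min_overlap) seq(lmax, min_overlap) else integer(0)) {
    suf <- substring(seq, len - l + 1, len)
    pre <- substring(adapter, 1, l)
    mm <- sum(strsplit(suf, "")[[1]] != strsplit(pre, "")[[1]])
    if (mm <= floor(max_mm * l)) { keep <- len - l; break }
  }
  q <- as.integer(charToRaw(substring(qual, 1, keep))) - 33L
  while (keep > 0 && q[keep] <= q_cutoff) keep <- keep - 1L
  list(seq = substring(seq, 1, keep), qual = substring(qual, 1, keep),
       mean_q = if (keep > 0) mean(q[1:keep]) else 0)
}

# per-mate fate under the cascade, one read at a time
oracle_mate_fate <- function(seq, qual, adapter, phix_kmers, host_kmers,
                             k = 21, min_length = 50, min_mean_q = 25) {
  if (grepl("N", seq, fixed = TRUE)) return(list(fate = "n_base"))
  if (oracle_decoy(seq, phix_kmers, k)) return(list(fate = "phix"))
  tr <- oracle_trim(seq, qual, adapter)
  if (nchar(tr$seq) < min_length) return(list(fate = "short"))
  if (tr$mean_q <= min_mean_q) return(list(fate = "low_meanq"))
  if (oracle_decoy(tr$seq, host_kmers, k)) return(list(fate = "host"))
  list(fate = "pass", seq = tr$seq)
}

oracle_qc <- function(r1, r2, config = filter_config()) {
  phix_kmers <- unique(unlist(lapply(config$decoy_phix, oracle_kmer_set,
                                     k = config$decoy_k)))
  host_kmers <- unique(unlist(lapply(config$decoy_host, oracle_kmer_set,
                                     k = config$decoy_k)))
  f1 <- vapply(seq_len(nrow(r1)), function(i)
    oracle_mate_fate(r1$seq[i], r1$qual[i], config$adapter_fwd,
                     phix_kmers, host_kmers, config$decoy_k,
                     config$min_length, config$min_mean_quality)$fate,
    character(1))
  f2 <- vapply(seq_len(nrow(r2)), function(i)
    oracle_mate_fate(r2$seq[i], r2$qual[i], config$adapter_rev,
                     phix_kmers, host_kmers, config$decoy_k,
                     config$min_length, config$min_mean_quality)$fate,
    character(1))
  # step 7: orphans
  ok1 <- r1$id[f1 == "pass"]; ok2 <- r2$id[f2 == "pass"]
  keep <- intersect(ok1, ok2)
  f1[f1 == "pass" & !(r1$id %in% keep)] <- "orphan"
  f2[f2 == "pass" & !(r2$id %in% keep)] <- "orphan"
  list(r1 = f1, r2 = f2)
}

# build ~n engineered read pairs covering every filter branch
engineered_reads <- function(n = 1000, seed = 123) {
  withr::with_seed(seed, {
    cfg <- filter_config()
    phix <- cfg$decoy_phix; host <- cfg$decoy_host
    adapters <- qc_default_adapters()
    npairs <- ceiling(n / 2)
    kinds <- c("clean", "nbase", "phix", "host", "adapter", "lowtail",
               "short_after_trim", "low_meanq", "meanq_saved_by_trim")
    mk_mate <- function(kind, adapter) {
      rl <- 150
      seq <- random_nt(rl)
      q <- pmin(40, pmax(28, round(rnorm(rl, 35, 2))))
      if (kind == "nbase") {
        pos <- sample(rl, 1)
        substr(seq, pos, pos) <- "N"
      }
      if (kind == "phix") {
        st <- sample(nchar(phix) - rl + 1, 1)
        seq <- substring(phix, st, st + rl - 1)
      }
      if (kind == "host") {
        st <- sample(nchar(host) - rl + 1, 1)
        seq <- substring(host, st, st + rl - 1)
        if (runif(1) < 0.5) seq <- strainspec::revcomp(seq)
      }
      if (kind == "adapter") {
        frag <- sample(110:118, 1)
        seq <- paste0(substring(seq, 1, frag),
                      substring(adapter, 1, rl - frag))
      }
      if (kind == "lowtail") {
        tl <- sample(10:60, 1)
        q[(rl - tl + 1):rl] <- sample(2:17, tl, TRUE)
      }
      if (kind == "short_after_trim") {
        tl <- sample(101:140, 1)   # trimmed length < 50
        q[(rl - tl + 1):rl] <- sample(2:17, tl, TRUE)
      }
      if (kind == "low_meanq") q <- rep(22, rl)
      if (kind == "meanq_saved_by_trim") {
        # poor tail drags the raw mean below the cutoff; the trimmed head
        # is clean, so the read is kept only because trimming runs first
        q <- c(rep(35, 90), rep(3, 60))
      }
      q <- q[seq_len(nchar(seq))]
      list(seq = seq, qual = rawToChar(as.raw(q + 33L)))
    }
    r1 <- list(); r2 <- list()
    for (i in seq_len(npairs)) {
      k1 <- sample(kinds, 1, prob = c(5, 1, 1, 1, 1, 1, 1, 1, 1))
      k2 <- sample(kinds, 1, prob = c(5, 1, 1, 1, 1, 1, 1, 1, 1))
      m1 <- mk_mate(k1, adapters[["fwd"]])
      m2 <- mk_mate(k2, adapters[["rev"]])
      id <- sprintf("er%06d", i)
      r1[[i]] <- data.table::data.table(id = id, seq = m1$seq, qual = m1$qual,
                                        kind = k1)
      r2[[i]] <- data.table::data.table(id = id, seq = m2$seq, qual = m2$qual,
                                        kind = k2)
    }
    list(r1 = data.table::rbindlist(r1), r2 = data.table::rbindlist(r2))
  })
}

# Smith-Waterman oracle: plain dynamic programming, unit scores
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- H[i, j] + if (A[i] == B[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, s, H[i, j + 1] + gap, H[i + 1, j] + gap)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# random additive tree distances for NJ exactness checks
random_additive <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    list(tree = ape::unroot(tr), d = ape::cophenetic.phylo(tr))
  })
}
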