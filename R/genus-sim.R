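#' Simulate a genus-level count table with planted group effects
#'
#' Compositional model: per-genus log-normal latent abundances (genus
#' baselines drawn once, per-sample lognormal noise), closed to proportions
#' and sampled multinomially at a fixed sequencing depth.  Planted effect
#' genera have their latent mean multiplied by the stated fold-change in the
#' case group.  An optional continuous score covariate (a cognitive-score
#' stand-in) is coupled to one genus' latent abundance at a target Spearman
#' correlation.
#'
#' @param n_per_group named vector `c(healthy = ..., case = ...)`.
#' @param n_genera number of genera.
#' @param planted_effects named numeric vector: fold-changes (case over
#'   healthy, > 0) for the named genus indices, e.g. `c(g5 = 3)`.
#' @param score_link optional list `list(genus = <index>, rho = <target
#'   Spearman>)`; the score is built so its Spearman correlation with the
#'   linked genus' latent abundance is approximately `rho` (bivariate-normal
#'   calibration: Pearson `r = 2 sin(pi * rho / 6)`).
#' @param depth multinomial sequencing depth per sample.
#' @param baseline_sd spread of genus log-baselines.
#' @param sample_sd per-sample lognormal noise.
#' @param seed RNG seed.
#' @return list with `counts` (samples x genera integer matrix),
#'   `metadata` (data.table sample, group, score) and `params`.
#' @export
simulate_genus_table <- function(n_per_group = c(healthy = 20L, case = 15L),
                                 n_genera = 40L,
                                 planted_effects = numeric(0),
                                 score_link = NULL,
                                 depth = 30000L,
                                 baseline_sd = 1.5,
                                 sample_sd = 0.6,
                                 seed = 1L) {
  if (any(n_per_group < 1)) stopf("group counts must be positive")
  if (length(planted_effects) && any(planted_effects <= 0))
    stopf("planted fold-changes must be > 0")
  withr::with_seed(as.integer(seed), {
    n <- sum(n_per_group)
    groups <- rep(names(n_per_group), n_per_group)
    samples <- sprintf("%s%02d",
                       ifelse(groups == names(n_per_group)[1], "H", "C"),
                       unlist(lapply(n_per_group, seq_len)))
    genera <- sprintf("g%d", seq_len(n_genera))
    mu <- rnorm(n_genera, 0, baseline_sd)
    if (!is.null(score_link)) {
      gi <- score_link$genus
      mu[gi] <- abs(mu[gi]) + 1   # keep the linked genus well observed
    }
    eps <- matrix(rnorm(n * n_genera), n, n_genera)
    z <- sweep(eps * sample_sd, 2, mu, "+")
    if (length(planted_effects)) {
      idx <- match(names(planted_effects), genera)
      if (anyNA(idx)) stopf("unknown genus in planted_effects")
      case <- groups != names(n_per_group)[1]
      z[case, idx] <- sweep(z[case, idx, drop = FALSE], 2,
                            log(planted_effects), "+")
    }
    p <- exp(z)
    p <- p / rowSums(p)
    counts <- t(apply(p, 1, function(pi) rmultinom(1, depth, pi)[, 1]))
    dimnames(counts) <- list(samples, genera)

    score <- rep(NA_real_, n)
    if (!is.null(score_link)) {
      r <- 2 * sin(pi * score_link$rho / 6)
      lat <- scale(z[, score_link$genus])[, 1]
      score <- r * lat + sqrt(1 - r^2) * rnorm(n)
    }
    list(counts = counts,
         metadata = data.table::data.table(sample = samples, group = groups,
                                           score = score),
         params = list(mu = mu, planted_effects = planted_effects,
                       score_link = score_link, depth = depth))
  })
}
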