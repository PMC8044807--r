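# Shared simulation scales for the test suite. The methods vignette documents
# these problem sizes; they shrink the gene universe relative to the
# full-study defaults while keeping the planted-effect structure, noise and
# prevalence of the generator defaults.

sim_with <- function(defaults, seed, ...) {
  args <- c(defaults, list(seed = seed))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# study-sized cohort (n = 131) over a reduced gene universe
desk_sim <- function(seed, ...) {
  sim_with(list(n_individuals = 131, n_training_genes = 31,
                n_candidate_genes = 100, n_control_genes = 600,
                variants_per_gene = 10), seed, ...)
}

# small cohort for fast unit tests
tiny_sim <- function(seed, ...) {
  sim_with(list(n_individuals = 100, n_training_genes = 5,
                n_candidate_genes = 10, n_control_genes = 60,
                variants_per_gene = 5,
                effect_variants = list(list(role = "training", count = 3,
                                            beta = 0.8))), seed, ...)
}

# phenotype frame for direct association/model tests
pheno_frame <- function(nrs, extra = NULL) {
  ph <- data.frame(individual_id = sprintf("i%04d", seq_along(nrs)),
                   nrs_6_12mo = nrs, cpsp = as.integer(nrs > 3),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) ph <- cbind(ph, extra)
  ph
}

gmat <- function(X) {
  rownames(X) <- sprintf("i%04d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("v%03d", seq_len(ncol(X)))
  genotype_matrix(X)
}

# independent brute-force LD pruning oracle: same removal dialect, naive
# implementation using per-pair ld_r2()
ld_prune_oracle <- function(calls, chrom, pos, window, step, r2_max) {
  ord <- order(chrom, pos)
  calls <- calls[, ord, drop = FALSE]
  m <- ncol(calls)
  maf <- apply(calls, 2, compute_maf)
  alive <- rep(TRUE, m)
  start <- 1
  repeat {
    end <- min(start + window - 1, m)
    repeat {
      idx <- which(alive[start:end]) + start - 1
      if (length(idx) < 2) break
      pairs <- t(combn(idx, 2))
      r2 <- apply(pairs, 1, function(pr)
        suppressWarnings(ld_r2(calls[, pr[1]], calls[, pr[2]])))
      if (!any(r2 > r2_max)) break
      best <- which(r2 == max(r2))[1]
      vi <- pairs[best, 1]; vj <- pairs[best, 2]
      drop_v <- if (maf[vi] < maf[vj]) vi
        else if (maf[vj] < maf[vi]) vj else max(vi, vj)
      alive[drop_v] <- FALSE
    }
    if (end >= m) break
    start <- start + step
  }
  colnames(calls)[alive]
}

# exhaustive pairwise AUC oracle: fraction of (case, control) pairs ranked
# correctly, ties counting one half
auc_oracle <- function(scores, outcomes) {
  cs <- scores[outcomes == 1]; ct <- scores[outcomes == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}
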