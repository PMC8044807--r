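#' Enrichment test configuration
#'
#' Parameters of the cumulative ranked gene-set enrichment test: the nominal
#' per-variant significance threshold, the number of matched control
#' resampling runs, the minor-allele-frequency bands used to match control
#' draws to the case set's frequency profile, and the candidate-gene
#' increment per cumulative step.
#'
#' @param alpha Nominal per-variant significance threshold.
#' @param n_runs Number of matched control draws.
#' @param maf_breaks Band edges; defaults give bands
#'   \[0.10, 0.15), \[0.15, 0.20), \[0.20, 0.30), \[0.30, 0.50\] (left-closed,
#'   right-open, last band closed).
#' @param increment Candidate-gene fraction added per cumulative step.
#' @param seed Integer seed for the resampling generator.
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(alpha = 0.05, n_runs = 10000,
                              maf_breaks = c(0.10, 0.15, 0.20, 0.30, 0.50),
                              increment = 0.10, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_runs >= 1,
            length(maf_breaks) >= 2, !is.unsorted(maf_breaks),
            increment > 0, increment <= 1)
  structure(list(alpha = alpha, n_runs = as.integer(n_runs),
                 maf_breaks = maf_breaks, increment = increment,
                 seed = as.integer(seed)),
            class = "enrichment_config")
}

#' Assign a minor-allele frequency band
#'
#' Bands are left-closed and right-open except the last, which is closed:
#' with the default breaks, \[0.10, 0.15), \[0.15, 0.20), \[0.20, 0.30),
#' \[0.30, 0.50\]. Frequencies below the first edge should have been removed
#' by QC and raise an error.
#'
#' @param maf Numeric vector of minor allele frequencies.
#' @param config An [enrichment_config()].
#' @return Integer band indices (1-based).
#' @export
assign_maf_band <- function(maf, config = enrichment_config()) {
  br <- config$maf_breaks
  if (any(maf < br[1] | maf > br[length(br)], na.rm = TRUE))
    stop("MAF outside banded range [", br[1], ", ", br[length(br)],
         "]: should have been excluded by QC")
  band <- findInterval(maf, br, rightmost.closed = TRUE)
  as.integer(band)
}

#' Cumulative ranked variant sets
#'
#' Builds the sequence of nested case variant sets tested for enrichment: set
#' 0 holds the variants of the curated training genes; set k adds the
#' variants of the top k x `increment` fraction of ranked candidate genes
#' (ceiling on fractional gene counts, so the final set contains every
#' candidate). With the default 10% increment there are 11 sets, labelled
#' `0%` through `100%`.
#'
#' @param ranked A [ranked_gene_sets()] object.
#' @param annotation Variant annotation data frame with `variant_id`, `gene`.
#' @param config An [enrichment_config()].
#' @return Named list of character vectors of variant ids, monotone nested.
#' @export
cumulative_sets <- function(ranked, annotation, config = enrichment_config()) {
  stopifnot(inherits(ranked, "ranked_gene_sets"))
  if (length(ranked$training) == 0) stop("empty training set")
  steps <- seq(0, 1, by = config$increment)
  if (steps[length(steps)] < 1) steps <- c(steps, 1)
  n_cand <- length(ranked$candidate)
  sets <- lapply(steps, function(f) {
    k <- ceiling(f * n_cand)
    genes <- c(ranked$training, if (k > 0) ranked$candidate[seq_len(k)])
    annotation$variant_id[annotation$gene %in% genes]
  })
  names(sets) <- paste0(round(steps * 100), "%")
  sets
}

#' Draw one MAF-matched control variant set
#'
#' Samples, without replacement, a control variant set with exactly the same
#' per-band MAF composition as the case set. Errors if the control pool
#' cannot supply a band.
#'
#' @param case_bands Integer band index per case variant.
#' @param pool_ids Character ids of the control pool variants.
#' @param pool_bands Integer band index per pool variant.
#' @return Character vector of drawn control variant ids (length = case set).
#' @export
draw_matched_control <- function(case_bands, pool_ids, pool_bands) {
  need <- table(factor(case_bands, levels = sort(unique(c(case_bands, pool_bands)))))
  out <- character(0)
  for (b in names(need)) {
    k <- as.integer(need[[b]])
    if (k == 0) next
    in_band <- which(pool_bands == as.integer(b))
    if (length(in_band) < k)
      stop("control pool has only ", length(in_band),
           " variants in band ", b, " but ", k, " are needed")
    out <- c(out, pool_ids[in_band[sample.int(length(in_band), k)]])
  }
  out
}

#' Resampling enrichment test for one variant set
#'
#' Compares the number of nominally significant case variants against the
#' null distribution of that count in `n_runs` MAF-band-matched control
#' draws. The empirical p-value is the proportion of draws whose significant
#' count equals or exceeds the observed count (raw count divided by
#' `n_runs`; an add-one corrected version is also reported). The `enriched`
#' flag follows the percentile rule: observed count strictly greater than the
#' 95th percentile of the null counts.
#'
#' @param case_pvals Association p-values of the case set.
#' @param case_bands MAF band index per case variant.
#' @param pool_pvals Association p-values of the control pool.
#' @param pool_bands MAF band index per pool variant.
#' @param config An [enrichment_config()]. The resampling generator is seeded
#'   from `config$seed` unless `use_current_rng` is `TRUE` (the pipeline sets
#'   this to draw all sets from one seeded stream).
#' @param use_current_rng Use the caller's RNG state instead of reseeding.
#' @return A list of class `enrichment_result` with `n_case_variants`,
#'   `observed_significant`, `null_counts`, `null_q95`, `empirical_p`,
#'   `empirical_p_corrected` and `enriched`.
#' @export
enrichment_test <- function(case_pvals, case_bands, pool_pvals, pool_bands,
                            config = enrichment_config(),
                            use_current_rng = FALSE) {
  stopifnot(length(case_pvals) == length(case_bands),
            length(pool_pvals) == length(pool_bands))
  if (!use_current_rng) set.seed(config$seed)
  alpha <- config$alpha
  observed <- sum(case_pvals < alpha, na.rm = TRUE)
  pool_sig <- pool_pvals < alpha
  bands <- sort(unique(case_bands))
  need <- vapply(bands, function(b) sum(case_bands == b), integer(1))
  band_sig <- lapply(bands, function(b) pool_sig[pool_bands == b])
  for (i in seq_along(bands)) {
    if (length(band_sig[[i]]) < need[i])
      stop("control pool has only ", length(band_sig[[i]]),
           " variants in band ", bands[i], " but ", need[i], " are needed")
  }
  null_counts <- integer(config$n_runs)
  for (r in seq_len(config$n_runs)) {
    cnt <- 0L
    for (i in seq_along(bands)) {
      sb <- band_sig[[i]]
      cnt <- cnt + sum(sb[sample.int(length(sb), need[i])], na.rm = TRUE)
    }
    null_counts[r] <- cnt
  }
  q95 <- stats::quantile(null_counts, 0.95, names = FALSE, type = 7)
  structure(list(n_case_variants = length(case_pvals),
                 observed_significant = observed,
                 null_counts = null_counts,
                 null_q95 = q95,
                 empirical_p = sum(null_counts >= observed) / config$n_runs,
                 empirical_p_corrected =
                   (sum(null_counts >= observed) + 1) / (config$n_runs + 1),
                 enriched = observed > q95),
            class = "enrichment_result")
}

#' Run the cumulative enrichment analysis
#'
#' Applies [enrichment_test()] to every cumulative ranked case set against
#' the control-gene variant pool, with per-set independent matched draws from
#' a single seeded stream. MAF bands are assigned from the observed MAF in
#' `annotation$maf`.
#'
#' @param assoc Association results ([snp_association()]) covering case and
#'   control variants.
#' @param annotation Variant annotation with `variant_id`, `gene`, `role`,
#'   `maf`.
#' @param ranked A [ranked_gene_sets()] object.
#' @param config An [enrichment_config()].
#' @return A list of class `enrichment_scan`: `summary` (one row per set),
#'   `results` (per-set `enrichment_result`s), `minimal_enriched`
#'   (label or `NA`).
#' @export
run_enrichment <- function(assoc, annotation, ranked,
                           config = enrichment_config()) {
  ann <- annotation[match(assoc$variant_id, annotation$variant_id), ]
  band <- assign_maf_band(ann$maf, config)
  pval <- assoc$p_value
  names(pval) <- assoc$variant_id
  names(band) <- assoc$variant_id
  pool_ids <- assoc$variant_id[ann$gene %in% ranked$control]
  sets <- cumulative_sets(ranked, ann, config)
  set.seed(config$seed)
  results <- lapply(sets, function(ids) {
    ids <- intersect(ids, assoc$variant_id)
    enrichment_test(pval[ids], band[ids], pval[pool_ids], band[pool_ids],
                    config, use_current_rng = TRUE)
  })
  summary <- data.frame(
    set_label = names(sets),
    n_case_variants = vapply(results, `[[`, integer(1), "n_case_variants"),
    observed_significant = vapply(results, `[[`, integer(1), "observed_significant"),
    null_mean = vapply(results, function(r) mean(r$null_counts), numeric(1)),
    null_q95 = vapply(results, `[[`, numeric(1), "null_q95"),
    empirical_p = vapply(results, `[[`, numeric(1), "empirical_p"),
    enriched = vapply(results, `[[`, logical(1), "enriched"),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(summary = summary, results = results,
                 minimal_enriched = minimal_enriched_set(summary),
                 sets = sets),
            class = "enrichment_scan")
}

#' Earliest enriched cumulative set
#'
#' Returns the label of the first cumulative set flagged enriched — the
#' minimal set of variants enriched for associations — or `NA` when no set
#' is enriched.
#'
#' @param summary Either an `enrichment_scan` or its `summary` data frame
#'   (rows ordered by centile).
#' @return Set label (e.g. `"0%"`) or `NA_character_`.
#' @export
minimal_enriched_set <- function(summary) {
  if (inherits(summary, "enrichment_scan")) summary <- summary$summary
  hit <- which(summary$enriched)
  if (length(hit) == 0) NA_character_ else summary$set_label[hit[1]]
}

#' @export
print.enrichment_scan <- function(x, ...) {
  cat("Cumulative gene-set enrichment scan\n")
  print(x$summary, row.names = FALSE)
  cat("minimal enriched set:",
      if (is.na(x$minimal_enriched)) "none" else x$minimal_enriched, "\n")
  invisible(x)
}
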