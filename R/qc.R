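#' Variant QC configuration
#'
#' Thresholds for variant-level quality control and LD pruning. Defaults
#' reproduce a conventional small-cohort candidate-gene workflow: 95% call
#' rate, Hardy-Weinberg goodness-of-fit p >= 1e-4, minor allele frequency
#' >= 10%, and sliding-window LD pruning with window 50 variants, step 5,
#' r^2 ceiling 0.8 (the PLINK `--indep-pairwise 50 5 0.8` convention).
#'
#' @param call_rate_min Minimum per-variant call rate (proportion).
#' @param hwe_p_min Minimum Hardy-Weinberg chi-square p-value.
#' @param maf_min Minimum minor allele frequency.
#' @param ld_window Sliding window size, in variants.
#' @param ld_step Window advance, in variants.
#' @param ld_r2_max Maximum tolerated pairwise r^2 within a window.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(call_rate_min = 0.95, hwe_p_min = 1e-4, maf_min = 0.10,
                      ld_window = 50, ld_step = 5, ld_r2_max = 0.8) {
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            maf_min >= 0, maf_min < 0.5,
            ld_window >= 2, ld_step >= 1,
            ld_r2_max > 0, ld_r2_max <= 1)
  structure(list(call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
                 maf_min = maf_min, ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step), ld_r2_max = ld_r2_max),
            class = "qc_config")
}

#' Minor allele frequency from allele-count calls
#'
#' @param calls Integer vector of minor-allele counts (0/1/2), `NA` = missing.
#' @return `min(p, 1 - p)` where `p` is the sample frequency of the counted
#'   allele among non-missing calls; always in `[0, 0.5]`.
#' @examples
#' compute_maf(rep(c(0L, 1L, 2L), c(25, 50, 25)))  # 0.5
#' @export
compute_maf <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("all calls missing: MAF undefined")
  p <- sum(calls) / (2 * length(calls))
  min(p, 1 - p)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed genotype
#' counts against Hardy-Weinberg expectations at the sample allele frequency.
#' Monomorphic variants return p = 1 by convention (no test possible).
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts.
#' @return The chi-square p-value.
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE, p = 1
#' hwe_test(50, 0, 50)   # total heterozygote deficit, p ~ 1.5e-23
#' @export
hwe_test <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  if (n <= 0) stop("no genotype calls")
  p <- (2 * n_hom_minor + n_het) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  observed <- c(n_hom_major, n_het, n_hom_minor)
  stat <- sum((observed - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

hwe_test_calls <- function(calls) {
  calls <- calls[!is.na(calls)]
  hwe_test(sum(calls == 0L), sum(calls == 1L), sum(calls == 2L))
}

#' Variant-level QC filter
#'
#' Retains autosomal, gene-annotated variants passing call-rate, Hardy-
#' Weinberg and minor-allele-frequency thresholds. Exclusions are applied and
#' reported in a fixed order so counts are reproducible: non-autosomal,
#' gene-less, call rate, HWE, MAF. A variant is counted against the first
#' criterion it fails.
#'
#' @param genotypes A [genotype_matrix()].
#' @param annotation Data frame with at least `variant_id`, `chrom`, `gene`.
#' @param config A [qc_config()].
#' @return A list with `genotypes` (filtered, same class), `annotation`
#'   (filtered rows, with observed `maf` recomputed) and `report` (data frame
#'   of per-criterion exclusion counts).
#' @export
filter_variants <- function(genotypes, annotation, config = qc_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "qc_config"))
  if (!all(genotypes$variant_ids %in% annotation$variant_id))
    stop("annotation does not cover all variants")
  ann <- annotation[match(genotypes$variant_ids, annotation$variant_id), ]
  calls <- genotypes$calls
  n_ind <- nrow(calls)

  chrom <- suppressWarnings(as.integer(as.character(ann$chrom)))
  autosomal <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  has_gene <- !is.na(ann$gene) & ann$gene != "" & ann$gene != "."
  call_rate <- colSums(!is.na(calls)) / n_ind
  keep <- autosomal
  excl <- ifelse(!autosomal, "non_autosomal", NA_character_)
  excl[is.na(excl) & !has_gene] <- "gene_less"
  keep <- keep & has_gene
  excl[is.na(excl) & call_rate < config$call_rate_min] <- "call_rate"
  keep <- keep & call_rate >= config$call_rate_min
  # HWE and MAF evaluated only for variants still in play
  hwe_p <- rep(NA_real_, ncol(calls))
  maf <- rep(NA_real_, ncol(calls))
  idx <- which(keep)
  if (length(idx) > 0) {
    hwe_p[idx] <- apply(calls[, idx, drop = FALSE], 2, hwe_test_calls)
    maf[idx] <- apply(calls[, idx, drop = FALSE], 2, compute_maf)
  }
  excl[is.na(excl) & keep & hwe_p < config$hwe_p_min] <- "hwe"
  keep <- keep & !is.na(hwe_p) & hwe_p >= config$hwe_p_min
  excl[is.na(excl) & keep & maf < config$maf_min] <- "maf"
  keep <- keep & maf >= config$maf_min

  report <- data.frame(
    criterion = c("non_autosomal", "gene_less", "call_rate", "hwe", "maf", "retained"),
    n = c(sum(excl == "non_autosomal", na.rm = TRUE),
          sum(excl == "gene_less", na.rm = TRUE),
          sum(excl == "call_rate", na.rm = TRUE),
          sum(excl == "hwe", na.rm = TRUE),
          sum(excl == "maf", na.rm = TRUE),
          sum(keep)),
    stringsAsFactors = FALSE
  )
  ann_out <- ann[keep, , drop = FALSE]
  ann_out$maf <- maf[keep]
  rownames(ann_out) <- NULL
  out_geno <- genotype_matrix(calls[, keep, drop = FALSE])
  list(genotypes = out_geno, annotation = ann_out, report = report)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two additive-coded call vectors,
#' using pairwise-complete observations. A zero-variance vector makes the
#' correlation undefined; it is treated as r^2 = 0 with a warning.
#'
#' @param calls_a,calls_b Integer vectors of minor-allele counts over the
#'   same individuals.
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(calls_a, calls_b) {
  ok <- !is.na(calls_a) & !is.na(calls_b)
  a <- calls_a[ok]; b <- calls_b[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance in pairwise-complete calls; r^2 treated as 0")
    return(0)
  }
  stats::cor(a, b)^2
}

# Pairwise-complete r^2 matrix over the columns of an allele-count matrix,
# via masked crossproducts (fast path for window-sized blocks). Undefined
# correlations (zero variance in the pairwise-complete subset) are 0, the
# ld_r2() convention.
r2_pairwise_matrix <- function(calls) {
  O <- !is.na(calls)
  A <- calls
  A[!O] <- 0
  storage.mode(A) <- "double"
  storage.mode(O) <- "double"
  n <- crossprod(O)
  s12 <- crossprod(A)
  s1 <- crossprod(A, O)        # s1[i, j] = sum of a_i over pairwise-complete ij
  s11 <- crossprod(A * A, O)   # s11[i, j] = sum of a_i^2 over pairwise-complete ij
  num <- n * s12 - s1 * t(s1)
  den <- (n * s11 - s1^2) * t(n * s11 - s1^2)
  r2 <- ifelse(den > 0, num^2 / den, 0)
  r2[n < 2] <- 0
  pmin(r2, 1)
}

#' Sliding-window LD pruning
#'
#' Greedy LD pruning in the `indep-pairwise` style: a window of `window`
#' variants (ordered by chromosome, then position) is scanned; while any pair
#' within the window has r^2 above `r2_max`, one member is removed; the
#' window then advances by `step` variants. Removal rule: among offending
#' pairs the pair with the largest r^2 is resolved first (ties by variant
#' order), dropping the member with the lower observed MAF; on a MAF tie the
#' later-position variant is dropped.
#'
#' @param genotypes A [genotype_matrix()].
#' @param annotation Data frame with `variant_id`, `chrom`, `pos` covering all
#'   variants.
#' @param window,step Window size and advance, in variants.
#' @param r2_max Maximum tolerated pairwise r^2.
#' @return Character vector of retained variant identifiers, in genomic order.
#' @export
ld_prune <- function(genotypes, annotation, window = 50, step = 5, r2_max = 0.8) {
  if (window < 2) stop("window must be at least 2 variants")
  stopifnot(step >= 1)
  ann <- annotation[match(genotypes$variant_ids, annotation$variant_id), ]
  ord <- order(suppressWarnings(as.integer(as.character(ann$chrom))), ann$pos)
  ids <- genotypes$variant_ids[ord]
  calls <- genotypes$calls[, ord, drop = FALSE]
  maf <- apply(calls, 2, compute_maf)
  m <- length(ids)
  alive <- rep(TRUE, m)

  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- which(alive[start:end]) + start - 1L
    if (length(idx) >= 2) {
      # pairwise r^2 is unaffected by removing other variants, so one
      # computation per window suffices
      r2 <- r2_pairwise_matrix(calls[, idx, drop = FALSE])
      r2[lower.tri(r2, diag = TRUE)] <- 0
      repeat {
        in_play <- alive[idx]
        r2w <- r2
        r2w[!in_play, ] <- 0
        r2w[, !in_play] <- 0
        off <- which(r2w > r2_max, arr.ind = TRUE)
        if (nrow(off) == 0) break
        best <- off[order(-r2w[off], off[, 1], off[, 2])[1], ]
        vi <- idx[best[1]]; vj <- idx[best[2]]
        drop_v <- if (maf[vi] < maf[vj]) vi
          else if (maf[vj] < maf[vi]) vj
          else max(vi, vj)  # later genomic position
        alive[drop_v] <- FALSE
        if (sum(alive[idx]) < 2) break
      }
    }
    if (end >= m) break
    start <- start + step
  }
  ids[alive]
}
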