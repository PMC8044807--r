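#' Simulation configuration for a synthetic surgical cohort
#'
#' Defines the statistical structure of a synthetic CPSP cohort: biallelic
#' autosomal genotypes in Hardy-Weinberg proportions with a configurable MAF
#' spectrum and optional within-gene LD, a ranked candidate-gene universe
#' seeded by a curated training set, planted additive variant effects on a
#' continuous 0-10 pain outcome, a CASI-like anxiety-sensitivity covariate
#' with a positive effect, and a dichotomous CPSP outcome (pain > 3) tuned to
#' a target prevalence.
#'
#' Defaults emulate a prospective adolescent spine-fusion cohort: 131
#' individuals with ~40% CPSP prevalence, CASI mean 28.6 (SD 5.5), a
#' 31-gene training set plus 1305 ranked candidate genes, a large
#' control-gene pool, and MAF uniform on \[0.10, 0.50\]. The planted signal
#' (30 training-gene variants at 0.8 NRS per risk allele, residual SD 2)
#' reproduces the scale of excess nominal associations such a cohort shows
#' in its training set.
#'
#' @param n_individuals Cohort size.
#' @param n_training_genes,n_candidate_genes,n_control_genes Gene counts for
#'   the curated training set, the ranked candidate list, and the disjoint
#'   control pool.
#' @param variants_per_gene Single count or `c(min, max)` range; the number
#'   of variants simulated per gene.
#' @param maf_range Length-2 numeric in `[0.10, 0.50]`; per-variant MAFs are
#'   drawn uniformly from this interval.
#' @param ld_rho Within-gene adjacent-variant latent correlation in `[0, 1)`
#'   (AR(1) Gaussian copula). Not an estimate of any real cohort; a free
#'   parameter for exercising the LD pruner.
#' @param effect_variants List of planted effects, each
#'   `list(role =, count =, beta =)` with `role` in
#'   `c("training", "candidate", "control")` and `beta` in NRS units per
#'   risk (minor) allele.
#' @param casi_effect NRS units per CASI point.
#' @param noise_sd Residual SD of the continuous pain outcome, NRS units.
#' @param dichotomize_threshold CPSP is pain score strictly greater than this.
#' @param target_prevalence Desired proportion with CPSP.
#' @param missing_rate Completely-at-random missing-call proportion.
#' @param seed Integer master seed; all randomness flows from it through
#'   named substreams (genes, genotypes, phenotypes, missingness).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 131,
                       n_training_genes = 31,
                       n_candidate_genes = 1305,
                       n_control_genes = 10000,
                       variants_per_gene = c(10, 40),
                       maf_range = c(0.10, 0.50),
                       ld_rho = 0.3,
                       effect_variants = list(list(role = "training", count = 30, beta = 0.8)),
                       casi_effect = 0.15,
                       noise_sd = 2,
                       dichotomize_threshold = 3,
                       target_prevalence = 0.40,
                       missing_rate = 0.01,
                       seed = 1L) {
  stopifnot(n_individuals > 0, n_training_genes > 0,
            n_candidate_genes >= 0, n_control_genes > 0,
            length(maf_range) == 2, maf_range[1] >= 0.10, maf_range[2] <= 0.50,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1,
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1,
            target_prevalence > 0, target_prevalence < 1)
  if (length(variants_per_gene) == 1) variants_per_gene <- rep(variants_per_gene, 2)
  stopifnot(variants_per_gene[1] >= 1, variants_per_gene[1] <= variants_per_gene[2])
  for (ev in effect_variants) {
    stopifnot(is.list(ev), ev$role %in% c("training", "candidate", "control"),
              ev$count >= 0, is.numeric(ev$beta))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_training_genes = as.integer(n_training_genes),
                 n_candidate_genes = as.integer(n_candidate_genes),
                 n_control_genes = as.integer(n_control_genes),
                 variants_per_gene = as.integer(variants_per_gene),
                 maf_range = maf_range, ld_rho = ld_rho,
                 effect_variants = effect_variants,
                 casi_effect = casi_effect, noise_sd = noise_sd,
                 dichotomize_threshold = dichotomize_threshold,
                 target_prevalence = target_prevalence,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic substream seed below 2^31, derived from the master seed and a
# stream name so stages are independently reproducible.
substream_seed <- function(seed, stream) {
  offset <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483647L) + 1L
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Ranked gene universe constructor
#'
#' @param training Character vector of curated training-gene symbols.
#' @param candidate Character vector of candidate genes, best rank first.
#' @param control Character vector of control-pool genes, disjoint from the
#'   case (training plus candidate) universe.
#' @return A list of class `ranked_gene_sets`. Training genes that also
#'   appear in the candidate ranking are de-duplicated into the training set.
#' @export
ranked_gene_sets <- function(training, candidate, control) {
  training <- as.character(training); candidate <- as.character(candidate)
  control <- as.character(control)
  if (anyDuplicated(training) || anyDuplicated(candidate) || anyDuplicated(control))
    stop("duplicate gene symbols within a set")
  candidate <- setdiff(candidate, training)  # training wins on overlap
  case <- c(training, candidate)
  overlap <- intersect(case, control)
  if (length(overlap) > 0)
    stop("control genes overlap case genes: ", paste(utils::head(overlap, 5), collapse = ", "))
  structure(list(training = training, candidate = candidate, control = control),
            class = "ranked_gene_sets")
}

#' Simulate a ranked gene universe
#'
#' Generates symbolic training, ranked candidate, and control gene sets of
#' the sizes given in the configuration. Candidate genes carry a total order
#' (rank 1 = most similar to the training set).
#'
#' @param config A [sim_config()].
#' @return A [ranked_gene_sets()] object.
#' @export
simulate_ranked_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fmt <- function(prefix, n) if (n == 0) character(0) else
    sprintf("%s%05d", prefix, seq_len(n))
  ranked_gene_sets(training = fmt("TRG", config$n_training_genes),
                   candidate = fmt("CND", config$n_candidate_genes),
                   control = fmt("CTL", config$n_control_genes))
}

# Genotypes in HWE at given MAFs with optional AR(1) latent LD within blocks.
# block_id groups adjacent variants (a gene); maf is per variant.
simulate_genotype_block <- function(n, maf, rho) {
  j <- length(maf)
  z <- matrix(stats::rnorm(n * j), n, j)
  if (rho > 0 && j > 1) {
    s <- sqrt(1 - rho^2)
    for (k in 2:j) z[, k] <- rho * z[, k - 1] + s * z[, k]
  }
  # threshold latent normals at HWE cumulative genotype probabilities
  t0 <- stats::qnorm((1 - maf)^2)          # below: hom major (0)
  t1 <- stats::qnorm(1 - maf^2)            # above: hom minor (2)
  g <- matrix(0L, n, j)
  g <- g + (z > rep(t0, each = n)) + (z > rep(t1, each = n))
  storage.mode(g) <- "integer"
  g
}

#' Simulate a synthetic CPSP cohort
#'
#' Draws genotypes in Hardy-Weinberg proportions (optionally with within-gene
#' LD via a Gaussian AR(1) copula), plants additive effects on configured
#' variants, simulates covariates, and builds the continuous pain outcome
#' `intercept + sum(beta * risk-allele count) + casi_effect * CASI + noise`.
#' The intercept is tuned so the dichotomized prevalence matches the target;
#' the realized prevalence is checked and an informative error is raised if
#' it cannot be attained (for example with zero residual noise and no
#' effects). Missing calls are then masked completely at random.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `genotypes`
#'   ([genotype_matrix()]), `annotation` (data frame), `ranked_genes`,
#'   `phenotypes` (data frame), `truth` (planted effects) and `intercept`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ranked <- simulate_ranked_genes(config)
  genes <- data.frame(
    gene = c(ranked$training, ranked$candidate, ranked$control),
    role = c(rep("training", length(ranked$training)),
             if (length(ranked$candidate) > 0)
               paste0("candidate:", seq_along(ranked$candidate)) else character(0),
             rep("control", length(ranked$control))),
    stringsAsFactors = FALSE
  )
  g_total <- nrow(genes)

  # --- gene structure substream: variant counts, MAFs, positions, alleles
  set.seed(substream_seed(config$seed, "genes"))
  vpg <- config$variants_per_gene
  n_var_gene <- if (vpg[1] == vpg[2]) rep(vpg[1], g_total) else
    sample(vpg[1]:vpg[2], g_total, replace = TRUE)
  m <- sum(n_var_gene)
  gene_of <- rep(genes$gene, n_var_gene)
  role_of <- rep(genes$role, n_var_gene)
  true_maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  # genes laid out contiguously across autosomes 1..22
  genes_per_chr <- ceiling(g_total / 22)
  chr_of_gene <- rep(1:22, each = genes_per_chr, length.out = g_total)
  gene_index_in_chr <- stats::ave(seq_len(g_total), chr_of_gene, FUN = seq_along)
  gene_start <- 1e6 + (gene_index_in_chr - 1) * 2e5
  pos <- unlist(lapply(seq_len(g_total), function(i)
    gene_start[i] + (seq_len(n_var_gene[i]) - 1L) * 1000L), use.names = FALSE)
  chrom <- rep(chr_of_gene, n_var_gene)
  allele_pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2, byrow = TRUE)
  ap <- allele_pairs[sample.int(4, m, replace = TRUE), , drop = FALSE]
  variant_id <- sprintf("var%07d", seq_len(m))

  annotation <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                           major_allele = ap[, 1], minor_allele = ap[, 2],
                           gene = gene_of, role = role_of, true_maf = true_maf,
                           stringsAsFactors = FALSE)

  # --- effect substream: which variants carry planted betas
  set.seed(substream_seed(config$seed, "effects"))
  truth <- data.frame(variant_id = character(0), gene = character(0),
                      role = character(0), beta = numeric(0),
                      stringsAsFactors = FALSE)
  base_role <- sub(":.*$", "", role_of)
  for (ev in config$effect_variants) {
    if (ev$count == 0) next
    pool <- which(base_role == ev$role)
    if (length(pool) < ev$count)
      stop("not enough ", ev$role, " variants to plant ", ev$count, " effects")
    pick <- sort(sample(pool, ev$count))
    truth <- rbind(truth, data.frame(variant_id = variant_id[pick],
                                     gene = gene_of[pick], role = base_role[pick],
                                     beta = ev$beta, stringsAsFactors = FALSE))
  }

  # --- genotype substream
  set.seed(substream_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  block_ends <- cumsum(n_var_gene)
  block_starts <- c(1L, utils::head(block_ends, -1) + 1L)
  calls <- matrix(0L, n, m)
  for (i in seq_len(g_total)) {
    idx <- block_starts[i]:block_ends[i]
    calls[, idx] <- simulate_genotype_block(n, true_maf[idx], config$ld_rho)
  }
  individual_ids <- sprintf("ind%04d", seq_len(n))
  rownames(calls) <- individual_ids
  colnames(calls) <- variant_id

  # --- phenotype substream
  set.seed(substream_seed(config$seed, "phenotypes"))
  casi <- rtruncnorm1(n, 28.6, 5.5, 10, 54)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.754, 0.246))
  race <- sample(c("white", "nonwhite"), n, replace = TRUE, prob = c(0.818, 0.182))
  age <- rtruncnorm1(n, 14.5, 1.8, 10, 18)
  weight <- rtruncnorm1(n, 57.4, 15.3, 30, 120)
  surgical_duration <- rtruncnorm1(n, 4.8, 1.2, 2, 10)
  levels_fused <- pmax(4L, pmin(18L, round(stats::rnorm(n, 11.5, 2.0))))
  propofol <- rtruncnorm1(n, 71.8, 27.2, 10, 200)
  remifentanil <- rtruncnorm1(n, 113.9, 40.9, 20, 300)
  auc_pod12 <- rtruncnorm1(n, 200.3, 73.5, 20, 500)
  morphine_meq <- rtruncnorm1(n, 1.63, 0.75, 0.1, 5)
  preop_pain <- ifelse(stats::runif(n) < 0.75, 0,
                       sample(1:5, n, replace = TRUE))
  noise <- stats::rnorm(n, 0, config$noise_sd)

  genetic <- if (nrow(truth) > 0)
    as.numeric(calls[, truth$variant_id, drop = FALSE] %*% truth$beta) else
    numeric(n)
  base <- genetic + config$casi_effect * casi + noise
  intercept <- config$dichotomize_threshold -
    stats::quantile(base, 1 - config$target_prevalence, names = FALSE)
  nrs <- pmin(10, pmax(0, base + intercept))
  cpsp <- as.integer(nrs > config$dichotomize_threshold)
  realized <- mean(cpsp)
  if (abs(realized - config$target_prevalence) > 0.1)
    stop(sprintf(paste("target prevalence %.2f unattainable: realized %.2f;",
                       "outcome distribution too discrete near the threshold",
                       "(check noise_sd and effect sizes)"),
                 config$target_prevalence, realized))

  phenotypes <- data.frame(
    individual_id = individual_ids, nrs_6_12mo = nrs, cpsp = cpsp,
    casi = casi, preop_pain = preop_pain, sex = sex, race = race, age = age,
    weight = weight, surgical_duration = surgical_duration,
    levels_fused = levels_fused, propofol = propofol,
    remifentanil = remifentanil, auc_pod12 = auc_pod12,
    morphine_meq = morphine_meq, stringsAsFactors = FALSE
  )

  # --- missingness substream (after phenotype construction: outcomes are
  # driven by true genotypes, observation is lossy)
  set.seed(substream_seed(config$seed, "missingness"))
  if (config$missing_rate > 0) {
    mask <- stats::runif(n * m) < config$missing_rate
    calls[mask] <- NA_integer_
  }
  annotation$maf <- apply(calls, 2, function(v)
    if (all(is.na(v))) NA_real_ else compute_maf(v))

  structure(list(genotypes = genotype_matrix(calls),
                 annotation = annotation, ranked_genes = ranked,
                 phenotypes = phenotypes, truth = truth,
                 intercept = intercept, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$genotypes$calls), "individuals,",
      ncol(x$genotypes$calls), "variants,",
      nrow(x$truth), "planted effect variants; CPSP prevalence",
      sprintf("%.1f%%", 100 * mean(x$phenotypes$cpsp)), "\n")
  invisible(x)
}
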