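#' Modal-genotype imputation within ancestry groups
#'
#' Penalized regression requires complete genotypes. This stand-in replaces
#' each missing call with the modal genotype among non-missing calls of the
#' same variant within the individual's ancestry group (ties broken toward
#' the smaller allele count). It is a deliberately simple in-package
#' imputation; reference-panel haplotype imputation is out of scope.
#'
#' @param genotypes A [genotype_matrix()].
#' @param group Character/factor vector of group labels, one per individual
#'   (e.g. self-reported race), or `NULL` for a single group.
#' @return A list: `genotypes` (complete), `n_imputed` (cells imputed),
#'   `n_observed` (non-missing cells available for accuracy accounting).
#' @export
impute_missing_mode <- function(genotypes, group = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  calls <- genotypes$calls
  n <- nrow(calls)
  if (is.null(group)) group <- rep("all", n)
  stopifnot(length(group) == n)
  n_missing <- sum(is.na(calls))
  if (n_missing > 0) {
    for (g in unique(group)) {
      rows <- which(group == g)
      sub <- calls[rows, , drop = FALSE]
      cols <- which(colSums(is.na(sub)) > 0)
      for (j in cols) {
        v <- sub[, j]
        obs <- v[!is.na(v)]
        if (length(obs) == 0)
          stop("variant ", genotypes$variant_ids[j],
               " missing in every member of group '", g, "'")
        tab <- table(obs)
        mode_g <- as.integer(names(tab)[which.max(tab)])  # ties -> smaller count
        v[is.na(v)] <- mode_g
        calls[rows, j] <- v
      }
    }
  }
  list(genotypes = genotype_matrix(calls),
       n_imputed = n_missing,
       n_observed = n * ncol(calls) - n_missing)
}

#' Dual-LASSO variant selection
#'
#' Fits an L1-penalized linear regression of the continuous pain outcome and
#' an L1-penalized logistic regression of the dichotomous CPSP outcome on the
#' additive-coded candidate variants, each with its penalty chosen by k-fold
#' cross-validation (`lambda.min`), and returns the variants with non-zero
#' coefficients in **both** models. Covariates are not penalized nor included
#' by default; genotype columns are left unstandardized (additive-count
#' scale) unless `standardize = TRUE`.
#'
#' @param genotypes Complete (no missing calls) [genotype_matrix()].
#' @param phenotypes Phenotype data frame with the two outcomes.
#' @param candidate_variants Variant ids to offer to the penalized models,
#'   typically the minimal enriched set.
#' @param cv_folds Number of CV folds.
#' @param seed Seed fixing the CV fold assignment.
#' @param outcome,binary_outcome Outcome column names.
#' @param standardize Standardize genotype columns inside glmnet.
#' @return List with `selected` (intersection), `selected_linear`,
#'   `selected_logistic`, and the two `cv.glmnet` fits.
#' @export
lasso_select <- function(genotypes, phenotypes, candidate_variants,
                         cv_folds = 10, seed = 1L,
                         outcome = "nrs_6_12mo", binary_outcome = "cpsp",
                         standardize = FALSE) {
  if (length(candidate_variants) == 0) stop("empty candidate variant set")
  geno <- subset_variants(genotypes, candidate_variants)
  if (anyNA(geno$calls))
    stop("missing genotype calls among candidates; impute first ",
         "(see impute_missing_mode)")
  idx <- match(geno$individual_ids, phenotypes$individual_id)
  if (anyNA(idx)) stop("phenotypes missing for some genotyped individuals")
  X <- geno$calls
  storage.mode(X) <- "double"
  y <- phenotypes[[outcome]][idx]
  yb <- phenotypes[[binary_outcome]][idx]
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(cv_folds), nrow(X)))
  nz <- function(cvfit) {
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
    names(cf)[cf != 0]
  }
  cv_lin <- glmnet::cv.glmnet(X, y, family = "gaussian", foldid = foldid,
                              standardize = standardize)
  cv_log <- glmnet::cv.glmnet(X, yb, family = "binomial", foldid = foldid,
                              standardize = standardize)
  sel_lin <- nz(cv_lin)
  sel_log <- nz(cv_log)
  selected <- intersect(sel_lin, sel_log)
  if (length(sel_lin) == 0 && length(sel_log) == 0)
    warning("both penalized models selected the null path; empty selection")
  list(selected = selected, selected_linear = sel_lin,
       selected_logistic = sel_log, cv_linear = cv_lin, cv_logistic = cv_log)
}

#' Orient the risk allele of an associated variant
#'
#' The PRS counts risk alleles, so each variant is oriented toward the allele
#' that increases the pain outcome: when the minor-allele coefficient is
#' positive the minor allele carries risk and counts directly; when negative,
#' the major allele carries risk and the count flips to `2 - minor count`.
#' The weight is the absolute coefficient. Allele recoding therefore leaves
#' the (risk allele, weight) pair unchanged.
#'
#' @param beta Linear-model coefficient per minor allele (NRS units).
#' @param major_allele,minor_allele Allele labels.
#' @return List with `risk_allele`, `weight`, `flip` (`TRUE` when the major
#'   allele carries the risk).
#' @export
orient_risk_allele <- function(beta, major_allele, minor_allele) {
  if (!is.finite(beta)) stop("non-finite association coefficient")
  if (beta == 0) stop("untestable variant (beta = 0) cannot enter the PRS")
  if (beta > 0)
    list(risk_allele = minor_allele, weight = beta, flip = FALSE)
  else
    list(risk_allele = major_allele, weight = -beta, flip = TRUE)
}

#' Build a weighted PRS model
#'
#' Assembles the PRS model from LASSO-selected variants: each weight is the
#' absolute single-variant covariate-adjusted linear-model coefficient (not
#' the penalized coefficient), and each variant is oriented to its risk
#' allele via [orient_risk_allele()].
#'
#' @param assoc Association results ([snp_association()]).
#' @param selected_variants Variant ids selected for the score.
#' @param annotation Variant annotation with alleles and gene symbols.
#' @return A list of class `prs_model`: `variants` data frame
#'   (`variant_id`, `gene`, `risk_allele`, `weight`, `flip`), `m`, `source`.
#' @export
build_prs_model <- function(assoc, selected_variants, annotation) {
  if (length(selected_variants) == 0) stop("no variants selected for the PRS")
  a <- assoc[match(selected_variants, assoc$variant_id), ]
  if (anyNA(a$variant_id)) stop("selected variants missing from association results")
  ann <- annotation[match(selected_variants, annotation$variant_id), ]
  orient <- Map(orient_risk_allele, a$beta, ann$major_allele, ann$minor_allele)
  variants <- data.frame(
    variant_id = selected_variants,
    gene = ann$gene,
    risk_allele = vapply(orient, `[[`, character(1), "risk_allele"),
    weight = vapply(orient, `[[`, numeric(1), "weight"),
    flip = vapply(orient, `[[`, logical(1), "flip"),
    stringsAsFactors = FALSE
  )
  structure(list(variants = variants, m = nrow(variants),
                 source = "single-variant covariate-adjusted linear model"),
            class = "prs_model")
}

#' Compute per-individual polygenic risk scores
#'
#' The score of individual n is the weighted sum over the model's m variants
#' of the risk-allele count times the absolute association coefficient:
#' `PRS_n = sum_i |b_i| * R_(i,n)`, with `R` in `{0, 1, 2}`. Scores are
#' therefore bounded by `[0, 2 * sum(|b_i|)]`.
#'
#' @param model A [build_prs_model()] object.
#' @param genotypes Complete [genotype_matrix()] covering the model variants.
#' @return Data frame with `individual_id`, `prs`; the risk-allele count
#'   matrix is attached as `attr(, "risk_allele_counts")`.
#' @export
compute_prs <- function(model, genotypes) {
  stopifnot(inherits(model, "prs_model"))
  missing_v <- setdiff(model$variants$variant_id, genotypes$variant_ids)
  if (length(missing_v) > 0)
    stop("model variants absent from genotypes: ",
         paste(missing_v, collapse = ", "))
  calls <- genotypes$calls[, model$variants$variant_id, drop = FALSE]
  if (anyNA(calls)) stop("missing calls at PRS variants; impute first")
  R <- calls
  flip <- model$variants$flip
  if (any(flip)) R[, flip] <- 2L - R[, flip, drop = FALSE]
  prs <- as.numeric(R %*% model$variants$weight)
  out <- data.frame(individual_id = genotypes$individual_ids, prs = prs,
                    stringsAsFactors = FALSE)
  attr(out, "risk_allele_counts") <- R
  out
}
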