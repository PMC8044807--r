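#' Univariate covariate screening against the continuous pain outcome
#'
#' Fits a univariate linear model of the continuous outcome on each candidate
#' covariate and retains those with p < 0.1 (strict inequality), the
#' conventional lenient gate for admission to the genetic association models.
#' Constant covariates are dropped with a warning.
#'
#' @param phenotypes Phenotype data frame (see [simulate_cohort()]).
#' @param candidate_covariates Character vector of column names to screen.
#' @param outcome Name of the continuous outcome column.
#' @param p_enter Retention threshold (strict `<`).
#' @return Data frame with `covariate`, `estimate`, `p_value`, `retained`;
#'   the retained names are in `attr(, "retained")`.
#' @export
screen_covariates <- function(phenotypes, candidate_covariates,
                              outcome = "nrs_6_12mo", p_enter = 0.1) {
  stopifnot(outcome %in% names(phenotypes))
  rows <- lapply(candidate_covariates, function(cv) {
    if (!cv %in% names(phenotypes)) stop("unknown covariate: ", cv)
    x <- phenotypes[[cv]]
    ok <- stats::complete.cases(phenotypes[[outcome]], x)
    xx <- x[ok]
    if (length(unique(xx)) < 2) {
      warning("constant covariate dropped: ", cv)
      return(data.frame(covariate = cv, estimate = NA_real_, p_value = NA_real_,
                        retained = FALSE, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(stats::reformulate(cv, response = outcome),
                     data = phenotypes[ok, , drop = FALSE])
    sm <- summary(fit)$coefficients
    # overall covariate p: slope Wald p for numeric, model F-test for factors
    if (nrow(sm) == 2) {
      est <- sm[2, 1]; p <- sm[2, 4]
    } else {
      f <- summary(fit)$fstatistic
      est <- NA_real_
      p <- stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
    }
    data.frame(covariate = cv, estimate = est, p_value = p,
               retained = is.finite(p) && p < p_enter, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "retained") <- out$covariate[out$retained]
  out
}

#' Per-variant additive linear association
#'
#' Ordinary least squares of the continuous pain outcome on the
#' additive-coded genotype (minor-allele count) plus screened covariates, one
#' model per variant. Individuals missing the genotype at a variant are
#' excluded for that variant only. The genotype coefficient's Wald (t)
#' p-value is reported. Variants with zero genotype variance among complete
#' cases are flagged untestable (`beta = 0`, `p = 1`).
#'
#' Variants with no missing calls share their design and are fit in one
#' vectorized Frisch-Waugh-Lovell pass; variants with missingness fall back
#' to per-variant fits.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes Phenotype data frame aligned to
#'   `genotypes$individual_ids` via `individual_id`.
#' @param covariates Character vector of covariate column names (possibly
#'   empty), e.g. the set retained by [screen_covariates()].
#' @param outcome Continuous outcome column name.
#' @param min_complete Minimum complete cases required per variant.
#' @return Data frame with `variant_id`, `beta`, `se`, `p_value`, `n_used`,
#'   `untestable`.
#' @export
snp_association <- function(genotypes, phenotypes, covariates = character(0),
                            outcome = "nrs_6_12mo", min_complete = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  idx <- match(genotypes$individual_ids, phenotypes$individual_id)
  if (anyNA(idx)) stop("phenotypes missing for some genotyped individuals")
  ph <- phenotypes[idx, , drop = FALSE]
  y <- ph[[outcome]]
  X <- if (length(covariates) > 0)
    stats::model.matrix(stats::reformulate(covariates), data = ph) else
    matrix(1, nrow(ph), 1)
  ok_base <- stats::complete.cases(y, X)
  calls <- genotypes$calls
  m <- ncol(calls)
  beta <- numeric(m); se <- numeric(m); p <- numeric(m)
  n_used <- integer(m); untestable <- logical(m)

  fit_one <- function(g, yy, XX) {
    keep <- !is.na(g)
    g <- g[keep]; yy <- yy[keep]; XX <- XX[keep, , drop = FALSE]
    n <- length(g)
    if (n < min_complete) return(c(NA, NA, NA, n, TRUE))
    if (stats::var(g) == 0) return(c(0, NA, 1, n, TRUE))
    q <- qr(XX)
    gr <- stats::residuals(stats::lm.fit(XX, g))
    yr <- stats::residuals(stats::lm.fit(XX, yy))
    sxx <- sum(gr^2)
    b <- sum(gr * yr) / sxx
    df <- n - q$rank - 1
    if (df <= 0) return(c(b, NA, NA, n, TRUE))
    rss <- sum((yr - b * gr)^2)
    s <- sqrt(rss / df / sxx)
    tval <- b / s
    c(b, s, 2 * stats::pt(abs(tval), df, lower.tail = FALSE), n, FALSE)
  }

  has_na <- colSums(is.na(calls[ok_base, , drop = FALSE])) > 0
  yy <- y[ok_base]; XX <- X[ok_base, , drop = FALSE]

  # shared-design variants: one residualization, vectorized slopes
  full <- which(!has_na)
  if (length(full) > 0) {
    q <- qr(XX)
    yr <- stats::residuals(stats::lm.fit(XX, yy))
    G <- calls[ok_base, full, drop = FALSE]
    storage.mode(G) <- "double"
    Gr <- G - XX %*% qr.coef(q, G)
    sxx <- colSums(Gr^2)
    zerov <- sxx < 1e-12
    b <- ifelse(zerov, 0, colSums(Gr * yr) / sxx)
    df <- length(yy) - q$rank - 1
    rss <- colSums((yr - sweep(Gr, 2, b, `*`))^2)
    s <- sqrt(rss / df / sxx)
    pv <- 2 * stats::pt(abs(b / s), df, lower.tail = FALSE)
    beta[full] <- b
    se[full] <- ifelse(zerov, NA_real_, s)
    p[full] <- ifelse(zerov, 1, pv)
    n_used[full] <- length(yy)
    untestable[full] <- zerov
  }
  for (j in which(has_na)) {
    r <- fit_one(calls[ok_base, j], yy, XX)
    beta[j] <- r[1]; se[j] <- r[2]; p[j] <- r[3]
    n_used[j] <- r[4]; untestable[j] <- as.logical(r[5])
  }
  data.frame(variant_id = genotypes$variant_ids, beta = beta, se = se,
             p_value = p, n_used = n_used, untestable = untestable,
             stringsAsFactors = FALSE)
}
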