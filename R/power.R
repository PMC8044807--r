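#' Power of a one- or two-sided two-sample proportion test
#'
#' Normal-approximation power for comparing two independent proportions with
#' equal group sizes, using the pooled variance under the null and unpooled
#' variances under the alternative, without continuity correction. This is
#' the classical design calculation for testing whether nominally significant
#' variants occur at a higher rate in a selected gene set than the background
#' rate in random sets.
#'
#' @param p0,p1 Null (background) and alternative proportions.
#' @param n_per_group Observations per group.
#' @param alpha Significance level.
#' @param one_sided One-sided test of `p1 > p0` (the enrichment direction).
#' @return Power in `[0, 1]`.
#' @examples
#' power_two_proportions(0.05, 0.064, 3310, one_sided = TRUE)  # ~0.79
#' @export
power_two_proportions <- function(p0, p1, n_per_group, alpha = 0.05,
                                  one_sided = TRUE) {
  stopifnot(p0 > 0, p0 < 1, p1 > 0, p1 < 1, n_per_group > 0,
            alpha > 0, alpha < 1)
  pbar <- (p0 + p1) / 2
  se0 <- sqrt(2 * pbar * (1 - pbar) / n_per_group)
  se1 <- sqrt(p0 * (1 - p0) / n_per_group + p1 * (1 - p1) / n_per_group)
  delta <- p1 - p0
  if (one_sided) {
    z <- stats::qnorm(1 - alpha)
    stats::pnorm((delta - z * se0) / se1)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm((delta - z * se0) / se1) + stats::pnorm((-delta - z * se0) / se1)
  }
}

#' Odds ratio implied by two proportions
#'
#' @param p0,p1 Proportions strictly inside (0, 1).
#' @return `(p1/(1-p1)) / (p0/(1-p0))`.
#' @examples
#' proportion_or(0.05, 0.064)  # ~1.30
#' @export
proportion_or <- function(p0, p1) {
  stopifnot(p0 > 0, p0 < 1, p1 > 0, p1 < 1)
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' Power of a two-sided two-sample mean comparison
#'
#' Normal-approximation power to detect a mean difference `diff` between two
#' groups with common standard deviation `sd`, e.g. the PRS difference
#' between individuals with and without CPSP.
#'
#' @param diff Mean difference, score units.
#' @param sd Common standard deviation.
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @examples
#' power_two_means(2, 4, 52, 79)  # ~0.80
#' @export
power_two_means <- function(diff, sd, n1, n2, alpha = 0.05) {
  stopifnot(sd > 0, n1 > 0, n2 > 0, alpha > 0, alpha < 1)
  se <- sd * sqrt(1 / n1 + 1 / n2)
  z <- abs(diff) / se
  crit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(z - crit) + stats::pnorm(-z - crit)
}

#' Monte-Carlo power of a single-variant case-control association test
#'
#' Simulates control genotypes in Hardy-Weinberg proportions at the given
#' minor allele frequency and case genotypes under the genotype-probability
#' shift implied by a per-allele odds ratio
#' (`P(g | case) proportional to P(g) * OR^g`), tests each replicate with an
#' additive logistic Wald test, and returns the rejection fraction at level
#' `alpha` (two-sided).
#'
#' @param or_ Per-allele odds ratio under the alternative.
#' @param maf Minor allele frequency in controls.
#' @param n_case,n_control Group sizes.
#' @param alpha Significance level.
#' @param n_reps Monte-Carlo replicates (at least 100).
#' @param seed Integer seed.
#' @return Estimated power in `[0, 1]`.
#' @examples
#' \donttest{
#' power_variant_or(2.1, 0.4, 53, 78, n_reps = 1000, seed = 1)  # ~0.84
#' }
#' @export
power_variant_or <- function(or_, maf, n_case, n_control, alpha = 0.05,
                             n_reps = 5000, seed = 1L) {
  stopifnot(or_ > 0, maf > 0, maf <= 0.5, n_case > 0, n_control > 0,
            alpha > 0, alpha < 1)
  if (n_reps < 100) stop("n_reps must be at least 100")
  p_control <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  p_case <- p_control * or_^(0:2)
  p_case <- p_case / sum(p_case)
  y <- c(rep(1L, n_case), rep(0L, n_control))
  set.seed(seed)
  rejections <- 0L
  for (r in seq_len(n_reps)) {
    g <- c(sample(0:2, n_case, replace = TRUE, prob = p_case),
           sample(0:2, n_control, replace = TRUE, prob = p_control))
    if (stats::var(g) == 0) next
    fit <- suppressWarnings(stats::glm(y ~ g, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    if (nrow(sm) == 2 && sm[2, 4] < alpha) rejections <- rejections + 1L
  }
  rejections / n_reps
}
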