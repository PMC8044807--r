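panel_path <- system.file("extdata", "cpsp_prs_panel.tsv", package = "enrichprs")
panel <- read.delim(panel_path, stringsAsFactors = FALSE)

panel_model <- function() {
  structure(list(
    variants = data.frame(variant_id = panel$snp, gene = panel$gene,
                          risk_allele = panel$risk_allele,
                          weight = panel$weight,
                          flip = panel$risk_allele == panel$major_allele,
                          stringsAsFactors = FALSE),
    m = nrow(panel), source = "published panel"), class = "prs_model")
}

test_that("modal imputation fills missing calls within groups", {
  X <- matrix(c(0L, 0L, 0L, 1L, NA,
                2L, 2L, NA, 2L, 1L), ncol = 2)
  g <- gmat(X)
  imp <- impute_missing_mode(g)
  expect_equal(imp$genotypes$calls[5, 1], 0L)   # mode of (0,0,0,1)
  expect_equal(imp$genotypes$calls[3, 2], 2L)
  expect_equal(imp$n_imputed, 2)
  # no missing calls: identity
  full <- gmat(matrix(rbinom(20, 2, 0.4), 5, 4))
  expect_identical(impute_missing_mode(full)$genotypes$calls, full$calls)
  # group-aware: modes differ by group
  X2 <- matrix(c(0L, 0L, NA, 2L, 2L, NA), ncol = 1)
  imp2 <- impute_missing_mode(gmat(X2), group = rep(c("a", "b"), each = 3))
  expect_equal(imp2$genotypes$calls[3, 1], 0L)
  expect_equal(imp2$genotypes$calls[6, 1], 2L)
  # all-missing within a group errors
  X3 <- matrix(c(NA, NA, 1L, 1L), ncol = 1)
  expect_error(impute_missing_mode(gmat(X3), group = c("a", "a", "b", "b")),
               "group 'a'")
})

test_that("imputation accounting reproduces the study's arithmetic", {
  # 131 individuals x 16 variants with 45 missing cells leaves 2,051 observed
  set.seed(51)
  X <- matrix(rbinom(131 * 16, 2, 0.3), 131, 16)
  X[sample.int(length(X), 45)] <- NA
  imp <- impute_missing_mode(gmat(X))
  expect_equal(imp$n_imputed, 45)
  expect_equal(imp$n_observed, 2051)
})

test_that("dual-LASSO returns the intersection and recovers planted variants", {
  # 3 planted variants (beta 0.8/allele) among 100 nulls at n = 500: the
  # intersection contains all three in at least 90% of 50 seeds
  n <- 500
  rec <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rbinom(n * 103, 2, 0.3), n, 103)
    colnames(X) <- paste0("v", 1:103)
    y <- X[, 1:3] %*% rep(0.8, 3) + rnorm(n, 0, 2)
    nrs <- pmin(10, pmax(0, y + 3 - quantile(y, 0.6)))
    sel <- lasso_select(gmat(X), pheno_frame(as.numeric(nrs)), colnames(X),
                        seed = s)
    all(c("v1", "v2", "v3") %in% sel$selected) &&
      setequal(sel$selected, intersect(sel$selected_linear, sel$selected_logistic))
  }, logical(1))
  expect_gte(mean(rec), 0.9)
  set.seed(52)
  X <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  g <- gmat(X)
  ph <- pheno_frame(pmin(10, pmax(0, rnorm(n, 3, 2))))
  expect_error(lasso_select(g, ph, character(0)), "empty")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(suppressWarnings(
    lasso_select(gmat(Xna), ph, colnames(g$calls))), "impute")
})

test_that("risk alleles are oriented toward higher pain with positive weights", {
  # minor allele increases pain: risk allele is the minor allele
  o1 <- orient_risk_allele(1.657, major_allele = "G", minor_allele = "A")
  expect_equal(o1$risk_allele, "A")
  expect_equal(o1$weight, 1.657)
  expect_false(o1$flip)
  # minor allele protective: the major allele carries the risk
  o2 <- orient_risk_allele(-2.299, major_allele = "G", minor_allele = "A")
  expect_equal(o2$risk_allele, "G")
  expect_equal(o2$weight, 2.299)
  expect_true(o2$flip)
  # recoding the counted allele flips beta but not the oriented pair
  o3 <- orient_risk_allele(2.299, major_allele = "A", minor_allele = "G")
  expect_equal(o3$risk_allele, o2$risk_allele)
  expect_equal(o3$weight, o2$weight)
  expect_error(orient_risk_allele(0, "G", "A"), "untestable")
  expect_error(orient_risk_allele(NaN, "G", "A"), "finite")
})

test_that("PRS on the published panel matches hand-computed scores", {
  m <- panel_model()
  w_sum <- sum(panel$weight)
  expect_equal(w_sum, 21.381)  # independent column-sum oracle
  # zero risk alleles everywhere -> 0; het at rs62069959 only -> its weight;
  # homozygous risk everywhere -> 2 * sum of weights
  zero <- ifelse(m$variants$flip, 2L, 0L)             # zero risk alleles
  het1 <- zero; het1[m$variants$variant_id == "rs62069959"] <- 1L
  allrisk <- ifelse(m$variants$flip, 0L, 2L)
  X <- rbind(zero, het1, allrisk)
  colnames(X) <- m$variants$variant_id
  scores <- compute_prs(m, gmat(X))
  expect_equal(scores$prs, c(0, 2.299, 2 * 21.381))
  # bounds hold by construction (tolerance for float summation order)
  expect_true(all(scores$prs >= 0 & scores$prs <= 2 * w_sum + 1e-9))
  # a variant absent from the genotypes is reported by name
  expect_error(compute_prs(m, gmat(X[, -1, drop = FALSE])), "rs62069959")
})

test_that("PRS is linear in risk-allele counts", {
  m <- panel_model()
  m$variants$flip <- FALSE  # orient all weights to the counted allele
  set.seed(53)
  R1 <- matrix(rbinom(5 * m$m, 1, 0.5), 5, m$m)
  R2 <- matrix(rbinom(5 * m$m, 1, 0.5), 5, m$m)
  colnames(R1) <- colnames(R2) <- m$variants$variant_id
  s1 <- compute_prs(m, gmat(R1))$prs
  s2 <- compute_prs(m, gmat(R2))$prs
  s12 <- compute_prs(m, gmat(R1 + R2))$prs
  expect_equal(s12, s1 + s2)
})

test_that("pure-noise candidates yield an empty median selection", {
  set.seed(54)
  n <- 500
  X <- matrix(rbinom(n * 103, 2, 0.3), n, 103)
  colnames(X) <- paste0("v", 1:103)
  g <- gmat(X)
  sizes <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    nrs <- pmin(10, pmax(0, rnorm(n, 3, 2)))
    sel <- suppressWarnings(lasso_select(g, pheno_frame(nrs), colnames(X),
                                         seed = s))
    length(sel$selected)
  }, numeric(1))
  expect_equal(median(sizes), 0)
})
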