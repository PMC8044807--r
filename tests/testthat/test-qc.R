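test_that("minor allele frequency is counted and folded correctly", {
  expect_equal(compute_maf(rep(c(0L, 1L, 2L), c(25, 50, 25))), 0.5)
  expect_equal(compute_maf(rep(c(0L, 1L, 2L), c(81, 18, 1))), 0.10)
  expect_equal(compute_maf(rep(0L, 40)), 0)
  expect_error(compute_maf(c(NA_integer_, NA_integer_)), "missing")
  # invariance under relabelling major <-> minor
  set.seed(1)
  v <- rbinom(200, 2, 0.35)
  expect_equal(compute_maf(v), compute_maf(2L - v))
})

test_that("Hardy-Weinberg chi-square test matches hand computations", {
  expect_equal(hwe_test(25, 50, 25), 1)
  # (50, 0, 50): expected (25, 50, 25), chi2 = 25 + 50 + 25 = 100
  expect_equal(hwe_test(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_equal(hwe_test(0, 100, 0), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 1e-4)   # fails the QC threshold
  expect_equal(hwe_test(100, 0, 0), 1)   # monomorphic: no test possible
})

test_that("chi-square HWE p agrees with the exact multinomial oracle on small counts", {
  exact_hwe <- function(a, b, c) {
    n <- a + b + c
    phat <- (2 * c + b) / (2 * n)
    pr <- c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
    stat <- function(x, y, z) {
      ph <- (2 * z + y) / (2 * n)
      if (ph == 0 || ph == 1) return(0)
      e <- n * c((1 - ph)^2, 2 * ph * (1 - ph), ph^2)
      sum((c(x, y, z) - e)^2 / e)
    }
    obs <- stat(a, b, c)
    tot <- 0
    for (x in 0:n) for (y in 0:(n - x)) {
      z <- n - x - y
      if (stat(x, y, z) >= obs - 1e-12) tot <- tot + dmultinom(c(x, y, z), prob = pr)
    }
    tot
  }
  cases <- list(c(10, 12, 8), c(12, 14, 4), c(8, 15, 7), c(5, 20, 5),
                c(15, 10, 5), c(20, 8, 2), c(6, 12, 12))
  for (cs in cases) {
    pe <- exact_hwe(cs[1], cs[2], cs[3])
    pc <- hwe_test(cs[1], cs[2], cs[3])
    expect_lt(abs(pc - pe) / pe, 0.15)
  }
})

make_ann <- function(geno, chrom = 1L, gene = "G1") {
  data.frame(variant_id = geno$variant_ids, chrom = chrom,
             pos = seq_along(geno$variant_ids) * 1000L,
             major_allele = "A", minor_allele = "G",
             gene = gene, stringsAsFactors = FALSE)
}

test_that("variant filter excludes by each criterion in the fixed order", {
  set.seed(2)
  n <- 200
  X <- cbind(
    good1 = rbinom(n, 2, 0.3),
    low_maf = rbinom(n, 2, 0.045),            # MAF ~0.045 < 0.10
    bad_call = rbinom(n, 2, 0.3),             # gets 10% missing
    bad_hwe = rep(c(0L, 2L), each = n / 2),   # no hets at p = 0.5
    good2 = rbinom(n, 2, 0.4),
    no_gene = rbinom(n, 2, 0.3),
    chr_x = rbinom(n, 2, 0.3)
  )
  X[1:11, "bad_call"] <- NA                    # call rate 0.945 < 0.95
  g <- gmat(X)
  ann <- make_ann(g)
  ann$gene[ann$variant_id == "no_gene"] <- NA
  ann$chrom <- ifelse(ann$variant_id == "chr_x", "X", "1")
  res <- filter_variants(g, ann, qc_config())
  expect_setequal(res$genotypes$variant_ids, c("good1", "good2"))
  rep <- setNames(res$report$n, res$report$criterion)
  expect_equal(rep[["non_autosomal"]], 1)
  expect_equal(rep[["gene_less"]], 1)
  expect_equal(rep[["call_rate"]], 1)
  expect_equal(rep[["hwe"]], 1)
  expect_equal(rep[["maf"]], 1)
  expect_equal(rep[["retained"]], 2)
  # idempotence
  res2 <- filter_variants(res$genotypes, res$annotation, qc_config())
  expect_identical(res2$genotypes$calls, res$genotypes$calls)
  expect_equal(sum(res2$report$n[res2$report$criterion != "retained"]), 0)
})

test_that("LD r-squared matches hand Pearson and handles degenerate input", {
  a <- c(0L, 1L, 2L, 0L, 1L)
  b <- c(0L, 1L, 1L, 0L, 2L)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2L - a), 1)           # sign-flip invariance
  expect_equal(ld_r2(a, b), cor(a, b)^2)      # 0.4132653 by hand Pearson
  expect_equal(ld_r2(a, b), 0.41326530612, tolerance = 1e-8)
  expect_warning(r0 <- ld_r2(a, rep(1L, 5)), "zero variance")
  expect_equal(r0, 0)
  # pairwise-complete handling
  a2 <- a; a2[2] <- NA
  expect_equal(ld_r2(a2, b), cor(a[-2], b[-2])^2)
})

test_that("LD pruning removes duplicates, keeps independents, matches the oracle", {
  set.seed(3)
  n <- 120
  base <- rbinom(n, 2, 0.3)
  X <- cbind(v1 = base, v2 = base,                      # perfect duplicate
             v3 = rbinom(n, 2, 0.4), v4 = rbinom(n, 2, 0.2),
             v5 = rbinom(n, 2, 0.45))
  g <- gmat(X)
  ann <- make_ann(g)
  kept <- ld_prune(g, ann, window = 5, step = 2, r2_max = 0.8)
  expect_equal(sum(c("v1", "v2") %in% kept), 1)
  expect_true(all(c("v3", "v4", "v5") %in% kept))
  expect_error(ld_prune(g, ann, window = 1, step = 1, r2_max = 0.8), "window")

  # randomized blocks (<= 20 variants) against the brute-force oracle,
  # including LD, missing calls and ties
  for (s in 1:8) {
    cfg <- sim_config(n_individuals = 150, n_training_genes = 2,
                      n_candidate_genes = 0, n_control_genes = 2,
                      variants_per_gene = 5, ld_rho = 0.85,
                      effect_variants = list(), missing_rate = 0.02, seed = s)
    co <- simulate_cohort(cfg)
    kept_pkg <- ld_prune(co$genotypes, co$annotation,
                         window = 6, step = 3, r2_max = 0.5)
    kept_oracle <- ld_prune_oracle(co$genotypes$calls, co$annotation$chrom,
                                   co$annotation$pos, window = 6, step = 3,
                                   r2_max = 0.5)
    expect_identical(sort(kept_pkg), sort(kept_oracle))
  }
})

test_that("after pruning no within-window pair exceeds the r2 ceiling", {
  cfg <- sim_config(n_individuals = 150, n_training_genes = 4,
                    n_candidate_genes = 0, n_control_genes = 4,
                    variants_per_gene = 8, ld_rho = 0.9,
                    effect_variants = list(), missing_rate = 0, seed = 21)
  co <- simulate_cohort(cfg)
  window <- 10; r2max <- 0.5
  kept <- ld_prune(co$genotypes, co$annotation, window = window, step = 2,
                   r2_max = r2max)
  # windows are ranges of the genomically ordered variant sequence; any kept
  # pair within one window must respect the ceiling
  ann <- co$annotation[order(co$annotation$chrom, co$annotation$pos), ]
  pos_in_seq <- match(kept, ann$variant_id)
  worst <- 0
  for (i in seq_along(kept)) for (j in seq_along(kept)) {
    if (j > i && pos_in_seq[j] - pos_in_seq[i] < window) {
      r2 <- suppressWarnings(
        ld_r2(co$genotypes$calls[, kept[i]], co$genotypes$calls[, kept[j]]))
      worst <- max(worst, r2)
    }
  }
  expect_lte(worst, r2max)
})
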