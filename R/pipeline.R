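#' Pipeline configuration
#'
#' One configuration object for the full analysis. Exactly one of `sim` (a
#' [sim_config()], for a synthetic run) or `inputs` (named paths `vcf`,
#' `annotation`, `genes`, `phenotypes`) must be supplied. The single global
#' seed fans out to per-stage named substreams so every stage is
#' independently reproducible.
#'
#' @param sim A [sim_config()] or `NULL`.
#' @param inputs Named list of input paths or `NULL`.
#' @param qc A [qc_config()].
#' @param enrichment An [enrichment_config()] (its seed is overridden by the
#'   pipeline's enrichment substream).
#' @param cv_folds LASSO cross-validation folds.
#' @param candidate_covariates Non-genetic covariates screened for the
#'   association models.
#' @param entry_p Stepwise entry/retention threshold for the prediction
#'   models.
#' @param n_boot Bootstrap resamples for internal validation.
#' @param seed Global integer seed.
#' @param out_dir Output directory; defaults to a fresh temporary directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            qc = qc_config(), enrichment = enrichment_config(),
                            cv_folds = 10,
                            candidate_covariates = c(
                              "casi", "preop_pain", "sex", "race", "age",
                              "weight", "surgical_duration", "levels_fused",
                              "propofol", "remifentanil", "auc_pod12",
                              "morphine_meq"),
                            entry_p = 0.05, n_boot = 1000, seed = 1L,
                            out_dir = NULL) {
  if (is.null(sim) == is.null(inputs))
    stop("exactly one of `sim` or `inputs` must be supplied")
  if (!is.null(inputs))
    stopifnot(all(c("vcf", "annotation", "genes", "phenotypes") %in% names(inputs)))
  structure(list(sim = sim, inputs = inputs, qc = qc, enrichment = enrichment,
                 cv_folds = cv_folds,
                 candidate_covariates = candidate_covariates,
                 entry_p = entry_p, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full CPSP PRS analysis
#'
#' Executes the stages in analysis order — data (simulate or load), variant
#' QC with LD pruning, covariate screening and per-variant association,
#' cumulative gene-set enrichment, PRS construction (modal imputation,
#' dual-LASSO selection, risk-allele-oriented weighting), prediction models
#' with AUC comparison, and bootstrap internal validation — writing each
#' stage's outputs under `out_dir` and hashing them into a run manifest.
#' Re-running with the same configuration and seed reproduces all outputs
#' byte-identically. On failure the pipeline halts naming the stage; outputs
#' of completed stages are retained.
#'
#' Race is always carried as a covariate in the genetic association models
#' (self-reported ancestry in place of genetic principal components), in
#' addition to the covariates passing the univariate p < 0.1 screen.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run` with the stage objects
#'   (`cohort`/`data`, `qc`, `covariates`, `assoc`, `enrichment`,
#'   `prs_model`, `prs_scores`, `clinical_model`, `genetic_model`,
#'   `auc_comparison`, `bootstrap`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("enrichprs_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  outputs <- character(0)
  add_output <- function(path) outputs <<- c(outputs, path)
  stages_done <- character(0)

  # --- stage 1: data -------------------------------------------------------
  dat <- stage_wrap("data", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- substream_seed(seed, "simulate")
      cohort <- simulate_cohort(sim)
      note("data: simulated cohort, n = ", nrow(cohort$genotypes$calls),
           ", variants = ", ncol(cohort$genotypes$calls),
           ", CPSP prevalence = ", sprintf("%.3f", mean(cohort$phenotypes$cpsp)))
      list(genotypes = cohort$genotypes, annotation = cohort$annotation,
           ranked = cohort$ranked_genes, phenotypes = cohort$phenotypes,
           cohort = cohort)
    } else {
      g <- read_genotypes_vcf(config$inputs$vcf)
      ann <- utils::read.delim(config$inputs$annotation, stringsAsFactors = FALSE)
      ranked <- read_ranked_genes(config$inputs$genes)
      note("data: loaded ", ncol(g$genotypes$calls), " variants from VCF")
      list(genotypes = g$genotypes, annotation = ann, ranked = ranked,
           phenotypes = NULL, cohort = NULL)
    }
  })
  stages_done <- c(stages_done, "data")

  # --- stage 2: qc ---------------------------------------------------------
  qc <- stage_wrap("qc", {
    f <- filter_variants(dat$genotypes, dat$annotation, config$qc)
    kept <- ld_prune(f$genotypes, f$annotation,
                     window = config$qc$ld_window, step = config$qc$ld_step,
                     r2_max = config$qc$ld_r2_max)
    pruned <- length(f$genotypes$variant_ids) - length(kept)
    geno <- subset_variants(f$genotypes, kept)
    ann <- f$annotation[match(kept, f$annotation$variant_id), ]
    note("qc: call rate >= ", config$qc$call_rate_min,
         ", HWE p >= ", config$qc$hwe_p_min, ", MAF >= ", config$qc$maf_min,
         "; LD prune ", config$qc$ld_window, " ", config$qc$ld_step, " ",
         config$qc$ld_r2_max, "; retained ", length(kept),
         " variants (", pruned, " pruned for LD)")
    p <- file.path(out_dir, "qc_report.tsv")
    utils::write.table(rbind(f$report,
                             data.frame(criterion = "ld_pruned", n = pruned)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(p)
    list(genotypes = geno, annotation = ann, report = f$report,
         n_ld_pruned = pruned)
  })
  stages_done <- c(stages_done, "qc")

  # --- stage 3: association ------------------------------------------------
  assoc_res <- stage_wrap("assoc", {
    phenotypes <- dat$phenotypes
    if (is.null(phenotypes)) phenotypes <- read_phenotypes(config$inputs$phenotypes)
    screen <- screen_covariates(phenotypes, config$candidate_covariates)
    covars <- union(attr(screen, "retained"), "race")
    note("assoc: univariate screen p < 0.1 retained {",
         paste(attr(screen, "retained"), collapse = ", "),
         "}; race always carried; additive linear model on continuous outcome")
    assoc <- snp_association(qc$genotypes, phenotypes, covariates = covars)
    p <- file.path(out_dir, "association.tsv")
    utils::write.table(assoc, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(p)
    list(assoc = assoc, screen = screen, covariates = covars,
         phenotypes = phenotypes)
  })
  stages_done <- c(stages_done, "assoc")
  phenotypes <- assoc_res$phenotypes

  # --- stage 4: enrichment -------------------------------------------------
  enr <- stage_wrap("enrich", {
    ec <- config$enrichment
    ec$seed <- substream_seed(seed, "enrichment")
    note("enrich: alpha = ", ec$alpha, ", runs = ", ec$n_runs,
         ", MAF bands {", paste(ec$maf_breaks, collapse = ", "),
         "}, increment = ", ec$increment)
    scan <- run_enrichment(assoc_res$assoc, qc$annotation, dat$ranked, ec)
    note("enrich: minimal enriched set = ",
         if (is.na(scan$minimal_enriched)) "none" else scan$minimal_enriched)
    p <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(scan$summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_output(p)
    scan
  })
  stages_done <- c(stages_done, "enrich")

  # --- stage 5: prs --------------------------------------------------------
  prs <- stage_wrap("prs", {
    if (is.na(enr$minimal_enriched))
      stop("no cumulative set is enriched; cannot build a PRS")
    cand <- intersect(enr$sets[[enr$minimal_enriched]],
                      qc$genotypes$variant_ids)
    imp <- impute_missing_mode(subset_variants(qc$genotypes, cand),
                               group = phenotypes$race[
                                 match(qc$genotypes$individual_ids,
                                       phenotypes$individual_id)])
    note("prs: ", imp$n_imputed, " genotypes imputed (modal within race), ",
         imp$n_observed, " observed genotypes available for accuracy accounting")
    sel <- lasso_select(imp$genotypes, phenotypes, cand,
                        cv_folds = config$cv_folds,
                        seed = substream_seed(seed, "lasso"))
    note("prs: LASSO linear selected ", length(sel$selected_linear),
         ", logistic ", length(sel$selected_logistic),
         ", intersection ", length(sel$selected))
    if (length(sel$selected) == 0)
      stop("dual-LASSO intersection is empty; no variants for the PRS")
    model <- build_prs_model(assoc_res$assoc, sel$selected, qc$annotation)
    scores <- compute_prs(model, imp$genotypes)
    pm <- file.path(out_dir, "prs_model.json")
    jsonlite::write_json(list(variants = model$variants, m = model$m,
                              source = model$source),
                         pm, auto_unbox = TRUE, digits = NA)
    ps <- file.path(out_dir, "prs_scores.csv")
    utils::write.csv(scores, ps, row.names = FALSE)
    add_output(pm); add_output(ps)
    list(model = model, scores = scores, selection = sel, imputation = imp)
  })
  stages_done <- c(stages_done, "prs")

  # --- stage 6: prediction models -----------------------------------------
  models <- stage_wrap("model", {
    ph <- phenotypes
    ph$prs <- prs$scores$prs[match(ph$individual_id, prs$scores$individual_id)]
    nongenetic <- setdiff(config$candidate_covariates, "race")
    clinical <- fit_stepwise_logistic(ph, nongenetic, entry_p = config$entry_p)
    genetic_terms <- unique(c(
      setdiff(attr(stats::terms(clinical$fit), "term.labels"), character(0)),
      "prs"))
    genetic <- fit_stepwise_logistic(ph, genetic_terms, entry_p = config$entry_p)
    cmp <- compare_auc(genetic, clinical, paired = TRUE)
    note("model: clinical AUC = ", sprintf("%.3f", clinical$auc),
         ", genetic AUC = ", sprintf("%.3f", genetic$auc),
         ", DeLong p = ", format(cmp$p_value, digits = 3))
    p <- file.path(out_dir, "models.json")
    jsonlite::write_json(list(
      clinical = list(terms = clinical$terms, auc = clinical$auc,
                      auc_ci = clinical$auc_ci),
      genetic = list(terms = genetic$terms, auc = genetic$auc,
                     auc_ci = genetic$auc_ci),
      comparison = cmp), p, auto_unbox = TRUE, digits = NA)
    add_output(p)
    list(clinical = clinical, genetic = genetic, comparison = cmp,
         phenotypes_prs = ph)
  })
  stages_done <- c(stages_done, "model")

  # --- stage 7: bootstrap --------------------------------------------------
  boot <- stage_wrap("bootstrap", {
    terms <- attr(stats::terms(models$genetic$fit), "term.labels")
    if (length(terms) == 0) stop("genetic model is intercept-only")
    note("bootstrap: ", config$n_boot,
         " resamples, percentile 95% CIs, bias-corrected coefficients")
    bs <- bootstrap_validate(models$phenotypes_prs, terms,
                             n_boot = config$n_boot,
                             seed = substream_seed(seed, "bootstrap"))
    p <- file.path(out_dir, "bootstrap.tsv")
    utils::write.table(as.data.frame(bs), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_output(p)
    bs
  })
  stages_done <- c(stages_done, "bootstrap")

  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("enrichprs")),
    seed = seed,
    stages = stages_done,
    parameters = list(alpha = config$enrichment$alpha,
                      n_runs = config$enrichment$n_runs,
                      maf_breaks = config$enrichment$maf_breaks,
                      n_boot = config$n_boot,
                      dichotomize_threshold =
                        if (!is.null(config$sim)) config$sim$dichotomize_threshold else 3,
                      qc = unclass(config$qc)),
    outputs = as.list(stats::setNames(
      as.character(tools::md5sum(outputs)), basename(outputs)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  structure(list(data = dat, qc = qc, covariates = assoc_res$screen,
                 assoc = assoc_res$assoc, enrichment = enr,
                 prs_model = prs$model, prs_scores = prs$scores,
                 lasso = prs$selection,
                 clinical_model = models$clinical,
                 genetic_model = models$genetic,
                 auc_comparison = models$comparison,
                 bootstrap = boot, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("enrichprs pipeline run (", length(x$manifest$stages), "stages )\n")
  cat("  variants after QC:", length(x$qc$genotypes$variant_ids), "\n")
  cat("  minimal enriched set:",
      if (is.na(x$enrichment$minimal_enriched)) "none" else
        x$enrichment$minimal_enriched, "\n")
  cat("  PRS variants:", x$prs_model$m, "\n")
  cat(sprintf("  clinical AUC %.3f vs genetic AUC %.3f (DeLong p = %.3g)\n",
              x$clinical_model$auc, x$genetic_model$auc,
              x$auc_comparison$p_value))
  invisible(x)
}
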