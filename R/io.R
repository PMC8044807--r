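#' Convert a genotype matrix to a vcfR object
#'
#' Variants are emitted with REF = major allele and ALT = minor allele, so
#' the GT dosage equals the additive minor-allele count. Missing calls become
#' `./.`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param annotation Data frame with `variant_id`, `chrom`, `pos`,
#'   `major_allele`, `minor_allele` covering all variants.
#' @return A `vcfR::vcfR` object.
#' @export
genotypes_to_vcfr <- function(genotypes, annotation) {
  ann <- annotation[match(genotypes$variant_ids, annotation$variant_id), ]
  ord <- order(suppressWarnings(as.integer(as.character(ann$chrom))), ann$pos)
  ann <- ann[ord, ]
  calls <- genotypes$calls[, ord, drop = FALSE]
  fix <- cbind(CHROM = as.character(ann$chrom), POS = as.character(ann$pos),
               ID = ann$variant_id, REF = ann$major_allele,
               ALT = ann$minor_allele, QUAL = ".", FILTER = "PASS", INFO = ".")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt_chr <- matrix("./.", nrow(fix), nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    gt_chr[!is.na(v), i] <- gt_code[as.character(v[!is.na(v)])]
  }
  colnames(gt_chr) <- genotypes$individual_ids
  gt <- cbind(FORMAT = "GT", gt_chr)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste0("##source=enrichprs ", as.character(utils::packageVersion("enrichprs"))))
  methods::new("vcfR", meta = meta, fix = fix, gt = gt)
}

#' Read genotypes from a VCF
#'
#' Reads autosomal biallelic records, coding each genotype as the ALT-allele
#' count (the files written by this package use ALT = minor allele). Returns
#' the genotype matrix together with a minimal annotation built from the
#' VCF's fixed fields.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return List with `genotypes` ([genotype_matrix()]) and `annotation`
#'   (`variant_id`, `chrom`, `pos`, `major_allele`, `minor_allele`).
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dosage[gt %in% c("0/0", "0|0")] <- 0L
  dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt %in% c("1/1", "1|1")] <- 2L
  calls <- t(dosage)
  rownames(calls) <- colnames(gt)
  colnames(calls) <- fix[, "ID"]
  ann <- data.frame(variant_id = fix[, "ID"],
                    chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    major_allele = fix[, "REF"],
                    minor_allele = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(calls), annotation = ann)
}

#' Write a synthetic cohort to disk
#'
#' Emits the four analysis inputs: a bgzipped VCF of genotypes, the variant
#' annotation TSV, the ranked gene table TSV (`gene`, `set`, `rank`) and the
#' phenotype CSV.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf.gz"),
             annotation = file.path(dir, "annotation.tsv"),
             genes = file.path(dir, "ranked_genes.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"))
  vcfR::write.vcf(genotypes_to_vcfr(cohort$genotypes, cohort$annotation),
                  file = paths["vcf"])
  utils::write.table(cohort$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ranked_genes(cohort$ranked_genes, paths["genes"])
  utils::write.csv(cohort$phenotypes, paths["phenotypes"], row.names = FALSE)
  invisible(paths)
}

#' Write / read a ranked gene table
#'
#' @param ranked A [ranked_gene_sets()] object.
#' @param path TSV path.
#' @return `write_ranked_genes` the path invisibly; `read_ranked_genes` a
#'   [ranked_gene_sets()].
#' @export
write_ranked_genes <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_gene_sets"))
  df <- data.frame(
    gene = c(ranked$training, ranked$candidate, ranked$control),
    set = c(rep("training", length(ranked$training)),
            rep("candidate", length(ranked$candidate)),
            rep("control", length(ranked$control))),
    rank = c(rep(NA_integer_, length(ranked$training)),
             seq_along(ranked$candidate),
             rep(NA_integer_, length(ranked$control))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_genes
#' @export
read_ranked_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cand <- df[df$set == "candidate", ]
  cand <- cand[order(cand$rank), ]
  ranked_gene_sets(training = df$gene[df$set == "training"],
                   candidate = cand$gene,
                   control = df$gene[df$set == "control"])
}

#' Read a phenotype table
#'
#' @param path CSV path with at least `individual_id`, `nrs_6_12mo`; a
#'   `cpsp` column is derived (pain > 3) when absent and validated when
#'   present.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "nrs_6_12mo") %in% names(ph)))
    stop("phenotype file must contain individual_id and nrs_6_12mo")
  if (any(ph$nrs_6_12mo < 0 | ph$nrs_6_12mo > 10, na.rm = TRUE))
    stop("nrs_6_12mo outside [0, 10]")
  derived <- as.integer(ph$nrs_6_12mo > 3)
  if (!"cpsp" %in% names(ph)) {
    ph$cpsp <- derived
  } else {
    both <- !is.na(ph$cpsp) & !is.na(derived)
    if (any(ph$cpsp[both] != derived[both]))
      stop("cpsp column inconsistent with nrs_6_12mo > 3")
  }
  ph
}
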