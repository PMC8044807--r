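#' Genotype matrix container
#'
#' A minimal container for hard-called biallelic genotypes: an
#' individuals-by-variants integer matrix of minor-allele counts (0, 1, 2)
#' with `NA` marking missing calls. Row names are individual identifiers,
#' column names variant identifiers.
#'
#' @param calls Integer matrix (individuals x variants) with entries in
#'   `{0, 1, 2, NA}`.
#' @param individual_ids Character vector of row identifiers. Defaults to the
#'   row names of `calls`.
#' @param variant_ids Character vector of column identifiers. Defaults to the
#'   column names of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individual_ids = rownames(calls),
                            variant_ids = colnames(calls)) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  ok <- calls %in% c(0L, 1L, 2L, NA_integer_)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(individual_ids)) individual_ids <- paste0("id", seq_len(nrow(calls)))
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(calls)))
  if (length(individual_ids) != nrow(calls)) stop("individual_ids length mismatch")
  if (length(variant_ids) != ncol(calls)) stop("variant_ids length mismatch")
  rownames(calls) <- individual_ids
  colnames(calls) <- variant_ids
  structure(list(calls = calls,
                 individual_ids = as.character(individual_ids),
                 variant_ids = as.character(variant_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x", ncol(x$calls),
      "variants;", sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by variant identifiers
#'
#' @param genotypes A [genotype_matrix()].
#' @param variant_ids Variants to keep, in the order given.
#' @return A `genotype_matrix` restricted to `variant_ids`.
#' @export
subset_variants <- function(genotypes, variant_ids) {
  miss <- setdiff(variant_ids, genotypes$variant_ids)
  if (length(miss) > 0)
    stop("variants absent from genotypes: ", paste(miss, collapse = ", "))
  genotype_matrix(genotypes$calls[, variant_ids, drop = FALSE])
}

#' Additive genotype coding
#'
#' Codes a biallelic call under the additive genetic model: major
#' homozygotes 0, heterozygotes 1, minor homozygotes 2 (the count of minor
#' alleles).
#'
#' @param calls Character vector of genotype calls such as `"G/A"` (either
#'   allele order).
#' @param major,minor Single characters, the major and minor allele.
#' @return Integer vector of minor-allele counts.
#' @examples
#' additive_code(c("G/G", "G/A", "A/A"), major = "G", minor = "A")
#' @export
additive_code <- function(calls, major, minor) {
  parts <- strsplit(calls, "[/|]")
  vapply(parts, function(al) {
    if (length(al) != 2 || !all(al %in% c(major, minor)))
      stop("allele not in {major, minor}: ", paste(al, collapse = "/"))
    sum(al == minor)
  }, integer(1))
}
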