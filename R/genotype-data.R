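#' Case-control genotype data
#'
#' Container pairing a SNP-by-sample matrix of minor-allele counts with SNP
#' metadata and a binary phenotype.  Genotype codes are 0/1/2 copies of the
#' minor allele (orientation computed from the loaded data) or `NA` for a
#' missing call.  Phenotype is 0 = control, 1 = case; every retained sample
#' is one or the other, and at least one of each must be present.
#'
#' @param genotypes integer matrix, SNPs in rows, samples in columns, values
#'   in `{0, 1, 2, NA}`.
#' @param phenotype integer vector of 0 (control) / 1 (case), one per sample.
#' @param snp_meta optional tibble with columns `snp_id`, `chr`, `pos`,
#'   `a1`, `a2` (one row per SNP).  Synthesized when omitted.  `a1` is the
#'   counted (minor) allele label, `pos` is 1-based base pairs.
#' @param sample_ids optional character vector of sample identifiers.
#'
#' @return An object of class `genotype_data`: a list with elements
#'   `genotypes`, `snp_meta`, `sample_ids`, `phenotype`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 2, byrow = TRUE)
#' genotype_data(g, phenotype = c(0L, 0L, 1L))
#' @export
genotype_data <- function(genotypes, phenotype, snp_meta = NULL,
                          sample_ids = NULL) {
  if (!is.matrix(genotypes)) stop("`genotypes` must be a matrix")
  storage.mode(genotypes) <- "integer"
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  m <- nrow(genotypes)
  n <- ncol(genotypes)
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != n) stop("phenotype length must equal sample count")
  if (anyNA(phenotype) || !all(phenotype %in% c(0L, 1L))) {
    stop("phenotype must be 0 (control) or 1 (case)")
  }
  if (!any(phenotype == 0L) || !any(phenotype == 1L)) {
    stop("need at least one case and one control")
  }
  if (is.null(snp_meta)) {
    snp_meta <- tibble::tibble(
      snp_id = sprintf("snp%06d", seq_len(m)),
      chr = 1L, pos = seq_len(m) * 10000L,
      a1 = "A", a2 = "B")
  }
  snp_meta <- tibble::as_tibble(snp_meta)
  if (nrow(snp_meta) != m) stop("snp_meta rows must equal SNP count")
  if (anyDuplicated(snp_meta$snp_id)) stop("SNP identifiers must be unique")
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%05d", seq_len(n))
  if (length(sample_ids) != n) stop("sample_ids length must equal sample count")
  structure(
    list(genotypes = genotypes, snp_meta = snp_meta,
         sample_ids = as.character(sample_ids), phenotype = phenotype),
    class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("<genotype_data> ", nrow(x$genotypes), " SNPs x ", ncol(x$genotypes),
      " samples (", sum(x$phenotype == 1L), " cases / ",
      sum(x$phenotype == 0L), " controls)\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  if (miss > 0) cat("  missing calls: ", format(100 * miss, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$genotypes)

n_snps <- function(x) nrow(x$genotypes)
n_samples <- function(x) ncol(x$genotypes)
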