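#' Genotype matrix container
#'
#' A `genotype_matrix` holds biallelic SNP calls for a set of diploid samples:
#' an integer matrix of alternate-allele counts (0/1/2, `NA` = missing call)
#' with samples in rows and loci in columns, a sample table carrying population
#' labels, a locus table carrying genomic coordinates and alleles, and an
#' optional per-cell read-depth matrix.
#'
#' @param calls Integer matrix, samples x loci, values in `{0, 1, 2, NA}`.
#' @param samples Tibble with columns `sample_id` and `pop`.
#' @param loci Tibble with columns `locus_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`. Must be sorted by `(chrom, pos)` and unique.
#' @param depth Optional integer matrix of read depths, same shape as `calls`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, loci, depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- tibble::as_tibble(samples)
  loci <- tibble::as_tibble(loci)
  g <- structure(
    list(calls = calls, samples = samples, loci = loci, depth = depth),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(g)
}

#' Validate a genotype matrix
#'
#' Checks every container invariant: call values in 0/1/2/NA, one population
#' label per sample, loci biallelic, sorted by `(chrom, pos)` and unique, and
#' dimension agreement between the call matrix and the two annotation tables.
#'
#' @param g A `genotype_matrix`.
#' @return `g`, invisibly unchanged, or an error describing the violation.
#' @export
validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(c("sample_id", "pop") %in% names(g$samples)))
    stop("samples table needs columns 'sample_id' and 'pop'", call. = FALSE)
  if (!all(c("locus_id", "chrom", "pos", "ref", "alt") %in% names(g$loci)))
    stop("loci table needs columns locus_id, chrom, pos, ref, alt", call. = FALSE)
  if (nrow(g$samples) != nrow(g$calls) || nrow(g$loci) != ncol(g$calls))
    stop("calls matrix dimensions do not match sample/locus tables", call. = FALSE)
  bad <- !(g$calls %in% c(0L, 1L, 2L) | is.na(g$calls))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  if (any(is.na(g$samples$pop) | !nzchar(g$samples$pop)))
    stop("every sample needs a non-empty population label", call. = FALSE)
  valid_base <- function(x) grepl("^[ACGT]+$", x)
  if (!all(valid_base(g$loci$ref)) || !all(valid_base(g$loci$alt)))
    stop("ref/alt alleles must be ACGT strings", call. = FALSE)
  ord <- order(g$loci$chrom, g$loci$pos)
  if (!identical(ord, seq_len(nrow(g$loci))))
    stop("loci must be sorted by (chrom, pos)", call. = FALSE)
  if (anyDuplicated(paste(g$loci$chrom, g$loci$pos)))
    stop("duplicate loci (same chrom and pos)", call. = FALSE)
  if (anyDuplicated(g$loci$locus_id)) stop("duplicate locus ids", call. = FALSE)
  if (!is.null(g$depth) && !identical(dim(g$depth), dim(g$calls)))
    stop("depth matrix must match calls matrix dimensions", call. = FALSE)
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf(
    "<genotype_matrix> %d samples x %d loci (%d populations, %.1f%% missing%s)\n",
    nrow(x$calls), ncol(x$calls), dplyr::n_distinct(x$samples$pop),
    100 * miss, if (is.null(x$depth)) "" else ", with depth"
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample and/or locus index
#'
#' @param g A `genotype_matrix`.
#' @param samples,loci Integer or logical index vectors; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selected rows/columns.
#' @export
subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(g$calls))
  if (is.null(loci)) loci <- seq_len(ncol(g$calls))
  genotype_matrix(
    calls = g$calls[samples, loci, drop = FALSE],
    samples = g$samples[samples, , drop = FALSE],
    loci = g$loci[loci, , drop = FALSE],
    depth = if (is.null(g$depth)) NULL else g$depth[samples, loci, drop = FALSE]
  )
}

#' Tidy per-locus genotype summary
#'
#' One row per locus with call counts, missingness and alternate-allele
#' frequency across all samples.
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `locus_id`, `chrom`, `pos`, `n_called`,
#'   `missing_rate`, `alt_freq`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  n_called <- colSums(!is.na(x$calls))
  alt <- colSums(x$calls, na.rm = TRUE)
  dplyr::mutate(
    dplyr::select(x$loci, "locus_id", "chrom", "pos"),
    n_called = n_called,
    missing_rate = 1 - n_called / nrow(x$calls),
    alt_freq = ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  )
}

#' Population labels as a named vector
#' @param g A `genotype_matrix`.
#' @return Named character vector `sample_id -> pop`.
#' @export
pop_labels <- function(g) {
  stats::setNames(g$samples$pop, g$samples$sample_id)
}
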