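#' SNP filter configuration
#'
#' Bundles the filtering thresholds applied to RAD-seq genotype matrices.
#' Defaults follow the stringent population-structure filter set: genotype
#' calls supported by at least 3 reads, call rate of at least 80% in every
#' population, minor allele frequency of at least 1%, at least 5000 bp
#' between retained SNPs, and removal of samples with more than 30% missing
#' data. `abc_filter_config()` returns the variant used for the demographic
#' ABC dataset (90% call rate, MAF 0.5%).
#'
#' @param min_depth Minimum reads supporting a genotype call.
#' @param min_call_rate_per_pop Minimum per-population call-rate fraction.
#' @param min_maf Minimum minor allele frequency.
#' @param min_spacing_bp Minimum distance between retained SNPs on a contig.
#' @param max_sample_missing Maximum tolerated per-sample missing fraction.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 3, min_call_rate_per_pop = 0.8,
                          min_maf = 0.01, min_spacing_bp = 5000,
                          max_sample_missing = 0.3) {
  stopifnot(
    min_call_rate_per_pop >= 0, min_call_rate_per_pop <= 1,
    min_maf >= 0, min_maf <= 0.5,
    min_spacing_bp >= 0,
    max_sample_missing >= 0, max_sample_missing <= 1
  )
  structure(list(
    min_depth = min_depth,
    min_call_rate_per_pop = min_call_rate_per_pop,
    min_maf = min_maf,
    min_spacing_bp = min_spacing_bp,
    max_sample_missing = max_sample_missing
  ), class = "filter_config")
}

#' @rdname filter_config
#' @export
abc_filter_config <- function() {
  filter_config(min_depth = 3, min_call_rate_per_pop = 0.9, min_maf = 0.005,
                min_spacing_bp = 5000, max_sample_missing = 0.3)
}

#' Mask genotype calls supported by too few reads
#'
#' Calls with depth below `min_depth` become missing; nothing else changes.
#'
#' @param g A [genotype_matrix()] carrying depth values.
#' @param min_depth Minimum read count for a call to stand.
#' @return The masked `genotype_matrix`.
#' @export
mask_low_depth <- function(g, min_depth = 3) {
  if (is.null(g$depth))
    stop("no depth values in this genotype matrix; skip the depth-mask stage",
         call. = FALSE)
  low <- !is.na(g$depth) & g$depth < min_depth
  g$calls[low] <- NA_integer_
  g
}

#' Minor allele frequency of one locus
#'
#' Gene-copy based: each diploid genotype contributes two copies, missing
#' cells are excluded from the denominator.
#'
#' @param g A [genotype_matrix()].
#' @param locus Locus index or `locus_id`.
#' @return `min(p, 1 - p)` where `p` is the alternate-allele frequency.
#' @export
minor_allele_frequency <- function(g, locus) {
  if (is.character(locus)) locus <- match(locus, g$loci$locus_id)
  calls <- g$calls[, locus]
  n <- sum(!is.na(calls))
  if (n == 0) stop("minor allele frequency undefined: all calls missing", call. = FALSE)
  p <- sum(calls, na.rm = TRUE) / (2 * n)
  min(p, 1 - p)
}

# Vectorized MAF over all loci (NaN where locus has no calls).
maf_all <- function(g) {
  n <- colSums(!is.na(g$calls))
  p <- colSums(g$calls, na.rm = TRUE) / (2 * n)
  pmin(p, 1 - p)
}

#' Keep loci genotyped in enough samples of every population
#'
#' A locus survives iff its call rate is at least `min_call_rate` in each
#' population separately.
#'
#' @param g A [genotype_matrix()].
#' @param min_call_rate Fraction in `[0, 1]`.
#' @return Filtered `genotype_matrix`.
#' @export
filter_by_call_rate <- function(g, min_call_rate = 0.8) {
  pops <- unique(g$samples$pop)
  ok <- rep(TRUE, ncol(g$calls))
  for (p in pops) {
    idx <- g$samples$pop == p
    rate <- colMeans(!is.na(g$calls[idx, , drop = FALSE]))
    ok <- ok & rate >= min_call_rate
  }
  subset_genotypes(g, loci = ok)
}

#' Drop loci below a minor-allele-frequency threshold
#'
#' @param g A [genotype_matrix()].
#' @param min_maf Minimum MAF (computed over all samples, gene copies).
#' @return Filtered `genotype_matrix`.
#' @export
filter_by_maf <- function(g, min_maf = 0.01) {
  maf <- maf_all(g)
  subset_genotypes(g, loci = !is.nan(maf) & maf >= min_maf)
}

#' Thin SNPs to a minimum physical spacing
#'
#' Greedy left-to-right keep-first rule within each contig: walk loci in
#' coordinate order and keep a locus iff it lies at least `min_spacing_bp`
#' beyond the last kept locus on the same contig. Loci on different contigs
#' never constrain each other. Deterministic.
#'
#' @param g A [genotype_matrix()].
#' @param min_spacing_bp Minimum distance (bp) between retained SNPs.
#' @return Thinned `genotype_matrix`.
#' @export
thin_by_spacing <- function(g, min_spacing_bp = 5000) {
  keep <- logical(ncol(g$calls))
  last_chrom <- ""
  last_pos <- -Inf
  for (j in seq_len(ncol(g$calls))) {
    ch <- g$loci$chrom[j]
    pos <- g$loci$pos[j]
    if (ch != last_chrom || pos - last_pos >= min_spacing_bp) {
      keep[j] <- TRUE
      last_chrom <- ch
      last_pos <- pos
    }
  }
  subset_genotypes(g, loci = keep)
}

#' Remove samples with excessive missing data
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Samples with missing fraction strictly greater than
#'   this are dropped.
#' @return Filtered `genotype_matrix`.
#' @export
drop_high_missing_samples <- function(g, max_missing = 0.3) {
  frac <- rowMeans(is.na(g$calls))
  keep <- frac <= max_missing
  if (!any(keep))
    stop("all samples exceed the missing-data threshold", call. = FALSE)
  subset_genotypes(g, samples = keep)
}

#' Run the full SNP filter pipeline
#'
#' Stage order: depth mask, per-population call rate, MAF, physical spacing,
#' sample missingness. Returns the filtered matrix with a per-stage survivor
#' count table attached as attribute `"stage_counts"` (also printed as a log
#' line when `verbose`).
#'
#' @param g A [genotype_matrix()].
#' @param config A [filter_config()].
#' @param verbose Print the stage-count log line.
#' @return Filtered `genotype_matrix` with attribute `stage_counts` (tibble
#'   of stage, n_loci, n_samples).
#' @export
apply_filter_pipeline <- function(g, config = filter_config(), verbose = FALSE) {
  stages <- list()
  note <- function(stage, g) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, n_loci = ncol(g$calls), n_samples = nrow(g$calls))
  }
  note("input", g)
  if (!is.null(g$depth)) g <- mask_low_depth(g, config$min_depth)
  note("depth_mask", g)
  g <- filter_by_call_rate(g, config$min_call_rate_per_pop)
  note("call_rate", g)
  g <- filter_by_maf(g, config$min_maf)
  note("maf", g)
  g <- thin_by_spacing(g, config$min_spacing_bp)
  note("spacing", g)
  g <- drop_high_missing_samples(g, config$max_sample_missing)
  note("sample_missing", g)
  counts <- dplyr::bind_rows(stages)
  if (verbose)
    message(paste(sprintf("%s: %d loci / %d samples", counts$stage,
                          counts$n_loci, counts$n_samples), collapse = " | "))
  attr(g, "stage_counts") <- counts
  g
}
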