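#' Nei's unbiased gene diversity of one locus within one population
#'
#' `H = n/(n-1) * (1 - sum p_i^2)` over the `n` non-missing gene copies
#' (two per genotyped diploid). Equals the fraction of differing pairs among
#' all distinct pairs of gene copies.
#'
#' @param calls Integer vector of genotypes (0/1/2, `NA` missing) for the
#'   population's samples at one locus.
#' @return Gene diversity in `[0, 1]`.
#' @export
gene_diversity <- function(calls) {
  n <- 2 * sum(!is.na(calls))
  if (n < 2) stop("gene diversity undefined: fewer than 2 gene copies", call. = FALSE)
  p <- sum(calls, na.rm = TRUE) / n
  n / (n - 1) * (1 - p^2 - (1 - p)^2)
}

# Vectorized per-locus gene diversity for a sub-matrix of calls
# (samples x loci). NaN where fewer than 2 gene copies.
gene_diversity_all <- function(calls) {
  n <- 2 * colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / n
  h <- n / (n - 1) * (1 - p^2 - (1 - p)^2)
  h[n < 2] <- NaN
  h
}

#' Within-population summary statistics
#'
#' The DIYABC-style within-population statistics: proportion of monomorphic
#' loci, mean and variance of gene diversity over polymorphic loci, and mean
#' gene diversity over all loci. Polymorphism is judged within the
#' population. For a newly founded population (`mode = "reduced"`) only the
#' proportion monomorphic and the mean gene diversity across all loci are
#' informative and returned.
#'
#' @param g A [genotype_matrix()].
#' @param pop Population label.
#' @param mode `"full"` (four statistics) or `"reduced"` (two).
#' @return A tibble with columns `stat`, `value`; names are prefixed with
#'   the population label.
#' @export
within_population_stats <- function(g, pop, mode = c("full", "reduced")) {
  mode <- match.arg(mode)
  if (!pop %in% g$samples$pop) stop("population not present: ", pop, call. = FALSE)
  calls <- g$calls[g$samples$pop == pop, , drop = FALSE]
  if (nrow(calls) < 2) stop("population needs >= 2 samples: ", pop, call. = FALSE)
  h <- gene_diversity_all(calls)
  informative <- !is.nan(h)
  h <- h[informative]
  poly <- h > 0
  prop_mono <- if (length(h)) mean(!poly) else NaN
  mean_all <- if (length(h)) mean(h) else NaN
  if (mode == "reduced") {
    return(tibble::tibble(
      stat = paste0(pop, c("_prop_monomorphic", "_mean_gene_div_all")),
      value = c(prop_mono, mean_all)
    ))
  }
  if (!any(poly)) {
    warning("no polymorphic loci in population ", pop,
            "; polymorphic-locus variance reported as 0", call. = FALSE)
    mean_poly <- 0
    var_poly <- 0
  } else {
    mean_poly <- mean(h[poly])
    var_poly <- if (sum(poly) > 1) stats::var(h[poly]) else 0
  }
  tibble::tibble(
    stat = paste0(pop, c("_prop_monomorphic", "_mean_gene_div_poly",
                         "_var_gene_div_poly", "_mean_gene_div_all")),
    value = c(prop_mono, mean_poly, var_poly, mean_all)
  )
}

#' Between-population summary statistics
#'
#' Per-locus Weir-Cockerham F_ST between two populations, summarized as:
#' ratio-of-averages mean F_ST, proportion of "null" per-locus values
#' (estimate <= 0), and mean and variance of the strictly positive
#' remainder.
#'
#' @param g A [genotype_matrix()].
#' @param pop_a,pop_b Population labels.
#' @return A tibble with columns `stat`, `value`.
#' @export
between_population_stats <- function(g, pop_a, pop_b) {
  res <- pairwise_fst(g, pop_a, pop_b)
  fst <- res$per_locus$fst
  fst <- fst[is.finite(fst)]
  nonnull <- fst[fst > 0]
  tibble::tibble(
    stat = paste0(pop_a, "_", pop_b,
                  c("_mean_fst", "_prop_null_fst",
                    "_mean_nonnull_fst", "_var_nonnull_fst")),
    value = c(
      res$mean_fst,
      if (length(fst)) mean(fst <= 0) else NaN,
      if (length(nonnull)) mean(nonnull) else 0,
      if (length(nonnull) > 1) stats::var(nonnull) else 0
    )
  )
}

#' Assemble the observed ABC summary-statistic vector
#'
#' Fixed ordering for the three-cluster S. invicta design: full
#' within-population statistics for the two native clusters, reduced
#' statistics for the introduced cluster, and between-population statistics
#' for the two pairs that diverged directly from each other (native1 vs
#' native2 and native1 vs introduced). Length 18.
#'
#' @param g A [genotype_matrix()].
#' @param native1,native2,introduced Population labels of the three clusters
#'   (native1 is the source of the introduction).
#' @return A tibble (`stat`, `value`) of 18 rows, in the documented order.
#' @export
observed_summary <- function(g, native1 = "N1", native2 = "N2",
                             introduced = "INT") {
  for (p in c(native1, native2, introduced)) {
    if (!p %in% g$samples$pop)
      stop("population cluster not present: ", p, call. = FALSE)
  }
  dplyr::bind_rows(
    within_population_stats(g, native1, "full"),
    within_population_stats(g, native2, "full"),
    within_population_stats(g, introduced, "reduced"),
    between_population_stats(g, native1, native2),
    between_population_stats(g, native1, introduced)
  )
}

# Canonical names of the 18-statistic vector for generic cluster labels,
# used to align observed and simulated vectors.
summary_stat_names <- function(native1 = "N1", native2 = "N2",
                               introduced = "INT") {
  c(
    paste0(native1, c("_prop_monomorphic", "_mean_gene_div_poly",
                      "_var_gene_div_poly", "_mean_gene_div_all")),
    paste0(native2, c("_prop_monomorphic", "_mean_gene_div_poly",
                      "_var_gene_div_poly", "_mean_gene_div_all")),
    paste0(introduced, c("_prop_monomorphic", "_mean_gene_div_all")),
    paste0(native1, "_", native2,
           c("_mean_fst", "_prop_null_fst", "_mean_nonnull_fst", "_var_nonnull_fst")),
    paste0(native1, "_", introduced,
           c("_mean_fst", "_prop_null_fst", "_mean_nonnull_fst", "_var_nonnull_fst"))
  )
}
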