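#' Parameters of the four-population S. invicta demographic scenario
#'
#' Backward-in-time model of the introduction to North America: the
#' introduced population (size `n_i`) goes through a founder bottleneck of
#' size `n_f` lasting `t_b` generations immediately after the introduction
#' `t_i` generations ago, when it split from the native source cluster
#' (size `n_n1`); a second native cluster (size `n_n2`) diverged from the
#' source `t_d` generations ago. Sizes are effective diploid-equivalent
#' individuals; the haplodiploid 3/4 correction is applied only at
#' parameter-interpretation time (see [theta_to_ne()]).
#'
#' @param n_n1,n_n2,n_f,n_i Effective sizes (>= 1).
#' @param t_d,t_i,t_b Times in generations; must satisfy
#'   `t_b <= t_i <= t_d`.
#' @return A list of class `invicta_scenario_params`.
#' @export
invicta_scenario_params <- function(n_n1, n_n2, n_f, n_i, t_d, t_i, t_b) {
  p <- list(n_n1 = n_n1, n_n2 = n_n2, n_f = n_f, n_i = n_i,
            t_d = t_d, t_i = t_i, t_b = t_b)
  if (any(vapply(p[1:4], function(x) x < 1, logical(1))))
    stop("effective sizes must be >= 1", call. = FALSE)
  if (any(vapply(p[5:7], function(x) x < 0, logical(1))))
    stop("times must be >= 0", call. = FALSE)
  if (!(t_b <= t_i && t_i <= t_d))
    stop("time ordering violated: need t_b <= t_i <= t_d", call. = FALSE)
  structure(p, class = "invicta_scenario_params")
}

#' Sampling layout for a simulated SNP dataset
#'
#' @param n_per_pop Named integer vector of diploid sample counts, names
#'   are the population labels of the three clusters in order (native
#'   source, second native, introduced).
#' @param n_loci Number of unlinked one-SNP loci.
#' @param locus_length Locus length in bp (used when writing coordinates).
#' @return A list of class `sample_spec`.
#' @export
sample_spec <- function(n_per_pop = c(N1 = 16, N2 = 12, INT = 12),
                        n_loci = 200, locus_length = 96) {
  stopifnot(length(n_per_pop) == 3, all(n_per_pop >= 0), n_loci >= 0,
            locus_length >= 1)
  structure(list(n_per_pop = n_per_pop, n_loci = n_loci,
                 locus_length = locus_length), class = "sample_spec")
}

#' Simulate a SNP genotype matrix under the four-population scenario
#'
#' Continuous-time coalescent over the scenario of
#' [invicta_scenario_params()]; each locus carries exactly one biallelic SNP
#' produced by placing a single mutation on the genealogy with probability
#' proportional to branch length (DIYABC-style SNP scheme; every branch lies
#' below the pooled-sample MRCA, so the pooled sample is always
#' polymorphic). Deterministic given `seed`.
#'
#' @param params An [invicta_scenario_params()].
#' @param spec A [sample_spec()].
#' @param seed Integer seed.
#' @return A [genotype_matrix()]; loci are placed on separate contigs
#'   (`contig_<i>`) so they are unlinked by construction.
#' @export
simulate_invicta_scenario <- function(params, spec, seed = 1) {
  stopifnot(inherits(params, "invicta_scenario_params"),
            inherits(spec, "sample_spec"))
  n <- spec$n_per_pop
  calls <- cpp_sim_genotypes(
    as.numeric(params[c("n_n1", "n_n2", "n_f", "n_i", "t_d", "t_i", "t_b")]),
    n[[1]], n[[2]], n[[3]], spec$n_loci, as.double(seed)
  )
  pops <- rep(names(n), times = n)
  samples <- tibble::tibble(
    sample_id = sprintf("%s_%02d", pops, unlist(lapply(n, seq_len))),
    pop = pops
  )
  width <- nchar(as.character(max(spec$n_loci, 1)))
  loci <- tibble::tibble(
    locus_id = sprintf("locus_%0*d", width, seq_len(spec$n_loci)),
    chrom = sprintf("contig_%0*d", width, seq_len(spec$n_loci)),
    pos = rep(as.integer(ceiling(spec$locus_length / 2)), spec$n_loci),
    ref = rep("A", spec$n_loci),
    alt = rep("G", spec$n_loci)
  )
  genotype_matrix(calls, samples, loci)
}

#' Summary statistics of many simulated datasets (reference-table path)
#'
#' Fast compiled path used to build ABC reference tables: simulates one
#' dataset per parameter row and returns the 18 summary statistics directly,
#' without materializing genotype matrices in R. Statistic ordering matches
#' [observed_summary()] / [summary_stat_names()].
#'
#' @param param_table Data frame / matrix with columns `n_n1, n_n2, n_f,
#'   n_i, t_d, t_i, t_b` (one row per simulation).
#' @param spec A [sample_spec()].
#' @param seed Integer seed; row `s` uses a stream derived from
#'   `(seed, s)`, so the table is reproducible and rows are independent.
#' @return Matrix `nrow(param_table)` x 18 with named columns.
#' @export
simulate_scenario_stats <- function(param_table, spec, seed = 1) {
  pt <- as.matrix(param_table[, c("n_n1", "n_n2", "n_f", "n_i",
                                  "t_d", "t_i", "t_b")])
  n <- spec$n_per_pop
  out <- cpp_reference_table_stats(pt, n[[1]], n[[2]], n[[3]],
                                   spec$n_loci, as.double(seed))
  colnames(out) <- summary_stat_names(names(n)[1], names(n)[2], names(n)[3])
  out
}
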