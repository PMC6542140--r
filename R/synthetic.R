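#' Generate a study-like synthetic SNP dataset with known truth
#'
#' Emulates the filtered RAD-seq genotype data: three population clusters
#' (large native source, smaller second native cluster roughly two orders
#' of magnitude below it, and an introduced cluster descended from the
#' source through a severe founder bottleneck), with per-cell read depths
#' and realistic missingness so every filter stage is exercised. At
#' `scale = 1` the default layout is ~40 diploid samples by ~1500 loci.
#'
#' @param dir Output directory (created if needed).
#' @param scale Size multiplier in `(0, 1]` applied to samples and loci.
#' @param seed Integer seed; the dataset is bit-reproducible from
#'   `(scale, seed)` and the manifest.
#' @param params Optional [invicta_scenario_params()] truth; the default is
#'   a prior-typical draw with a founder size in the tens.
#' @return List with `vcf`, `popmap`, `manifest` file paths, the `truth`
#'   parameters and the generated [genotype_matrix()].
#' @export
make_study_like_genotypes <- function(dir = tempfile("synthgeno"), scale = 1,
                                      seed = 1, params = NULL) {
  stopifnot(scale > 0, scale <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params)) {
    params <- invicta_scenario_params(
      n_n1 = 1.2e7, n_n2 = 2.5e5, n_f = 39, n_i = 5e6,
      t_d = 80000, t_i = 120, t_b = 2
    )
  }
  spec <- sample_spec(
    n_per_pop = c(N1 = max(2, round(16 * scale)),
                  N2 = max(2, round(12 * scale)),
                  INT = max(2, round(12 * scale))),
    n_loci = max(20, round(1500 * scale))
  )
  g <- simulate_invicta_scenario(params, spec, seed = derive_seed(seed, 1))
  # read depths: negative-binomial-ish coverage around 12x, and a sprinkle
  # of low-coverage cells so the depth mask has work to do
  withr::with_seed(as.integer(derive_seed(seed, 2)), {
    depth <- matrix(
      stats::rnbinom(length(g$calls), mu = 12, size = 4),
      nrow = nrow(g$calls)
    )
  })
  g$depth <- depth
  g <- make_missingness(g, sample_rate = 0.04, locus_rate = 0.04,
                        seed = derive_seed(seed, 3))
  vcf <- file.path(dir, "synthetic_genotypes.vcf")
  popmap <- file.path(dir, "synthetic_popmap.tsv")
  write_genotypes(g, vcf, popmap)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    kind = "synthetic_genotypes",
    seed = seed, scale = scale,
    truth = lapply(unclass(params), identity),
    layout = list(n_per_pop = as.list(spec$n_per_pop), n_loci = spec$n_loci),
    files = list(vcf = basename(vcf), popmap = basename(popmap))
  ), manifest)
  list(vcf = vcf, popmap = popmap, manifest = manifest,
       truth = params, genotypes = g)
}

#' Generate a synthetic triplet-alignment fixture with known truth
#'
#' Triplets at the shipped isolation-model parameter point (divergence
#' times ~6.5e-4 and ~8.4e-3 substitutions/site; per-species diversities
#' per [table1_estimates()]) under either the complete-isolation model or
#' an isolation-with-migration model, written as multi-FASTA plus a
#' ground-truth manifest.
#'
#' @param dir Output directory.
#' @param model `"null"` or `"im"`.
#' @param n_loci Number of triplets (default 2000, the desk-scale fitting
#'   size).
#' @param mig Migration rate (migrants/generation, both directions) used
#'   when `model = "im"`.
#' @param seed Integer seed.
#' @return List with `fasta`, `manifest` paths, `truth` ([im_params()])
#'   and the [triplet_dataset()].
#' @export
make_triplet_fixture <- function(dir = tempfile("synthtrip"),
                                 model = c("null", "im"), n_loci = 2000,
                                 mig = 2, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_loci >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- if (model == "null") default_im_params() else
    default_im_params(mig_ab = mig, mig_ba = mig)
  ds <- simulate_triplets(truth, n_loci = n_loci, seed = seed)
  fasta <- file.path(dir, "synthetic_triplets.fasta")
  write_triplets(ds, fasta)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    kind = "synthetic_triplets", model = model, seed = seed, n_loci = n_loci,
    truth = lapply(unclass(truth), identity),
    files = list(fasta = basename(fasta))
  ), manifest)
  list(fasta = fasta, manifest = manifest, truth = truth, triplets = ds)
}

#' Mask genotype calls under a random missingness pattern
#'
#' Each cell is masked with probability
#' `1 - (1 - sample_rate_i) * (1 - locus_rate_j)` where the per-sample and
#' per-locus rates are jittered around the requested targets, emulating
#' sample- and locus-level dropout in RAD data.
#'
#' @param g A [genotype_matrix()].
#' @param sample_rate,locus_rate Target missingness rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return The masked `genotype_matrix`.
#' @export
make_missingness <- function(g, sample_rate = 0.05, locus_rate = 0.05,
                             seed = 1) {
  stopifnot(sample_rate >= 0, sample_rate <= 1,
            locus_rate >= 0, locus_rate <= 1)
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    n <- nrow(g$calls); L <- ncol(g$calls)
    # per-sample rates jittered around the target (mean exactly on target)
    rs <- if (sample_rate >= 1) rep(1, n) else
      pmin(sample_rate * stats::runif(n, 0.5, 1.5), 1)
    rl <- rep(locus_rate, L)
    p_keep <- outer(1 - pmin(rs, 1), 1 - pmin(rl, 1))
    mask <- matrix(stats::runif(n * L) > p_keep, nrow = n)
    g$calls[mask] <- NA_integer_
    g
  })
}
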