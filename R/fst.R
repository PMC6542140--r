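#' Per-locus Weir-Cockerham F_ST between two populations
#'
#' The Weir & Cockerham (1984) theta-hat estimator computed per locus from
#' genotype counts (sample sizes, allele frequencies and observed
#' heterozygote frequencies per population), plus the multi-locus
#' ratio-of-averages mean (sum of the `a` components over the sum of
#' `a + b + c`). Negative per-locus values are retained, not clipped.
#'
#' @param g A [genotype_matrix()].
#' @param pop_a,pop_b Population labels present in `g`.
#' @return A list with `per_locus` (tibble: locus_id, fst, a, abc) and
#'   `mean_fst` (ratio-of-averages over loci with defined components).
#' @export
pairwise_fst <- function(g, pop_a, pop_b) {
  pops <- unique(g$samples$pop)
  for (p in c(pop_a, pop_b)) {
    if (!p %in% pops) stop("population not present: ", p, call. = FALSE)
  }
  ia <- g$samples$pop == pop_a
  ib <- g$samples$pop == pop_b
  comp <- wc_components(g$calls[ia, , drop = FALSE], g$calls[ib, , drop = FALSE])
  per_locus <- tibble::tibble(
    locus_id = g$loci$locus_id,
    fst = comp$a / comp$abc,
    a = comp$a,
    abc = comp$abc
  )
  ok <- is.finite(per_locus$fst)
  list(
    per_locus = per_locus,
    mean_fst = sum(comp$a[ok]) / sum(comp$abc[ok])
  )
}

# Weir-Cockerham (1984) variance components for r = 2 populations, all loci
# at once. Returns a (among-population) and abc = a + b + c per locus; the
# per-locus estimator is a / (a + b + c). Loci where either population has
# no genotyped sample, or where the denominator is zero (monomorphic across
# both samples), yield NaN.
wc_components <- function(calls_a, calls_b) {
  n1 <- colSums(!is.na(calls_a))          # genotyped individuals
  n2 <- colSums(!is.na(calls_b))
  p1 <- colSums(calls_a, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(calls_b, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(calls_a == 1L, na.rm = TRUE) / n1   # observed het frequency
  h2 <- colSums(calls_b == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  bad <- n1 == 0 | n2 == 0 | nbar <= 1
  a[bad] <- NaN
  abc <- a + b + c
  abc[bad] <- NaN
  list(a = a, abc = abc)
}
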