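# Shared fixtures and independent (brute-force) oracles. Everything here is
# deliberately written without reusing package internals, so tests compare
# two independent routes to the same quantity.

# small random genotype matrix with depth and missingness
random_genotypes <- function(n_samples = 12, n_loci = 30, n_pops = 2,
                             miss = 0.1, seed = 1, depth = TRUE) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n_samples * n_loci, replace = TRUE),
                  nrow = n_samples)
  calls[matrix(runif(n_samples * n_loci) < miss, nrow = n_samples)] <- NA
  pops <- paste0("P", rep_len(seq_len(n_pops), n_samples))
  chrom <- sprintf("ctg%02d", rep(seq_len(ceiling(n_loci / 5)), each = 5))[1:n_loci]
  pos <- as.integer(unlist(lapply(rle(chrom)$lengths,
                                  function(k) sort(sample(1:2e4, k)))))
  genotype_matrix(
    calls = calls,
    samples = tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n_samples)), pop = pops),
    loci = tibble::tibble(
      locus_id = sprintf("L%03d", seq_len(n_loci)), chrom = chrom, pos = pos,
      ref = "A", alt = "T"),
    depth = if (depth) matrix(rpois(n_samples * n_loci, 8), nrow = n_samples)
  )
}

# pair-enumeration oracle for gene diversity: fraction of differing pairs
# among all distinct pairs of gene copies
oracle_gene_diversity <- function(calls) {
  copies <- unlist(lapply(calls[!is.na(calls)], function(g) {
    c(rep(1, g), rep(0, 2 - g))
  }))
  n <- length(copies)
  diffs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + (copies[i] != copies[j])
  diffs / choose(n, 2)
}

# independent transcription of the Weir & Cockerham (1984) theta-hat for
# two populations at one locus
oracle_wc_fst <- function(ca, cb) {
  ca <- ca[!is.na(ca)]; cb <- cb[!is.na(cb)]
  n1 <- length(ca); n2 <- length(cb); r <- 2
  p1 <- sum(ca) / (2 * n1); p2 <- sum(cb) / (2 * n2)
  h1 <- mean(ca == 1); h2 <- mean(cb == 1)
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, abc = a + b + cc)
}

# independent single-population coalescent with the one-mutation-per-locus
# scheme (plain R, no shared code with the compiled simulator)
oracle_single_pop_locus <- function(n_copies, N) {
  k <- n_copies
  nodes <- seq_len(k)
  times <- rep(0, 2 * k - 1)
  children <- vector("list", 2 * k - 1)
  t <- 0
  nxt <- k + 1
  while (length(nodes) > 1) {
    m <- length(nodes)
    t <- t + rexp(1, m * (m - 1) / 2 / (2 * N))
    pick <- sample(m, 2)
    times[nxt] <- t
    children[[nxt]] <- nodes[pick]
    nodes <- c(nodes[-pick], nxt)
    nxt <- nxt + 1
  }
  root <- 2 * k - 1
  parent <- rep(NA_integer_, 2 * k - 1)
  for (v in (k + 1):root) for (ch in children[[v]]) parent[ch] <- v
  lens <- times[parent[-root]] - times[-root]
  br <- sample(2 * k - 2, 1, prob = lens)
  tips_below <- function(v) {
    if (v <= k) return(v)
    unlist(lapply(children[[v]], tips_below))
  }
  derived <- rep(0L, k)
  derived[tips_below(br)] <- 1L
  derived
}

# a tiny deterministic VCF + popmap fixture written by hand
write_tiny_vcf <- function(dir = tempfile()) {
  dir.create(dir)
  vcf <- file.path(dir, "tiny.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "ctg1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "ctg1\t900\tsnp2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0"
  ), vcf)
  popmap <- file.path(dir, "tiny_popmap.tsv")
  writeLines(c("s1\tA", "s2\tA", "s3\tB"), popmap)
  list(vcf = vcf, popmap = popmap)
}
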