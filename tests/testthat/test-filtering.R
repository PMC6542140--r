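test_that("depth masking matches a brute-force scan and min_depth 0 is identity", {
  g <- random_genotypes(seed = 11)
  masked <- mask_low_depth(g, 3)
  should_mask <- !is.na(g$depth) & g$depth < 3 & !is.na(g$calls)
  expect_true(all(is.na(masked$calls[should_mask])))
  expect_equal(masked$calls[!should_mask], g$calls[!should_mask])
  expect_equal(mask_low_depth(g, 0)$calls, g$calls)
  g$depth <- NULL
  expect_error(mask_low_depth(g, 3), "skip")
})

test_that("minor allele frequency is a gene-copy tally", {
  g <- random_genotypes(n_samples = 3, n_loci = 1, miss = 0, seed = 2)
  g$calls[, 1] <- c(0L, 0L, 1L)
  expect_equal(minor_allele_frequency(g, 1), 1 / 6)
  g$calls[, 1] <- c(0L, 0L, 0L)
  expect_equal(minor_allele_frequency(g, 1), 0)
  # brute force on a 50-sample locus
  g2 <- random_genotypes(n_samples = 50, n_loci = 1, miss = 0.2, seed = 3)
  copies <- unlist(lapply(g2$calls[!is.na(g2$calls[, 1]), 1],
                          function(x) c(rep(1, x), rep(0, 2 - x))))
  expect_equal(minor_allele_frequency(g2, 1),
               min(mean(copies), 1 - mean(copies)))
})

test_that("per-population call-rate filtering keeps exactly the right loci", {
  g <- random_genotypes(n_samples = 20, n_loci = 40, n_pops = 2, miss = 0.25,
                        seed = 4)
  filt <- filter_by_call_rate(g, 0.8)
  keep_brute <- vapply(seq_len(ncol(g$calls)), function(j) {
    all(vapply(unique(g$samples$pop), function(p) {
      mean(!is.na(g$calls[g$samples$pop == p, j])) >= 0.8
    }, logical(1)))
  }, logical(1))
  expect_equal(filt$loci$locus_id, g$loci$locus_id[keep_brute])
  expect_equal(ncol(filter_by_call_rate(g, 0)$calls), ncol(g$calls))
})

test_that("a locus below threshold in one population is dropped even if perfect elsewhere", {
  g <- random_genotypes(n_samples = 20, n_loci = 2, n_pops = 2, miss = 0,
                        seed = 5)
  in_a <- which(g$samples$pop == "P1")
  g$calls[in_a[1:3], 1] <- NA   # 7/10 called in P1 at locus 1
  filt <- filter_by_call_rate(g, 0.8)
  expect_false("L001" %in% filt$loci$locus_id)
  expect_true("L002" %in% filt$loci$locus_id)
})

test_that("spacing thinning is greedy keep-first per contig", {
  g <- random_genotypes(n_samples = 4, n_loci = 3, miss = 0, seed = 6)
  g$loci$chrom <- "ctg1"
  g$loci$pos <- c(100L, 4000L, 6000L)
  thin <- thin_by_spacing(g, 5000)
  expect_equal(thin$loci$pos, c(100L, 6000L))
  expect_equal(ncol(thin_by_spacing(g, 0)$calls), 3L)
  # loci on different contigs never constrain each other
  g$loci$chrom <- c("ctg1", "ctg2", "ctg3")
  g$loci$pos <- c(100L, 101L, 102L)
  expect_equal(ncol(thin_by_spacing(g, 5000)$calls), 3L)
})

test_that("sample missingness filter matches brute force and errors when empty", {
  g <- random_genotypes(n_samples = 15, n_loci = 40, miss = 0.3, seed = 7)
  out <- drop_high_missing_samples(g, 0.3)
  keep_brute <- rowMeans(is.na(g$calls)) <= 0.3
  expect_equal(out$samples$sample_id, g$samples$sample_id[keep_brute])
  expect_equal(nrow(drop_high_missing_samples(g, 1)$calls), nrow(g$calls))
  expect_error(drop_high_missing_samples(g, -0.1), "threshold")
})

test_that("a sample at 31% missing is dropped at the 30% threshold", {
  g <- random_genotypes(n_samples = 5, n_loci = 100, miss = 0, seed = 8)
  g$calls[1, 1:31] <- NA
  out <- drop_high_missing_samples(g, 0.30)
  expect_false("s01" %in% out$samples$sample_id)
  expect_equal(nrow(out$calls), 4L)
})

test_that("filters are idempotent projections that never edit retained calls", {
  g <- random_genotypes(n_samples = 16, n_loci = 50, n_pops = 2, miss = 0.2,
                        seed = 9)
  filters <- list(
    function(x) filter_by_call_rate(x, 0.8),
    function(x) filter_by_maf(x, 0.05),
    function(x) thin_by_spacing(x, 3000),
    function(x) drop_high_missing_samples(x, 0.4)
  )
  for (f in filters) {
    once <- f(g)
    twice <- f(once)
    expect_equal(twice$calls, once$calls)
    expect_equal(twice$loci, once$loci)
    kept <- match(once$loci$locus_id, g$loci$locus_id)
    kept_s <- match(once$samples$sample_id, g$samples$sample_id)
    expect_equal(once$calls, g$calls[kept_s, kept, drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("the pipeline composes stages in order with non-increasing counts", {
  g <- random_genotypes(n_samples = 20, n_loci = 60, n_pops = 3, miss = 0.15,
                        seed = 10)
  cfg <- filter_config(min_depth = 3, min_call_rate_per_pop = 0.7,
                       min_maf = 0.05, min_spacing_bp = 2000,
                       max_sample_missing = 0.5)
  out <- apply_filter_pipeline(g, cfg)
  counts <- attr(out, "stage_counts")
  expect_equal(counts$stage,
               c("input", "depth_mask", "call_rate", "maf", "spacing",
                 "sample_missing"))
  expect_true(all(diff(counts$n_loci) <= 0))
  expect_true(all(diff(counts$n_samples) <= 0))
  # brute-force sequential application gives the same survivors
  step <- mask_low_depth(g, 3)
  step <- filter_by_call_rate(step, 0.7)
  step <- filter_by_maf(step, 0.05)
  step <- thin_by_spacing(step, 2000)
  step <- drop_high_missing_samples(step, 0.5)
  expect_equal(out$calls, step$calls)
  expect_equal(out$loci, step$loci)
  # all-pass config is the identity
  noop <- apply_filter_pipeline(
    g, filter_config(min_depth = 0, min_call_rate_per_pop = 0, min_maf = 0,
                     min_spacing_bp = 0, max_sample_missing = 1))
  expect_equal(noop$calls, g$calls, ignore_attr = TRUE)
})
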