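test_that("gene diversity equals the pair-enumeration oracle", {
  expect_equal(gene_diversity(c(0L, 0L, 0L)), 0)
  # 8 copies, 4 ref / 4 alt -> 16 differing pairs of C(8,2) = 28
  expect_equal(gene_diversity(c(2L, 2L, 0L, 0L)), 16 / 28)
  set.seed(21)
  for (i in 1:5) {
    calls <- sample(c(0:2, NA), 12, replace = TRUE)
    if (sum(!is.na(calls)) < 1) next
    expect_equal(gene_diversity(calls), oracle_gene_diversity(calls))
  }
  expect_error(gene_diversity(c(NA, NA)), "undefined")
})

test_that("within-population statistics match hand computation", {
  g <- random_genotypes(n_samples = 6, n_loci = 2, n_pops = 1, miss = 0,
                        seed = 22)
  g$calls[, 1] <- c(0L, 0L, 0L, 0L, 0L, 0L)   # monomorphic
  g$calls[, 2] <- c(0L, 1L, 1L, 2L, 0L, 1L)   # 5/12 alt copies
  st <- within_population_stats(g, "P1", "full")
  h2 <- 12 / 11 * (1 - (5 / 12)^2 - (7 / 12)^2)
  expect_equal(st$value, c(0.5, h2, 0, (0 + h2) / 2))
  red <- within_population_stats(g, "P1", "reduced")
  expect_equal(nrow(red), 2L)
  expect_equal(red$value, c(0.5, (0 + h2) / 2))
})

test_that("all-monomorphic population gives prop 1 and zero diversity", {
  g <- random_genotypes(n_samples = 4, n_loci = 5, n_pops = 1, miss = 0,
                        seed = 23)
  g$calls[] <- 2L
  st <- suppressWarnings(within_population_stats(g, "P1", "full"))
  expect_equal(st$value[st$stat == "P1_prop_monomorphic"], 1)
  expect_equal(st$value[st$stat == "P1_mean_gene_div_all"], 0)
  expect_warning(within_population_stats(g, "P1", "full"), "polymorphic")
})

test_that("per-locus Weir-Cockerham estimator matches an independent transcription", {
  g <- random_genotypes(n_samples = 20, n_loci = 25, n_pops = 2, miss = 0.1,
                        seed = 24)
  res <- pairwise_fst(g, "P1", "P2")
  ca_all <- g$calls[g$samples$pop == "P1", , drop = FALSE]
  cb_all <- g$calls[g$samples$pop == "P2", , drop = FALSE]
  oa <- t(vapply(seq_len(ncol(ca_all)), function(j)
    oracle_wc_fst(ca_all[, j], cb_all[, j]), numeric(2)))
  expect_equal(res$per_locus$fst, oa[, 1] / oa[, 2])
  ok <- is.finite(oa[, 1] / oa[, 2])
  expect_equal(res$mean_fst, sum(oa[ok, 1]) / sum(oa[ok, 2]))
  expect_error(pairwise_fst(g, "P1", "nope"), "not present")
})

test_that("fixed differences give F_ST of 1; identical populations near 0", {
  g <- random_genotypes(n_samples = 20, n_loci = 10, n_pops = 2, miss = 0,
                        seed = 25)
  g$calls[g$samples$pop == "P1", ] <- 0L
  g$calls[g$samples$pop == "P2", ] <- 2L
  res <- pairwise_fst(g, "P1", "P2")
  expect_equal(res$per_locus$fst, rep(1, 10))
  bt <- between_population_stats(g, "P1", "P2")
  expect_equal(bt$value[bt$stat == "P1_P2_mean_fst"], 1)
  expect_equal(bt$value[bt$stat == "P1_P2_prop_null_fst"], 0)

  # two subsamples of one panmictic pool: mostly null, mean near zero
  set.seed(26)
  g2 <- random_genotypes(n_samples = 60, n_loci = 60, n_pops = 1, miss = 0,
                         seed = 26)
  g2$samples$pop <- rep(c("X", "Y"), 30)
  bt2 <- between_population_stats(g2, "X", "Y")
  expect_lt(abs(bt2$value[bt2$stat == "X_Y_mean_fst"]), 0.05)
  expect_gt(bt2$value[bt2$stat == "X_Y_prop_null_fst"], 0.3)
})

test_that("between-population statistics equal a brute-force recomputation", {
  p <- invicta_scenario_params(5e4, 5e3, 40, 1e4, 8000, 100, 20)
  g <- simulate_invicta_scenario(p, sample_spec(c(N1 = 10, N2 = 8, INT = 8),
                                                n_loci = 120), seed = 27)
  bt <- between_population_stats(g, "N1", "N2")
  fst <- pairwise_fst(g, "N1", "N2")$per_locus$fst
  fst <- fst[is.finite(fst)]
  pos <- fst[fst > 0]
  expect_equal(bt$value[2:4],
               c(mean(fst <= 0), mean(pos), var(pos)))
})

test_that("the observed vector has the documented 18-statistic layout", {
  p <- invicta_scenario_params(1e5, 1e3, 30, 1e4, 5000, 100, 10)
  g <- simulate_invicta_scenario(p, sample_spec(c(N1 = 8, N2 = 6, INT = 6),
                                                n_loci = 80), seed = 28)
  obs <- observed_summary(g, "N1", "N2", "INT")
  expect_equal(nrow(obs), 18L)
  expect_equal(obs$stat, summary_stat_names("N1", "N2", "INT"))
  # componentwise recomputation
  expect_equal(obs$value[1:4],
               within_population_stats(g, "N1", "full")$value)
  expect_equal(obs$value[9:10],
               within_population_stats(g, "INT", "reduced")$value)
  expect_equal(obs$value[11:14],
               between_population_stats(g, "N1", "N2")$value)
  expect_error(observed_summary(g, "N1", "N2", "ghost"), "ghost")
})

test_that("statistics are invariant to sample order and allele relabeling", {
  p <- invicta_scenario_params(1e5, 1e3, 30, 1e4, 5000, 100, 10)
  g <- simulate_invicta_scenario(p, sample_spec(c(N1 = 8, N2 = 6, INT = 6),
                                                n_loci = 60), seed = 29)
  obs <- observed_summary(g, "N1", "N2", "INT")
  set.seed(30)
  perm <- sample(nrow(g$calls))
  g_perm <- genotype_matrix(g$calls[perm, ], g$samples[perm, ], g$loci)
  expect_equal(observed_summary(g_perm, "N1", "N2", "INT"), obs)
  # ref/alt swap: genotype g -> 2 - g
  g_swap <- genotype_matrix(2L - g$calls, g$samples,
                            dplyr::mutate(g$loci, ref = "G", alt = "A"))
  expect_equal(observed_summary(g_swap, "N1", "N2", "INT")$value, obs$value)
})

test_that("compiled reference-table statistics agree with the R module", {
  p <- invicta_scenario_params(2e5, 4e3, 25, 2e4, 9000, 150, 15)
  spec <- sample_spec(c(N1 = 8, N2 = 6, INT = 6), n_loci = 150)
  g <- simulate_invicta_scenario(p, spec, seed = 31)
  r_stats <- observed_summary(g, "N1", "N2", "INT")
  cpp_stats <- fireantdemog:::cpp_stats_from_genotypes(g$calls, 8L, 6L, 6L)
  expect_equal(unname(cpp_stats), r_stats$value, tolerance = 1e-12)
})
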