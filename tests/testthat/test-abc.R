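test_that("prior draws respect the documented ranges and the time ordering", {
  prior <- prior_spec()
  d <- draw_priors(prior, 5000, seed = 61)
  expect_true(all(d$t_i >= 0 & d$t_i <= 180))
  expect_true(all(d$n_f >= 1 & d$n_f <= 500))
  expect_true(all(d$t_b >= 0 & d$t_b <= 40))
  expect_true(all(d$t_b <= d$t_i & d$t_i <= d$t_d))
  # KS check of the marginal families (t_b <= t_i barely truncates n_f)
  ks <- suppressWarnings(stats::ks.test(d$n_f, "punif", 1, 500))
  expect_gt(ks$p.value, 1e-4)
  lu <- log(draw_priors(prior_spec(t_b = list(max = 0)), 5000, seed = 62)$n_n1)
  ks2 <- suppressWarnings(stats::ks.test(lu, "punif", log(1e2), log(1e8)))
  expect_gt(ks2$p.value, 1e-4)
  expect_error(prior_spec(n_f = list(min = 10, max = 1)), "empty")
})

test_that("reference tables are reproducible, sized, and prior-responsive", {
  prior <- prior_spec()
  spec <- sample_spec(c(N1 = 6, N2 = 4, INT = 4), n_loci = 40)
  r1 <- build_reference_table(prior, spec, n_sims = 10, seed = 63)
  r2 <- build_reference_table(prior, spec, n_sims = 10, seed = 63)
  expect_equal(nrow(r1$stats), 10L)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$stats, r2$stats)
  # a larger founder size shifts introduced-population diversity upward
  small_nf <- prior_spec(n_f = list(min = 1, max = 5))
  large_nf <- prior_spec(n_f = list(min = 400, max = 500))
  rs <- build_reference_table(small_nf, spec, n_sims = 150, seed = 64)
  rl <- build_reference_table(large_nf, spec, n_sims = 150, seed = 64)
  expect_lt(mean(rs$stats[, "INT_mean_gene_div_all"]),
            mean(rl$stats[, "INT_mean_gene_div_all"]))
})

test_that("rejection retains exactly the closest simulations (brute-force sort)", {
  set.seed(65)
  n <- 1000
  params <- tibble::tibble(a = runif(n), b = runif(n))
  stats_m <- matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("s", 1:4)))
  ref <- structure(list(params = params, stats = stats_m, seed = 0),
                   class = "reference_table")
  obs <- stats::setNames(rnorm(4), paste0("s", 1:4))
  rej <- abc_reject(ref, obs, tolerance = 0.01)
  expect_equal(nrow(rej$params), 10L)
  sc <- apply(stats_m, 2, mad)
  d_brute <- sqrt(colSums((t(stats_m) / sc - obs / sc)^2))
  expect_equal(sort(rej$distance), sort(d_brute)[1:10])
  expect_equal(rej$params, params[order(d_brute)[1:10], ])
  # a row equal to the observation is retained at distance 0
  stats_m[500, ] <- obs
  ref$stats <- stats_m
  rej2 <- abc_reject(ref, obs, tolerance = 0.005)
  expect_equal(min(rej2$distance), 0)
  expect_true(500 %in% match(
    apply(rej2$stats, 1, paste, collapse = ","),
    apply(stats_m, 1, paste, collapse = ",")))
})

test_that("constant statistic columns are excluded with a warning", {
  set.seed(66)
  stats_m <- cbind(matrix(rnorm(300), 100, 3), 1)
  colnames(stats_m) <- paste0("s", 1:4)
  ref <- structure(list(params = tibble::tibble(a = runif(100)),
                        stats = stats_m, seed = 0),
                   class = "reference_table")
  obs <- c(s1 = 0, s2 = 0, s3 = 0, s4 = 1)
  expect_warning(rej <- abc_reject(ref, obs, 0.1), "constant")
  expect_equal(sum(rej$usable), 3L)
})

test_that("shrinking the tolerance never increases the mean retained distance", {
  set.seed(67)
  stats_m <- matrix(rnorm(2000 * 3), 2000, 3,
                    dimnames = list(NULL, paste0("s", 1:3)))
  ref <- structure(list(params = tibble::tibble(a = rnorm(2000)),
                        stats = stats_m, seed = 0),
                   class = "reference_table")
  obs <- c(s1 = 0.5, s2 = -0.5, s3 = 0)
  tols <- c(0.2, 0.1, 0.05, 0.01)
  means <- vapply(tols, function(tl) mean(abc_reject(ref, obs, tl)$distance),
                  numeric(1))
  expect_true(all(diff(means) <= 1e-12))
})

test_that("regression adjustment recovers an exact linear relationship", {
  set.seed(68)
  n <- 200
  s1 <- rnorm(n)
  stats_m <- cbind(s1 = s1, s2 = rnorm(n))
  params <- tibble::tibble(a = 3 + 2 * s1)   # exact linear, no noise
  ref <- structure(list(params = params, stats = stats_m, seed = 0),
                   class = "reference_table")
  obs <- c(s1 = 0.25, s2 = 0)
  rej <- abc_reject(ref, obs, tolerance = 0.5)
  post <- abc_adjust(rej)
  expect_equal(post$particles$a, rep(3 + 2 * 0.25, nrow(post$particles)),
               tolerance = 1e-10)
  # identical statistics leave parameters unadjusted
  ref2 <- ref
  ref2$stats <- matrix(1, n, 2, dimnames = list(NULL, c("s1", "s2")))
  expect_warning(rej2 <- abc_reject(ref2, c(s1 = 1, s2 = 1), 0.5), "constant")
  post2 <- suppressWarnings(abc_adjust(rej2))
  expect_equal(post2$particles$a, rej2$params$a)
})

test_that("adjustment equals an independent weighted-least-squares oracle", {
  set.seed(69)
  n <- 300
  stats_m <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("s", 1:3)))
  params <- tibble::tibble(a = 1 + stats_m %*% c(0.5, -1, 0.2) + rnorm(n, 0, 0.1))
  params$a <- as.numeric(params$a)
  ref <- structure(list(params = params, stats = stats_m, seed = 0),
                   class = "reference_table")
  obs <- c(s1 = 0.2, s2 = -0.1, s3 = 0.3)
  rej <- abc_reject(ref, obs, tolerance = 0.3)
  post <- abc_adjust(rej)
  # normal-equations oracle
  sc <- apply(stats_m, 2, mad)
  X <- cbind(1, sweep(sweep(rej$stats, 2, sc, "/"), 2, obs / sc, "-"))
  W <- diag(pmax(1 - (rej$distance / (max(rej$distance) * (1 + 1e-12)))^2, 1e-12))
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% rej$params$a)
  oracle <- beta[1] + (rej$params$a - X %*% beta)
  expect_equal(post$particles$a, as.numeric(oracle), tolerance = 1e-8)
})

test_that("posterior summaries: degenerate particles and Gaussian quantiles", {
  post <- structure(list(particles = tibble::tibble(a = rep(2.5, 10)),
                         weights = rep(1, 10)), class = "abc_posterior")
  s <- posterior_summarize(post)
  expect_equal(s$map, 2.5)
  expect_equal(s$q97.5 - s$q2.5, 0)
  set.seed(70)
  x <- rnorm(20000, mean = 3, sd = 2)
  post2 <- structure(list(particles = tibble::tibble(a = x),
                          weights = rep(1, 20000)), class = "abc_posterior")
  s2 <- posterior_summarize(post2)
  expect_equal(s2$q2.5, 3 + 2 * qnorm(0.025), tolerance = 0.05)
  expect_equal(s2$q97.5, 3 + 2 * qnorm(0.975), tolerance = 0.05)
  expect_equal(s2$map, 3, tolerance = 0.15)
})

test_that("weighted quantiles equal brute-force expansion of integer weights", {
  set.seed(71)
  x <- rnorm(50)
  w <- sample(1:5, 50, replace = TRUE)
  expanded <- rep(x, w)
  for (p in c(0.025, 0.5, 0.975)) {
    expect_equal(weighted_quantile(x, w, p),
                 sort(expanded)[ceiling(p * length(expanded))])
  }
})

test_that("PCA goodness of fit scores center and outlier correctly", {
  set.seed(72)
  stats_m <- matrix(rnorm(500 * 6), 500, 6,
                    dimnames = list(NULL, paste0("s", 1:6)))
  center <- colMeans(stats_m)
  gof_center <- abc_gof_pca(stats_m, center, fraction = 0.5, seed = 1)
  expect_lt(gof_center$percentile, 10)
  outlier <- center + 10 * apply(stats_m, 2, sd)
  gof_out <- abc_gof_pca(stats_m, outlier, fraction = 0.5, seed = 1)
  expect_gt(gof_out$percentile, 99)
  # projection agrees with an independent eigen-decomposition
  sub <- withr::with_seed(1, stats_m[sample.int(500, 250), ])
  z <- scale(sub)
  ev <- eigen(cov(z), symmetric = TRUE)
  pc_var <- stats::prcomp(sub, center = TRUE, scale. = TRUE)$sdev^2
  expect_equal(pc_var, ev$values, tolerance = 1e-10)
})

test_that("unidentifiable parameters show high prior-posterior overlap", {
  # t_i barely affects these statistics; its posterior should look like the
  # prior while the informative founder size separates from its prior more
  prior <- prior_spec()
  spec <- sample_spec(c(N1 = 8, N2 = 6, INT = 6), n_loci = 60)
  ref <- build_reference_table(prior, spec, n_sims = 3000, seed = 73)
  truth <- invicta_scenario_params(1e6, 1e4, 10, 1e5, 5e4, 100, 30)
  g <- simulate_invicta_scenario(truth, spec, seed = 74)
  obs <- observed_summary(g, "N1", "N2", "INT")
  rej <- abc_reject(ref, obs, tolerance = 0.05)
  post <- suppressWarnings(abc_adjust(rej, prior))
  ov_ti <- prior_posterior_overlap(post, prior, "t_i")
  expect_gt(ov_ti, 0.6)
})
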