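#' JC69 transition probability
#'
#' Probability of observing base `to` given base `from` after a branch of
#' length `t` expected substitutions per site:
#' `1/4 + 3/4 exp(-4t/3)` when `from == to`, `1/4 - 1/4 exp(-4t/3)`
#' otherwise.
#'
#' @param from,to Bases (A/C/G/T), recycled.
#' @param t Branch length (>= 0), recycled.
#' @return Transition probability.
#' @export
jc69_transition <- function(from, to, t) {
  if (any(t < 0)) stop("branch length must be >= 0", call. = FALSE)
  ifelse(from == to, 0.25 + 0.75 * exp(-4 * t / 3),
         0.25 - 0.25 * exp(-4 * t / 3))
}

jc69_p_same <- function(t) 0.25 + 0.75 * exp(-4 * t / 3)

# Site-pattern counts of one triplet in observed order:
# (all same, a==b!=out, a==out!=b, b==out!=a, all different).
# Sites containing N in any sequence are skipped.
triplet_pattern_counts <- function(seq_a, seq_b, seq_out) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  o <- strsplit(seq_out, "")[[1]]
  keep <- a != "N" & b != "N" & o != "N"
  a <- a[keep]; b <- b[keep]; o <- o[keep]
  ab <- a == b; ao <- a == o; bo <- b == o
  c(sum(ab & ao), sum(ab & !ao), sum(ao & !ab), sum(bo & !ab & !ao),
    sum(!ab & !ao & !bo))
}

pattern_count_matrix <- function(triplets) {
  t(mapply(triplet_pattern_counts, triplets$seq_a, triplets$seq_b,
           triplets$seq_out, USE.NAMES = FALSE))
}

# Probability of one *specific* site pattern for the rooted triplet gene
# tree in which two "paired" tips join at t1 and the far tip joins at the
# root t2 (>= t1). Canonical class order:
# (all same, pair same != far, tip1 == far, tip2 == far, all different).
# Vectorized over (t1, t2); plain sum over the two internal 4-state nodes.
canonical_class_probs <- function(t1, t2) {
  s1 <- jc69_p_same(t1);      d1 <- (1 - s1) / 3
  s12 <- jc69_p_same(t2 - t1); d12 <- (1 - s12) / 3
  s2 <- jc69_p_same(t2);      d2 <- (1 - s2) / 3
  reps <- list(c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(2, 1, 1), c(1, 2, 3))
  out <- matrix(0, length(t1), 5)
  for (k in 1:5) {
    al <- reps[[k]][1]; be <- reps[[k]][2]; ga <- reps[[k]][3]
    acc <- 0
    for (m in 1:4) {
      t1a <- if (m == al) s1 else d1
      t1b <- if (m == be) s1 else d1
      for (r in 1:4) {
        acc <- acc + 0.25 *
          (if (r == m) s12 else d12) * t1a * t1b *
          (if (r == ga) s2 else d2)
      }
    }
    out[, k] <- acc
  }
  out
}

# Column permutation mapping canonical classes to observed
# (all, a==b, a==out, b==out, diff) order, per gene-tree topology.
topology_class_cols <- function(topology) {
  switch(topology,
    ingroup = c(1, 2, 3, 4, 5),
    a_out   = c(1, 3, 2, 4, 5),
    b_out   = c(1, 3, 4, 2, 5),
    stop("unknown topology: ", topology, call. = FALSE)
  )
}

#' Log-likelihood of one triplet alignment given a gene tree
#'
#' JC69 pruning over the 96 sites (sites with `N` skipped), summing over
#' the two internal node states, with a uniform root distribution.
#'
#' @param triplet One-row slice of a [triplet_dataset()]'s `triplets` table
#'   (or any list with `seq_a`, `seq_b`, `seq_out`).
#' @param topology `"ingroup"`, `"a_out"` or `"b_out"`.
#' @param t_inner,t_outer Node times (expected substitutions per site),
#'   `t_inner <= t_outer`.
#' @return Log-probability of the alignment.
#' @export
alignment_likelihood_given_tree <- function(triplet, topology, t_inner, t_outer) {
  if (t_outer < t_inner) stop("need t_inner <= t_outer", call. = FALSE)
  counts <- triplet_pattern_counts(triplet$seq_a, triplet$seq_b, triplet$seq_out)
  probs <- canonical_class_probs(t_inner, t_outer)[1, topology_class_cols(topology)]
  seen <- counts > 0
  sum(counts[seen] * log(probs[seen]))
}

# Pre-divergence machinery: density of the first (ingroup) coalescence time
# on (0, tau_ir) and the survival probability, for one pair configuration.
# Null model: closed-form exponential. IM model: 3-state CTMC over lineage
# locations {both-in-invicta, both-in-richteri, split}, solved by eigen
# decomposition (pracma::expm fallback for defective cases).
pre_divergence_model <- function(params, pair_config) {
  p <- params
  if (p$mig_ab == 0 && p$mig_ba == 0) {
    if (pair_config == "RI") {
      return(list(density = function(t) rep(0, length(t)),
                  survival = function(t) rep(1, length(t)),
                  exit_rate = 0))
    }
    th <- if (pair_config == "II") p$theta_inv else p$theta_rich
    lam <- 2 / th
    return(list(density = function(t) lam * exp(-lam * t),
                survival = function(t) exp(-lam * t),
                exit_rate = lam))
  }
  mA <- 4 * p$mig_ab / p$theta_inv
  mB <- 4 * p$mig_ba / p$theta_rich
  cA <- 2 / p$theta_inv
  cB <- 2 / p$theta_rich
  # states: 1 both-in-A (invicta), 2 both-in-B, 3 split
  Q <- matrix(c(
    -(2 * mA + cA), 0,              2 * mA,
    0,              -(2 * mB + cB), 2 * mB,
    mB,             mA,             -(mA + mB)
  ), nrow = 3, byrow = TRUE)
  init <- switch(pair_config, II = 1L, RR = 2L, RI = 3L)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg) && abs(det(eg$vectors)) > 1e-12) {
    V <- eg$vectors
    coef <- (diag(3)[init, , drop = FALSE] %*% V)[1, ]
    Vinv <- solve(V)
    state_probs <- function(t) {
      E <- exp(outer(t, eg$values))       # length(t) x 3
      Re(sweep(E, 2, coef, "*") %*% Vinv) # length(t) x 3 state occupancy
    }
  } else {
    state_probs <- function(t) {
      t(vapply(t, function(tt)
        (diag(3)[init, , drop = FALSE] %*% pracma::expm(Q * tt))[1, ],
        numeric(3)))
    }
  }
  exit0 <- -Q[init, init]
  list(
    density = function(t) {
      P <- state_probs(t)
      P[, 1] * cA + P[, 2] * cB
    },
    survival = function(t) rowSums(pmax(state_probs(t), 0)),
    exit_rate = exit0
  )
}

#' Gene-tree density under the complete-isolation null model
#'
#' Multispecies-coalescent density of (topology, first coalescence time,
#' root coalescence time) for one pair configuration with no migration:
#' same-species pairs may coalesce before `tau_ir` at rate `2/theta`,
#' surviving pairs coalesce in the ancestral population on
#' `(tau_ir, tau_root)` at rate `2/theta_anc`, and any lineages remaining
#' at `tau_root` coalesce in the root population (three equally likely
#' pairings for the first of the two root coalescences). Integrates to 1
#' over topologies and times.
#'
#' @param params An [im_params()] (migration rates ignored, treated as 0).
#' @param pair_config `"II"`, `"RR"` or `"RI"`.
#' @return `function(topology, t_inner, t_outer)` returning the joint
#'   density (vectorized over times).
#' @export
gene_tree_density_null <- function(params, pair_config = c("II", "RR", "RI")) {
  pair_config <- match.arg(pair_config)
  p <- params
  p$mig_ab <- 0; p$mig_ba <- 0
  gene_tree_density_im(p, pair_config)
}

#' Gene-tree density under the isolation-with-migration model
#'
#' As [gene_tree_density_null()], but before `tau_ir` the two ingroup
#' lineages follow a continuous-time Markov chain over location
#' configurations (both-in-invicta / both-in-richteri / split) with
#' migration transitions, coalescing at rate `2/theta` of the deme where
#' they are co-located. Reduces to the null density as the migration rates
#' go to 0.
#'
#' @param params An [im_params()].
#' @param pair_config `"II"`, `"RR"` or `"RI"`.
#' @return `function(topology, t_inner, t_outer)` returning the joint
#'   density (vectorized over times).
#' @export
gene_tree_density_im <- function(params, pair_config = c("II", "RR", "RI")) {
  pair_config <- match.arg(pair_config)
  p <- params
  pre <- pre_divergence_model(p, pair_config)
  lam_anc <- 2 / p$theta_anc
  lam_root <- 2 / p$theta_root
  s_pre <- pre$survival(p$tau_ir)
  s_anc <- exp(-lam_anc * (p$tau_root - p$tau_ir))
  function(topology, t_inner, t_outer) {
    n <- max(length(t_inner), length(t_outer))
    t1 <- rep_len(t_inner, n)
    t2 <- rep_len(t_outer, n)
    out <- numeric(n)
    bad <- t2 < t1 | t1 < 0
    root2 <- lam_root * exp(-lam_root * pmax(t2 - p$tau_root, 0))
    if (topology == "ingroup") {
      seg_a <- t1 < p$tau_ir
      out[seg_a] <- pre$density(t1[seg_a]) * root2[seg_a]
      seg_b <- t1 >= p$tau_ir & t1 < p$tau_root
      out[seg_b] <- s_pre * lam_anc * exp(-lam_anc * (t1[seg_b] - p$tau_ir)) *
        root2[seg_b]
      out[t2 < p$tau_root] <- 0
    }
    seg_c <- t1 >= p$tau_root
    out[seg_c] <- s_pre * s_anc *
      (6 / p$theta_root) * exp(-6 * (t1[seg_c] - p$tau_root) / p$theta_root) *
      (1 / 3) *
      lam_root * exp(-lam_root * (t2[seg_c] - t1[seg_c]))
    out[bad] <- 0
    out
  }
}

# K-point-per-panel Gauss-Legendre rule for an exponential-decay dimension:
# integrates density rate*exp(-rate*(t-a)) times a smooth factor over
# (a, a+cut/rate), split into a near panel (a, a+split/rate) and a far
# panel beyond it. Two geometric panels keep the rule accurate no matter
# how much additional exponential decay the alignment-likelihood factor
# contributes (its decay rate varies with the site-pattern counts, so no
# single change of variables suits every locus). The truncated mass is
# e^-cut (~1e-11 of the integral). `hi` optionally caps the domain at an
# epoch boundary. Weights include the density factor.
gl_exp_panels <- function(K, a, rate, hi = Inf, cut = 25, split = 6) {
  b1 <- min(a + split / rate, hi)
  b2 <- min(a + cut / rate, hi)
  g1 <- gauss_legendre(K, a, b1)
  nodes <- g1$nodes
  weights <- g1$weights * rate * exp(-rate * (g1$nodes - a))
  if (b2 > b1 * (1 + 1e-12)) {
    g2 <- gauss_legendre(K, b1, b2)
    nodes <- c(nodes, g2$nodes)
    weights <- c(weights, g2$weights * rate * exp(-rate * (g2$nodes - a)))
  }
  list(nodes = nodes, weights = weights)
}

# Quadrature grid for one pair configuration: nodes (t1, t2, topology) and
# weights such that sum_i w_i * h(t1_i, t2_i, topo_i) approximates the
# integral of the gene-tree density times h. Each coalescence-time
# dimension uses K-point Gauss-Legendre per panel directly in time
# (gl_exp_panels); the integrand (density x alignment likelihood) is
# entire in the node times, so the rule converges superexponentially and
# uniformly over loci. With h = 1 the weights sum to 1 up to the
# truncation of the exponential tails.
im_quad_grid <- function(params, pair_config, K) {
  p <- params
  pre <- pre_divergence_model(p, pair_config)
  lam_anc <- 2 / p$theta_anc
  lam_root <- 2 / p$theta_root
  s_pre <- pre$survival(p$tau_ir)
  s_anc <- exp(-lam_anc * (p$tau_root - p$tau_ir))

  # shared t2 nodes on (tau_root, ...) for the two-lineage root phase
  g2 <- gl_exp_panels(K, p$tau_root, lam_root)
  t2_tail <- g2$nodes
  w2_tail <- g2$weights

  t1 <- t2 <- w <- numeric(0)
  topo <- character(0)
  add_segment <- function(t1_seg, w1_seg, t2_seg, w2_seg, topology) {
    t1 <<- c(t1, rep(t1_seg, each = length(t2_seg)))
    t2 <<- c(t2, rep(t2_seg, times = length(t1_seg)))
    w <<- c(w, as.vector(t(outer(w1_seg, w2_seg))))
    topo <<- c(topo, rep(topology, length(t1_seg) * length(t2_seg)))
  }

  # segment A: coalescence before tau_ir (CTMC or single-exponential
  # density; finite interval, two equal panels for uniformity)
  if (pre$exit_rate > 0) {
    gA1 <- gauss_legendre(K, 0, p$tau_ir / 2)
    gA2 <- gauss_legendre(K, p$tau_ir / 2, p$tau_ir)
    t1A <- c(gA1$nodes, gA2$nodes)
    w1A <- c(gA1$weights, gA2$weights) * pre$density(t1A)
    add_segment(t1A, w1A, t2_tail, w2_tail, "ingroup")
  }
  # segment B: coalescence in the ancestral population
  if (s_pre > 0) {
    gB <- gl_exp_panels(K, p$tau_ir, lam_anc, hi = p$tau_root)
    add_segment(gB$nodes, s_pre * gB$weights, t2_tail, w2_tail, "ingroup")
  }
  # segment C: three lineages reach the root population; t2 = t1 + s
  s3 <- s_pre * s_anc
  if (s3 > 0) {
    gC1 <- gl_exp_panels(K, p$tau_root, 6 / p$theta_root)
    gCs <- gl_exp_panels(K, 0, lam_root)
    n1 <- length(gC1$nodes); ns <- length(gCs$nodes)
    for (tp in c("ingroup", "a_out", "b_out")) {
      t1_rep <- rep(gC1$nodes, each = ns)
      t2_rep <- t1_rep + rep(gCs$nodes, times = n1)
      w_rep <- (s3 / 3) * as.vector(t(outer(gC1$weights, gCs$weights)))
      t1 <- c(t1, t1_rep); t2 <- c(t2, t2_rep); w <- c(w, w_rep)
      topo <- c(topo, rep(tp, n1 * ns))
    }
  }
  list(t1 = t1, t2 = t2, topology = topo, w = w)
}

#' Configuration for the isolation/IM maximum-likelihood fit
#'
#' @param quadrature_points Gauss-Legendre points per integration dimension
#'   (default 16, the setting used throughout the analysis).
#' @param n_starts Random multi-starts for the optimizer.
#' @param seed Seed for start-point jitter.
#' @param maxit Iteration cap per optimizer run.
#' @param reltol Convergence tolerance passed to [stats::optim()].
#' @return A list of class `im_fit_config`.
#' @export
im_fit_config <- function(quadrature_points = 16, n_starts = 3, seed = 1,
                          maxit = 800, reltol = 1e-8) {
  stopifnot(quadrature_points >= 2, n_starts >= 1)
  structure(list(quadrature_points = quadrature_points, n_starts = n_starts,
                 seed = seed, maxit = maxit, reltol = reltol),
            class = "im_fit_config")
}

#' Total log-likelihood of a triplet dataset
#'
#' Sum over loci of the log marginal probability of each alignment:
#' the gene-tree density (null or IM) integrated against the JC69
#' alignment likelihood, with both coalescence-time dimensions integrated
#' by K-point Gauss-Legendre quadrature on an exponential change of
#' variables anchored at the relevant epoch boundary, and the three root
#' topologies summed.
#'
#' @param dataset A [triplet_dataset()] (or its `triplets` tibble).
#' @param params An [im_params()].
#' @param model `"null"` (migration forced to 0) or `"im"`.
#' @param config An [im_fit_config()].
#' @param per_locus Return the per-locus log-likelihood vector instead of
#'   the sum.
#' @return Total log-likelihood (or per-locus vector).
#' @export
total_loglik <- function(dataset, params, model = c("null", "im"),
                         config = im_fit_config(), per_locus = FALSE) {
  model <- match.arg(model)
  trip <- if (inherits(dataset, "triplet_dataset")) dataset$triplets else dataset
  if (nrow(trip) == 0) stop("empty triplet dataset", call. = FALSE)
  p <- params
  if (model == "null") { p$mig_ab <- 0; p$mig_ba <- 0 }
  pc <- precompute_pattern_counts(trip)
  ll <- loglik_by_locus(pc, p, config)
  if (per_locus) ll else sum(ll)
}

# Pattern-count preprocessing shared by total_loglik and fit_im_model:
# per pair configuration, the unique site-pattern count rows, the mapping
# of each locus to its unique row, and the locus ids (for error messages).
precompute_pattern_counts <- function(trip) {
  counts <- pattern_count_matrix(trip)
  lapply(split(seq_len(nrow(trip)), trip$pair_config), function(idx) {
    cm <- counts[idx, , drop = FALSE]
    key <- apply(cm, 1, paste, collapse = ",")
    first <- !duplicated(key)
    list(idx = idx, unique = cm[first, , drop = FALSE],
         map = match(key, key[first]), locus_id = trip$locus_id[idx])
  })
}

loglik_by_locus <- function(pc, p, config) {
  ll <- numeric(sum(vapply(pc, function(x) length(x$idx), integer(1))))
  for (cfg in names(pc)) {
    grid <- im_quad_grid(p, cfg, config$quadrature_points)
    probs <- canonical_class_probs(grid$t1, grid$t2)
    logp_obs <- matrix(0, length(grid$t1), 5)
    for (tp in unique(grid$topology)) {
      sel <- grid$topology == tp
      logp_obs[sel, ] <- log(probs[sel, topology_class_cols(tp), drop = FALSE])
    }
    part <- pc[[cfg]]
    lik_u <- exp(part$unique %*% t(logp_obs)) %*% grid$w
    lik <- lik_u[part$map]
    if (any(!is.finite(lik)) || any(lik <= 0)) {
      bad <- part$locus_id[which(!is.finite(lik) | lik <= 0)[1]]
      stop("non-finite likelihood at locus ", bad, call. = FALSE)
    }
    ll[part$idx] <- log(lik)
  }
  ll
}

#' Monte-Carlo oracle for the per-locus likelihood
#'
#' Estimates the marginal log-probability of one triplet alignment by
#' simulating gene trees from the model density
#' ([simulate_triplet_genealogy()]) and averaging the JC69 alignment
#' likelihood over them; an independent integration route used to validate
#' the quadrature in [total_loglik()].
#'
#' @param triplet One row of a triplet table.
#' @param params An [im_params()].
#' @param n_sims Number of simulated gene trees.
#' @return List with `loglik` (log of the Monte-Carlo mean) and `se`
#'   (standard error of `loglik`, delta method).
#' @export
mc_locus_loglik <- function(triplet, params, n_sims = 2000) {
  counts <- triplet_pattern_counts(triplet$seq_a, triplet$seq_b, triplet$seq_out)
  liks <- vapply(seq_len(n_sims), function(i) {
    tr <- simulate_triplet_genealogy(params, triplet$pair_config)
    probs <- canonical_class_probs(tr$t_inner, tr$t_outer)[
      1, topology_class_cols(tr$topology)]
    exp(sum(counts * log(probs)))
  }, numeric(1))
  m <- mean(liks)
  list(loglik = log(m), se = stats::sd(liks) / (m * sqrt(n_sims)))
}
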