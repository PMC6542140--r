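#' Parameters of the three-species isolation(-with-migration) model
#'
#' Two ingroup species -- S. invicta (a) and S. richteri (b) -- diverged
#' `tau_ir` expected substitutions per site ago; the outgroup lineage
#' (S. fugax) split from their common ancestor `tau_root` ago. Scaled
#' diversities `theta_*` (per site) set the coalescence rate `2/theta`
#' within each (ancestral) population. Migration between the two ingroup
#' species, active on `(0, tau_ir)`, is parameterized as expected migrant
#' individuals per generation in each direction: a lineage currently in
#' invicta traces back to richteri at rate `4 * mig_ab / theta_inv` per unit
#' of mutational time, and symmetrically. `mig_ab = mig_ba = 0` is the
#' complete-isolation null model.
#'
#' @param tau_ir,tau_root Divergence times, `0 < tau_ir < tau_root`.
#' @param theta_inv,theta_rich,theta_anc,theta_root Scaled diversities (> 0)
#'   of S. invicta, S. richteri, their common ancestor, and the root
#'   population ancestral to all three species.
#' @param mig_ab,mig_ba Migration rates (>= 0), migrants per generation.
#' @return A list of class `im_params`.
#' @export
im_params <- function(tau_ir, tau_root, theta_inv, theta_rich,
                      theta_anc, theta_root, mig_ab = 0, mig_ba = 0) {
  if (!(tau_ir > 0 && tau_root > tau_ir))
    stop("need 0 < tau_ir < tau_root", call. = FALSE)
  th <- c(theta_inv, theta_rich, theta_anc, theta_root)
  if (any(th <= 0)) stop("all theta parameters must be > 0", call. = FALSE)
  if (mig_ab < 0 || mig_ba < 0) stop("migration rates must be >= 0", call. = FALSE)
  structure(list(tau_ir = tau_ir, tau_root = tau_root,
                 theta_inv = theta_inv, theta_rich = theta_rich,
                 theta_anc = theta_anc, theta_root = theta_root,
                 mig_ab = mig_ab, mig_ba = mig_ba),
            class = "im_params")
}

# Table-1-like default parameter point used by fixtures.
default_im_params <- function(mig_ab = 0, mig_ba = 0) {
  im_params(tau_ir = 0.000646, tau_root = 0.008369,
            theta_inv = 0.004062, theta_rich = 0.003596,
            theta_anc = 0.002293, theta_root = 0.026874,
            mig_ab = mig_ab, mig_ba = mig_ba)
}

#' Simulate one triplet gene tree under the (isolation-with-)migration model
#'
#' Draws a gene-tree topology and the two coalescence times from the exact
#' model: before `tau_ir` the two ingroup lineages migrate between the two
#' species and may coalesce when co-located; on `(tau_ir, tau_root)` a
#' surviving pair coalesces at rate `2/theta_anc`; after `tau_root` all
#' remaining lineages (including the outgroup's) coalesce at rate
#' `2/theta_root` per pair, with a uniformly chosen pair first. Used both
#' for data generation and as the Monte-Carlo oracle for the quadrature
#' likelihood.
#'
#' @param params An [im_params()].
#' @param pair_config `"II"`, `"RR"` or `"RI"`.
#' @return List with `topology` (`"ingroup"`, `"a_out"` or `"b_out"`),
#'   `t_inner` (first coalescence) and `t_outer` (root coalescence), times
#'   in expected substitutions per site. Uses the R RNG stream.
#' @export
simulate_triplet_genealogy <- function(params, pair_config = c("II", "RR", "RI")) {
  pair_config <- match.arg(pair_config)
  p <- params
  loc <- switch(pair_config, II = c("A", "A"), RR = c("B", "B"), RI = c("A", "B"))
  mA <- if (p$theta_inv > 0) 4 * p$mig_ab / p$theta_inv else 0
  mB <- if (p$theta_rich > 0) 4 * p$mig_ba / p$theta_rich else 0
  t <- 0
  t1 <- NA_real_
  repeat {
    same <- loc[1] == loc[2]
    coal_rate <- if (same) 2 / (if (loc[1] == "A") p$theta_inv else p$theta_rich) else 0
    mig_rates <- ifelse(loc == "A", mA, mB)
    total <- coal_rate + sum(mig_rates)
    if (total <= 0) { t <- p$tau_ir; break }
    dt <- stats::rexp(1, total)
    if (t + dt >= p$tau_ir) { t <- p$tau_ir; break }
    t <- t + dt
    u <- stats::runif(1) * total
    if (u < coal_rate) { t1 <- t; break }
    u <- u - coal_rate
    k <- if (u < mig_rates[1]) 1 else 2
    loc[k] <- if (loc[k] == "A") "B" else "A"
  }
  if (!is.na(t1)) {                        # coalesced within a species
    t2 <- p$tau_root + stats::rexp(1, 2 / p$theta_root)
    return(list(topology = "ingroup", t_inner = t1, t_outer = t2))
  }
  t1_anc <- p$tau_ir + stats::rexp(1, 2 / p$theta_anc)
  if (t1_anc < p$tau_root) {               # coalesced in the ancestor
    t2 <- p$tau_root + stats::rexp(1, 2 / p$theta_root)
    return(list(topology = "ingroup", t_inner = t1_anc, t_outer = t2))
  }
  # three lineages reach the root population
  t1 <- p$tau_root + stats::rexp(1, 6 / p$theta_root)
  t2 <- t1 + stats::rexp(1, 2 / p$theta_root)
  topology <- sample(c("ingroup", "a_out", "b_out"), 1)
  list(topology = topology, t_inner = t1, t_outer = t2)
}

# Evolve a JC69 sequence along one branch (vectorized over sites).
jc69_evolve <- function(bases, t) {
  n <- length(bases)
  p_same <- 0.25 + 0.75 * exp(-4 * t / 3)
  change <- stats::runif(n) > p_same
  if (any(change)) {
    nucs <- c("A", "C", "G", "T")
    cur <- bases[change]
    pick <- vapply(cur, function(b) sample(setdiff(nucs, b), 1), character(1))
    bases[change] <- pick
  }
  bases
}

# Simulate the three aligned sequences for one gene tree.
triplet_sequences_from_tree <- function(tree, n_sites) {
  nucs <- c("A", "C", "G", "T")
  root <- sample(nucs, n_sites, replace = TRUE)
  inner <- jc69_evolve(root, tree$t_outer - tree$t_inner)
  if (tree$topology == "ingroup") {
    a <- jc69_evolve(inner, tree$t_inner)
    b <- jc69_evolve(inner, tree$t_inner)
    out <- jc69_evolve(root, tree$t_outer)
  } else if (tree$topology == "a_out") {
    a <- jc69_evolve(inner, tree$t_inner)
    out <- jc69_evolve(inner, tree$t_inner)
    b <- jc69_evolve(root, tree$t_outer)
  } else {
    b <- jc69_evolve(inner, tree$t_inner)
    out <- jc69_evolve(inner, tree$t_inner)
    a <- jc69_evolve(root, tree$t_outer)
  }
  list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
       seq_out = paste(out, collapse = ""))
}

#' Simulate a dataset of triplet alignments
#'
#' Per locus: draws a pair configuration from `config_mix`, simulates a gene
#' tree with [simulate_triplet_genealogy()] and evolves 96-bp (by default)
#' sequences under JC69 with branch lengths in expected substitutions per
#' site. Deterministic under `seed`.
#'
#' @param params An [im_params()].
#' @param n_loci Number of independent triplets.
#' @param locus_length Alignment length in bp.
#' @param config_mix Named proportions for `II`, `RR`, `RI`; must sum to 1.
#' @param seed Integer seed.
#' @return A [triplet_dataset()].
#' @export
simulate_triplets <- function(params, n_loci, locus_length = 96,
                              config_mix = c(II = 1/3, RR = 1/3, RI = 1/3),
                              seed = 1) {
  stopifnot(abs(sum(config_mix) - 1) < 1e-8)
  if (n_loci == 0) {
    return(triplet_dataset(tibble::tibble(
      locus_id = character(), pair_config = character(),
      seq_a = character(), seq_b = character(), seq_out = character()
    )))
  }
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    cfgs <- sample(names(config_mix), n_loci, replace = TRUE, prob = config_mix)
    rows <- lapply(seq_len(n_loci), function(i) {
      tree <- simulate_triplet_genealogy(params, cfgs[i])
      sq <- triplet_sequences_from_tree(tree, locus_length)
      tibble::tibble(locus_id = sprintf("t%05d", i), pair_config = cfgs[i],
                     seq_a = sq$seq_a, seq_b = sq$seq_b, seq_out = sq$seq_out)
    })
    triplet_dataset(dplyr::bind_rows(rows))
  })
}
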