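#' Prior specification for the four-population scenario
#'
#' Per-parameter prior families with the study's documented ranges:
#' introduction time `t_i` uniform on 0-180 generations, founder size
#' `n_f` uniform on 1-500 individuals, bottleneck duration `t_b` uniform
#' on 0-40 generations; the weakly informed sizes (`n_n1`, `n_n2`, `n_i`)
#' and the native divergence time `t_d` are log-uniform over ranges
#' spanning several orders of magnitude. Truncated-normal entries are also
#' supported (`family = "tnorm"` with `mean`/`sd`). Draws violating the
#' time ordering `t_b <= t_i <= t_d` are rejected and resampled.
#'
#' @param ... Named overrides; each entry is a list with `family`
#'   (`"uniform"`, `"loguniform"` or `"tnorm"`), `min`, `max` and, for
#'   `tnorm`, `mean` and `sd`.
#' @return A named list of class `prior_spec`.
#' @export
prior_spec <- function(...) {
  defaults <- list(
    n_n1 = list(family = "loguniform", min = 1e2, max = 1e8),
    n_n2 = list(family = "loguniform", min = 1e2, max = 1e8),
    n_f  = list(family = "uniform",    min = 1,   max = 500),
    n_i  = list(family = "loguniform", min = 1e2, max = 1e8),
    t_d  = list(family = "loguniform", min = 180, max = 1e6),
    t_i  = list(family = "uniform",    min = 0,   max = 180),
    t_b  = list(family = "uniform",    min = 0,   max = 40)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults)) stop("unknown parameter: ", nm, call. = FALSE)
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], overrides[[nm]])
  }
  for (nm in names(defaults)) {
    pr <- defaults[[nm]]
    if (pr$min > pr$max) stop("empty prior support for ", nm, call. = FALSE)
  }
  structure(defaults, class = "prior_spec")
}

draw_one_prior <- function(pr, n) {
  switch(pr$family,
    uniform = stats::runif(n, pr$min, pr$max),
    loguniform = exp(stats::runif(n, log(pr$min), log(pr$max))),
    tnorm = {
      x <- stats::rnorm(2 * n + 20, pr$mean, pr$sd)
      x <- x[x >= pr$min & x <= pr$max]
      while (length(x) < n)
        x <- c(x, stats::rnorm(n, pr$mean, pr$sd))
      x[x >= pr$min & x <= pr$max][seq_len(n)]
    },
    stop("unknown prior family: ", pr$family, call. = FALSE)
  )
}

#' Draw scenario parameters from the prior
#'
#' Independent draws per parameter, with rejection-resampling of rows
#' violating `t_b <= t_i <= t_d`.
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Tibble of `n` rows with columns `n_n1, n_n2, n_f, n_i, t_d,
#'   t_i, t_b`.
#' @export
draw_priors <- function(prior, n, seed = 1) {
  stopifnot(n >= 1)
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    draw_block <- function(m) {
      tibble::as_tibble(lapply(prior, draw_one_prior, n = m))
    }
    out <- draw_block(n)
    ok <- out$t_b <= out$t_i & out$t_i <= out$t_d
    tries <- 0
    while (!all(ok)) {
      m <- sum(!ok)
      out[!ok, ] <- draw_block(m)
      ok <- out$t_b <= out$t_i & out$t_i <= out$t_d
      tries <- tries + 1
      if (tries > 1000)
        stop("prior has (near-)zero mass satisfying t_b <= t_i <= t_d",
             call. = FALSE)
    }
    out
  })
}

#' Build an ABC reference table
#'
#' Each row pairs a prior draw with the 18 summary statistics of one
#' dataset simulated from it under the four-population scenario
#' (compiled simulation path, [simulate_scenario_stats()]). Rows with any
#' non-finite statistic (possible only in degenerate corners, e.g. a
#' locus set with no defined F_ST) are dropped with a warning.
#'
#' @param prior A [prior_spec()].
#' @param spec A [sample_spec()].
#' @param n_sims Number of simulations.
#' @param seed Integer seed (controls both prior draws and simulations).
#' @return A list of class `reference_table`: `params` (tibble), `stats`
#'   (matrix), `spec`, `seed`.
#' @export
build_reference_table <- function(prior, spec, n_sims, seed = 1) {
  stopifnot(n_sims >= 1)
  params <- draw_priors(prior, n_sims, seed = derive_seed(seed, 1))
  stats <- simulate_scenario_stats(params, spec, seed = derive_seed(seed, 2))
  ok <- apply(is.finite(stats), 1, all)
  if (!all(ok)) {
    warning(sum(!ok), " simulation(s) with undefined statistics dropped",
            call. = FALSE)
    params <- params[ok, ]
    stats <- stats[ok, , drop = FALSE]
  }
  structure(list(params = params, stats = stats, spec = spec, seed = seed),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("<reference_table> %d simulations x %d statistics (seed %s)\n",
              nrow(x$stats), ncol(x$stats), format(x$seed)))
  invisible(x)
}

# Align an observed summary vector (tibble stat/value or named numeric)
# with the reference table's statistic columns.
align_observed <- function(observed, stat_names) {
  if (is.data.frame(observed)) {
    v <- stats::setNames(observed$value, observed$stat)
  } else v <- observed
  if (!all(stat_names %in% names(v)))
    stop("observed vector missing statistics: ",
         paste(setdiff(stat_names, names(v)), collapse = ", "), call. = FALSE)
  v[stat_names]
}

#' Rejection step: retain the simulations closest to the observation
#'
#' Euclidean distance on statistics standardized by the reference table's
#' median absolute deviation (constant columns are excluded with a
#' warning); retains exactly `ceiling(tolerance * n_sims)` rows, ties
#' broken by row index.
#'
#' @param reference A [build_reference_table()] result.
#' @param observed Observed summary vector ([observed_summary()] tibble or
#'   named numeric).
#' @param tolerance Retained fraction in `(0, 1]` (study setting: 0.01).
#' @return A list of class `abc_rejection`: retained `params` and `stats`,
#'   `distance`, the standardization used, and the aligned observation.
#' @export
abc_reject <- function(reference, observed, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  obs <- align_observed(observed, colnames(reference$stats))
  scale <- apply(reference$stats, 2, stats::mad)
  usable <- scale > 0
  if (!all(usable))
    warning("constant statistic column(s) excluded from the distance: ",
            paste(colnames(reference$stats)[!usable], collapse = ", "),
            call. = FALSE)
  z <- sweep(reference$stats[, usable, drop = FALSE], 2, scale[usable], "/")
  zo <- obs[usable] / scale[usable]
  d <- sqrt(rowSums(sweep(z, 2, zo, "-")^2))
  n_keep <- ceiling(tolerance * nrow(reference$stats))
  keep <- order(d)[seq_len(n_keep)]   # order() breaks ties by row index
  structure(list(
    params = reference$params[keep, ],
    stats = reference$stats[keep, , drop = FALSE],
    distance = d[keep],
    scale = scale, usable = usable,
    observed = obs,
    tolerance = tolerance,
    n_sims = nrow(reference$stats)
  ), class = "abc_rejection")
}

#' Weighted local-linear regression adjustment of retained particles
#'
#' Beaumont-style post-rejection adjustment: Epanechnikov weights on the
#' rejection distances, a weighted least-squares fit of each parameter on
#' the standardized statistics centered at the observation, and particles
#' shifted to the regression's prediction at the observation plus their
#' residuals. Adjusted values are clamped to the prior support. If the
#' design is singular or there are fewer particles than statistics, the
#' unadjusted particles are returned with a warning.
#'
#' @param rejection An [abc_reject()] result.
#' @param prior The [prior_spec()] used (for support clamping and for
#'   putting multiplicative-scale parameters on the log scale); `NULL`
#'   adjusts every parameter linearly with no clamping.
#' @return A list of class `abc_posterior`: `particles` (adjusted tibble),
#'   `raw` (unadjusted), `weights`.
#' @export
abc_adjust <- function(rejection, prior = NULL) {
  r <- rejection
  n <- nrow(r$params)
  X <- sweep(r$stats[, r$usable, drop = FALSE], 2,
             r$scale[r$usable], "/")
  X <- sweep(X, 2, r$observed[r$usable] / r$scale[r$usable], "-")
  dmax <- max(r$distance) * (1 + 1e-12)
  w <- 1 - (r$distance / dmax)^2           # Epanechnikov kernel
  w <- pmax(w, 1e-12)
  adjusted <- r$params
  if (n < 3 * (ncol(X) + 1)) {
    warning("too few retained particles (", n, ") to regress on ", ncol(X),
            " statistics; returning unadjusted particles", call. = FALSE)
  } else {
    Xd <- cbind(1, X)
    for (par in names(r$params)) {
      pr <- prior[[par]]
      # multiplicative-scale parameters are adjusted on the log scale
      log_scale <- !is.null(pr) && pr$family == "loguniform"
      y <- if (log_scale) log(r$params[[par]]) else r$params[[par]]
      fit <- tryCatch(stats::lm.wfit(Xd, y, w), error = function(e) NULL)
      if (is.null(fit) || any(is.na(fit$coefficients))) {
        warning("singular regression design for ", par,
                "; parameter left unadjusted", call. = FALSE)
        next
      }
      # prediction at the observation is the intercept (X centered there)
      adj <- fit$coefficients[1] + fit$residuals
      if (log_scale) adj <- exp(adj)
      if (!is.null(pr)) adj <- pmin(pmax(adj, pr$min), pr$max)
      adjusted[[par]] <- adj
    }
  }
  structure(list(particles = adjusted, raw = r$params, weights = w,
                 rejection = r), class = "abc_posterior")
}

#' Posterior summaries: MAP and 95% credible intervals
#'
#' Per parameter: the MAP is the mode of a weighted Gaussian kernel density
#' estimate (bandwidth: Silverman's rule via [stats::density()]'s `nrd0`),
#' and the credible interval the weighted 2.5% / 97.5% quantiles.
#'
#' @param posterior An [abc_adjust()] result (or an [abc_reject()] result,
#'   summarized with uniform weights).
#' @return Tibble with columns `parameter`, `map`, `q2.5`, `q97.5`.
#' @export
posterior_summarize <- function(posterior) {
  if (inherits(posterior, "abc_rejection")) {
    posterior <- structure(list(particles = posterior$params,
                                weights = rep(1, nrow(posterior$params))),
                           class = "abc_posterior")
  }
  particles <- posterior$particles
  w <- posterior$weights / sum(posterior$weights)
  if (nrow(particles) < 2) stop("need >= 2 particles", call. = FALSE)
  purrr::map_dfr(names(particles), function(par) {
    x <- particles[[par]]
    if (stats::sd(x) == 0) {
      map <- x[1]
    } else {
      dens <- stats::density(x, weights = w, bw = stats::bw.nrd0(x))
      map <- dens$x[which.max(dens$y)]
    }
    q <- weighted_quantile(x, w, c(0.025, 0.975))
    tibble::tibble(parameter = par, map = map, q2.5 = q[1], q97.5 = q[2])
  })
}

#' @export
tidy.abc_posterior <- function(x, ...) posterior_summarize(x)

#' @export
glance.abc_posterior <- function(x, ...) {
  tibble::tibble(
    n_particles = nrow(x$particles),
    tolerance = x$rejection$tolerance,
    n_sims = x$rejection$n_sims
  )
}

#' PCA goodness-of-fit of the model to the observed statistics
#'
#' Projects a random fraction (10% in the study design) of the simulated
#' statistic vectors together with the observed vector onto principal
#' components, and scores the observation by the percentile of its
#' Mahalanobis distance (in the retained component space) relative to the
#' simulated cloud. A percentile near 100 flags an observation the model
#' cannot reproduce.
#'
#' @param reference A [build_reference_table()] result (or any statistics
#'   matrix).
#' @param observed Observed summary vector.
#' @param fraction Fraction of simulations to project.
#' @param seed Integer seed for the subsample.
#' @return A list of class `abc_gof`: `scores` (tibble of PC coordinates,
#'   observed row flagged), `percentile`, `n_components`.
#' @export
abc_gof_pca <- function(reference, observed, fraction = 0.1, seed = 1) {
  stats_mat <- if (inherits(reference, "reference_table")) reference$stats
    else as.matrix(reference)
  obs <- align_observed(observed, colnames(stats_mat))
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    n <- nrow(stats_mat)
    idx <- sample.int(n, max(3, ceiling(fraction * n)))
    sims <- stats_mat[idx, , drop = FALSE]
    keep <- apply(sims, 2, stats::sd) > 0
    sims <- sims[, keep, drop = FALSE]
    pc <- stats::prcomp(sims, center = TRUE, scale. = TRUE)
    pos <- pc$sdev^2 > 1e-10
    if (!all(pos))
      warning("rank-deficient statistics: using ", sum(pos), " components",
              call. = FALSE)
    k <- sum(pos)
    proj_sims <- pc$x[, seq_len(k), drop = FALSE]
    proj_obs <- stats::predict(pc, t(obs[keep]))[, seq_len(k), drop = FALSE]
    # Mahalanobis distance in PC space = sum((score / sdev)^2)
    d_sims <- rowSums(sweep(proj_sims, 2, pc$sdev[seq_len(k)], "/")^2)
    d_obs <- sum((proj_obs / pc$sdev[seq_len(k)])^2)
    scores <- tibble::as_tibble(rbind(proj_sims, proj_obs))
    scores$observed <- c(rep(FALSE, nrow(proj_sims)), TRUE)
    structure(list(
      scores = scores,
      percentile = 100 * mean(d_sims < d_obs),
      n_components = k
    ), class = "abc_gof")
  })
}

#' Prior-vs-posterior overlap diagnostic
#'
#' Overlap coefficient between the prior density and the weighted posterior
#' density of one parameter (both estimated on a common grid). Values near
#' 1 indicate the data carry little information about the parameter, the
#' behavior reported for the contemporary introduced size and the two
#' deep/recent times in this scenario.
#'
#' @param posterior An `abc_posterior`.
#' @param prior The [prior_spec()].
#' @param parameter Parameter name.
#' @param n_prior Prior reference draws.
#' @param seed Seed for the prior draws.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
prior_posterior_overlap <- function(posterior, prior, parameter,
                                    n_prior = 20000, seed = 1) {
  x <- posterior$particles[[parameter]]
  w <- posterior$weights / sum(posterior$weights)
  pr <- prior[[parameter]]
  prior_draws <- withr::with_seed(as.integer(seed), {
    draw_one_prior(pr, n_prior)
  })
  log_scale <- pr$family == "loguniform"
  tx <- function(v) if (log_scale) log(v) else v
  rng <- range(tx(c(x, prior_draws)))
  grid <- seq(rng[1], rng[2], length.out = 512)
  d_post <- stats::density(tx(x), weights = w, bw = stats::bw.nrd0(tx(x)),
                           from = rng[1], to = rng[2], n = 512)$y
  d_prior <- stats::density(tx(prior_draws), from = rng[1], to = rng[2],
                            n = 512)$y
  dx <- diff(grid)[1]
  sum(pmin(d_post, d_prior)) * dx
}
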