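#' Maximum-likelihood fit of the isolation or IM model to triplet data
#'
#' Maximizes [total_loglik()] over log-transformed parameters
#' (`tau_root` is parameterized as `tau_ir + exp(x)` so the ordering
#' constraint always holds) with Nelder-Mead from `n_starts` jittered
#' moment-based initializations; the best run is reported and every start
#' is recorded.
#'
#' @param dataset A [triplet_dataset()].
#' @param model `"null"` (no migration, 6 free parameters) or `"im"`
#'   (two directional migration rates, 8 free parameters).
#' @param config An [im_fit_config()].
#' @param init Optional [im_params()] used as the first start.
#' @return An object of class `im_fit`: `model`, `params` (MLE as
#'   [im_params()]), `loglik`, `starts` (tibble of all runs),
#'   `convergence`.
#' @export
fit_im_model <- function(dataset, model = c("null", "im"),
                         config = im_fit_config(), init = NULL) {
  model <- match.arg(model)
  trip <- if (inherits(dataset, "triplet_dataset")) dataset$triplets else dataset
  if (nrow(trip) == 0) stop("empty triplet dataset", call. = FALSE)
  n_par <- if (model == "im") 8L else 6L

  to_params <- function(x) {
    tau_ir <- exp(x[1])
    im_params(
      tau_ir = tau_ir, tau_root = tau_ir + exp(x[2]),
      theta_inv = exp(x[3]), theta_rich = exp(x[4]),
      theta_anc = exp(x[5]), theta_root = exp(x[6]),
      mig_ab = if (model == "im") exp(x[7]) else 0,
      mig_ba = if (model == "im") exp(x[8]) else 0
    )
  }
  pc <- precompute_pattern_counts(trip)
  negll <- function(x) {
    p <- tryCatch(to_params(x), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    if (model == "null") { p$mig_ab <- 0; p$mig_ba <- 0 }
    ll <- tryCatch(sum(loglik_by_locus(pc, p, config)),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) 1e12 else -ll
  }

  x0 <- if (is.null(init)) im_start_point(trip) else
    log(c(init$tau_ir, max(init$tau_root - init$tau_ir, 1e-8),
          init$theta_inv, init$theta_rich, init$theta_anc, init$theta_root))
  if (model == "im") {
    m0 <- c(1e-3, 1e-3)   # weak-migration starting point
    if (!is.null(init)) {
      if (init$mig_ab > 0) m0[1] <- init$mig_ab
      if (init$mig_ba > 0) m0[2] <- init$mig_ba
    }
    x0 <- c(x0[1:6], log(m0))
  }

  starts <- list()
  best <- NULL
  withr::with_seed(as.integer(config$seed %% .Machine$integer.max), {
    for (s in seq_len(config$n_starts)) {
      xs <- if (s == 1) x0 else x0 + stats::rnorm(n_par, 0, 0.5)
      fit <- stats::optim(xs, negll, method = "Nelder-Mead",
                          control = list(maxit = config$maxit,
                                         reltol = config$reltol))
      starts[[s]] <- tibble::tibble(start = s, loglik = -fit$value,
                                    converged = fit$convergence == 0)
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (best$value >= 1e12)
    stop("no optimizer start reached a finite likelihood", call. = FALSE)
  structure(list(
    model = model,
    params = to_params(best$par),
    loglik = -best$value,
    starts = dplyr::bind_rows(starts),
    convergence = best$convergence == 0,
    n_loci = nrow(trip),
    config = config
  ), class = "im_fit")
}

# Moment-based starting point on the internal log scale: JC69-corrected
# pairwise distances give rough tau and theta magnitudes.
im_start_point <- function(trip) {
  pdist <- function(s1, s2) {
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    keep <- a != "N" & b != "N"
    mean(a[keep] != b[keep])
  }
  jc <- function(p) {
    p <- min(p, 0.74)
    -0.75 * log(1 - 4 * p / 3)
  }
  d_out <- jc(mean(mapply(pdist, trip$seq_a, trip$seq_out)))
  within <- function(cfg) {
    sel <- trip$pair_config == cfg
    if (!any(sel)) return(NA_real_)
    jc(mean(mapply(pdist, trip$seq_a[sel], trip$seq_b[sel])))
  }
  d_ii <- within("II"); d_rr <- within("RR"); d_ri <- within("RI")
  d_in <- mean(c(d_ii, d_rr, d_ri), na.rm = TRUE)
  if (!is.finite(d_in) || d_in <= 0) d_in <- d_out / 10
  tau_root0 <- max(d_out / 2 * 0.8, 1e-5)
  tau_ir0 <- min(max(d_in / 2 * 0.5, 1e-6), tau_root0 / 2)
  th_i <- max(d_ii, d_in / 2, 1e-5, na.rm = TRUE)
  th_r <- max(d_rr, d_in / 2, 1e-5, na.rm = TRUE)
  log(c(tau_ir0, tau_root0 - tau_ir0, th_i, th_r, th_i,
        max(d_out - 2 * tau_root0, th_i)))
}

#' @export
print.im_fit <- function(x, ...) {
  cat(sprintf("<im_fit> model=%s  lnL=%.4f  (%d loci, %d starts)\n",
              x$model, x$loglik, x$n_loci, nrow(x$starts)))
  p <- x$params
  cat(sprintf("  tau_ir=%.3g tau_root=%.3g theta(inv,rich,anc,root)=(%.3g, %.3g, %.3g, %.3g)\n",
              p$tau_ir, p$tau_root, p$theta_inv, p$theta_rich,
              p$theta_anc, p$theta_root))
  if (x$model == "im")
    cat(sprintf("  mig_ab=%.3g mig_ba=%.3g\n", p$mig_ab, p$mig_ba))
  invisible(x)
}

#' Tidy the parameter estimates of an IM fit
#'
#' @param x An `im_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.im_fit <- function(x, ...) {
  p <- x$params
  terms <- c("tau_ir", "tau_root", "theta_inv", "theta_rich",
             "theta_anc", "theta_root")
  est <- unlist(p[terms])
  if (x$model == "im") {
    terms <- c(terms, "mig_ab", "mig_ba")
    est <- c(est, p$mig_ab, p$mig_ba)
  }
  tibble::tibble(term = terms, estimate = unname(est))
}

#' One-line summary of an IM fit
#'
#' @param x An `im_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `logLik`, `n_loci`, `n_params`, `converged`.
#' @export
glance.im_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, logLik = x$loglik, n_loci = x$n_loci,
    n_params = if (x$model == "im") 8L else 6L,
    converged = x$convergence
  )
}

#' Likelihood-ratio test for gene flow
#'
#' Compares the complete-isolation null against the
#' isolation-with-migration model: `delta_lnl = lnL_im - lnL_null`, test
#' statistic `2 * delta_lnl` against a chi-square with `df` degrees of
#' freedom (2 by default, the two directional migration rates; because the
#' rates are constrained to be non-negative the test is conservative).
#'
#' @param lnl_null,lnl_im Maximized log-likelihoods (or `im_fit` objects).
#' @param df Extra free parameters in the IM model.
#' @param tol Numerical slack allowed on `lnl_im >= lnl_null`.
#' @return Tibble with `delta_lnl`, `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(lnl_null, lnl_im, df = 2, tol = 1e-3) {
  if (inherits(lnl_null, "im_fit")) lnl_null <- lnl_null$loglik
  if (inherits(lnl_im, "im_fit")) lnl_im <- lnl_im$loglik
  delta <- lnl_im - lnl_null
  if (delta < -tol)
    stop("lnL_im < lnL_null beyond tolerance: optimizer failure", call. = FALSE)
  delta <- max(delta, 0)
  tibble::tibble(
    delta_lnl = delta,
    statistic = 2 * delta,
    df = df,
    p_value = stats::pchisq(2 * delta, df = df, lower.tail = FALSE)
  )
}
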