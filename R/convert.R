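#' Mutation rate with confidence interval
#'
#' Substitutions per site per generation. The default is the honey-bee
#' direct estimate used for these hymenopterans: 3.4e-9 (95% CI
#' 2.2e-9 - 4.9e-9).
#'
#' @param point Point estimate.
#' @param ci_low,ci_high 95% CI bounds, `ci_low <= point <= ci_high`.
#' @return A list of class `mutation_rate`.
#' @export
mutation_rate <- function(point = 3.4e-9, ci_low = 2.2e-9, ci_high = 4.9e-9) {
  if (!(ci_low > 0 && ci_low <= point && point <= ci_high))
    stop("need 0 < ci_low <= point <= ci_high", call. = FALSE)
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high),
            class = "mutation_rate")
}

#' Generation time in years
#'
#' Fire-ant generation length is uncertain (overlapping generations,
#' year-round nuptial flights); the working estimate is 3-6 years with 6
#' as the average used for headline conversions.
#'
#' @param years Average generation time (> 0).
#' @param plausible_range Low/high plausible values in years.
#' @return A list of class `generation_time`.
#' @export
generation_time <- function(years = 6, plausible_range = c(3, 6)) {
  stopifnot(years > 0)
  structure(list(years = years, plausible_range = plausible_range),
            class = "generation_time")
}

# Interval arithmetic: min/max over the endpoint combinations of
# (value interval) / (mu interval).
divide_intervals <- function(val, val_lo, val_hi, mu, mu_lo, mu_hi) {
  combos <- c(val_lo / mu_lo, val_lo / mu_hi, val_hi / mu_lo, val_hi / mu_hi)
  list(point = val / mu, low = min(combos), high = max(combos))
}

#' Convert a scaled divergence time to generations
#'
#' `tau` is the expected number of substitutions per site since the split;
#' dividing by the per-generation mutation rate gives generations. The CI
#' combines the estimate's CI with the mutation rate's CI by interval
#' arithmetic (lower bound `tau_low / mu_high`, upper `tau_high / mu_low`).
#'
#' @param tau Point estimate (> 0, or 0 for no divergence).
#' @param ci Length-2 CI for `tau` (defaults to the point).
#' @param mu A [mutation_rate()].
#' @param sig_figs Significant figures for the reported values (`NULL` to
#'   skip rounding).
#' @return Tibble with `generations`, `ci_low`, `ci_high`.
#' @export
tau_to_generations <- function(tau, ci = c(tau, tau), mu = mutation_rate(),
                               sig_figs = 2) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  r <- divide_intervals(tau, ci[1], ci[2], mu$point, mu$ci_low, mu$ci_high)
  out <- c(r$point, r$low, r$high)
  if (!is.null(sig_figs)) out <- signif_round(out, sig_figs)
  tibble::tibble(generations = out[1], ci_low = out[2], ci_high = out[3])
}

#' Convert a scaled diversity (theta) to an effective population size
#'
#' `theta = 4 mu Ne` for diploids; `theta = 3 mu Ne` for haplodiploids
#' (males haploid, females diploid, so the ploidy ratio lowers the
#' coefficient). CI propagated by interval arithmetic over the theta and
#' mu intervals.
#'
#' @param theta Point estimate (> 0).
#' @param ci Length-2 CI for `theta`.
#' @param mu A [mutation_rate()].
#' @param ploidy `"haplodiploid"` (ants; default) or `"diploid"`.
#' @param sig_figs Significant figures (`NULL` to skip rounding).
#' @return Tibble with `ne`, `ci_low`, `ci_high`.
#' @export
theta_to_ne <- function(theta, ci = c(theta, theta), mu = mutation_rate(),
                        ploidy = c("haplodiploid", "diploid"), sig_figs = 2) {
  ploidy <- match.arg(ploidy)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  k <- if (ploidy == "diploid") 4 else 3
  r <- divide_intervals(theta, ci[1], ci[2],
                        k * mu$point, k * mu$ci_low, k * mu$ci_high)
  out <- c(r$point, r$low, r$high)
  if (!is.null(sig_figs)) out <- signif_round(out, sig_figs)
  tibble::tibble(ne = out[1], ci_low = out[2], ci_high = out[3])
}

#' Effective size implied by breeding females and males
#'
#' Diploid: `Ne = 4 Nf Nm / (Nf + Nm)`. Haplodiploid (haploid males carry
#' half the autosomal copies): `Ne = 9 Nf Nm / (4 Nf + 2 Nm)` (Wright /
#' Crozier); with single mating (`Nm = Nf`) this reduces to
#' `Ne = 1.5 Nf`, the ratio used to translate founder effective sizes into
#' queen counts.
#'
#' @param n_f,n_m Numbers of breeding females and males (`n_f + n_m > 0`).
#' @param ploidy `"haplodiploid"` or `"diploid"`.
#' @return Effective size.
#' @export
effective_size_from_breeders <- function(n_f, n_m,
                                         ploidy = c("haplodiploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(n_f >= 0, n_m >= 0)
  if (n_f + n_m == 0) stop("need at least one breeder", call. = FALSE)
  if (ploidy == "diploid") 4 * n_f * n_m / (n_f + n_m)
  else 9 * n_f * n_m / (4 * n_f + 2 * n_m)
}

#' Founder effective size to founding-queen count
#'
#' Inverts `Ne = 1.5 Nf` (singly-mated haplodiploid queens): queens =
#' `ceiling(ne / 1.5)`, exact when `ne / 1.5` is integral. Applied to the
#' point estimate and both CI bounds.
#'
#' @param ne Founder effective size (> 0).
#' @param ci Length-2 CI for `ne`.
#' @return Tibble with `queens`, `ci_low`, `ci_high` (integers).
#' @export
founder_ne_to_queens <- function(ne, ci = c(ne, ne)) {
  if (ne <= 0 || any(ci <= 0)) stop("founder size must be > 0", call. = FALSE)
  q <- function(x) as.integer(ceiling(x / 1.5 - 1e-9))
  tibble::tibble(queens = q(ne), ci_low = q(ci[1]), ci_high = q(ci[2]))
}

#' Convert generations to years
#'
#' @param generations Point estimate in generations.
#' @param ci Length-2 CI in generations.
#' @param gen_time A [generation_time()].
#' @param sig_figs Significant figures (`NULL` to skip rounding).
#' @return Tibble with `years`, `ci_low`, `ci_high`.
#' @export
generations_to_years <- function(generations, ci = c(generations, generations),
                                 gen_time = generation_time(), sig_figs = 2) {
  stopifnot(generations > 0, all(ci > 0))
  out <- c(generations, ci) * gen_time$years
  if (!is.null(sig_figs)) out <- signif_round(out, sig_figs)
  tibble::tibble(years = out[1], ci_low = out[2], ci_high = out[3])
}

#' Full conversion report for the six coalescent-scale estimates
#'
#' Takes the six tau/theta estimates of the highest-scoring
#' isolation-model run (two divergence times; diversities of S. invicta,
#' S. richteri, their ancestor, and the root population) and emits every
#' derived quantity: both split times in generations and in years, and the
#' four haplodiploid effective sizes, each with propagated CIs.
#'
#' @param estimates Tibble/data frame with columns `name`, `value`,
#'   `ci_low`, `ci_high`, `kind` (`"tau"` or `"theta"`); see
#'   [table1_estimates()] for the shipped values.
#' @param mu A [mutation_rate()].
#' @param gen_time A [generation_time()].
#' @param sig_figs Significant figures for display.
#' @return Tibble with columns `name`, `quantity`, `value`, `ci_low`,
#'   `ci_high`, `unit`.
#' @export
table1_report <- function(estimates = table1_estimates(),
                          mu = mutation_rate(),
                          gen_time = generation_time(), sig_figs = 2) {
  rows <- purrr::pmap_dfr(estimates, function(name, value, ci_low, ci_high, kind) {
    ci <- c(ci_low, ci_high)
    if (kind == "tau") {
      g <- tau_to_generations(value, ci, mu, sig_figs = sig_figs)
      gu <- tau_to_generations(value, ci, mu, sig_figs = NULL)
      y <- generations_to_years(gu$generations, c(gu$ci_low, gu$ci_high),
                                gen_time, sig_figs = sig_figs)
      tibble::tibble(
        name = name,
        quantity = c("divergence", "divergence"),
        value = c(g$generations, y$years),
        ci_low = c(g$ci_low, y$ci_low),
        ci_high = c(g$ci_high, y$ci_high),
        unit = c("generations", "years")
      )
    } else {
      ne <- theta_to_ne(value, ci, mu, "haplodiploid", sig_figs = sig_figs)
      neu <- theta_to_ne(value, ci, mu, "haplodiploid", sig_figs = NULL)
      # queen-equivalent: breeding females sustaining that Ne under single
      # mating (Ne = 1.5 Nf)
      tibble::tibble(
        name = name,
        quantity = c("effective_size", "breeding_females"),
        value = c(ne$ne, signif_round(neu$ne / 1.5, sig_figs)),
        ci_low = c(ne$ci_low, signif_round(neu$ci_low / 1.5, sig_figs)),
        ci_high = c(ne$ci_high, signif_round(neu$ci_high / 1.5, sig_figs)),
        unit = c("individuals", "queens")
      )
    }
  })
  rows
}

#' Shipped coalescent-scale estimates of the isolation model
#'
#' The six (tau, theta) estimates of the highest-scoring complete-isolation
#' run on the native-range triplet data, with 95% CIs, used as input to
#' [table1_report()].
#'
#' @return Tibble with columns `name`, `value`, `ci_low`, `ci_high`,
#'   `kind`.
#' @export
table1_estimates <- function() {
  tibble::tribble(
    ~name,                ~value,   ~ci_low,  ~ci_high, ~kind,
    "invicta_richteri_split", 0.000646, 0.00052,  0.00077,  "tau",
    "root_split",             0.008369, 0.00789,  0.00884,  "tau",
    "theta_anc_ir",           0.002293, 0.00211,  0.00247,  "theta",
    "theta_root",             0.026874, 0.02591,  0.02783,  "theta",
    "theta_richteri",         0.003596, 0.00309,  0.00409,  "theta",
    "theta_invicta",          0.004062, 0.00343,  0.00469,  "theta"
  )
}
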