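#' Plot prior and posterior densities of the ABC parameters
#'
#' Faceted density plot of the adjusted particles (weighted) with the
#' prior density overlaid, mirroring the usual prior/posterior panels of
#' a DIYABC analysis.
#'
#' @param object An `abc_posterior`.
#' @param prior A [prior_spec()] (overlays the prior when supplied).
#' @param n_prior Prior reference draws per parameter.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abc_posterior <- function(object, prior = NULL, n_prior = 5000, ...) {
  w <- object$weights / sum(object$weights)
  post <- tidyr::pivot_longer(
    dplyr::mutate(object$particles, .w = w),
    -".w", names_to = "parameter", values_to = "value")
  post$source <- "posterior"
  df <- post
  if (!is.null(prior)) {
    pr <- purrr::map_dfr(names(object$particles), function(nm) {
      tibble::tibble(parameter = nm,
                     value = draw_one_prior(prior[[nm]], n_prior),
                     .w = 1 / n_prior, source = "prior")
    })
    df <- dplyr::bind_rows(post, pr)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, weight = .data$.w,
                                   color = .data$source)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = NULL, y = "density", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the PCA goodness-of-fit cloud
#'
#' First two principal components of the simulated summary-statistic
#' vectors with the observed point highlighted.
#'
#' @param object An `abc_gof` from [abc_gof_pca()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abc_gof <- function(object, ...) {
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(data = sc[!sc$observed, ], alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = sc[sc$observed, ], color = "red", size = 3,
                        shape = 17) +
    ggplot2::labs(
      title = sprintf("observed point at the %.1f%% distance percentile",
                      object$percentile)) +
    ggplot2::theme_minimal()
}

#' Plot per-locus SNP filter attrition
#'
#' Survivor counts after each filter stage, from the `stage_counts`
#' attribute attached by [apply_filter_pipeline()].
#'
#' @param g A filtered [genotype_matrix()] (or the stage-count tibble).
#' @return A ggplot object.
#' @export
plot_filter_stages <- function(g) {
  counts <- if (is.data.frame(g)) g else attr(g, "stage_counts")
  if (is.null(counts)) stop("no stage counts attached; run apply_filter_pipeline",
                            call. = FALSE)
  counts$stage <- factor(counts$stage, levels = counts$stage)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$stage, y = .data$n_loci,
                                       group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "loci surviving") +
    ggplot2::theme_minimal()
}
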