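# broom-style tidiers and ggplot2 methods for fitted objects.

#' Tidy a trained segmentation HMM
#'
#' @param x A `pmd_hmm` fit.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.pmd_hmm <- function(x, ...) {
  p <- x$params
  mu <- state_means(p)
  tibble(
    term = c("pi_pmd", "pi_background",
             "A_pmd_pmd", "A_pmd_background", "A_background_pmd",
             "A_background_background",
             "alpha_pmd", "beta_pmd", "mean_pmd",
             "alpha_background", "beta_background", "mean_background"),
    estimate = c(p$pi[1], p$pi[2],
                 p$A[1, 1], p$A[1, 2], p$A[2, 1], p$A[2, 2],
                 p$emis$pmd$alpha, p$emis$pmd$beta, mu[["pmd"]],
                 p$emis$background$alpha, p$emis$background$beta,
                 mu[["background"]])
  )
}

#' One-row summary of a trained segmentation HMM
#'
#' @param x A `pmd_hmm` fit.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `iterations`, `converged`,
#'   `relabelled`, `n_bins`, `bin_size`.
#' @export
glance.pmd_hmm <- function(x, ...) {
  tibble(logLik = tail(x$logliks, 1L), iterations = x$iterations,
         converged = x$converged, relabelled = x$relabelled,
         n_bins = x$n_bins, bin_size = as.numeric(x$bin_size %||% NA_real_))
}

#' @rdname tidy.pmd_hmm
#' @export
tidy.pmd_segmentation <- function(x, ...) {
  out <- x$pmds
  as_tibble(out)
}

#' @rdname glance.pmd_hmm
#' @export
glance.pmd_segmentation <- function(x, ...) {
  dplyr::bind_cols(x$summary, glance(x$fit)[, c("logLik", "iterations", "converged")])
}

#' Plot a segmentation along the genome
#'
#' Per-bin methylation levels (`m/n`) as points, the PMD-state posterior as
#' a line, and called domains as shaded rectangles.
#'
#' @param object A `pmd_segmentation`.
#' @param chrom Chromosome to plot; defaults to the first.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmd_segmentation <- function(object, chrom = NULL, ...) {
  bins <- object$bins
  chrom <- chrom %||% bins$chrom[1L]
  b <- dplyr::filter(bins, .data$chrom == .env$chrom, .data$n > 0)
  tr <- dplyr::filter(object$fit$track, .data$chrom == .env$chrom)
  dom <- dplyr::filter(as_tibble(object$pmds), .data$chrom == .env$chrom)
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = dom,
                       ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                                    ymin = -Inf, ymax = Inf),
                       fill = "steelblue", alpha = 0.15) +
    ggplot2::geom_point(data = b,
                        ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                     y = .data$m / .data$n),
                        size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(data = tr,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$posterior_pmd),
                       colour = "firebrick", linewidth = 0.3) +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom),
                  y = "methylation level / PMD posterior",
                  title = "PMD segmentation") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot the Baum-Welch log-likelihood trace
#'
#' @param object A `pmd_hmm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmd_hmm <- function(object, ...) {
  d <- tibble(iteration = seq_along(object$logliks), logLik = object$logliks)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$logLik)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = "Baum-Welch convergence", y = "log-likelihood") +
    ggplot2::theme_minimal()
}

#' Plot a downsampling stability curve
#'
#' @param curves A tibble from [stability_curve()], optionally row-bound
#'   across modes with a `mode` column.
#' @return A ggplot object.
#' @export
plot_stability_curve <- function(curves) {
  aes <- if ("mode" %in% names(curves)) {
    ggplot2::aes(x = .data$fraction, y = .data$jaccard, colour = .data$mode)
  } else {
    ggplot2::aes(x = .data$fraction, y = .data$jaccard)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fraction of observations retained",
                  y = "Jaccard vs full-coverage PMDs",
                  title = "Segmentation stability under downsampling") +
    ggplot2::theme_minimal()
}

#' Plot the PC / non-PC decision surface
#'
#' Fraction of genome segmented against mean segment size for a collection
#' of samples, with the classification cutoffs drawn.
#'
#' @param summaries Row-bound one-row tibbles from [decide_pc()] (optionally
#'   with a `sample` column).
#' @param frac_cutoff,size_cutoff Cutoffs to draw. Defaults 0.05 and 50 kb.
#' @return A ggplot object.
#' @export
plot_decision <- function(summaries, frac_cutoff = 0.05, size_cutoff = 50000) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$fraction_segmented,
                               y = .data$mean_segment_size / 1000,
                               colour = .data$is_pc)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = frac_cutoff, linetype = 2) +
    ggplot2::geom_hline(yintercept = size_cutoff / 1000, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fraction of genome segmented",
                  y = "mean segment size (kb)", colour = "PC",
                  title = "PMD-containing decision surface") +
    ggplot2::theme_minimal()
}
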