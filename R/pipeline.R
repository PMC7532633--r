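# End-to-end segmentation pipeline: bin-size selection -> binning ->
# Baum-Welch -> posterior decoding -> boundary sharpening -> shuffle FDR ->
# sample classification.

#' Segment a methylome into partially methylated domains
#'
#' Runs the full pipeline. With `bin_size = NULL` the sample-specific bin
#' size is chosen by the 40-observations-in-80%-of-bins rule; passing a
#' number fixes the bin size (e.g. `1000` for the classic fixed 1-kb bins).
#'
#' @param meth Methylome tibble from [read_methcounts()] or
#'   [simulate_methylome()].
#' @param bin_size Bin size override in bp, or `NULL` for dynamic selection.
#' @param min_obs,bin_fraction Bin-size selection thresholds (see
#'   [select_bin_size()]).
#' @param init Initial HMM parameters. Default [hmm_params()].
#' @param max_iter,tol Baum-Welch stopping rule.
#' @param posterior_cutoff Posterior cutoff for domain calling. Default 0.5.
#' @param sharpen Sharpen boundaries to single-basepair resolution?
#'   Default TRUE.
#' @param fdr Empirical FDR level for the shuffle filter, or `NA` to skip
#'   filtering. Default 0.01.
#' @param n_shuffles Shuffles pooled into the null. Default 1.
#' @param frac_cutoff,size_cutoff PC-classification cutoffs (see
#'   [decide_pc()]).
#' @param seed Integer seed (governs only the shuffle permutation).
#' @param chrom_sizes Optional chromosome lengths; defaults to the attribute
#'   attached to `meth`.
#' @return An object of class `pmd_segmentation`: `pmds` (final domain
#'   tibble), `fit` (the `pmd_hmm`), `bins`, `summary` (one-row
#'   classification tibble), `null` (null size distribution or `NULL`), and
#'   `bin_size`.
#' @export
pmd_segment <- function(meth, bin_size = NULL, min_obs = 40,
                        bin_fraction = 0.80, init = hmm_params(),
                        max_iter = 100, tol = 1e-6,
                        posterior_cutoff = 0.5, sharpen = TRUE,
                        fdr = 0.01, n_shuffles = 1,
                        frac_cutoff = 0.05, size_cutoff = 50000,
                        seed = 1, chrom_sizes = NULL) {
  cs <- need_chrom_sizes(meth, chrom_sizes)
  if (is.null(bin_size)) {
    bin_size <- select_bin_size(meth, min_obs = min_obs,
                                bin_fraction = bin_fraction, chrom_sizes = cs)
  }
  bins <- bin_methylome(meth, bin_size, chrom_sizes = cs, min_obs = min_obs)
  fit <- baum_welch(bins, init = init, max_iter = max_iter, tol = tol)
  pmds <- call_domains(fit$track, cutoff = posterior_cutoff)

  if (sharpen) {
    pmds <- sharpen_boundaries(pmds, meth, fit$params)
  }
  null <- NULL
  if (!is.na(fdr)) {
    # pool enough shuffled segments that the empirical p-value floor
    # 1/(1 + N) sits safely below the requested FDR level
    null <- build_null(bins, fit$params, n_shuffles = n_shuffles, seed = seed,
                       cutoff = posterior_cutoff, min_null = ceiling(2 / fdr))
    pmds <- fdr_filter(pmds, null, q_cutoff = fdr)
  }

  summary <- decide_pc(pmds, genome_size = sum(cs),
                       frac_cutoff = frac_cutoff, size_cutoff = size_cutoff)
  summary <- dplyr::mutate(summary, bin_size = bin_size, .before = 1L)

  structure(list(pmds = pmds, fit = fit, bins = bins, summary = summary,
                 null = null, bin_size = bin_size),
            class = "pmd_segmentation")
}

#' @export
print.pmd_segmentation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PMD segmentation: %d domains at bin size %d bp\n",
              s$n_segments, as.integer(x$bin_size)))
  cat(sprintf("  fraction segmented %.3f, mean size %.1f kb -> %s\n",
              s$fraction_segmented, s$mean_segment_size / 1000,
              if (s$is_pc) "PMD-containing" else "non-PMD-containing"))
  cat(sprintf("  Baum-Welch: %d iterations, %sconverged, logLik %.2f\n",
              x$fit$iterations, if (x$fit$converged) "" else "NOT ",
              tail(x$fit$logliks, 1L)))
  invisible(x)
}
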