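# Bin-size selection and aggregation of per-CpG counts into the HMM
# observation sequence.
#
# A bin's information content is its total read count across CpGs: 40
# observations of one CpG and single observations of 40 CpGs are equivalent.
# 40 observations give an 80% Clopper-Pearson interval of 39%-61% around an
# observed level of 50%, enough to call a bin's methylation low, medium or
# high. Bin size is chosen per sample as the smallest candidate for which at
# least 80% of eligible bins reach that threshold, which equalises
# information across samples of very different sequencing depth.

#' Aggregate a methylome into fixed-width genomic bins
#'
#' Bins tile each chromosome contiguously from position 0; the final bin is
#' truncated at the chromosome end. Each bin carries the summed methylated
#' read count `m`, total read count `n` and the number of CpG sites it
#' contains. Counts are conserved exactly: the column sums of `m` and `n`
#' equal the methylome's total methylated count and coverage.
#'
#' @param meth A methylome tibble from [read_methcounts()] or
#'   [simulate_methylome()].
#' @param bin_size Bin width in basepairs (>= 1).
#' @param chrom_sizes Optional chromosome lengths; defaults to the attribute
#'   attached to `meth`.
#' @param min_obs Observation threshold used to report the attached
#'   `sufficiency_fraction` attribute (fraction of CpG-containing bins with
#'   `n >= min_obs`).
#' @return A tibble of bins (`chrom`, `start`, `end`, `m`, `n`, `n_cpgs`)
#'   with attributes `bin_size`, `sufficiency_fraction` and `chrom_sizes`.
#' @export
bin_methylome <- function(meth, bin_size, chrom_sizes = NULL, min_obs = 40) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1) {
    abort("`bin_size` must be a single number >= 1.")
  }
  cs <- need_chrom_sizes(meth, chrom_sizes)

  per_chrom <- lapply(names(cs), function(chr) {
    len <- cs[[chr]]
    n_bins <- max(1L, as.integer(ceiling(len / bin_size)))
    start <- (seq_len(n_bins) - 1) * bin_size
    end <- pmin(start + bin_size, len)
    m <- numeric(n_bins); n <- numeric(n_bins); n_cpgs <- integer(n_bins)
    idx <- which(meth$chrom == chr)
    if (length(idx) > 0L) {
      b <- as.integer(meth$pos[idx] %/% bin_size) + 1L
      m_add <- tapply(meth$meth[idx], b, sum)
      n_add <- tapply(meth$coverage[idx], b, sum)
      c_add <- tapply(rep(1L, length(idx)), b, sum)
      at <- as.integer(names(m_add))
      m[at] <- as.numeric(m_add)
      n[at] <- as.numeric(n_add)
      n_cpgs[at] <- as.integer(c_add)
    }
    tibble(chrom = chr, start = start, end = end, m = m, n = n, n_cpgs = n_cpgs)
  })
  bins <- dplyr::bind_rows(per_chrom)

  eligible <- bins$n_cpgs >= 1L
  suff <- if (any(eligible)) mean(bins$n[eligible] >= min_obs) else 0
  attr(bins, "bin_size") <- bin_size
  attr(bins, "sufficiency_fraction") <- suff
  chrom_sizes(bins) <- cs
  bins
}

#' Total read-level observations in each bin
#'
#' @param bins A bin tibble from [bin_methylome()].
#' @return A numeric vector of per-bin observation counts (the `n` column).
#' @export
observation_count <- function(bins) bins$n

#' Choose the sample-specific bin size
#'
#' Scans candidate widths (`start`, `start + step`, ..., `max_size`) and
#' returns the smallest for which at least `bin_fraction` of eligible bins
#' (those containing at least one CpG site) hold `min_obs` or more read-level
#' observations. Bins in CpG-free stretches -- assembly gaps, unassayed
#' regions -- are excluded from the denominator so they cannot dominate the
#' criterion. If no candidate qualifies, `max_size` is returned with a
#' warning.
#'
#' @param meth A methylome tibble with at least one covered site.
#' @param min_obs Minimum read-level observations for a bin to count as
#'   sufficiently informed. Default 40.
#' @param bin_fraction Required fraction of eligible bins meeting `min_obs`.
#'   Default 0.80.
#' @param start,step,max_size Candidate-grid parameters in basepairs.
#' @param chrom_sizes Optional chromosome lengths; defaults to the attribute
#'   attached to `meth`.
#' @return The selected bin size in basepairs.
#' @export
select_bin_size <- function(meth, min_obs = 40, bin_fraction = 0.80,
                            start = 1000, step = 1000, max_size = 100000,
                            chrom_sizes = NULL) {
  cs <- need_chrom_sizes(meth, chrom_sizes)
  if (nrow(meth) == 0L || sum(meth$coverage) == 0) {
    abort("Cannot select a bin size: the methylome has no covered sites.")
  }
  candidates <- seq(start, max_size, by = step)
  for (size in candidates) {
    frac <- sufficiency_fraction(meth, size, cs, min_obs)
    if (!is.na(frac) && frac >= bin_fraction) return(size)
  }
  warn(sprintf("No candidate bin size up to %d bp reached %.0f%% sufficiency; using %d bp.",
               max_size, bin_fraction * 100, max_size))
  max_size
}

# Fraction of CpG-containing bins with >= min_obs observations at one
# candidate size, without materialising the full bin table.
sufficiency_fraction <- function(meth, bin_size, cs, min_obs) {
  n_suff <- 0L
  n_elig <- 0L
  for (chr in unique(meth$chrom)) {
    idx <- which(meth$chrom == chr)
    b <- as.integer(meth$pos[idx] %/% bin_size)
    n_per_bin <- tapply(meth$coverage[idx], b, sum)
    n_elig <- n_elig + length(n_per_bin)
    n_suff <- n_suff + sum(n_per_bin >= min_obs)
  }
  if (n_elig == 0L) return(NA_real_)
  n_suff / n_elig
}

#' Exact binomial confidence interval for a bin's methylation level
#'
#' Clopper-Pearson (exact) two-sided interval for `m` methylated out of `n`
#' observed reads. With the default observation threshold of 40 reads and an
#' 80% level, an observed level of 50% carries an interval of 39%-61% --
#' wide, but sufficient to distinguish low, medium and high methylation,
#' which is what motivates 40 observations as the per-bin sufficiency
#' threshold.
#'
#' @param n Total read-level observations (>= 1).
#' @param m Methylated observations, `0 <= m <= n`.
#' @param level Confidence level in (0, 1). Default 0.80.
#' @return A named numeric vector `c(lower, upper)` of level fractions.
#' @export
min_obs_confidence_interval <- function(n, m, level = 0.80) {
  if (n < 1) abort("`n` must be >= 1.")
  if (m < 0 || m > n) abort("`m` must satisfy 0 <= m <= n.")
  ci <- binom.test(round(m), round(n), conf.level = level)$conf.int
  c(lower = ci[1L], upper = ci[2L])
}
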