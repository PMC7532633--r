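# Sample-level decision machinery: PMD-containing classification, Jaccard
# comparison of segmentations, read downsampling and multi-sample
# conservation tracks.

#' Classify a sample as PMD-containing or not
#'
#' A methylome counts as PMD-containing (PC) when the segmentation covers
#' strictly more than `frac_cutoff` of the genome AND the mean segment size
#' strictly exceeds `size_cutoff`. The defaults (5% of the genome, 50 kb)
#' sit at the empirical inflection that separates genuine PMD samples from
#' samples whose hypomethylated basepairs are just regulatory features
#' (promoters, CpG islands): those cover roughly 5% of the genome in
#' segments of tens of kilobases, while PC samples jump to over 10% coverage
#' with mean sizes above a hundred kilobases.
#'
#' @param pmds PMD tibble.
#' @param genome_size Total genome size in basepairs (sum of the lengths of
#'   the chromosomes present); defaults to the attached chromosome sizes.
#' @param frac_cutoff Fraction-of-genome cutoff (strict). Default 0.05.
#' @param size_cutoff Mean-segment-size cutoff in bp (strict). Default 50000.
#' @return A one-row tibble: `fraction_segmented`, `mean_segment_size`,
#'   `n_segments`, `is_pc`.
#' @export
decide_pc <- function(pmds, genome_size = NULL, frac_cutoff = 0.05,
                      size_cutoff = 50000) {
  if (is.null(genome_size)) {
    cs <- chrom_sizes(pmds)
    if (is.null(cs)) abort("`genome_size` is required when `pmds` carries no chromosome sizes.")
    genome_size <- sum(cs)
  }
  if (genome_size <= 0) abort("`genome_size` must be positive.")
  if (nrow(pmds) == 0L) {
    return(tibble(fraction_segmented = 0, mean_segment_size = 0,
                  n_segments = 0L, is_pc = FALSE))
  }
  sizes <- pmds$end - pmds$start
  frac <- sum(sizes) / genome_size
  mean_size <- mean(sizes)
  tibble(fraction_segmented = frac,
         mean_segment_size = mean_size,
         n_segments = nrow(pmds),
         is_pc = frac > frac_cutoff && mean_size > size_cutoff)
}

#' Basepair Jaccard index of two interval sets
#'
#' `|A intersect B| / |A union B|` counted in basepairs over both genomes'
#' chromosomes. Two empty sets have an undefined index; 0 is returned with a
#' warning.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`) over the same genome.
#' @return A fraction in [0, 1].
#' @export
jaccard <- function(a, b) {
  gr_a <- GenomicRanges::reduce(intervals_to_granges(a))
  gr_b <- GenomicRanges::reduce(intervals_to_granges(b))
  if (length(gr_a) == 0L && length(gr_b) == 0L) {
    warn("Both interval sets are empty; Jaccard defined as 0.")
    return(0)
  }
  inter <- sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(gr_a, gr_b))))
  uni <- sum(as.numeric(GenomicRanges::width(GenomicRanges::union(gr_a, gr_b))))
  inter / uni
}

#' Downsample a methylome by read-level thinning
#'
#' Each site's retained coverage is Binomial(coverage, retain) and the
#' retained methylated count is drawn hypergeometrically from the site's
#' reads, so the unit of thinning is the read-level observation, not the CpG
#' site. Expected methylation level is preserved at every site. Deterministic
#' given `seed`.
#'
#' @param meth Methylome tibble.
#' @param retain Fraction of observations to retain, in [0, 1].
#' @param seed Integer seed.
#' @return A methylome tibble with recomputed `coverage`, `meth` and `level`.
#' @export
downsample_methylome <- function(meth, retain, seed = NULL) {
  if (!is.numeric(retain) || length(retain) != 1L || retain < 0 || retain > 1) {
    abort("`retain` must be a single fraction in [0, 1].")
  }
  out <- meth
  if (nrow(meth) == 0L) return(out)
  with_seed(seed, {
    k <- rbinom(nrow(meth), size = meth$coverage, prob = retain)
    m_ret <- rhyper(nrow(meth), m = meth$meth, n = meth$coverage - meth$meth, k = k)
    out$coverage <- k
    out$meth <- m_ret
    out$level <- ifelse(k > 0, m_ret / k, 0)
  })
  chrom_sizes(out) <- chrom_sizes(meth)
  out
}

#' Segmentation stability under downsampling
#'
#' For each retention fraction: thin the methylome, segment it end-to-end
#' (with either the dynamically selected bin size or a fixed 1-kb bin) and
#' compute the basepair Jaccard index against the full-coverage PMD set.
#' Failures at individual fractions are recorded rather than aborting the
#' sweep.
#'
#' @param meth Methylome tibble, segmentable at full coverage.
#' @param fractions Retention fractions. Default `seq(0.1, 0.9, by = 0.1)`.
#' @param mode `"dynamic"` (bin size reselected per downsample) or
#'   `"fixed"` (1-kb bins throughout).
#' @param seed Integer seed for thinning.
#' @param full_pmds Optional precomputed full-coverage PMD set; segmented
#'   from `meth` if omitted.
#' @param ... Further arguments passed to [pmd_segment()].
#' @return A tibble: `fraction`, `jaccard`, `bin_size`, `n_segments`,
#'   `error` (NA on success).
#' @export
stability_curve <- function(meth, fractions = seq(0.1, 0.9, by = 0.1),
                            mode = c("dynamic", "fixed"), seed = 1,
                            full_pmds = NULL, ...) {
  mode <- match.arg(mode)
  if (length(fractions) == 0L) {
    return(tibble(fraction = numeric(), jaccard = numeric(),
                  bin_size = numeric(), n_segments = integer(),
                  error = character()))
  }
  if (is.null(full_pmds)) {
    full <- pmd_segment(meth, seed = seed, ...)
    full_pmds <- full$pmds
  }
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    res <- tryCatch({
      ds <- downsample_methylome(meth, f, seed = seed + i)
      seg <- if (mode == "dynamic") {
        pmd_segment(ds, seed = seed + i, ...)
      } else {
        pmd_segment(ds, bin_size = 1000, seed = seed + i, ...)
      }
      tibble(fraction = f, jaccard = jaccard(seg$pmds, full_pmds),
             bin_size = as.numeric(attr(seg$bins, "bin_size")),
             n_segments = nrow(seg$pmds), error = NA_character_)
    }, error = function(e) {
      tibble(fraction = f, jaccard = NA_real_, bin_size = NA_real_,
             n_segments = NA_integer_, error = conditionMessage(e))
    })
    res
  })
  dplyr::bind_rows(rows)
}

#' Multi-sample PMD conservation track
#'
#' Tiles the genome in fixed windows (50 kb by default) and, for each
#' window, counts the samples in which the window lies completely inside a
#' PMD -- containment, not mere overlap -- and reports each sample's
#' coverage-weighted mean methylation level in the window.
#'
#' @param pmd_sets List of PMD tibbles, one per sample.
#' @param meths Matching list of methylome tibbles.
#' @param window Window size in basepairs. Default 50000.
#' @param chrom_sizes Optional chromosome lengths; defaults to those attached
#'   to the first methylome.
#' @return A long tibble: `chrom`, `start`, `end`, `sample`, `in_pmd`,
#'   `mean_level`, `n_pmd_samples` (the per-window count, repeated across
#'   samples).
#' @export
conservation_track <- function(pmd_sets, meths, window = 50000,
                               chrom_sizes = NULL) {
  stopifnot(length(pmd_sets) >= 1L, length(pmd_sets) == length(meths))
  cs <- as_chrom_sizes(chrom_sizes %||% chrom_sizes(meths[[1L]]))
  if (is.null(cs)) abort("Chromosome sizes are required.")
  samples <- names(pmd_sets) %||% paste0("sample_", seq_along(pmd_sets))
  if (is.null(names(pmd_sets))) names(pmd_sets) <- samples

  wins <- dplyr::bind_rows(lapply(names(cs), function(chr) {
    n <- max(1L, as.integer(ceiling(cs[[chr]] / window)))
    start <- (seq_len(n) - 1) * window
    tibble(chrom = chr, start = start, end = pmin(start + window, cs[[chr]]))
  }))
  gr_wins <- intervals_to_granges(wins)

  per_sample <- lapply(seq_along(pmd_sets), function(s) {
    gr_pmd <- GenomicRanges::reduce(intervals_to_granges(pmd_sets[[s]]))
    contained <- IRanges::overlapsAny(gr_wins, gr_pmd, type = "within")
    meth <- meths[[s]]
    bin <- as.integer(meth$pos %/% window)
    key_site <- paste(meth$chrom, bin)
    key_win <- paste(wins$chrom, as.integer(wins$start %/% window))
    n_tot <- tapply(meth$coverage, key_site, sum)
    m_tot <- tapply(meth$meth, key_site, sum)
    lvl <- setNames(as.numeric(m_tot) / pmax(as.numeric(n_tot), 1), names(n_tot))
    lvl[as.numeric(n_tot) == 0] <- NA_real_
    tibble(chrom = wins$chrom, start = wins$start, end = wins$end,
           sample = samples[s], in_pmd = as.logical(contained),
           mean_level = unname(lvl[key_win]))
  })
  long <- dplyr::bind_rows(per_sample)
  counts <- long |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(n_pmd_samples = sum(.data$in_pmd), .groups = "drop")
  dplyr::left_join(long, counts, by = c("chrom", "start"))
}
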