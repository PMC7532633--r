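# Feature-level annotation of PMD calls: escapee genes and
# observed/expected overlap enrichment.

coverage_fraction <- function(features_gr, regions_gr) {
  if (length(features_gr) == 0L) return(numeric(0))
  regions_gr <- GenomicRanges::reduce(regions_gr)
  hits <- GenomicRanges::findOverlaps(features_gr, regions_gr)
  covered <- numeric(length(features_gr))
  if (length(hits) > 0L) {
    ov <- IRanges::pintersect(features_gr[S4Vectors::queryHits(hits)],
                              regions_gr[S4Vectors::subjectHits(hits)])
    w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  covered / GenomicRanges::width(features_gr)
}

#' Find escapee genes
#'
#' An escapee is a gene whose body largely evades the hypomethylation of its
#' neighbourhood: its body is less than `body_max` covered by a PMD while
#' both 100-kb flanking regions are each at least `flank_min` covered. Genes
#' whose flanks would be truncated by a chromosome end are disqualified,
#' since the per-flank coverage criterion is ill-defined there.
#'
#' @param genes Feature tibble (`chrom`, `start`, `end`, `name`).
#' @param pmds PMD tibble over the same genome.
#' @param flank Flank width in bp. Default 100000.
#' @param body_max Maximum PMD coverage of the gene body (strict `<`).
#'   Default 0.20.
#' @param flank_min Minimum PMD coverage of each flank (`>=`). Default 0.80.
#' @param chrom_sizes Optional chromosome lengths; defaults to those attached
#'   to `pmds`.
#' @return The subset of `genes` that qualify, with added columns
#'   `body_coverage`, `left_flank_coverage`, `right_flank_coverage`.
#' @export
find_escapees <- function(genes, pmds, flank = 100000, body_max = 0.20,
                          flank_min = 0.80, chrom_sizes = NULL) {
  cs <- as_chrom_sizes(chrom_sizes %||% chrom_sizes(pmds))
  if (nrow(genes) == 0L) {
    out <- genes
    out$body_coverage <- numeric(0)
    out$left_flank_coverage <- numeric(0)
    out$right_flank_coverage <- numeric(0)
    return(out)
  }
  gr_pmd <- intervals_to_granges(pmds)
  gr_body <- intervals_to_granges(genes)
  left <- genes; left$end <- genes$start; left$start <- genes$start - flank
  right <- genes; right$start <- genes$end; right$end <- genes$end + flank

  ok_span <- left$start >= 0
  if (!is.null(cs)) {
    ok_span <- ok_span & right$end <= unname(cs[genes$chrom])
  }
  # clip so GRanges construction stays valid; truncated genes are
  # disqualified below regardless of their coverage
  left$start <- pmax(left$start, 0)
  if (!is.null(cs)) right$end <- pmin(right$end, unname(cs[genes$chrom]))

  body_cov <- coverage_fraction(gr_body, gr_pmd)
  left_cov <- coverage_fraction(intervals_to_granges(left), gr_pmd)
  right_cov <- coverage_fraction(intervals_to_granges(right), gr_pmd)

  out <- genes
  out$body_coverage <- body_cov
  out$left_flank_coverage <- left_cov
  out$right_flank_coverage <- right_cov
  out[ok_span & body_cov < body_max & left_cov >= flank_min &
        right_cov >= flank_min, , drop = FALSE]
}

#' Escapees recurring across samples
#'
#' @param per_sample List of per-sample escapee tibbles (as returned by
#'   [find_escapees()]), each with a `name` column.
#' @param min_samples Minimum number of samples a gene must appear in.
#'   Default 2.
#' @return A feature tibble of recurrent escapees with an `n_samples`
#'   occurrence count; coordinates from the first sample the gene appears in.
#' @export
recurrent_escapees <- function(per_sample, min_samples = 2) {
  stopifnot(length(per_sample) >= 1L)
  all <- dplyr::bind_rows(per_sample, .id = "sample_id")
  if (nrow(all) == 0L) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), n_samples = integer())
    return(out)
  }
  all |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = dplyr::first(.data$start),
                     end = dplyr::first(.data$end),
                     n_samples = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_samples >= min_samples) |>
    dplyr::select("chrom", "start", "end", "name", "n_samples") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Observed/expected enrichment of features in regions
#'
#' Counts features whose midpoint lies inside the regions and tests the
#' count against Binomial(n, p0) with `p0 = region bp / genome bp` by a
#' two-tailed exact binomial test. Midpoint membership avoids double-counting
#' partial overlaps. The ratio is `observed / expected` with
#' `expected = n * p0`.
#'
#' @param features Feature tibble (`chrom`, `start`, `end`).
#' @param regions Region tibble (e.g. a PMD set).
#' @param genome_size Genome size in bp (must be at least the total region
#'   span); defaults to chromosome sizes attached to `regions`.
#' @param class Optional label recorded in the output.
#' @return A one-row tibble: `class`, `n_features`, `observed`, `expected`,
#'   `ratio`, `p_value`, `q_value` (equal to `p_value` for a single class;
#'   see [adjust_enrichment()]).
#' @export
obs_exp_enrichment <- function(features, regions, genome_size = NULL,
                               class = NA_character_) {
  if (nrow(features) == 0L) abort("At least one feature is required.")
  if (is.null(genome_size)) {
    cs <- chrom_sizes(regions)
    if (is.null(cs)) abort("`genome_size` is required when `regions` carries no chromosome sizes.")
    genome_size <- sum(cs)
  }
  gr_reg <- GenomicRanges::reduce(intervals_to_granges(regions))
  region_bp <- sum(as.numeric(GenomicRanges::width(gr_reg)))
  if (region_bp > genome_size) abort("Regions span more basepairs than `genome_size`.")
  p0 <- region_bp / genome_size
  mid <- floor((features$start + features$end) / 2)
  gr_mid <- GenomicRanges::GRanges(features$chrom,
                                   IRanges::IRanges(mid + 1, mid + 1))
  observed <- sum(IRanges::overlapsAny(gr_mid, gr_reg))
  n <- nrow(features)
  expected <- n * p0
  if (p0 == 0) {
    warn("Regions cover 0 bp; ratio is degenerate.")
    ratio <- if (observed > 0) Inf else NaN
    p <- if (observed == 0) 1 else 0
  } else {
    ratio <- observed / expected
    p <- as.numeric(binom.test(observed, n, p0, alternative = "two.sided")$p.value)
  }
  tibble(class = class, n_features = n, observed = observed,
         expected = expected, ratio = ratio, p_value = p, q_value = p)
}

#' Benjamini-Hochberg adjustment across enrichment classes
#'
#' @param results Row-bound enrichment tibbles from [obs_exp_enrichment()] or
#'   [boundary_enrichment()].
#' @return The same tibble with `q_value` recomputed across all rows.
#' @export
adjust_enrichment <- function(results) {
  results$q_value <- p.adjust(results$p_value, method = "BH")
  results
}

#' Enrichment of point features at PMD boundaries
#'
#' Builds symmetric windows (+/- `half_window`) around every PMD start and
#' end, merges overlapping windows, and computes midpoint observed/expected
#' enrichment of the features against the merged windows.
#'
#' @param points Feature tibble (point features; midpoints are used).
#' @param pmds PMD tibble.
#' @param half_window Half-width of the boundary window in bp. Default 2500.
#' @param genome_size Genome size in bp; defaults to chromosome sizes
#'   attached to `pmds`.
#' @param class Optional label recorded in the output.
#' @return A one-row enrichment tibble as in [obs_exp_enrichment()].
#' @export
boundary_enrichment <- function(points, pmds, half_window = 2500,
                                genome_size = NULL, class = NA_character_) {
  cs <- chrom_sizes(pmds)
  if (is.null(genome_size)) {
    if (is.null(cs)) abort("`genome_size` is required when `pmds` carries no chromosome sizes.")
    genome_size <- sum(cs)
  }
  edges <- c(pmds$start, pmds$end)
  chroms <- c(pmds$chrom, pmds$chrom)
  wins <- tibble(chrom = chroms,
                 start = pmax(edges - half_window, 0),
                 end = edges + half_window)
  if (!is.null(cs)) wins$end <- pmin(wins$end, unname(cs[wins$chrom]))
  wins <- wins[wins$end > wins$start, , drop = FALSE]
  merged <- granges_to_intervals(GenomicRanges::reduce(intervals_to_granges(wins)))
  obs_exp_enrichment(points, merged, genome_size = genome_size, class = class)
}
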