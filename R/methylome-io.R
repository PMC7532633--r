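# Reading and writing per-CpG methylation tables and interval output.
#
# The on-disk format is the 6-column whitespace-delimited per-CpG table used
# throughout the MethPipe ecosystem: chrom, position, strand, context,
# methylation level (fraction of reads methylated) and read coverage.
# Positions are interpreted as 0-based single-base coordinates and all
# intervals in this package are 0-based half-open, matching BED.

#' Read a chrom.sizes file
#'
#' @param path Path to a two-column (chromosome, length) whitespace-delimited
#'   file, as produced by `samtools faidx` post-processing or UCSC fetchChromSizes.
#' @return A tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.table(path, header = FALSE, col.names = c("chrom", "size"),
                  colClasses = c("character", "numeric"))
  as_tibble(d)
}

#' Read a per-CpG methylation count table
#'
#' Parses a methcounts-style 6-column table (chrom, pos, strand, context,
#' level, coverage) into a validated methylome tibble. The methylated read
#' count is recovered once, at read time, as `round(level * coverage)` and is
#' the single source of truth for all downstream counting.
#'
#' Sites with zero coverage are retained: they contribute to per-bin CpG
#' counts but carry no read-level observations. Their level is stored as 0 by
#' convention. Input is assumed to be symmetric-CpG merged, as produced by
#' standard pipelines; strands are kept as given.
#'
#' @param path Path to the methylation table.
#' @param chrom_sizes Chromosome lengths: a named numeric vector, a
#'   two-column data frame, or a path to a chrom.sizes file. Must cover every
#'   chromosome present in the file.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `context`,
#'   `level`, `coverage`, `meth` (recovered methylated read count), carrying
#'   the chromosome sizes as an attribute (see [chrom_sizes()]).
#' @export
read_methcounts <- function(path, chrom_sizes) {
  cs <- as_chrom_sizes(chrom_sizes)
  if (is.null(cs)) abort("`chrom_sizes` is required.")

  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) {
    meth <- tibble(chrom = character(), pos = numeric(), strand = character(),
                   context = character(), level = numeric(),
                   coverage = numeric(), meth = numeric())
    chrom_sizes(meth) <- cs
    return(meth)
  }

  d <- tryCatch(
    read.table(path, header = FALSE,
               col.names = c("chrom", "pos", "strand", "context", "level", "coverage"),
               colClasses = c("character", "numeric", "character", "character",
                              "numeric", "numeric")),
    error = function(e) abort(sprintf("Failed to parse '%s': %s", path, conditionMessage(e)))
  )
  d <- as_tibble(d)

  bad <- which(!is.finite(d$level) | d$level < 0 | d$level > 1)
  if (length(bad) > 0L) {
    abort(sprintf("Parse error at line %d: methylation level %s outside [0, 1].",
                  bad[1L], format(d$level[bad[1L]])))
  }
  bad <- which(!is.finite(d$coverage) | d$coverage < 0 | d$coverage != round(d$coverage))
  if (length(bad) > 0L) {
    abort(sprintf("Parse error at line %d: coverage %s is not a non-negative integer.",
                  bad[1L], format(d$coverage[bad[1L]])))
  }

  missing_chrom <- setdiff(unique(d$chrom), names(cs))
  if (length(missing_chrom) > 0L) {
    abort(sprintf("Chromosome(s) absent from chrom_sizes: %s",
                  paste(missing_chrom, collapse = ", ")))
  }
  if (any(d$pos < 0 | d$pos >= cs[d$chrom])) {
    abort("Site position outside its chromosome length.")
  }

  for (chr in unique(d$chrom)) {
    p <- d$pos[d$chrom == chr]
    if (is.unsorted(p, strictly = TRUE)) {
      abort(sprintf("Positions not strictly increasing on %s.", chr))
    }
  }

  d$level[d$coverage == 0] <- 0
  d$meth <- round(d$level * d$coverage)
  chrom_sizes(d) <- cs
  d
}

#' Write a methylome back to methcounts format
#'
#' Levels are printed at 6 decimals, which round-trips exactly with
#' [read_methcounts()] for any coverage the format can represent.
#'
#' @param meth A methylome tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_methcounts <- function(meth, path) {
  lines <- sprintf("%s\t%d\t%s\t%s\t%.6f\t%d",
                   meth$chrom, as.integer(meth$pos), meth$strand,
                   meth$context, meth$level, as.integer(meth$coverage))
  writeLines(lines, path)
  invisible(path)
}

#' Write PMD calls as BED6
#'
#' Emits one line per domain: chrom, start, end (0-based half-open), name,
#' score and strand `"."`. The score column carries the mean posterior
#' probability of the PMD state over the domain's bins, scaled to an integer
#' in [0, 1000].
#'
#' @param pmds A PMD tibble (sorted, non-overlapping, half-open per chromosome).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pmds_bed <- function(pmds, path) {
  check_intervals_sorted(pmds, "PMDs")
  if (nrow(pmds) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  nm <- if ("name" %in% names(pmds)) pmds$name else sprintf("PMD_%d", seq_len(nrow(pmds)))
  score <- if ("score" %in% names(pmds)) as.integer(round(pmax(0, pmin(1, pmds$score)) * 1000)) else 0L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   pmds$chrom, as.integer(pmds$start), as.integer(pmds$end), nm, score)
  writeLines(lines, path)
  invisible(path)
}

#' Read an interval (BED) file into a feature tibble
#'
#' Only the first 3-6 columns are used: chrom, start, end, optional name,
#' score and strand.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  d <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  out <- tibble(chrom = as.character(d[[1L]]), start = as.numeric(d[[2L]]),
                end = as.numeric(d[[3L]]))
  if (ncol(d) >= 4L) out$name <- as.character(d[[4L]])
  if (ncol(d) >= 5L) out$score <- suppressWarnings(as.numeric(d[[5L]]))
  if (ncol(d) >= 6L) out$strand <- as.character(d[[6L]])
  if (any(out$end <= out$start)) abort("BED intervals must satisfy end > start.")
  out
}

#' Write a per-window track as bedGraph
#'
#' @param track A tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output file path.
#' @param value Name of the column to write as the bedGraph value.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, value = "n_pmd_samples") {
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                   as.integer(track$end), format(track[[value]], trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
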