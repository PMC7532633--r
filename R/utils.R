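# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Normalise the many acceptable chrom-sizes representations (named numeric
# vector, two-column data frame, path to a chrom.sizes file) into a named
# numeric vector.
as_chrom_sizes <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- read_chrom_sizes(x)
  }
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2L)
    out <- as.numeric(x[[2L]])
    names(out) <- as.character(x[[1L]])
    return(out)
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  abort("`chrom_sizes` must be a named numeric vector, a two-column data frame, or a chrom.sizes file path.")
}

#' Retrieve the chromosome sizes attached to a pmdscan table
#'
#' Methylome, bin and PMD tables produced by this package carry their genome's
#' chromosome lengths as an attribute so downstream steps need not be handed
#' them again.
#'
#' @param x A tibble produced by [read_methcounts()], [simulate_methylome()],
#'   [bin_methylome()] or the segmentation functions.
#' @return A named numeric vector of chromosome lengths in basepairs, or
#'   `NULL` if none are attached.
#' @export
chrom_sizes <- function(x) attr(x, "chrom_sizes", exact = TRUE)

`chrom_sizes<-` <- function(x, value) {
  attr(x, "chrom_sizes") <- value
  x
}

need_chrom_sizes <- function(x, chrom_sizes = NULL) {
  cs <- as_chrom_sizes(chrom_sizes %||% attr(x, "chrom_sizes", exact = TRUE))
  if (is.null(cs)) {
    abort("Chromosome sizes are required but neither supplied nor attached to the input.")
  }
  cs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# PMD/feature interval tables -> GRanges (half-open intervals become the
# closed 1-based convention GRanges uses internally; widths are preserved).
intervals_to_granges <- function(x) {
  if (nrow(x) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_intervals <- function(gr) {
  if (length(gr) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

check_intervals_sorted <- function(x, what = "intervals") {
  if (nrow(x) < 2L) return(invisible(TRUE))
  by_chrom <- split(x, x$chrom)
  for (d in by_chrom) {
    if (nrow(d) < 2L) next
    if (is.unsorted(d$start)) {
      abort(sprintf("%s must be sorted by start within each chromosome.", what))
    }
    if (any(d$start[-1L] < d$end[-nrow(d)])) {
      abort(sprintf("%s must be non-overlapping within each chromosome.", what))
    }
  }
  invisible(TRUE)
}
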