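# Post-processing of decoded domains: single-basepair boundary sharpening
# and removal of small domains by a shuffle-based empirical FDR.

#' Sharpen domain boundaries to single-basepair resolution
#'
#' Decoded domain edges sit on bin boundaries. For each edge, within a window
#' spanning one bin outside and one bin inside the edge, every inter-CpG
#' breakpoint is scored as the summed beta-binomial log-likelihood of the
#' outside-side sites under the background parameters plus the inside-side
#' sites under the PMD parameters; the maximising breakpoint becomes the new
#' edge, placed at the first CpG position on the PMD side. Edges therefore
#' move at most one bin-width, domains never invert and never cross their
#' neighbours. An edge whose window contains no CpG sites is left at the bin
#' boundary (with a warning).
#'
#' @param pmds PMD tibble from [call_domains()].
#' @param meth The methylome the domains were derived from.
#' @param params The trained `pmd_hmm_params`.
#' @param window_bins Window half-width in bins on each side of the edge.
#'   Default 1.
#' @return The sharpened PMD tibble (attribute `sharpened = TRUE`).
#' @export
sharpen_boundaries <- function(pmds, meth, params, window_bins = 1) {
  bin_size <- attr(pmds, "bin_size", exact = TRUE)
  if (is.null(bin_size)) abort("`pmds` must carry a bin_size attribute.")
  if (nrow(pmds) == 0L) {
    attr(pmds, "sharpened") <- TRUE
    return(pmds)
  }
  w <- window_bins * bin_size
  cs <- chrom_sizes(pmds) %||% chrom_sizes(meth)
  out <- pmds
  n_empty <- 0L

  a_p <- params$emis$pmd$alpha;  b_p <- params$emis$pmd$beta
  a_b <- params$emis$background$alpha; b_b <- params$emis$background$beta

  meth_by_chrom <- split(meth[, c("pos", "meth", "coverage")], meth$chrom)

  for (chr in unique(pmds$chrom)) {
    rows <- which(pmds$chrom == chr)
    sites <- meth_by_chrom[[chr]]
    if (is.null(sites)) sites <- tibble(pos = numeric(), meth = numeric(), coverage = numeric())
    chr_len <- if (!is.null(cs) && chr %in% names(cs)) cs[[chr]] else Inf

    for (j in seq_along(rows)) {
      i <- rows[j]
      d_start <- out$start[i]; d_end <- out$end[i]
      prev_end <- if (j > 1L) out$end[rows[j - 1L]] else 0
      next_start <- if (j < length(rows)) pmds$start[rows[j + 1L]] else chr_len

      # left edge: background on the left, PMD on the right
      lo <- max(d_start - w, prev_end, 0)
      hi <- min(d_start + w, d_end)
      res <- best_breakpoint(sites, lo, hi, pmd_side = "right",
                             a_p, b_p, a_b, b_b)
      if (is.null(res)) {
        n_empty <- n_empty + 1L
      } else {
        d_start <- res
      }

      # right edge: PMD on the left, background on the right
      lo <- max(d_end - w, d_start + 1)
      hi <- min(d_end + w, next_start, chr_len)
      res <- best_breakpoint(sites, lo, hi, pmd_side = "left",
                             a_p, b_p, a_b, b_b)
      if (is.null(res)) {
        n_empty <- n_empty + 1L
      } else {
        d_end <- res
      }

      if (d_start < d_end) {
        out$start[i] <- d_start
        out$end[i] <- d_end
      }
    }
  }
  if (n_empty > 0L) {
    warn(sprintf("%d domain edge(s) had no CpGs in their window; left at bin boundaries.",
                 n_empty))
  }
  attr(out, "sharpened") <- TRUE
  out
}

# Scan every inter-CpG breakpoint in [lo, hi) and return the basepair
# position of the best edge, or NULL if the window holds no CpGs. The edge is
# placed at the first CpG on the PMD side of the winning breakpoint; if every
# site is assigned to the non-PMD side, the edge moves to the window end on
# the PMD side.
best_breakpoint <- function(sites, lo, hi, pmd_side, a_p, b_p, a_b, b_b) {
  if (hi <= lo) return(NULL)
  idx <- which(sites$pos >= lo & sites$pos < hi)
  if (length(idx) == 0L) return(NULL)
  pos <- sites$pos[idx]
  ll_p <- betabinom_logpmf(sites$meth[idx], sites$coverage[idx], a_p, b_p)
  ll_b <- betabinom_logpmf(sites$meth[idx], sites$coverage[idx], a_b, b_b)
  K <- length(idx)
  # breakpoint k = number of sites on the left side, k in 0..K
  cum_p <- c(0, cumsum(ll_p))
  cum_b <- c(0, cumsum(ll_b))
  if (pmd_side == "right") {
    # left side is background, right side is PMD; the new start is the first
    # PMD-side CpG, or the window end if every site is background
    score <- cum_b[1:(K + 1)] + (cum_p[K + 1] - cum_p[1:(K + 1)])
    k <- which.max(score) - 1L
    if (k < K) pos[k + 1L] else hi
  } else {
    # left side is PMD, right side is background; the (exclusive) new end
    # falls just after the last PMD-side CpG, or at the window start if every
    # site is background
    score <- cum_p[1:(K + 1)] + (cum_b[K + 1] - cum_b[1:(K + 1)])
    k <- which.max(score) - 1L
    if (k > 0L) pos[k] + 1 else lo
  }
}

#' Build a null segment-size distribution from a shuffled methylome
#'
#' Permutes the per-bin observations `(m, n, n_cpgs)` uniformly at random
#' across all bins genome-wide (coordinates stay fixed), decodes the shuffled
#' sequence with the already-trained parameters (no retraining) and pools the
#' resulting segment sizes over shuffles. Shuffling preserves the marginal
#' observation distribution while destroying spatial structure, so surviving
#' segments reflect what the decoder produces by chance.
#'
#' On a full-size genome a single shuffle yields thousands of null segments.
#' On small genomes (or large bins) it may yield too few to resolve the
#' target FDR level -- the empirical p-value is floored at
#' `1 / (1 + #null sizes)` -- so shuffles beyond `n_shuffles` are pooled
#' until the null holds at least `min_null` segments (bounded by
#' `max_shuffles`).
#'
#' @param bins Bin tibble the model was trained on.
#' @param params Trained `pmd_hmm_params`.
#' @param n_shuffles Minimum number of independent shuffles to pool.
#'   Default 1.
#' @param seed Integer seed controlling the permutations.
#' @param cutoff Posterior cutoff used on the shuffled decode. Default 0.5.
#' @param min_null Minimum pooled null size before stopping. Default 0
#'   (stop after `n_shuffles`).
#' @param max_shuffles Hard cap on pooled shuffles. Default 50.
#' @return A tibble with one column `size` (basepairs), plus attributes
#'   `n_shuffles`, `seed` and `empty` (TRUE when no null segment was found).
#' @export
build_null <- function(bins, params, n_shuffles = 1, seed = NULL, cutoff = 0.5,
                       min_null = 0, max_shuffles = 50) {
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1.")
  done <- 0L
  sizes <- with_seed(seed, {
    acc <- list()
    repeat {
      done <- done + 1L
      perm <- sample.int(nrow(bins))
      shuffled <- bins
      shuffled$m <- bins$m[perm]
      shuffled$n <- bins$n[perm]
      shuffled$n_cpgs <- bins$n_cpgs[perm]
      track <- posterior_decode(shuffled, params)
      dom <- call_domains(track, cutoff = cutoff)
      acc[[done]] <- dom$end - dom$start
      n_acc <- length(unlist(acc))
      if (done >= n_shuffles && (n_acc >= min_null || done >= max_shuffles)) break
    }
    unlist(acc)
  })
  out <- tibble(size = as.numeric(sizes))
  attr(out, "n_shuffles") <- done
  attr(out, "seed") <- seed
  attr(out, "empty") <- nrow(out) == 0L
  out
}

#' Remove small domains by empirical false-discovery control
#'
#' Each domain receives the empirical upper-tail p-value
#' `p = (1 + #null sizes >= domain size) / (1 + #null sizes)` against the
#' shuffled-methylome size distribution, Benjamini-Hochberg adjustment is
#' applied across domains, and domains with `q > q_cutoff` are removed. The
#' +1 pseudocount keeps p strictly positive. An empty null retains all
#' domains with a warning.
#'
#' @param pmds PMD tibble.
#' @param null Null size distribution from [build_null()].
#' @param q_cutoff FDR level. Default 0.01.
#' @return The filtered PMD tibble with added columns `p_empirical` and
#'   `q_value` (attribute `fdr_filtered = TRUE`).
#' @export
fdr_filter <- function(pmds, null, q_cutoff = 0.01) {
  if (nrow(pmds) == 0L) {
    attr(pmds, "fdr_filtered") <- TRUE
    return(pmds)
  }
  null_sizes <- if (is.data.frame(null)) null$size else as.numeric(null)
  if (length(null_sizes) == 0L) {
    warn("Empty null distribution; all domains retained.")
    pmds$p_empirical <- NA_real_
    pmds$q_value <- NA_real_
    attr(pmds, "fdr_filtered") <- TRUE
    return(pmds)
  }
  sizes <- pmds$end - pmds$start
  p <- vapply(sizes, function(s) (1 + sum(null_sizes >= s)) / (1 + length(null_sizes)),
              numeric(1))
  q <- p.adjust(p, method = "BH")
  pmds$p_empirical <- p
  pmds$q_value <- q
  out <- pmds[q <= q_cutoff, , drop = FALSE]
  for (a in c("bin_size", "sharpened", "chrom_sizes")) {
    attr(out, a) <- attr(pmds, a, exact = TRUE)
  }
  attr(out, "fdr_filtered") <- TRUE
  out
}
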