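# Synthetic methylome simulator with planted PMD architecture.
#
# The generative model mirrors the segmentation model: hypomethylated
# domains are planted as non-overlapping intervals until a target genome
# fraction is reached, CpG positions follow geometric inter-site gaps,
# per-site coverage is Poisson, and methylated counts are beta-binomial
# under the site's true state. Everything is deterministic per seed.

#' Simulate a methylome with planted partially methylated domains
#'
#' Domain sizes are drawn from a shifted exponential (mean `domain_size_mean`,
#' floored at `domain_size_min`) until the target fraction of the genome is
#' reached, then placed without overlap with a minimum inter-domain gap.
#' Each CpG site draws its own methylation propensity from the state's beta
#' distribution and its methylated count binomially, i.e. counts are
#' beta-binomial with the same per-state overdispersion the caller models.
#'
#' The defaults emulate a deeply sequenced PMD-containing cancer methylome:
#' 35% of a 10-Mb genome in domains of mean 150 kb, PMD mean methylation
#' 0.45 against a 0.85 background, both at precision `alpha + beta = 10`,
#' one CpG per ~100 bp and 30x mean site coverage.
#'
#' @param chrom_sizes Named vector of chromosome lengths. Default one 10-Mb
#'   chromosome.
#' @param target_fraction Fraction of the genome to plant as PMD, in
#'   [0, 0.95]. Default 0.35.
#' @param domain_size_mean,domain_size_min Domain size distribution (bp).
#'   Defaults 150000 and 10000.
#' @param min_gap Minimum gap between planted domains (bp). Default 20000.
#' @param pmd_mean,background_mean Per-state mean methylation levels.
#'   Defaults 0.45 and 0.85.
#' @param precision Beta precision `alpha + beta` of both states. Default 10.
#' @param cpg_gap_mean Mean inter-CpG gap (bp, geometric). Default 100.
#' @param depth Mean per-site read coverage (Poisson). Default 30.
#' @param seed Integer seed; same seed, same output.
#' @return A list with `methylome` (tibble as from [read_methcounts()]),
#'   `truth` (planted domain tibble) and `config`.
#' @export
simulate_methylome <- function(chrom_sizes = c(chr1 = 1e7),
                               target_fraction = 0.35,
                               domain_size_mean = 150000,
                               domain_size_min = 10000,
                               min_gap = 20000,
                               pmd_mean = 0.45, background_mean = 0.85,
                               precision = 10,
                               cpg_gap_mean = 100, depth = 30, seed = 1) {
  cs <- as_chrom_sizes(chrom_sizes)
  if (target_fraction < 0 || target_fraction > 0.95) {
    abort("`target_fraction` must be in [0, 0.95].")
  }
  stopifnot(pmd_mean > 0, pmd_mean < 1, background_mean > 0, background_mean < 1,
            precision > 0, cpg_gap_mean > 0, depth >= 0)
  config <- list(chrom_sizes = cs, target_fraction = target_fraction,
                 domain_size_mean = domain_size_mean,
                 domain_size_min = domain_size_min, min_gap = min_gap,
                 pmd_mean = pmd_mean, background_mean = background_mean,
                 precision = precision, cpg_gap_mean = cpg_gap_mean,
                 depth = depth, seed = seed)

  res <- with_seed(seed, {
    truth <- dplyr::bind_rows(lapply(names(cs), function(chr) {
      plant_domains(cs[[chr]], target_fraction, domain_size_mean,
                    domain_size_min, min_gap, chr)
    }))
    meth <- dplyr::bind_rows(lapply(names(cs), function(chr) {
      sample_sites(chr, cs[[chr]], truth[truth$chrom == chr, , drop = FALSE],
                   pmd_mean, background_mean, precision, cpg_gap_mean, depth)
    }))
    list(truth = truth, meth = meth)
  })

  meth <- res$meth
  chrom_sizes(meth) <- cs
  truth <- res$truth
  chrom_sizes(truth) <- cs
  list(methylome = meth, truth = truth, config = config)
}

# Draw domain sizes until the target bp is reached, then scatter them along
# the chromosome with dirichlet-like gaps of at least min_gap.
plant_domains <- function(len, target_fraction, size_mean, size_min,
                          min_gap, chr) {
  target_bp <- target_fraction * len
  if (target_bp <= 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  sizes <- numeric(0)
  while (sum(sizes) < target_bp) {
    sizes <- c(sizes, size_min + rexp(1, rate = 1 / max(size_mean - size_min, 1)))
  }
  # trim the last domain so the planted fraction lands on target
  overshoot <- sum(sizes) - target_bp
  sizes[length(sizes)] <- max(sizes[length(sizes)] - overshoot, size_min)
  sizes <- round(sizes)
  k <- length(sizes)
  free <- len - sum(sizes) - (k + 1) * min_gap
  if (free < 0) {
    # small chromosomes: shrink the guard gap rather than fail
    min_gap <- max(floor((len - sum(sizes)) / (k + 1)), 0)
    free <- len - sum(sizes) - (k + 1) * min_gap
  }
  if (free < 0) {
    abort("Planted domains do not fit: lower `target_fraction`.")
  }
  u <- runif(k + 1)
  gaps <- min_gap + free * u / sum(u)
  starts <- round(cumsum(gaps[seq_len(k)]) + cumsum(c(0, sizes[-k])))
  tibble(chrom = chr, start = starts, end = starts + sizes)
}

sample_sites <- function(chr, len, truth, pmd_mean, background_mean,
                         precision, cpg_gap_mean, depth) {
  n_exp <- ceiling(len / cpg_gap_mean * 1.3) + 100
  gaps <- rgeom(n_exp, prob = 1 / cpg_gap_mean) + 1
  pos <- cumsum(gaps)
  while (pos[length(pos)] <= len) {
    extra <- rgeom(1000, prob = 1 / cpg_gap_mean) + 1
    pos <- c(pos, pos[length(pos)] + cumsum(extra))
  }
  pos <- pos[pos < len]
  n_sites <- length(pos)

  in_pmd <- rep(FALSE, n_sites)
  if (nrow(truth) > 0L) {
    idx <- findInterval(pos, truth$start)
    hit <- idx >= 1L
    in_pmd[hit] <- pos[hit] < truth$end[idx[hit]]
  }

  coverage <- rpois(n_sites, depth)
  mu <- ifelse(in_pmd, pmd_mean, background_mean)
  p_site <- rbeta(n_sites, mu * precision, (1 - mu) * precision)
  m <- rbinom(n_sites, coverage, p_site)
  tibble(chrom = chr, pos = as.numeric(pos), strand = "+", context = "CpG",
         level = ifelse(coverage > 0, m / coverage, 0),
         coverage = as.numeric(coverage), meth = as.numeric(m),
         true_pmd = in_pmd)
}

#' Simulate a non-PMD-containing methylome
#'
#' The same generator, but the hypomethylated intervals are small and rare
#' -- emulating CpG-island/promoter hypomethylation rather than PMDs. Under
#' the defaults (2-kb features covering 2% of the genome) an end-to-end
#' segmentation classifies the sample as non-PC.
#'
#' @inheritParams simulate_methylome
#' @param feature_size Mean hypomethylated feature size (bp). Default 2000.
#' @param feature_fraction Genome fraction in such features. Default 0.02.
#' @return As [simulate_methylome()].
#' @export
simulate_nonpc <- function(chrom_sizes = c(chr1 = 1e7),
                           feature_size = 2000, feature_fraction = 0.02,
                           pmd_mean = 0.1, background_mean = 0.85,
                           precision = 10, cpg_gap_mean = 100, depth = 30,
                           seed = 1) {
  simulate_methylome(chrom_sizes = chrom_sizes,
                     target_fraction = feature_fraction,
                     domain_size_mean = feature_size,
                     domain_size_min = max(feature_size / 4, 200),
                     min_gap = max(feature_size, 2000),
                     pmd_mean = pmd_mean, background_mean = background_mean,
                     precision = precision, cpg_gap_mean = cpg_gap_mean,
                     depth = depth, seed = seed)
}

#' Write a simulated sample to disk
#'
#' Emits the methcounts table, a chrom.sizes file and the planted truth as
#' BED, all plain text.
#'
#' @param sim Output of [simulate_methylome()] or [simulate_nonpc()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix. Default `"sim"`.
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulated <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cs <- chrom_sizes(sim$methylome)
  paths <- list(
    methcounts = file.path(dir, paste0(prefix, ".meth")),
    chrom_sizes = file.path(dir, paste0(prefix, ".chrom.sizes")),
    truth = file.path(dir, paste0(prefix, ".truth.bed"))
  )
  write_methcounts(sim$methylome, paths$methcounts)
  writeLines(sprintf("%s\t%d", names(cs), as.integer(cs)), paths$chrom_sizes)
  truth <- sim$truth
  truth$name <- sprintf("true_PMD_%d", seq_len(nrow(truth)))
  truth$score <- 1
  write_pmds_bed(truth, paths$truth)
  invisible(paths)
}
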