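default_params <- function() hmm_params()

test_that("a clean methylation step is sharpened to the exact breakpoint", {
  # left domain edge at 1000; 10 background CpGs then 10 PMD CpGs in the
  # window, step at position 1000 -> breakpoint at first PMD-side CpG
  pos <- seq(50, 1950, by = 100)
  lev <- c(rep(0.85, 10), rep(0.45, 10))
  meth <- make_methylome("chr1", pos, lev, 20, c(chr1 = 4000))
  pmds <- tibble::tibble(chrom = "chr1", start = 1000, end = 3000,
                         name = "PMD_1", score = 1, n_bins = 2L)
  attr(pmds, "bin_size") <- 1000
  attr(pmds, "chrom_sizes") <- c(chr1 = 4000)
  sh <- suppressWarnings(sharpen_boundaries(pmds, meth, default_params()))
  expect_equal(sh$start, 1050)  # first CpG of the hypomethylated run

  # a step placed off the bin boundary is still found exactly
  lev2 <- c(rep(0.85, 7), rep(0.45, 13))
  meth2 <- make_methylome("chr1", pos, lev2, 20, c(chr1 = 4000))
  sh2 <- suppressWarnings(sharpen_boundaries(pmds, meth2, default_params()))
  expect_equal(sh2$start, 750)
})

test_that("an edge window without CpGs leaves the boundary unchanged", {
  meth <- make_methylome("chr1", 3500, 0.45, 20, c(chr1 = 8000))
  pmds <- tibble::tibble(chrom = "chr1", start = 1000, end = 3000,
                         name = "PMD_1", score = 1, n_bins = 2L)
  attr(pmds, "bin_size") <- 1000
  attr(pmds, "chrom_sizes") <- c(chr1 = 8000)
  expect_warning(sh <- sharpen_boundaries(pmds, meth, default_params()),
                 "no CpGs")
  expect_equal(sh$start, 1000)
})

test_that("a uniformly methylated start window shrinks the domain", {
  pos <- seq(50, 1950, by = 100)
  meth <- make_methylome("chr1", pos, 0.85, 20, c(chr1 = 6000))
  pmds <- tibble::tibble(chrom = "chr1", start = 1000, end = 5000,
                         name = "PMD_1", score = 1, n_bins = 4L)
  attr(pmds, "bin_size") <- 1000
  attr(pmds, "chrom_sizes") <- c(chr1 = 6000)
  sh <- suppressWarnings(sharpen_boundaries(pmds, meth, default_params()))
  expect_gt(sh$start, 1000)
})

test_that("sharpening stays within one bin and never creates overlaps", {
  sim <- simulate_methylome(chrom_sizes = c(chr1 = 3e6), seed = 13)
  bins <- bin_methylome(sim$methylome, 1000)
  fit <- baum_welch(bins)
  pmds <- call_domains(fit)
  sh <- suppressWarnings(sharpen_boundaries(pmds, sim$methylome, fit$params))
  expect_true(all(abs(sh$start - pmds$start) <= 1000))
  expect_true(all(abs(sh$end - pmds$end) <= 1000))
  expect_true(all(sh$end > sh$start))
  expect_no_error(check_sorted <- pmdscan:::check_intervals_sorted(sh))
})

test_that("sharpening reduces the boundary error on planted domains", {
  errs <- vapply(1:12, function(s) {
    sim <- simulate_methylome(chrom_sizes = c(chr1 = 3e6), seed = 300 + s)
    bins <- bin_methylome(sim$methylome, 1000)
    fit <- baum_welch(bins)
    pmds <- call_domains(fit)
    sh <- suppressWarnings(sharpen_boundaries(pmds, sim$methylome, fit$params))
    c(before = median(edge_errors(pmds, sim$truth)),
      after = median(edge_errors(sh, sim$truth)))
  }, numeric(2))
  expect_lt(median(errs["after", ]), median(errs["before", ]))
})

test_that("the shuffled null yields smaller segments than structured input", {
  sim <- simulate_methylome(chrom_sizes = c(chr1 = 3e6), seed = 17)
  bins <- bin_methylome(sim$methylome, 1000)
  fit <- baum_welch(bins)
  pmds <- call_domains(fit)
  null <- build_null(bins, fit$params, seed = 17, min_null = 100)
  expect_gt(nrow(null), 0)
  expect_lt(median(null$size), median(pmds$end - pmds$start))
  expect_error(build_null(bins, fit$params, n_shuffles = 0), "n_shuffles")
})

test_that("empirical FDR keeps large domains and drops null-sized ones", {
  null <- tibble::tibble(size = rep(1000, 1000))
  pmds <- tibble::tibble(chrom = "chr1", start = c(0, 600000),
                         end = c(500000, 602000),
                         name = c("a", "b"), score = c(1, 1), n_bins = c(500L, 2L))
  filt <- fdr_filter(pmds, null, q_cutoff = 0.01)
  # hand-computed: both sizes exceed every null size -> p = 1/1001, q < 0.01
  expect_equal(filt$name, c("a", "b"))
  expect_equal(filt$p_empirical, rep(1 / 1001, 2))

  # null dominating every observed size removes everything
  null_big <- tibble::tibble(size = rep(1e6, 1000))
  expect_equal(nrow(fdr_filter(pmds, null_big, 0.01)), 0L)

  # null below every observed size keeps everything at p = 1/(1+N)
  null_small <- tibble::tibble(size = rep(10, 99))
  kept <- fdr_filter(pmds, null_small, 0.05)
  expect_equal(kept$p_empirical, rep(1 / 100, 2))
  expect_equal(nrow(kept), 2L)
})

test_that("FDR output is a subset with size-monotone p-values", {
  set.seed(3)
  null <- tibble::tibble(size = sample(1000 * (1:50), 300, replace = TRUE))
  sizes <- c(2000, 10000, 30000, 80000, 200000)
  pmds <- tibble::tibble(chrom = "chr1",
                         start = cumsum(c(0, sizes[-5] + 10000)),
                         end = cumsum(c(0, sizes[-5] + 10000)) + sizes,
                         name = letters[1:5], score = 1, n_bins = 1L)
  filt <- fdr_filter(pmds, null, q_cutoff = 0.2)
  expect_true(all(filt$name %in% pmds$name))
  p <- vapply(sizes, function(s) (1 + sum(null$size >= s)) / (1 + nrow(null)),
              numeric(1))
  expect_true(all(diff(p) <= 0))

  expect_warning(all_kept <- fdr_filter(pmds, tibble::tibble(size = numeric())),
                 "Empty null")
  expect_equal(nrow(all_kept), nrow(pmds))
})
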