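genes_fix <- function() {
  tibble::tibble(chrom = "chr1", start = 300000, end = 320000, name = "geneA")
}

# A PMD landscape where geneA's body is uncovered but both 100-kb flanks are
# fully covered.
escapee_pmds <- function() {
  p <- tibble::tibble(chrom = "chr1", start = c(150000, 320000),
                      end = c(300000, 500000),
                      name = c("PMD_1", "PMD_2"), score = 1, n_bins = 1L)
  attr(p, "chrom_sizes") <- c(chr1 = 1e6)
  p
}

test_that("the definitional escapee case is detected", {
  esc <- find_escapees(genes_fix(), escapee_pmds())
  expect_equal(esc$name, "geneA")
  expect_equal(esc$body_coverage, 0)
  expect_equal(esc$left_flank_coverage, 1)
  expect_equal(esc$right_flank_coverage, 1)
})

test_that("genes inside PMDs or with weak flanks are not escapees", {
  inside <- tibble::tibble(chrom = "chr1", start = 400000, end = 420000,
                           name = "geneB")
  expect_equal(nrow(find_escapees(inside, escapee_pmds())), 0L)

  # left flank 85%, right flank 50%: per-flank threshold fails
  p <- tibble::tibble(chrom = "chr1", start = c(215000, 320000),
                      end = c(300000, 370000),
                      name = c("a", "b"), score = 1, n_bins = 1L)
  attr(p, "chrom_sizes") <- c(chr1 = 1e6)
  g <- tibble::tibble(chrom = "chr1", start = 300000, end = 320000,
                      name = "geneC")
  out <- find_escapees(g, p)
  expect_equal(nrow(out), 0L)
})

test_that("flanks truncated by chromosome ends disqualify a gene", {
  g <- tibble::tibble(chrom = "chr1", start = 50000, end = 70000, name = "edge")
  p <- tibble::tibble(chrom = "chr1", start = c(0, 70000), end = c(50000, 250000),
                      name = c("a", "b"), score = 1, n_bins = 1L)
  attr(p, "chrom_sizes") <- c(chr1 = 1e6)
  expect_equal(nrow(find_escapees(g, p)), 0L)
})

test_that("escapee status is invariant to splitting a PMD into abutting pieces", {
  p2 <- escapee_pmds()
  split <- tibble::tibble(chrom = "chr1",
                          start = c(150000, 200000, 320000, 400000),
                          end = c(200000, 300000, 400000, 500000),
                          name = paste0("p", 1:4), score = 1, n_bins = 1L)
  attr(split, "chrom_sizes") <- c(chr1 = 1e6)
  expect_equal(find_escapees(genes_fix(), p2)$name,
               find_escapees(genes_fix(), split)$name)
})

test_that("recurrence filtering counts distinct samples per gene", {
  g1 <- tibble::tibble(chrom = "chr1", start = 1, end = 10, name = c("a", "b"))
  g2 <- tibble::tibble(chrom = "chr1", start = 1, end = 10, name = "a")
  g3 <- tibble::tibble(chrom = "chr1", start = 1, end = 10, name = "c")
  rec <- recurrent_escapees(list(g1, g2, g3), min_samples = 2)
  expect_equal(rec$name, "a")
  expect_equal(rec$n_samples, 2L)

  all_of_them <- recurrent_escapees(list(g1, g2, g3), min_samples = 1)
  expect_setequal(all_of_them$name, c("a", "b", "c"))
})

test_that("observed/expected enrichment uses midpoints and the exact binomial test", {
  # all 100 features inside regions covering 10% of the genome
  feats <- tibble::tibble(chrom = "chr1", start = seq(0, 99000, by = 1000),
                          end = seq(0, 99000, by = 1000) + 500)
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5)
  res <- obs_exp_enrichment(feats, regions, genome_size = 1e6)
  expect_equal(res$ratio, 10)
  expect_lt(res$p_value, 1e-6)
  # oracle: exact two-sided binomial tail
  expect_equal(res$p_value, binom.test(100, 100, 0.1)$p.value, tolerance = 1e-12)

  # regions = whole genome: ratio 1, p = 1
  whole <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  res2 <- obs_exp_enrichment(feats, whole, genome_size = 1e6)
  expect_equal(res2$ratio, 1)
  expect_equal(res2$p_value, 1)

  # degenerate zero-width regions
  expect_warning(
    res3 <- obs_exp_enrichment(feats, regions[0, ], genome_size = 1e6),
    "0 bp")
  expect_true(is.nan(res3$ratio) || is.infinite(res3$ratio))

  expect_error(obs_exp_enrichment(feats[0, ], regions, genome_size = 1e6),
               "feature")
})

test_that("boundary windows merge before enrichment is computed", {
  pmds <- tibble::tibble(chrom = "chr1", start = 100000, end = 103000,
                         name = "PMD_1", score = 1, n_bins = 1L)
  attr(pmds, "chrom_sizes") <- c(chr1 = 1e6)

  at_start <- tibble::tibble(chrom = "chr1", start = 100000, end = 100001)
  expect_equal(boundary_enrichment(at_start, pmds)$observed, 1)

  far <- tibble::tibble(chrom = "chr1", start = 500000, end = 500001)
  expect_equal(boundary_enrichment(far, pmds)$observed, 0)

  # boundaries 3 kb apart: +/-2.5 kb windows overlap and merge
  res <- boundary_enrichment(at_start, pmds)
  merged_bp <- res$expected / nrow(at_start) * 1e6
  expect_lt(merged_bp, 2 * 2 * 2500)
  expect_equal(merged_bp, 8000)  # [97500, 105500)
})

test_that("BH adjustment across classes preserves p-value order", {
  res <- dplyr::bind_rows(
    tibble::tibble(class = "a", n_features = 10, observed = 9, expected = 1,
                   ratio = 9, p_value = 1e-6, q_value = NA_real_),
    tibble::tibble(class = "b", n_features = 10, observed = 5, expected = 3,
                   ratio = 5 / 3, p_value = 0.2, q_value = NA_real_),
    tibble::tibble(class = "c", n_features = 10, observed = 3, expected = 3,
                   ratio = 1, p_value = 0.9, q_value = NA_real_)
  )
  adj <- adjust_enrichment(res)
  expect_equal(order(adj$q_value), order(adj$p_value))
  expect_true(all(adj$q_value >= adj$p_value))
  expect_equal(adj$q_value, p.adjust(res$p_value, "BH"))
})
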