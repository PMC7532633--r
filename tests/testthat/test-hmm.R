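test_that("posterior decoding matches exact path enumeration on short sequences", {
  set.seed(21)
  for (rep in 1:5) {
    L <- sample(2:10, 1)
    n <- sample(0:5, L, replace = TRUE)
    m <- vapply(n, function(k) sample(0:k, 1), numeric(1))
    bins <- make_bins(m, n)
    params <- hmm_params(pi = c(0.3, 0.7),
                         A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
                         pmd = list(alpha = 2, beta = 5),
                         background = list(alpha = 6, beta = 1))
    track <- posterior_decode(bins, params)
    logB <- cbind(betabinom_logpmf(m, n, 2, 5), betabinom_logpmf(m, n, 6, 1))
    oracle <- enum_posterior(logB, params$pi, params$A)
    expect_equal(track$posterior_pmd, oracle$posterior_pmd, tolerance = 1e-9)
    expect_equal(attr(track, "loglik"), oracle$loglik, tolerance = 1e-9)
  }
})

test_that("uninformative emissions give a pi-driven constant posterior", {
  bins <- make_bins(rep(2, 20), rep(4, 20))
  params <- hmm_params(pi = c(0.5, 0.5),
                       A = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
                       pmd = list(alpha = 3, beta = 3),
                       background = list(alpha = 3, beta = 3))
  track <- posterior_decode(bins, params)
  expect_equal(track$posterior_pmd, rep(0.5, 20), tolerance = 1e-12)
})

test_that("well-separated regimes give near-certain interior posteriors", {
  m <- round(c(rep(0.85, 5), rep(0.45, 8), rep(0.85, 5)) * 40)
  bins <- make_bins(m, rep(40, 18))
  track <- posterior_decode(bins, hmm_params())
  expect_true(all(track$posterior_pmd[7:12] > 0.99))
  expect_true(all(track$posterior_pmd[c(1:4, 15:18)] < 0.01))
})

test_that("Baum-Welch recovers the generating parameters", {
  sim <- sim_hmm_bins(10000, seed = 31)
  fit <- baum_welch(sim$bins)
  mu <- tidy(fit)
  est <- setNames(mu$estimate, mu$term)
  expect_equal(unname(est["mean_pmd"]), 0.45, tolerance = 0.03)
  expect_equal(unname(est["mean_background"]), 0.85, tolerance = 0.03)
  expect_equal(unname(est["A_pmd_pmd"]), 0.99, tolerance = 0.01)
  expect_equal(unname(est["A_background_background"]), 0.99, tolerance = 0.01)
  expect_true(fit$converged)
})

test_that("training log-likelihood never decreases", {
  for (s in 1:5) {
    sim <- sim_hmm_bins(400, seed = 100 + s)
    fit <- baum_welch(sim$bins)
    expect_gte(min(diff(fit$logliks)), -1e-8)
  }
})

test_that("single-regime data is assigned to the background after relabelling", {
  bins <- make_bins(rep(34, 50), rep(40, 50))
  fit <- baum_welch(bins)
  expect_true(all(fit$track$posterior_pmd < 0.5))
})

test_that("minimal two-bin input trains without error", {
  bins <- make_bins(c(10, 35), c(40, 40))
  expect_no_error(fit <- baum_welch(bins))
  expect_true(is.logical(fit$converged))
  expect_error(baum_welch(make_bins(c(5), c(40))), "at least 2")
})

test_that("permuting the initial state labels yields identical domains", {
  sim <- sim_hmm_bins(2000, seed = 77)
  init_a <- hmm_params()
  init_b <- hmm_params(pi = rev(init_a$pi), A = init_a$A[2:1, 2:1],
                       pmd = init_a$emis$background,
                       background = init_a$emis$pmd)
  dom_a <- call_domains(baum_welch(sim$bins, init = init_a))
  dom_b <- call_domains(baum_welch(sim$bins, init = init_b))
  expect_equal(dom_a$start, dom_b$start)
  expect_equal(dom_a$end, dom_b$end)
})

test_that("domain extraction follows strict-cutoff run splitting", {
  tr <- tibble::tibble(chrom = "chr1", start = c(0, 1000, 2000),
                       end = c(1000, 2000, 3000), n = 40,
                       posterior_pmd = c(0.9, 0.9, 0.1))
  attr(tr, "bin_size") <- 1000
  dom <- call_domains(tr)
  expect_equal(nrow(dom), 1L)
  expect_equal(c(dom$start, dom$end), c(0, 2000))
  expect_equal(dom$score, 0.9)

  tr$posterior_pmd <- c(0.1, 0.1, 0.1)
  expect_equal(nrow(call_domains(tr)), 0L)

  tr$posterior_pmd <- c(0.9, 0.4, 0.9)
  expect_equal(nrow(call_domains(tr)), 2L)

  # ties at the cutoff go to the background
  tr$posterior_pmd <- c(0.5, 0.5, 0.5)
  expect_equal(nrow(call_domains(tr)), 0L)
})

test_that("domains never cross chromosome boundaries", {
  tr <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 2),
                       start = c(0, 1000, 0, 1000),
                       end = c(1000, 2000, 1000, 2000), n = 40,
                       posterior_pmd = rep(0.95, 4))
  attr(tr, "bin_size") <- 1000
  dom <- call_domains(tr)
  expect_equal(nrow(dom), 2L)
  expect_equal(dom$chrom, c("chr1", "chr2"))
})

test_that("trained parameters survive a JSON round trip", {
  sim <- sim_hmm_bins(500, seed = 5)
  fit <- baum_welch(sim$bins)
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm_params(fit, f)
  back <- read_hmm_params(f)
  expect_equal(back$pi, fit$params$pi, tolerance = 1e-12)
  expect_equal(back$A, fit$params$A, tolerance = 1e-12)
  expect_equal(back$emis, fit$params$emis, tolerance = 1e-12)
})
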