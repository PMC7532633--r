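# Two-state beta-binomial hidden Markov model: parameter container,
# Baum-Welch training and posterior decoding over the binned observation
# sequence. State 1 is the PMD (hypomethylated) state, state 2 the highly
# methylated background; the labelling is enforced after training.

#' Construct (and validate) HMM parameters
#'
#' @param pi Initial state probabilities `c(pmd, background)`, summing to 1.
#' @param A 2x2 transition matrix with rows summing to 1; row/column order is
#'   (pmd, background).
#' @param pmd,background Per-state beta-binomial shapes as `list(alpha, beta)`.
#' @return An object of class `pmd_hmm_params`.
#' @export
hmm_params <- function(pi = c(0.5, 0.5),
                       A = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE),
                       pmd = list(alpha = 4.5, beta = 5.5),
                       background = list(alpha = 8.5, beta = 1.5)) {
  stopifnot(length(pi) == 2L, all(dim(A) == c(2L, 2L)))
  if (abs(sum(pi) - 1) > 1e-8 || any(abs(rowSums(A) - 1) > 1e-8)) {
    abort("`pi` and each row of `A` must sum to 1.")
  }
  if (any(pi < 0) || any(A < 0)) abort("Probabilities must be non-negative.")
  for (e in list(pmd, background)) {
    if (e$alpha <= 0 || e$beta <= 0) abort("Emission shapes must be positive.")
  }
  structure(list(pi = pi, A = A, emis = list(pmd = pmd, background = background)),
            class = "pmd_hmm_params")
}

state_means <- function(params) {
  vapply(params$emis, function(e) e$alpha / (e$alpha + e$beta), numeric(1))
}

#' @export
print.pmd_hmm_params <- function(x, ...) {
  mu <- state_means(x)
  cat("Two-state beta-binomial HMM parameters\n")
  cat(sprintf("  pmd:        alpha=%.4g beta=%.4g mean=%.3f\n",
              x$emis$pmd$alpha, x$emis$pmd$beta, mu[["pmd"]]))
  cat(sprintf("  background: alpha=%.4g beta=%.4g mean=%.3f\n",
              x$emis$background$alpha, x$emis$background$beta, mu[["background"]]))
  cat(sprintf("  A diagonal: %.4f / %.4f; pi = (%.2f, %.2f)\n",
              x$A[1, 1], x$A[2, 2], x$pi[1], x$pi[2]))
  invisible(x)
}

emission_logprobs <- function(bins, params) {
  cbind(betabinom_logpmf(bins$m, bins$n, params$emis$pmd$alpha, params$emis$pmd$beta),
        betabinom_logpmf(bins$m, bins$n, params$emis$background$alpha,
                         params$emis$background$beta))
}

chrom_run_lengths <- function(bins) {
  r <- rle(bins$chrom)
  as.integer(r$lengths)
}

swap_params <- function(params) {
  hmm_params(pi = rev(params$pi),
             A = params$A[2:1, 2:1],
             pmd = params$emis$background,
             background = params$emis$pmd)
}

#' Train the segmentation HMM by Baum-Welch
#'
#' Expectation-maximisation on the binned observation sequence: the E-step is
#' a scaled forward-backward pass (chromosomes are independent sequences
#' sharing one parameter set), the M-step re-estimates the transition matrix
#' from expected transition counts and each state's beta-binomial shapes by
#' weighted maximum likelihood under the state responsibilities. Bins with no
#' observations contribute emission log-probability 0 in both states but stay
#' in the transition chain, so domain-length geometry respects genomic
#' distance across coverage gaps. An emission update is accepted only if it
#' improves the weighted emission objective, so the total log-likelihood is
#' non-decreasing across iterations (generalised EM).
#'
#' After training, states are relabelled if necessary so that the PMD state
#' is the one with the lower emission mean.
#'
#' @param bins A bin tibble from [bin_methylome()].
#' @param init Initial parameters; default [hmm_params()] places the PMD
#'   state mean at 0.45 and background at 0.85, both at precision
#'   `alpha + beta = 10`, with transition diagonal 0.99.
#' @param max_iter Maximum EM iterations. Default 100.
#' @param tol Relative log-likelihood change declaring convergence.
#'   Default 1e-6.
#' @return An object of class `pmd_hmm`: trained `params`, a posterior
#'   `track` tibble (chrom, start, end, posterior_pmd), the log-likelihood
#'   trace, iteration count and convergence flag. Training is deterministic
#'   given `init`.
#' @export
baum_welch <- function(bins, init = hmm_params(), max_iter = 100, tol = 1e-6) {
  informative <- bins$n >= 1
  if (sum(informative) < 2L) {
    abort("Baum-Welch requires at least 2 bins with observations.")
  }
  params <- init
  seq_len_vec <- chrom_run_lengths(bins)
  logliks <- numeric(0)
  converged <- FALSE
  fb <- NULL
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    logB <- emission_logprobs(bins, params)
    fb <- fb_cpp(logB, params$pi, params$A, seq_len_vec)
    logliks <- c(logliks, fb$loglik)
    if (iter > 1L) {
      prev <- logliks[iter - 1L]
      if (abs(fb$loglik - prev) < tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }

    # M-step
    gf <- fb$gamma_first
    new_pi <- gf / sum(gf)
    xi <- fb$xi
    new_A <- xi / rowSums(xi)
    # guard against empty rows (state never occupied)
    bad <- !is.finite(rowSums(new_A))
    if (any(bad)) new_A[bad, ] <- params$A[bad, ]

    g <- fb$gamma[informative, , drop = FALSE]
    m <- bins$m[informative]
    n <- bins$n[informative]
    new_emis <- params$emis
    for (k in 1:2) {
      if (sum(g[, k]) <= 0) next
      cand <- tryCatch(fit_betabinom(m, n, g[, k]), error = function(e) NULL)
      if (is.null(cand)) next
      cur <- params$emis[[k]]
      q_cur <- sum(g[, k] * betabinom_logpmf(m, n, cur$alpha, cur$beta))
      q_new <- sum(g[, k] * betabinom_logpmf(m, n, cand$alpha, cand$beta))
      if (q_new > q_cur) new_emis[[k]] <- list(alpha = cand$alpha, beta = cand$beta)
    }
    params <- hmm_params(pi = new_pi, A = new_A, pmd = new_emis$pmd,
                         background = new_emis$background)
  }

  relabelled <- FALSE
  mu <- state_means(params)
  if (mu[["pmd"]] > mu[["background"]]) {
    params <- swap_params(params)
    relabelled <- TRUE
  }

  track <- posterior_decode(bins, params)

  structure(list(params = params, track = track, logliks = logliks,
                 iterations = iter, converged = converged,
                 relabelled = relabelled,
                 bin_size = attr(bins, "bin_size"),
                 n_bins = nrow(bins)),
            class = "pmd_hmm")
}

#' @export
print.pmd_hmm <- function(x, ...) {
  cat(sprintf("pmd_hmm fit: %d bins (bin size %s bp), %d iterations, %s\n",
              x$n_bins, format(x$bin_size), x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  final log-likelihood: %.3f\n", tail(x$logliks, 1L)))
  print(x$params)
  invisible(x)
}

#' Posterior decoding of a binned methylome
#'
#' Scaled forward-backward under fixed parameters. Per-bin posteriors of the
#' two states sum to 1.
#'
#' @param bins A bin tibble from [bin_methylome()].
#' @param params `pmd_hmm_params`, typically trained by [baum_welch()].
#' @return A tibble (`chrom`, `start`, `end`, `n`, `posterior_pmd`) aligned
#'   with `bins`, with the sequence log-likelihood as attribute `loglik`.
#' @export
posterior_decode <- function(bins, params) {
  logB <- emission_logprobs(bins, params)
  fb <- fb_cpp(logB, params$pi, params$A, chrom_run_lengths(bins))
  track <- tibble(chrom = bins$chrom, start = bins$start, end = bins$end,
                  n = bins$n, posterior_pmd = fb$gamma[, 1L])
  attr(track, "loglik") <- fb$loglik
  attr(track, "bin_size") <- attr(bins, "bin_size")
  chrom_sizes(track) <- chrom_sizes(bins)
  track
}

#' Extract PMD intervals from a posterior track
#'
#' Maximal runs of bins whose PMD-state posterior strictly exceeds the cutoff
#' become half-open domains; ties at exactly the cutoff go to the background.
#' Runs never cross chromosome boundaries. Each domain's score is the mean
#' posterior over its bins.
#'
#' @param track Posterior track from [posterior_decode()] or a `pmd_hmm` fit.
#' @param cutoff Posterior cutoff. Default 0.5.
#' @return A PMD tibble (`chrom`, `start`, `end`, `name`, `score`, `n_bins`)
#'   carrying `bin_size` and `chrom_sizes` attributes.
#' @export
call_domains <- function(track, cutoff = 0.5) {
  if (inherits(track, "pmd_hmm")) track <- track$track
  in_pmd <- track$posterior_pmd > cutoff
  out <- list()
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    r <- rle(in_pmd[idx])
    ends_at <- cumsum(r$lengths)
    starts_at <- ends_at - r$lengths + 1L
    hit <- which(r$values)
    if (length(hit) == 0L) next
    out[[chr]] <- tibble(
      chrom = chr,
      start = track$start[idx[starts_at[hit]]],
      end = track$end[idx[ends_at[hit]]],
      score = vapply(hit, function(h) {
        mean(track$posterior_pmd[idx[starts_at[h]:ends_at[h]]])
      }, numeric(1)),
      n_bins = r$lengths[hit]
    )
  }
  pmds <- if (length(out) > 0L) dplyr::bind_rows(out) else {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           score = numeric(), n_bins = integer())
  }
  if (nrow(pmds) > 0L) {
    pmds$name <- sprintf("PMD_%d", seq_len(nrow(pmds)))
    pmds <- pmds[, c("chrom", "start", "end", "name", "score", "n_bins")]
  } else {
    pmds$name <- character()
    pmds <- pmds[, c("chrom", "start", "end", "name", "score", "n_bins")]
  }
  attr(pmds, "bin_size") <- attr(track, "bin_size")
  attr(pmds, "sharpened") <- FALSE
  attr(pmds, "fdr_filtered") <- FALSE
  chrom_sizes(pmds) <- chrom_sizes(track)
  pmds
}

#' Serialise trained HMM parameters to a JSON text file
#'
#' Records pi, the transition matrix, per-state shapes, the bin size and the
#' final log-likelihood, so the same trained model can be reused (for
#' example, to decode a shuffled methylome in the FDR step).
#'
#' @param fit A `pmd_hmm` fit or `pmd_hmm_params`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hmm_params <- function(fit, path) {
  params <- if (inherits(fit, "pmd_hmm")) fit$params else fit
  obj <- list(pi = params$pi, A = params$A,
              pmd = params$emis$pmd, background = params$emis$background)
  if (inherits(fit, "pmd_hmm")) {
    obj$bin_size <- fit$bin_size
    obj$loglik <- tail(fit$logliks, 1L)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read HMM parameters written by [write_hmm_params()]
#'
#' @param path Path to the JSON parameter file.
#' @return A `pmd_hmm_params` object.
#' @export
read_hmm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_params(pi = obj$pi, A = matrix(unlist(obj$A), 2, 2),
             pmd = as.list(obj$pmd[c("alpha", "beta")]),
             background = as.list(obj$background[c("alpha", "beta")]))
}
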