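#' Estimate mitochondrial contamination by grid likelihood
#'
#' Two-source mixture model at diagnostic sites (sites where the endogenous
#' consensus and the putative contaminant allele differ). Each read base is
#' endogenous with probability `1 - c` and contaminant-derived with
#' probability `c`; sequencing error flips a base to one of the three
#' others with probability `error_rate`. The log-likelihood
#' `sum over sites and reads of log[(1-c) P(base | endogenous) + c P(base | contaminant)]`
#' is maximized over the grid `c = 0, 0.001, ..., 1`; the standard error
#' comes from the curvature of the log-likelihood at the maximum. This is a
#' single-round estimator over a fixed contaminant frequency table (no
#' iterative consensus refinement), tagged `mt-likelihood`.
#'
#' @param pileup data.frame with columns `endogenous`, `contaminant`
#'   (single-base alleles) and `bases` (string of observed read bases per
#'   site), as produced by [simulate_mt_pileup()] or read from a pileup TSV.
#' @param contaminant_allele_frequencies per-site frequency of the
#'   contaminant allele in the putative contaminant population (recycled;
#'   default 1).
#' @param error_rate per-base error probability in [0, 0.25]
#' @param grid_step resolution of the contamination grid
#' @return a `contamination_estimate`: list with `estimate`, `stderr`,
#'   `method`, `n_sites`, `log_likelihood_curve` (data.frame c, loglik)
#' @export
estimate_mt_contamination <- function(pileup,
                                      contaminant_allele_frequencies = 1,
                                      error_rate = 0.01,
                                      grid_step = 0.001) {
  if (error_rate < 0 || error_rate > 0.25)
    stopf("`error_rate` must be in [0, 0.25]")
  need <- c("endogenous", "contaminant", "bases")
  if (!all(need %in% names(pileup)))
    stopf("pileup needs columns %s", paste(need, collapse = ", "))
  diag <- pileup$endogenous != pileup$contaminant
  pileup <- pileup[diag, , drop = FALSE]
  if (nrow(pileup) == 0L) stopf("no diagnostic sites")
  f <- rep_len(contaminant_allele_frequencies, nrow(pileup))

  # per-site counts of reads matching the endogenous allele, the
  # contaminant allele, or neither
  n_e <- n_c <- n_o <- integer(nrow(pileup))
  for (s in seq_len(nrow(pileup))) {
    b <- strsplit(pileup$bases[s], "", fixed = TRUE)[[1]]
    n_e[s] <- sum(b == pileup$endogenous[s])
    n_c[s] <- sum(b == pileup$contaminant[s])
    n_o[s] <- length(b) - n_e[s] - n_c[s]
  }
  e <- error_rate
  # emission probabilities per source
  pe_e <- 1 - e; pe_c <- e / 3; pe_o <- 2 * e / 3
  pc_e <- (1 - f) * (1 - e) + f * e / 3
  pc_c <- f * (1 - e) + (1 - f) * e / 3
  pc_o <- 2 * e / 3

  grid <- seq(0, 1, by = grid_step)
  n_sites_d <- nrow(pileup)
  loglik <- vapply(grid, function(c) {
    le <- rep_len(log((1 - c) * pe_e + c * pc_e), n_sites_d)
    lc <- rep_len(log((1 - c) * pe_c + c * pc_c), n_sites_d)
    lo <- rep_len(log((1 - c) * pe_o + c * pc_o), n_sites_d)
    lo[n_o == 0L & !is.finite(lo)] <- 0  # error_rate 0: impossible only if observed
    lc[n_c == 0L & !is.finite(lc)] <- 0
    le[n_e == 0L & !is.finite(le)] <- 0
    sum(n_e * le + n_c * lc + n_o * lo)
  }, numeric(1))

  k <- which.max(loglik)
  est <- grid[k]
  # curvature-based standard error from a quadratic fit at the maximum;
  # at a boundary use the one-sided second difference
  if (k > 1L && k < length(grid)) {
    d2 <- (loglik[k + 1L] - 2 * loglik[k] + loglik[k - 1L]) / grid_step^2
  } else {
    j <- if (k == 1L) k + 1L else k - 1L
    jj <- if (k == 1L) k + 2L else k - 2L
    d2 <- (loglik[jj] - 2 * loglik[j] + loglik[k]) / grid_step^2
  }
  if (is.finite(d2) && d2 < 0) {
    se <- sqrt(-1 / d2)
  } else {
    warning("flat likelihood: standard error spans [0, 1]")
    se <- 1
  }
  structure(list(estimate = est, stderr = se, method = "mt-likelihood",
                 n_sites = nrow(pileup),
                 log_likelihood_curve = data.frame(c = grid, loglik = loglik)),
            class = "contamination_estimate")
}

#' Estimate nuclear contamination from male X-chromosome heterozygosity
#'
#' A male carries one X, so any minor-allele signal at polymorphic X sites
#' above the error baseline indicates contamination. The base statistic is
#' `max(0, mismatch rate at polymorphic sites - mismatch rate at flanking
#' monomorphic sites)`; the standard error comes from a block jackknife
#' over polymorphic sites (default 20 blocks, with monomorphic sites
#' deleted in parallel blocks).
#'
#' The raw rate difference understates the contaminant fraction: under a
#' uniform base-error model an error restores a contaminant base to the
#' reference one time in three, and contaminant reads displace endogenous
#' reads that would otherwise contribute error mismatches, attenuating the
#' difference by a factor `1 - 4e/3` where `e` is the per-base error rate.
#' Since `e` is exactly what the monomorphic sites measure, the default
#' estimate divides the difference by `1 - 4/3 * (monomorphic rate)`;
#' `correct_attenuation = FALSE` gives the plain subtraction.
#'
#' @param polymorphic,monomorphic data.frames with columns `n_match`,
#'   `n_mismatch` per site
#' @param sample_is_male must be `TRUE`; the method is undefined for
#'   females
#' @param n_blocks jackknife blocks
#' @param correct_attenuation divide out the error attenuation factor
#'   (default `TRUE`)
#' @return a `contamination_estimate` with method `"x-heterozygosity"`
#' @export
estimate_x_contamination <- function(polymorphic, monomorphic,
                                     sample_is_male = TRUE, n_blocks = 20,
                                     correct_attenuation = TRUE) {
  if (!isTRUE(sample_is_male))
    stopf("X-heterozygosity contamination is undefined for female samples")
  for (d in list(polymorphic, monomorphic))
    if (!all(c("n_match", "n_mismatch") %in% names(d)))
      stopf("pileups need columns n_match, n_mismatch")
  if (nrow(polymorphic) == 0L || sum(polymorphic$n_match + polymorphic$n_mismatch) == 0L)
    stopf("no covered polymorphic sites")

  rate <- function(d) sum(d$n_mismatch) / sum(d$n_match + d$n_mismatch)
  stat <- function(poly, mono) {
    e <- rate(mono)
    atten <- if (correct_attenuation) 1 - 4 * e / 3 else 1
    max(0, (rate(poly) - e) / atten)
  }
  point <- stat(polymorphic, monomorphic)

  n_blocks <- min(n_blocks, nrow(polymorphic))
  bp <- cut(seq_len(nrow(polymorphic)), n_blocks, labels = FALSE)
  bm <- cut(seq_len(nrow(monomorphic)), n_blocks, labels = FALSE)
  theta <- vapply(seq_len(n_blocks), function(b) {
    stat(polymorphic[bp != b, , drop = FALSE],
         monomorphic[bm != b, , drop = FALSE])
  }, numeric(1))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((theta - mean(theta))^2))

  structure(list(estimate = point, stderr = se, method = "x-heterozygosity",
                 n_sites = nrow(polymorphic), log_likelihood_curve = NULL),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf("contamination (%s): %.4f +/- %.4f over %d sites\n",
              x$method, x$estimate, x$stderr, x$n_sites))
  invisible(x)
}
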