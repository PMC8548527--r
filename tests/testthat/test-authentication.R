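test_that("misincorporation profile matches a single-read hand count", {
  # read TCGA over ref CCGA: 5' pos 1 is a damaged C (freq 1), pos 2 an
  # intact C (freq 0); pos 3 (ref G) and 4 (ref A) carry no 5' C
  # opportunity. From the 3' end only position 3 has a ref G (read G).
  ref <- c(chr1 = "CCGA")
  prof <- compute_misincorporation_profile(aln_df("TCGA"), ref, window = 4)
  expect_equal(unname(prof$five_prime_ct[1]), 1.0)
  expect_equal(unname(prof$five_prime_ct[2]), 0.0)
  expect_true(is.na(prof$five_prime_ct[3]))
  expect_true(is.na(prof$five_prime_ct[4]))
  expect_equal(unname(prof$three_prime_ga[2]), 0.0)  # the G, 2nd from 3' end
  expect_true(is.na(prof$three_prime_ga[1]))
  expect_equal(prof$n_fragments, 1L)
})

test_that("undamaged reads give a flat profile and zero background", {
  ref <- random_reference(20000)
  cfg <- damage_model_config(terminal_ct_rate = 0, seed = 6)
  sim <- simulate_adna_fragments(cfg, ref, 1000)
  prof <- compute_misincorporation_profile(sim$alignments, ref)
  expect_true(all(prof$five_prime_ct[!is.na(prof$five_prime_ct)] <=
                    prof$other_subst))
  expect_equal(prof$other_subst, 0)
})

test_that("profile reports undefined (not zero) at positions without opportunities", {
  ref <- c(chr1 = "AATTAATT")
  prof <- compute_misincorporation_profile(aln_df("AATTAATT"), ref, window = 8)
  expect_true(all(is.na(prof$five_prime_ct)))
  expect_true(all(is.na(prof$three_prime_ga)))
  expect_error(compute_misincorporation_profile(aln_df(character(0)), ref),
               "no aligned reads")
})

test_that("reads without reference context are skipped with a message", {
  ref <- c(chr1 = "CCGACCGA")
  aln <- rbind(aln_df("TCGA"),
               data.frame(qname = "bad", chrom = "chrZ", pos = 1, seq = "TCGA"))
  expect_message(prof <- compute_misincorporation_profile(aln, ref, window = 2),
                 "skipping 1 reads")
  expect_equal(prof$n_fragments, 1L)
})

test_that("fragment length summaries are exact on hand-built inputs", {
  aln <- aln_df(c(strrep("A", 80), strrep("A", 90), strrep("A", 100)))
  s <- summarize_fragment_lengths(aln)
  expect_equal(s$mean, 90); expect_equal(s$median, 90); expect_equal(s$n, 3L)
  expect_equal(sum(s$histogram), 3L)
  s1 <- summarize_fragment_lengths(aln_df(strrep("A", 86)))
  expect_equal(s1$mean, 86)
  expect_error(summarize_fragment_lengths(aln_df(character(0))), "no alignments")
})

test_that("simulated fragment lengths recover the configured mean", {
  ref <- random_reference(50000)
  cfg <- damage_model_config(mean_fragment_length = 90,
                             length_dispersion = 0.35, seed = 12)
  sim <- simulate_adna_fragments(cfg, ref, 20000)
  s <- summarize_fragment_lengths(sim$alignments)
  lens <- nchar(sim$alignments$seq)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(s$mean - 90), 3 * se)
})

test_that("Ry sex classification follows the published thresholds", {
  xy <- determine_genetic_sex(nX = 9115, nY = 885)
  expect_equal(xy$ry, 0.0885)
  expect_equal(xy$se, sqrt(0.0885 * (1 - 0.0885) / 10000))
  expect_equal(xy$classification, "consistent-with-XY")

  xx <- determine_genetic_sex(nX = 10000, nY = 0)
  expect_equal(xx$ry, 0)
  expect_equal(xx$classification, "consistent-with-XX")

  # ry = 0.04: the 95% interval straddles neither cutoff
  mid <- determine_genetic_sex(nX = 960, nY = 40)
  expect_equal(mid$ry, 0.04)
  expect_equal(mid$classification, "indeterminate")

  expect_warning(low <- determine_genetic_sex(nX = 30, nY = 3),
                 "indeterminate")
  expect_equal(low$classification, "indeterminate")
})

test_that("Ry is scale-invariant while its standard error shrinks", {
  for (k in c(2L, 10L, 100L)) {
    a <- determine_genetic_sex(nX = 950, nY = 50)
    b <- determine_genetic_sex(nX = 950L * k, nY = 50L * k)
    expect_equal(b$ry, a$ry)
    expect_lt(b$se, a$se)
  }
})

test_that("mt contamination estimator is exact at the mixture extremes", {
  p0 <- simulate_mt_pileup(0, depth = 40, n_diagnostic_sites = 12,
                           error_rate = 0, seed = 21)
  e0 <- estimate_mt_contamination(p0$pileup, error_rate = 0)
  expect_equal(e0$estimate, 0)
  p1 <- simulate_mt_pileup(1, depth = 40, n_diagnostic_sites = 12,
                           error_rate = 0, seed = 21)
  e1 <- estimate_mt_contamination(p1$pileup, error_rate = 0)
  expect_equal(e1$estimate, 1)
  expect_error(estimate_mt_contamination(
    data.frame(endogenous = "A", contaminant = "A", bases = "AAAA")),
    "no diagnostic sites")
})

test_that("mt estimator matches an independent per-read grid oracle", {
  for (s in c(31, 32, 33)) {
    pm <- simulate_mt_pileup(runif(1, 0, 0.2), depth = 60,
                             n_diagnostic_sites = 8, error_rate = 0.01,
                             seed = s)
    est <- estimate_mt_contamination(pm$pileup, error_rate = 0.01)
    expect_equal(est$estimate, oracle_mt_grid(pm$pileup, 0.01))
  }
})

test_that("mt estimator recovers a simulated 2% mixture within its error", {
  pm <- simulate_mt_pileup(0.02, depth = 500, n_diagnostic_sites = 50,
                           error_rate = 0.01, seed = 14)
  est <- estimate_mt_contamination(pm$pileup, error_rate = 0.01)
  expect_lt(abs(est$estimate - 0.02), 2 * est$stderr)
  expect_equal(est$method, "mt-likelihood")
  expect_equal(range(est$log_likelihood_curve$c), c(0, 1))
})

test_that("X-heterozygosity estimator subtracts the error baseline", {
  mk <- function(rate, n = 100, depth = 1000) {
    mm <- round(depth * rate)
    data.frame(site = 1:n, n_match = depth - mm, n_mismatch = mm)
  }
  expect_equal(estimate_x_contamination(mk(0), mk(0))$estimate, 0)
  # raw subtraction: 0.012 - 0.010 = 0.002
  est_raw <- estimate_x_contamination(mk(0.012), mk(0.010),
                                      correct_attenuation = FALSE)
  expect_equal(est_raw$estimate, 0.002)
  # attenuation-corrected: divided by 1 - 4 * 0.010 / 3
  est <- estimate_x_contamination(mk(0.012), mk(0.010))
  expect_equal(est$estimate, 0.002 / (1 - 4 * 0.010 / 3))
  expect_error(estimate_x_contamination(mk(0.01), mk(0.01),
                                        sample_is_male = FALSE),
               "undefined for female")
  expect_error(estimate_x_contamination(mk(0.01)[0, ], mk(0.01)),
               "no covered polymorphic sites")
})

test_that("X-heterozygosity estimator recovers simulated contamination", {
  xp <- simulate_x_pileup(0.02, n_polymorphic = 1344, n_monomorphic = 1344,
                          depth = 30, seed = 15)
  est <- estimate_x_contamination(xp$polymorphic, xp$monomorphic)
  expect_lt(abs(est$estimate - 0.02), 2 * est$stderr)
  expect_equal(est$method, "x-heterozygosity")
})

test_that("both contamination estimators are monotone in true contamination", {
  levels <- c(0, 0.05, 0.2)
  mt_means <- x_means <- numeric(length(levels))
  for (i in seq_along(levels)) {
    mt_e <- x_e <- numeric(20)
    for (s in 1:20) {
      pm <- simulate_mt_pileup(levels[i], depth = 60, n_diagnostic_sites = 20,
                               error_rate = 0.01, seed = 100 * i + s)
      mt_e[s] <- estimate_mt_contamination(pm$pileup,
                                           error_rate = 0.01)$estimate
      xp <- simulate_x_pileup(levels[i], n_polymorphic = 150,
                              n_monomorphic = 150, depth = 20,
                              seed = 100 * i + s)
      x_e[s] <- estimate_x_contamination(xp$polymorphic,
                                         xp$monomorphic)$estimate
    }
    mt_means[i] <- mean(mt_e); x_means[i] <- mean(x_e)
  }
  expect_true(all(diff(mt_means) > 0))
  expect_true(all(diff(x_means) > 0))
})
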