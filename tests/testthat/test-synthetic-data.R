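test_that("damage-disabled simulation introduces no C>T mismatches", {
  ref <- random_reference(20000)
  cfg <- damage_model_config(terminal_ct_rate = 0, contamination_fraction = 0,
                             seed = 1)
  sim <- simulate_adna_fragments(cfg, ref, 1000)
  prof <- compute_misincorporation_profile(sim$alignments, ref, window = 15)
  expect_true(all(prof$five_prime_ct[!is.na(prof$five_prime_ct)] == 0))
  expect_true(all(prof$three_prime_ga[!is.na(prof$three_prime_ga)] == 0))
  expect_equal(sum(sim$truth$n_damage_ct), 0L)
})

test_that("empirical damage follows the configured exponential decay law", {
  ref <- random_reference(50000)
  cfg <- damage_model_config(terminal_ct_rate = 0.3, decay = 0.5, seed = 7)
  sim <- simulate_adna_fragments(cfg, ref, 30000)
  prof <- compute_misincorporation_profile(sim$alignments, ref, window = 10)
  opp <- attr(prof$five_prime_ct, "opportunities")
  for (i in 1:4) {
    expected <- 0.3 * 0.5^(i - 1)
    se <- sqrt(expected * (1 - expected) / opp[i])
    expect_lt(abs(prof$five_prime_ct[i] - expected), 3 * se)
  }
  # 3' G>A mirrors the 5' law
  opp3 <- attr(prof$three_prime_ga, "opportunities")
  se1 <- sqrt(0.3 * 0.7 / opp3[1])
  expect_lt(abs(prof$three_prime_ga[1] - 0.3), 3 * se1)
})

test_that("partial-UDG mode confines damage to the terminal base", {
  ref <- random_reference(50000)
  cfg <- damage_model_config(terminal_ct_rate = 0.02, udg_mode = "partial",
                             seed = 3)
  sim <- simulate_adna_fragments(cfg, ref, 30000)
  prof <- compute_misincorporation_profile(sim$alignments, ref, window = 10)
  opp <- attr(prof$five_prime_ct, "opportunities")
  se1 <- sqrt(0.02 * 0.98 / opp[1])
  expect_lt(abs(prof$five_prime_ct[1] - 0.02), 3 * se1)
  expect_true(all(prof$five_prime_ct[2:10] == 0))
  expect_true(all(prof$three_prime_ga[2:10] == 0))
})

test_that("contaminant fragments carry no damage and honor the mixing fraction", {
  ref <- random_reference(50000)
  cfg <- damage_model_config(terminal_ct_rate = 0.5, decay = 0.9,
                             contamination_fraction = 0.3, seed = 11)
  sim <- simulate_adna_fragments(cfg, ref, 5000)
  tr <- sim$truth
  expect_true(all(tr$n_damage_ct[tr$contaminant] == 0))
  expect_true(all(tr$n_damage_ga[tr$contaminant] == 0))
  se <- sqrt(0.3 * 0.7 / 5000)
  expect_lt(abs(mean(tr$contaminant) - 0.3), 3 * se)
})

test_that("fragment simulation is deterministic under a fixed seed and validates inputs", {
  ref <- random_reference(10000)
  cfg <- damage_model_config(seed = 42)
  expect_identical(simulate_adna_fragments(cfg, ref, 200),
                   simulate_adna_fragments(cfg, ref, 200))
  expect_error(simulate_adna_fragments(cfg, ref, 0), "must be >= 1")
  expect_error(simulate_adna_fragments(cfg, character(0), 10), "empty")
  expect_error(damage_model_config(contamination_fraction = 1.5),
               "probability")
  expect_error(damage_model_config(decay = 0), "decay")
})

test_that("sexed alignment counts reflect the requested karyotype", {
  expect_identical(
    simulate_sexed_alignment_counts("XX", 1000, seed = 1, mismap_rate = 0)$nY,
    0L)
  xy <- simulate_sexed_alignment_counts("XY", 100000, seed = 5)
  ry <- xy$nY / (xy$nX + xy$nY)
  expect_gt(ry, 0.075); expect_lt(ry, 0.12)
  xx <- simulate_sexed_alignment_counts("XX", 100000, seed = 5)
  expect_lt(xx$nY / (xx$nX + xx$nY), 0.016)
  expect_error(simulate_sexed_alignment_counts("XZ", 10), "unknown sex")
})

test_that("mt pileup simulator hits its configured mixture exactly at the extremes", {
  p0 <- simulate_mt_pileup(0, depth = 40, n_diagnostic_sites = 10,
                           error_rate = 0, seed = 2)
  expect_true(all(mapply(function(b, e) all(strsplit(b, "")[[1]] == e),
                         p0$pileup$bases, p0$pileup$endogenous)))
  p1 <- simulate_mt_pileup(1, depth = 40, n_diagnostic_sites = 10,
                           error_rate = 0, seed = 2)
  expect_true(all(mapply(function(b, a) all(strsplit(b, "")[[1]] == a),
                         p1$pileup$bases, p1$pileup$contaminant)))
  # binomial check on the mixture fraction
  pm <- simulate_mt_pileup(0.02, depth = 500, n_diagnostic_sites = 50,
                           error_rate = 0, seed = 8)
  frac <- sum(pm$truth$n_contaminant_reads) / (500 * 50)
  se <- sqrt(0.02 * 0.98 / (500 * 50))
  expect_lt(abs(frac - 0.02), 3 * se)
})

test_that("variant table truth bookkeeping and planted pair behave as configured", {
  # with no background clinical fraction, only the planted pair carries
  # classes, so the annotated arm retains exactly the pair
  vt <- simulate_variant_table(variant_table_config(n_variants = 300,
                                                    fraction_clinical = 0,
                                                    seed = 4))
  expect_setequal(vt$truth$annotated_retained, vt$truth$planted_pair_ids)
  v <- vt$variants
  pair <- v[v$id %in% vt$truth$planted_pair_ids, ]
  expect_true(all(pair$gene == "GAA"))
  expect_true(all(pair$genotype == "het"))

  # homozygous planting flips the recessive mechanism
  cfg <- variant_table_config(n_variants = 300, fraction_clinical = 0, seed = 4)
  cfg$planted_pair$variant1$genotype <- "hom"
  cfg$planted_pair$variant2$genotype <- "hom"
  vt2 <- simulate_variant_table(cfg)
  ann <- annotated_pipeline(vt2$variants)
  cand <- recessive_candidates(ann$retained[ann$retained$rare_flag, ])
  mech <- vapply(cand, `[[`, "", "mechanism")
  expect_true("homozygous" %in% mech)
  expect_false("possible-compound-het" %in% mech)
})

test_that("haplotype panel simulator plants a carrier-shared block", {
  # no recombination: every carrier is a clean copy of the anchor founder
  pan0 <- simulate_haplotype_panel(panel_config(n_haplotypes = 60,
                                                n_sites = 40,
                                                recomb_rate = 0,
                                                anchor_frequency = 0.1,
                                                seed = 9))
  carr <- pan0$truth$carriers
  expect_gt(length(carr), 1)
  first <- pan0$panel$alleles[carr[1], ]
  for (h in carr) expect_identical(pan0$panel$alleles[h, ], first)
  blk <- find_anchor_block(pan0$panel, pan0$anchor)
  expect_identical(blk$member_sites, seq_along(pan0$panel$positions))
  expect_true(all(blk$concordance == 1))

  pan <- simulate_haplotype_panel(panel_config(seed = 10))
  expect_false(is.unsorted(pan$panel$positions, strictly = TRUE))
  expect_equal(sum(pan$panel$alleles[, pan$anchor$site]),
               pan$truth$n_carriers)
  # trans planting leaves the query allele absent from the whole panel
  expect_equal(sum(pan$panel$alleles[, pan$query$site]), 0)
  expect_error(panel_config(n_haplotypes = 10, anchor_frequency = 0.01),
               "no carrier")
})
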