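# A minimal hand-built variant row; fields default to an unremarkable
# exonic missense het with no classes and mid-range frequencies.
vrow <- function(id = "v1", gene = "G1", genotype = "het",
                 effect = "Missense", region = "exonic",
                 clinvar = NA, hgmd = NA,
                 af = 0.2, fg = 0.5, n_damaging = 0) {
  pred <- rep("tolerated", 5)
  if (n_damaging > 0) pred[seq_len(n_damaging)] <- "damaging"
  d <- data.frame(id = id, chrom = "chr1", pos = 100, ref = "A", alt = "G",
                  genotype = genotype, gene = gene, effect = effect,
                  region = region, clinvar_class = clinvar, hgmd_class = hgmd,
                  af_1000g = af, af_gnomad = af, af_esp = af,
                  internal_freq = NA_real_, fg_freq = fg,
                  stringsAsFactors = FALSE)
  d[relicdx:::PREDICTOR_COLUMNS] <- as.list(pred)
  d
}

test_that("annotated arm retains by clinical class and flags by frequency", {
  v <- rbind(
    vrow("path", clinvar = "Pathogenic/Likely pathogenic", hgmd = "DM",
         af = 1.5e-05),
    vrow("benign_dmq", clinvar = "Benign/Likely benign", hgmd = "DM?",
         af = 0.03),
    vrow("benign_only", clinvar = "Benign/Likely benign", af = 0.03),
    vrow("unannotated"))
  out <- annotated_pipeline(v)
  expect_setequal(out$retained$id, c("path", "benign_dmq"))
  # both planted-pattern variants are rare at the 5% threshold
  expect_true(all(out$retained$rare_flag))
  # the benign+DM? variant is retained through the HGMD arm only
  expect_equal(out$retained$provenance[out$retained$id == "benign_dmq"],
               "hgmd")
  # absence from every frequency database is not evidence of commonness
  v2 <- vrow("nofreq", clinvar = "Uncertain Significance", af = NA_real_)
  expect_true(annotated_pipeline(v2)$retained$rare_flag)
})

test_that("predicted arm requires coding region, no classes, predictor and fg support", {
  keep <- vrow("keep", fg = 0.01, af = 0.005, n_damaging = 3)
  few_pred <- vrow("few", fg = 0.01, af = 0.005, n_damaging = 2)
  intronic <- vrow("intr", region = "other", fg = 0.01, n_damaging = 5)
  classed <- vrow("cls", clinvar = "Pathogenic", fg = 0.01, n_damaging = 5)
  high_fg <- vrow("fg", fg = 0.05, n_damaging = 5)
  out <- predicted_pipeline(rbind(keep, few_pred, intronic, classed, high_fg))
  expect_identical(out$retained$id, "keep")
  expect_true(out$retained$rare_flag)  # 0.005 < 1%
})

test_that("the two arms are disjoint by construction", {
  for (s in c(51, 52)) {
    vt <- simulate_variant_table(variant_table_config(n_variants = 300,
                                                      seed = s))
    a <- annotated_pipeline(vt$variants)$retained$id
    p <- predicted_pipeline(vt$variants)$retained$id
    expect_length(intersect(a, p), 0)
  }
})

test_that("retained sets equal generator truth across random tables", {
  for (s in 1:25) {
    vt <- simulate_variant_table(variant_table_config(n_variants = 250,
                                                      seed = 1000 + s))
    ann <- annotated_pipeline(vt$variants)
    prd <- predicted_pipeline(vt$variants)
    expect_setequal(ann$retained$id, vt$truth$annotated_retained)
    expect_setequal(prd$retained$id, vt$truth$predicted_retained)
    expect_setequal(ann$retained$id[ann$retained$rare_flag],
                    vt$truth$annotated_rare)
    expect_setequal(prd$retained$id[prd$retained$rare_flag],
                    vt$truth$predicted_rare)
  }
})

test_that("raising the rare-flag threshold never unflags a variant", {
  vt <- simulate_variant_table(variant_table_config(n_variants = 400,
                                                    seed = 61))
  flagged <- function(thr) {
    cfg <- prioritization_config(annotated_maf_flag_threshold = thr)
    out <- annotated_pipeline(vt$variants, cfg)
    out$retained$id[out$retained$rare_flag]
  }
  prev <- flagged(0.01)
  for (thr in c(0.05, 0.2, 0.8)) {
    cur <- flagged(thr)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("clinical intersection partitions by database membership", {
  v <- rbind(vrow("v1", clinvar = "Pathogenic"),
             vrow("v2", clinvar = "Pathogenic", hgmd = "DM"),
             vrow("v3", hgmd = "DM"))
  ci <- clinical_intersection(annotated_pipeline(v))
  expect_equal(ci$n_clinvar, 2); expect_equal(ci$n_hgmd, 2)
  expect_equal(ci$n_common_to_both, 1)
  expect_identical(ci$both_ids, "v2")
  expect_false(ci$severity_filtered)

  empty <- clinical_intersection(annotated_pipeline(vrow("x")))
  expect_equal(empty$n_clinvar, 0); expect_equal(empty$n_hgmd, 0)
  expect_equal(empty$n_common_to_both, 0)

  # a severity lookup narrows the rare-clinical (rare-flagged) subset
  vr <- rbind(vrow("v1", clinvar = "Pathogenic", af = 0.001),
              vrow("v2", clinvar = "Pathogenic", hgmd = "DM", af = 0.001),
              vrow("v3", hgmd = "DM", af = 0.001))
  sev <- c(v1 = TRUE, v2 = FALSE, v3 = FALSE)
  ci2 <- clinical_intersection(annotated_pipeline(vr), severity_lookup = sev)
  expect_identical(ci2$rare_clinical_ids, "v1")
  expect_true(ci2$severity_filtered)
})

test_that("intersection counts over generator fixtures equal truth", {
  vt <- simulate_variant_table(variant_table_config(n_variants = 500,
                                                    seed = 71))
  ci <- clinical_intersection(annotated_pipeline(vt$variants))
  expect_setequal(ci$clinvar_ids, vt$truth$clinvar_members)
  expect_setequal(ci$hgmd_ids, vt$truth$hgmd_members)
  expect_equal(ci$n_common_to_both,
               length(intersect(vt$truth$clinvar_members,
                                vt$truth$hgmd_members)))
})

test_that("recessive candidate detection distinguishes mechanisms", {
  two_het <- rbind(vrow("a", gene = "GAA"), vrow("b", gene = "GAA"))
  cand <- recessive_candidates(two_het)
  expect_length(cand, 1)
  expect_equal(cand[[1]]$mechanism, "possible-compound-het")
  expect_setequal(cand[[1]]$variant_ids, c("a", "b"))

  expect_length(recessive_candidates(vrow("solo", gene = "GAA")), 0)

  hom <- vrow("h", gene = "GAA", genotype = "hom")
  cand_h <- recessive_candidates(hom)
  expect_equal(cand_h[[1]]$mechanism, "homozygous")
})

test_that("modifier scan splits rare from common at a strict threshold", {
  vt <- simulate_variant_table(variant_table_config(n_variants = 300,
                                                    seed = 81))
  ms <- modifier_scan(vt$variants)
  expect_equal(unname(ms$rare_by_gene["ATP6"]), 6L)
  expect_equal(unname(ms$rare_by_gene["RUNX1"]), 1L)
  expect_equal(ms$n_common, 28L)

  # frequency exactly at the threshold counts as rare (strict > for common)
  at <- vrow("at", gene = "ATP6", af = 0.05)
  ms2 <- modifier_scan(at)
  expect_equal(ms2$n_common, 0L)
  expect_equal(unname(ms2$rare_by_gene["ATP6"]), 1L)

  expect_equal(modifier_scan(vt$variants, character(0))$n_common, 0L)
})
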