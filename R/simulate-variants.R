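#' Simulate an annotated exome variant table with planted ground truth
#'
#' Generates a table of exome variants carrying the annotation content the
#' prioritization cascade consumes: genotype, gene, effect, region,
#' ClinVar and HGMD classes, per-database population frequencies
#' (1000G / gnomAD / ESP), internal-database and functional-genomics
#' frequencies, and five named predictor calls. On top of the random
#' background it plants (i) a compound-heterozygous pathogenic pair in one
#' gene and (ii) rare and common exonic missense variants in
#' lysosomal-modifier genes.
#'
#' The returned `truth` is computed inside the generator by direct,
#' per-variant application of the prioritization rules (a code path
#' independent of the pipeline functions), so downstream recovery tests
#' compare against planted truth rather than re-derived values.
#'
#' @param config a [variant_table_config()]
#' @return list with `variants` (data.frame, one row per variant) and
#'   `truth` (expected retained sets, rare flags, intersection counts,
#'   modifier counts and genotype composition)
#' @export
simulate_variant_table <- function(config) {
  stopifnot(inherits(config, "variant_table_config"))
  n_bg <- config$n_variants
  pp <- config$planted_pair
  n_mod_rare <- sum(config$n_modifier_rare)
  n_planted <- 2L + n_mod_rare + config$n_modifier_common
  if (n_bg < 1L) stopf("planted pair incompatible with n_variants")

  clinvar_pool <- c("Pathogenic", "Likely Pathogenic", "Conflicting",
                    "Uncertain Significance", "Other",
                    "Benign", "Likely Benign", "Benign/Likely benign")
  hgmd_pool <- c("DM", "DM?", "other")
  effects <- c("LOF", "Missense", "Splice_region", "other")
  regions <- c("exonic", "splice-site", "other")
  predictors <- c("SIFT", "Polyphen2", "MutationTaster",
                  "MutationAssessor", "FATHMM")
  modifier_genes <- names(config$n_modifier_rare)

  with_seed(config$seed, {
    n <- n_bg + n_planted
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    # transition-biased alternate alleles for a realistic Ti/Tv
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    is_ti <- runif(n) < 0.73
    alt <- ifelse(is_ti, transition[ref],
                  vapply(ref, function(b) sample(setdiff(bases, c(b, transition[b])), 1L), ""))

    genotype <- sample(c("het", "hom"), n, replace = TRUE, prob = c(0.66, 0.34))
    gene <- sprintf("GENE%04d", sample.int(max(50L, n %/% 8L), n, replace = TRUE))
    effect <- sample(effects, n, replace = TRUE, prob = c(0.05, 0.45, 0.10, 0.40))
    region <- ifelse(effect == "other",
                     sample(regions, n, replace = TRUE, prob = c(0.3, 0.1, 0.6)),
                     sample(regions, n, replace = TRUE, prob = c(0.85, 0.10, 0.05)))

    has_clin <- runif(n) < config$fraction_clinical
    clinvar <- ifelse(has_clin & runif(n) < 0.8,
                      sample(clinvar_pool, n, replace = TRUE), NA_character_)
    hgmd <- ifelse(has_clin & runif(n) < 0.6,
                   sample(hgmd_pool, n, replace = TRUE), NA_character_)

    # frequencies: log-uniform, missing-at-random per database
    rfreq <- function(n) {
      f <- 10^runif(n, -6, log10(0.5))
      f[runif(n) < 0.25] <- NA
      f
    }
    af_1000g <- rfreq(n); af_gnomad <- rfreq(n); af_esp <- rfreq(n)
    internal_freq <- rfreq(n)
    fg_freq <- 10^runif(n, -6, log10(0.5))
    pred <- matrix(sample(c("damaging", "tolerated", "missing"), n * 5L,
                          replace = TRUE, prob = c(0.35, 0.5, 0.15)),
                   nrow = n, dimnames = list(NULL, paste0("pred_", tolower(predictors))))

    # --- plant the compound-het pair -------------------------------------
    i1 <- n_bg + 1L; i2 <- n_bg + 2L
    gene[c(i1, i2)] <- pp$gene
    for (k in 1:2) {
      i <- if (k == 1) i1 else i2
      v <- pp[[paste0("variant", k)]]
      clinvar[i] <- v$clinvar; hgmd[i] <- v$hgmd
      genotype[i] <- v$genotype
      af_1000g[i] <- unname(v$freqs[1]); af_gnomad[i] <- unname(v$freqs[2])
      af_esp[i] <- unname(v$freqs[3])
      effect[i] <- "Missense"; region[i] <- "exonic"
      internal_freq[i] <- NA; fg_freq[i] <- 1e-05
    }

    # --- plant modifier-gene variants ------------------------------------
    idx <- n_bg + 2L
    mod_idx_rare <- integer(0); mod_idx_common <- integer(0)
    for (g in modifier_genes) {
      k <- config$n_modifier_rare[[g]]
      if (k > 0) {
        ii <- idx + seq_len(k); idx <- idx + k
        gene[ii] <- g; effect[ii] <- "Missense"; region[ii] <- "exonic"
        af_1000g[ii] <- 10^runif(k, -6, -4); af_gnomad[ii] <- 10^runif(k, -6, -4)
        af_esp[ii] <- NA
        clinvar[ii] <- NA; hgmd[ii] <- NA
        mod_idx_rare <- c(mod_idx_rare, ii)
      }
    }
    if (config$n_modifier_common > 0) {
      k <- config$n_modifier_common
      ii <- idx + seq_len(k); idx <- idx + k
      gene[ii] <- sample(modifier_genes, k, replace = TRUE)
      effect[ii] <- "Missense"; region[ii] <- "exonic"
      af_1000g[ii] <- runif(k, 0.06, 0.5); af_gnomad[ii] <- runif(k, 0.06, 0.5)
      af_esp[ii] <- runif(k, 0.06, 0.5)
      clinvar[ii] <- NA; hgmd[ii] <- NA
      mod_idx_common <- ii
    }
    # keep the random background out of the modifier genes so planted
    # counts are exact
    bg_in_mod <- which(seq_len(n) <= n_bg & gene %in% c(modifier_genes, pp$gene))
    if (length(bg_in_mod)) gene[bg_in_mod] <- sprintf("GENE%04d", 9900L + bg_in_mod %% 90L)

    variants <- data.frame(
      id = sprintf("var%05d", seq_len(n)),
      chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
      pos = sample.int(5e7, n, replace = TRUE),
      ref = ref, alt = unname(alt),
      genotype = genotype, gene = gene, effect = effect, region = region,
      clinvar_class = clinvar, hgmd_class = hgmd,
      af_1000g = af_1000g, af_gnomad = af_gnomad, af_esp = af_esp,
      internal_freq = internal_freq, fg_freq = fg_freq,
      stringsAsFactors = FALSE)
    variants <- cbind(variants, as.data.frame(pred, stringsAsFactors = FALSE))
    variants$chrom[c(i1, i2)] <- "chr17"
    variants$pos[i1] <- 80111593L; variants$pos[i2] <- 80101556L

    # --- truth by direct rule application --------------------------------
    cfg <- prioritization_config()
    clin_keep <- c("Pathogenic", "Likely Pathogenic", "Conflicting",
                   "Uncertain Significance", "Other")
    pf <- cbind(af_1000g, af_gnomad, af_esp)
    clinvar_hit <- vapply(clinvar, function(x) {
      !is.na(x) && any(trimws(strsplit(x, "/")[[1]]) %in%
                         c(clin_keep, "Likely pathogenic"))
    }, logical(1), USE.NAMES = FALSE)
    hgmd_hit <- !is.na(hgmd) & hgmd %in% c("DM", "DM?")
    ann_keep <- clinvar_hit | hgmd_hit
    all_below <- function(thr)
      apply(pf, 1L, function(r) all(is.na(r)) || all(r[!is.na(r)] < thr))
    ann_rare <- all_below(cfg$annotated_maf_flag_threshold)
    n_dmg <- rowSums(pred == "damaging")
    pred_keep <- region %in% c("exonic", "splice-site") &
      is.na(clinvar) & is.na(hgmd) &
      effect %in% c("LOF", "Missense", "Splice_region") &
      n_dmg >= cfg$min_damaging_predictors &
      fg_freq < cfg$fg_freq_threshold
    pred_rare <- all_below(cfg$predicted_maf_flag_threshold)

    common_mod <- apply(pf, 1L, function(r)
      any(!is.na(r) & r > cfg$modifier_common_threshold))
    in_mod <- gene %in% modifier_genes & region == "exonic" & effect == "Missense"

    truth <- list(
      annotated_retained = variants$id[ann_keep],
      annotated_rare = variants$id[ann_keep & ann_rare],
      predicted_retained = variants$id[pred_keep],
      predicted_rare = variants$id[pred_keep & pred_rare],
      clinvar_members = variants$id[ann_keep & clinvar_hit],
      hgmd_members = variants$id[ann_keep & hgmd_hit],
      planted_pair_ids = variants$id[c(i1, i2)],
      planted_gene = pp$gene,
      modifier_rare_by_gene = vapply(
        modifier_genes,
        function(g) sum(in_mod & gene == g & !common_mod), integer(1)),
      modifier_common_total = sum(in_mod & common_mod),
      composition = list(
        n = n,
        pct_hom = 100 * mean(genotype == "hom"),
        pct_het = 100 * mean(genotype == "het")))

    list(variants = variants, truth = truth)
  })
}
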