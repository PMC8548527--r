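# Two-arm clinical variant prioritization:
#   annotated arm     — variants already classified in ClinVar or HGMD
#   predicted arm     — unclassified coding variants with in-silico support
# Frequency rules *flag* variants as rare (annotation, not a hard filter);
# downstream selections then act on the flag.

CLINVAR_RETAINED <- c("Pathogenic", "Likely Pathogenic", "Conflicting",
                      "Uncertain Significance", "Other")
HGMD_RETAINED <- c("DM", "DM?")
PREDICTOR_COLUMNS <- c("pred_sift", "pred_polyphen2", "pred_mutationtaster",
                       "pred_mutationassessor", "pred_fathmm")
POP_FREQ_COLUMNS <- c("af_1000g", "af_gnomad", "af_esp")

# ClinVar assigns multi-label strings like "Pathogenic/Likely pathogenic";
# a variant is retained if ANY component label is in the retained set
# (case-insensitive). "Benign/Likely benign" maps to the benign spectrum.
clinvar_retained <- function(clinvar_class,
                             retained = CLINVAR_RETAINED) {
  retained <- tolower(retained)
  vapply(clinvar_class, function(x) {
    if (is.na(x) || !nzchar(x)) return(FALSE)
    any(tolower(trimws(strsplit(x, "/", fixed = TRUE)[[1]])) %in% retained)
  }, logical(1), USE.NAMES = FALSE)
}

# TRUE when every non-missing population frequency is below `threshold`;
# absence from every database is not evidence of commonness, so
# all-missing is rare.
rare_flag <- function(variants, threshold,
                      freq_cols = POP_FREQ_COLUMNS) {
  freq_cols <- intersect(freq_cols, names(variants))
  m <- as.matrix(variants[, freq_cols, drop = FALSE])
  if (nrow(m) == 0L) return(logical(0))
  apply(m, 1L, function(r) all(is.na(r)) || all(r[!is.na(r)] < threshold))
}

#' Annotated-variants prioritization arm
#'
#' Retains variants carrying a clinically interpreted class: ClinVar
#' "Pathogenic", "Likely Pathogenic", "Conflicting", "Uncertain
#' Significance" or "Other" (any component of a multi-label string), or
#' HGMD "DM"/"DM?". Retained variants are rare-flagged when every
#' non-missing population frequency is below
#' `annotated_maf_flag_threshold` (default 5%).
#'
#' @param variants data.frame with at least `id`, `clinvar_class`,
#'   `hgmd_class` and the population-frequency columns `af_1000g`,
#'   `af_gnomad`, `af_esp`
#' @param config a [prioritization_config()]
#' @return a `prioritized_set`: list with `retained` (data.frame including
#'   `rare_flag` and per-variant `provenance`), `pipeline`, `config`
#' @export
annotated_pipeline <- function(variants, config = prioritization_config()) {
  cv <- clinvar_retained(variants$clinvar_class)
  hg <- !is.na(variants$hgmd_class) & variants$hgmd_class %in% HGMD_RETAINED
  keep <- cv | hg
  out <- variants[keep, , drop = FALSE]
  out$rare_flag <- rare_flag(out, config$annotated_maf_flag_threshold)
  out$provenance <- ifelse(cv[keep] & hg[keep], "clinvar+hgmd",
                           ifelse(cv[keep], "clinvar", "hgmd"))
  structure(list(retained = out, pipeline = "annotated", config = config),
            class = "prioritized_set")
}

#' Predicted-coding-variants prioritization arm
#'
#' Retains variants in exonic or splice-site regions with no reported
#' clinical significance in ClinVar or HGMD, a LOF / Missense /
#' Splice_region effect, a "damaging" call from at least
#' `min_damaging_predictors` of the five predictors, and a
#' functional-genomics database frequency below `fg_freq_threshold`.
#' Rare-flagging uses `predicted_maf_flag_threshold` (default 1%).
#'
#' @inheritParams annotated_pipeline
#' @return a `prioritized_set` with pipeline `"predicted"`
#' @export
predicted_pipeline <- function(variants, config = prioritization_config()) {
  no_class <- (is.na(variants$clinvar_class) | !nzchar(variants$clinvar_class)) &
    (is.na(variants$hgmd_class) | !nzchar(variants$hgmd_class))
  pm <- as.matrix(variants[, intersect(PREDICTOR_COLUMNS, names(variants)),
                           drop = FALSE])
  n_dmg <- rowSums(pm == "damaging", na.rm = TRUE)
  fg <- variants$fg_freq
  keep <- variants$region %in% c("exonic", "splice-site") &
    no_class &
    variants$effect %in% c("LOF", "Missense", "Splice_region") &
    n_dmg >= config$min_damaging_predictors &
    (is.na(fg) | fg < config$fg_freq_threshold)
  out <- variants[keep, , drop = FALSE]
  out$rare_flag <- rare_flag(out, config$predicted_maf_flag_threshold)
  out$provenance <- sprintf("predicted:%d_damaging", n_dmg[keep])
  structure(list(retained = out, pipeline = "predicted", config = config),
            class = "prioritized_set")
}

#' Partition an annotated prioritized set by clinical-database membership
#'
#' Splits the retained variants into ClinVar-only, HGMD-only and
#' both-database subsets, and intersects database membership with the rare
#' flag (and an optional caller-supplied severity lookup) to produce the
#' rare-clinical subset.
#'
#' @param annotated_set result of [annotated_pipeline()]
#' @param severity_lookup optional named logical vector (by variant `id`):
#'   `TRUE` marks association with a severe phenotype. Without it the
#'   rare-clinical subset is severity-unfiltered and labeled as such.
#' @return list of counts and id subsets
#' @export
clinical_intersection <- function(annotated_set, severity_lookup = NULL) {
  stopifnot(inherits(annotated_set, "prioritized_set"),
            annotated_set$pipeline == "annotated")
  r <- annotated_set$retained
  in_cv <- grepl("clinvar", r$provenance)
  in_hg <- grepl("hgmd", r$provenance)
  rare <- r$rare_flag
  if (!is.null(severity_lookup)) {
    sev <- severity_lookup[r$id]
    sev[is.na(sev)] <- FALSE
    severity_filtered <- TRUE
  } else {
    sev <- rep(TRUE, nrow(r))
    severity_filtered <- FALSE
  }
  list(n_clinvar = sum(in_cv), n_hgmd = sum(in_hg),
       n_common_to_both = sum(in_cv & in_hg),
       clinvar_ids = r$id[in_cv], hgmd_ids = r$id[in_hg],
       both_ids = r$id[in_cv & in_hg],
       rare_clinical_ids = r$id[rare & sev],
       n_rare_clinical = sum(rare & sev),
       severity_filtered = severity_filtered)
}

#' Detect recessive-diagnosis candidate genes
#'
#' A gene is a candidate when it carries at least two heterozygous
#' retained variants (mechanism: possible compound heterozygote, phase
#' unresolved — the pair is handed to phase inference) or at least one
#' homozygous retained variant (mechanism: homozygous).
#'
#' @param rare_clinical_variants data.frame with `id`, `gene`, `genotype`
#' @return list of candidates, each with `gene`, `mechanism`,
#'   `variant_ids`
#' @export
recessive_candidates <- function(rare_clinical_variants) {
  v <- rare_clinical_variants
  if (nrow(v) == 0L) return(list())
  out <- list()
  for (g in unique(v$gene)) {
    vg <- v[v$gene == g, , drop = FALSE]
    hets <- vg$id[vg$genotype == "het"]
    homs <- vg$id[vg$genotype == "hom"]
    if (length(homs) >= 1L)
      out[[length(out) + 1L]] <- list(gene = g, mechanism = "homozygous",
                                      variant_ids = homs)
    if (length(hets) >= 2L)
      out[[length(out) + 1L]] <- list(gene = g,
                                      mechanism = "possible-compound-het",
                                      variant_ids = hets)
  }
  out
}

#' Scan lysosomal-modifier genes for rare and common missense variants
#'
#' Among exonic missense variants in the supplied modifier genes, splits
#' common (any population frequency strictly above
#' `modifier_common_threshold`) from rare and reports per-gene rare
#' counts. A frequency exactly at the threshold counts as rare.
#'
#' @param all_variants full annotated variant data.frame
#' @param modifier_gene_list character vector of gene symbols; default is
#'   the lysosomal-regulator set led by ATP6 and RUNX1
#' @param config a [prioritization_config()]
#' @return list with `rare_by_gene` (named counts), `n_common`,
#'   `rare_ids`, `common_ids`
#' @export
modifier_scan <- function(all_variants,
                          modifier_gene_list = c("ATP6", "RUNX1", "TFEB",
                                                 "LAMP1", "GBA", "CTSB"),
                          config = prioritization_config()) {
  if (length(modifier_gene_list) == 0L)
    return(list(rare_by_gene = integer(0), n_common = 0L,
                rare_ids = character(0), common_ids = character(0)))
  v <- all_variants
  sel <- v$gene %in% modifier_gene_list & v$region == "exonic" &
    v$effect == "Missense"
  v <- v[sel, , drop = FALSE]
  m <- as.matrix(v[, intersect(POP_FREQ_COLUMNS, names(v)), drop = FALSE])
  common <- if (nrow(v) == 0L) logical(0) else
    apply(m, 1L, function(r) any(!is.na(r) & r > config$modifier_common_threshold))
  rare_by_gene <- vapply(modifier_gene_list,
                         function(g) sum(v$gene == g & !common), integer(1))
  list(rare_by_gene = rare_by_gene,
       n_common = sum(common),
       rare_ids = v$id[!common], common_ids = v$id[common])
}
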