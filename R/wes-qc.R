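#' Library-level mapping and duplication metrics
#'
#' Human-content percentage is the fraction of sequenced fragments mapping
#' to the human reference; the duplicate percentage is the fraction of
#' mapped reads removed as PCR duplicates. Report fields are rounded
#' half-up to 2 decimals; full precision is kept in the `*_exact` fields.
#'
#' @param n_fragments total sequenced (merged) fragments
#' @param mapped_before,mapped_after mapped read counts before/after
#'   duplicate removal
#' @param read_gc_contents optional per-read GC fractions (mapped reads);
#'   summarized as a percentage
#' @return a `library_metrics` list
#' @export
compute_library_metrics <- function(n_fragments, mapped_before, mapped_after,
                                    read_gc_contents = NULL) {
  if (any(c(n_fragments, mapped_before, mapped_after) < 0))
    stopf("counts must be non-negative")
  if (mapped_after > mapped_before)
    stopf("mapped_after (%s) exceeds mapped_before (%s)",
          mapped_after, mapped_before)
  human <- if (n_fragments > 0) 100 * mapped_before / n_fragments else NA_real_
  dupl <- if (mapped_before > 0) 100 * (1 - mapped_after / mapped_before) else NA_real_
  gc <- if (!is.null(read_gc_contents)) 100 * mean(read_gc_contents) else NA_real_
  structure(list(n_fragments = n_fragments,
                 mapped_before_dedup = mapped_before,
                 mapped_after_dedup = mapped_after,
                 gc_percent = round_half_up(gc, 2),
                 human_percent = round_half_up(human, 2),
                 duplicate_percent = round_half_up(dupl, 2),
                 human_percent_exact = human,
                 duplicate_percent_exact = dupl),
            class = "library_metrics")
}

#' Target coverage summary: mean, breadth, genotypability, FOLD80
#'
#' `fold80` is the hybrid-selection fold-80 base penalty: mean target
#' coverage divided by the 20th percentile of the per-base depth
#' distribution (linear interpolation between order statistics) — the fold
#' of extra sequencing needed to raise 80% of target bases to the mean;
#' 1.0 means perfectly uniform capture. Genotypability is approximated as
#' the fraction of target bases at or above a callable depth threshold.
#'
#' @param depths per-base depths over the target (integer vector)
#' @param min_callable_depth depth at which a base counts as callable
#' @return a `coverage_summary` list with `mean_coverage`, `pct_ge_10x`,
#'   `genotypability`, `fold80`
#' @export
compute_coverage_summary <- function(depths, min_callable_depth = 4) {
  if (length(depths) == 0L) stopf("empty target")
  mean_cov <- mean(depths)
  p20 <- unname(quantile(depths, 0.2, type = 7))
  if (p20 == 0) {
    warning("20th percentile of depth is 0: FOLD80 is infinite")
    fold80 <- Inf
  } else {
    fold80 <- mean_cov / p20
  }
  structure(list(mean_coverage = mean_cov,
                 pct_ge_10x = 100 * mean(depths >= 10),
                 genotypability = 100 * mean(depths >= min_callable_depth),
                 fold80 = fold80,
                 n_target_bases = length(depths)),
            class = "coverage_summary")
}

#' Summarize a called variant set: zygosity composition and Ti/Tv
#'
#' Transitions are A<->G and C<->T; the Ti/Tv ratio is computed over
#' biallelic SNVs. Zygosity percentages are over all genotyped variants,
#' subdivided by SNV/indel.
#'
#' @param variants data.frame with columns `ref`, `alt`, `genotype`
#'   ("het"/"hom")
#' @return a `variant_set_summary` list
#' @export
summarize_variant_set <- function(variants) {
  need <- c("ref", "alt", "genotype")
  if (!all(need %in% names(variants)))
    stopf("variants need columns %s", paste(need, collapse = ", "))
  n <- nrow(variants)
  if (n == 0L) stopf("empty variant set")
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% c("A", "C", "G", "T") & variants$alt %in% c("A", "C", "G", "T")
  hom <- variants$genotype == "hom"
  pair <- paste0(variants$ref, variants$alt)
  ti <- is_snv & pair %in% c("AG", "GA", "CT", "TC")
  tv <- is_snv & !ti
  titv <- if (sum(tv) > 0) sum(ti) / sum(tv) else NA_real_
  if (sum(tv) == 0) warning("no transversions: Ti/Tv undefined")
  pct <- function(x) 100 * sum(x) / n
  structure(list(n_variants = n,
                 pct_hom = pct(hom), pct_het = pct(!hom),
                 pct_hom_snv = pct(hom & is_snv), pct_hom_indel = pct(hom & !is_snv),
                 pct_het_snv = pct(!hom & is_snv), pct_het_indel = pct(!hom & !is_snv),
                 titv = titv),
            class = "variant_set_summary")
}
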