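#' Damage model configuration for the ancient-read simulator
#'
#' Parameterizes post-mortem cytosine deamination (C>T at the 5' end, read
#' as G>A at the 3' end) with a single-exponential decay moving inward from
#' each fragment end, a log-normal fragment-length model, and a modern
#' (undamaged) contaminant admixture fraction.
#'
#' @param terminal_ct_rate probability of C>T at 5' position 1 (and G>A at
#'   3' position 1). Untreated medieval bone libraries typically show
#'   0.1-0.3; a partially UDG-treated library retains only a small terminal
#'   signal (the default partial-UDG rate used in examples is ~0.02).
#' @param decay per-position multiplicative decay of the damage probability
#'   moving inward; position i carries rate `terminal_ct_rate * decay^(i-1)`.
#' @param udg_mode `"none"` (damage at all positions under the decay law) or
#'   `"partial"` (uracil-DNA glycosylase removed internal uracils; damage is
#'   retained only at the terminal base of each end).
#' @param mean_fragment_length mean endogenous fragment length in bp.
#' @param length_dispersion log-scale standard deviation of the log-normal
#'   length distribution (dimensionless).
#' @param contamination_fraction proportion of fragments drawn from a modern
#'   contaminant: full-length model but no deamination damage.
#' @param seed integer seed; `NULL` draws one from entropy and logs it.
#' @return an object of class `damage_model_config`
#' @export
damage_model_config <- function(terminal_ct_rate = 0.25,
                                decay = 0.5,
                                udg_mode = c("none", "partial"),
                                mean_fragment_length = 90,
                                length_dispersion = 0.35,
                                contamination_fraction = 0,
                                seed = NULL) {
  udg_mode <- match.arg(udg_mode)
  check_prob(terminal_ct_rate, "terminal_ct_rate")
  check_prob(contamination_fraction, "contamination_fraction")
  if (!is.numeric(decay) || decay <= 0 || decay > 1)
    stopf("`decay` must be in (0, 1]")
  if (mean_fragment_length <= 0) stopf("`mean_fragment_length` must be > 0")
  if (length_dispersion < 0) stopf("`length_dispersion` must be >= 0")
  structure(list(terminal_ct_rate = terminal_ct_rate,
                 decay = decay,
                 udg_mode = udg_mode,
                 mean_fragment_length = mean_fragment_length,
                 length_dispersion = length_dispersion,
                 contamination_fraction = contamination_fraction,
                 seed = seed),
            class = "damage_model_config")
}

#' Haplotype panel configuration for the founder-mosaic simulator
#'
#' @param n_haplotypes number of phased panel haplotypes.
#' @param n_sites number of polymorphic panel sites.
#' @param region_span region length in bp over which sites are placed.
#' @param n_founders number of founder haplotypes the panel is a mosaic of.
#' @param recomb_rate expected number of recombination breakpoints per
#'   panel haplotype over the region.
#' @param anchor_frequency panel allele frequency of the anchor variant
#'   (the panel-present member of the variant pair).
#' @param planted_configuration `"cis"` or `"trans"`: the true phase of the
#'   query allele relative to the anchor in the simulated proband.
#' @param seed integer seed.
#' @return an object of class `panel_config`
#' @export
panel_config <- function(n_haplotypes = 500,
                         n_sites = 120,
                         region_span = 50000,
                         n_founders = 8,
                         recomb_rate = 1,
                         anchor_frequency = 0.03,
                         planted_configuration = c("trans", "cis"),
                         seed = NULL) {
  planted_configuration <- match.arg(planted_configuration)
  if (n_haplotypes < 2 || n_sites < 3) stopf("panel too small")
  if (n_founders < 2) stopf("need >= 2 founders")
  check_prob(anchor_frequency, "anchor_frequency")
  if (anchor_frequency * n_haplotypes < 1)
    stopf("anchor_frequency * n_haplotypes < 1: no carrier haplotypes")
  if (recomb_rate < 0) stopf("`recomb_rate` must be >= 0")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_sites = as.integer(n_sites),
                 region_span = as.integer(region_span),
                 n_founders = as.integer(n_founders),
                 recomb_rate = recomb_rate,
                 anchor_frequency = anchor_frequency,
                 planted_configuration = planted_configuration,
                 seed = seed),
            class = "panel_config")
}

#' Annotated variant table configuration
#'
#' Configures the simulator for exome variant tables carrying the
#' annotation content of a clinical pipeline: genotype, gene, effect,
#' ClinVar/HGMD classes, population and functional-genomics frequencies and
#' five in-silico predictor calls, plus a planted compound-heterozygous
#' pathogenic pair in one gene.
#'
#' @param n_variants number of background variants (the planted variants are
#'   added on top).
#' @param fraction_clinical proportion of background variants carrying a
#'   ClinVar and/or HGMD class.
#' @param planted_pair list describing the compound-het pair: `gene`, and
#'   for each of the two variants `clinvar`, `hgmd`, `freq` (shared
#'   population-database frequency; `NA` entries mean absent from that
#'   database) and `genotype`. The default mirrors a classic pattern: one
#'   ultra-rare Pathogenic/Likely pathogenic + DM allele and one 3%-frequency
#'   Benign/Likely benign + DM? allele, both heterozygous.
#' @param n_modifier_rare named integer vector: rare exonic missense
#'   variants planted per lysosomal-modifier gene.
#' @param n_modifier_common number of common (MAF > 5%) exonic missense
#'   variants planted across the modifier genes.
#' @param seed integer seed.
#' @return an object of class `variant_table_config`
#' @export
variant_table_config <- function(n_variants = 2000,
                                 fraction_clinical = 0.10,
                                 planted_pair = NULL,
                                 n_modifier_rare = c(ATP6 = 6L, RUNX1 = 1L),
                                 n_modifier_common = 28L,
                                 seed = NULL) {
  if (is.null(planted_pair)) {
    planted_pair <- list(
      gene = "GAA",
      variant1 = list(clinvar = "Pathogenic/Likely pathogenic", hgmd = "DM",
                      freqs = c(`1000G` = NA, gnomAD = 9e-06, ESP = 1.5e-05),
                      genotype = "het"),
      variant2 = list(clinvar = "Benign/Likely benign", hgmd = "DM?",
                      freqs = c(`1000G` = 0.03, gnomAD = 0.03, ESP = 0.03),
                      genotype = "het"))
  }
  check_prob(fraction_clinical, "fraction_clinical")
  if (n_variants < 1) stopf("`n_variants` must be >= 1")
  if (!identical(planted_pair$variant1$genotype, planted_pair$variant2$genotype) &&
      !all(c(planted_pair$variant1$genotype, planted_pair$variant2$genotype) %in%
             c("het", "hom")))
    stopf("planted pair genotypes must be 'het' or 'hom'")
  structure(list(n_variants = as.integer(n_variants),
                 fraction_clinical = fraction_clinical,
                 planted_pair = planted_pair,
                 n_modifier_rare = n_modifier_rare,
                 n_modifier_common = as.integer(n_modifier_common),
                 seed = seed),
            class = "variant_table_config")
}

#' Prioritization thresholds
#'
#' Thresholds of the two-arm prioritization cascade. The frequency rules
#' *flag* variants as rare; they never remove a variant retained by a
#' class rule (flag-then-select semantics).
#'
#' @param annotated_maf_flag_threshold population-database alternative
#'   allele frequency below which an annotated-arm variant is rare-flagged.
#' @param predicted_maf_flag_threshold same for the predicted-coding arm.
#' @param fg_freq_threshold functional-genomics database frequency a
#'   predicted-coding variant must fall below to be retained.
#' @param min_damaging_predictors minimum number of "damaging" calls among
#'   the five in-silico predictors for the predicted-coding arm.
#' @param modifier_common_threshold MAF strictly above which a modifier-gene
#'   variant counts as common.
#' @return an object of class `prioritization_config`
#' @export
prioritization_config <- function(annotated_maf_flag_threshold = 0.05,
                                  predicted_maf_flag_threshold = 0.01,
                                  fg_freq_threshold = 0.02,
                                  min_damaging_predictors = 3L,
                                  modifier_common_threshold = 0.05) {
  for (x in c("annotated_maf_flag_threshold", "predicted_maf_flag_threshold",
              "fg_freq_threshold", "modifier_common_threshold")) {
    v <- get(x)
    if (v <= 0 || v >= 1) stopf("`%s` must be in (0, 1)", x)
  }
  if (min_damaging_predictors < 1 || min_damaging_predictors > 5)
    stopf("`min_damaging_predictors` must be in [1, 5]")
  structure(list(annotated_maf_flag_threshold = annotated_maf_flag_threshold,
                 predicted_maf_flag_threshold = predicted_maf_flag_threshold,
                 fg_freq_threshold = fg_freq_threshold,
                 min_damaging_predictors = as.integer(min_damaging_predictors),
                 modifier_common_threshold = modifier_common_threshold),
            class = "prioritization_config")
}
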