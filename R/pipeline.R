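#' Run the full degraded-DNA clinical-exome pipeline
#'
#' Executes authentication, capture QC, prioritization and phase inference
#' on the inputs present in `config`, skipping stages whose inputs are
#' absent (recorded in `skipped`) and capturing stage errors by name in
#' `errors` without aborting independent stages. Stage outputs are
#' embedded verbatim: composition adds no numerical transformation.
#'
#' @param config list; recognized entries (all optional unless a stage is
#'   wanted):
#'   \describe{
#'     \item{alignments, reference}{SAM/BAM + FASTA paths (or a data.frame
#'       and a named character vector) for the damage profile and
#'       fragment-length summary}
#'     \item{sex_counts}{list with `nX`, `nY`}
#'     \item{mt_pileup}{pileup TSV path or data.frame; `mt_error_rate`
#'       (default 0.01)}
#'     \item{x_polymorphic, x_monomorphic}{site-count TSV paths or
#'       data.frames}
#'     \item{library_counts}{list with `n_fragments`, `mapped_before`,
#'       `mapped_after`}
#'     \item{depths}{per-base depth vector or single-column TSV path}
#'     \item{variants}{annotated VCF path or variant data.frame}
#'     \item{panel, anchor, query, sample_genotypes, variant_freqs}{phase
#'       stage inputs; `phase_threshold` (default 0.98)}
#'     \item{damage_window}{profile window (default 25)}
#'     \item{seed}{recorded in provenance}
#'     \item{out_dir}{if set, the report is written there as JSON and TSV}
#'   }
#' @return an `analysis_report` list with sections `authentication`, `qc`,
#'   `prioritization`, `phase`, plus `skipped`, `errors` and `provenance`
#' @export
run_pipeline <- function(config) {
  report <- list(authentication = list(), qc = list(),
                 prioritization = list(), phase = list(),
                 skipped = character(0), errors = list(),
                 provenance = list(seed = config$seed,
                                   package_version = as.character(
                                     utils::packageVersion("relicdx"))))
  run_stage <- function(name, have, expr) {
    if (!have) {
      report$skipped <<- c(report$skipped, name)
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  load_df <- function(x) if (is.character(x)) read_pileup_tsv(x) else x

  # --- authentication -----------------------------------------------------
  aln <- NULL
  if (!is.null(config$alignments)) {
    aln <- if (is.character(config$alignments)) read_sam(config$alignments)
           else config$alignments
  }
  ref <- NULL
  if (!is.null(config$reference)) {
    ref <- if (is.character(config$reference) && length(config$reference) == 1L &&
                 file.exists(config$reference)) read_reference_fasta(config$reference)
           else config$reference
  }
  report$authentication$damage_profile <- run_stage(
    "damage_profile", !is.null(aln) && !is.null(ref),
    compute_misincorporation_profile(aln, ref,
                                     window = config$damage_window %||% 25))
  report$authentication$fragment_lengths <- run_stage(
    "fragment_lengths", !is.null(aln), summarize_fragment_lengths(aln))
  report$authentication$sex_call <- run_stage(
    "sex_call", !is.null(config$sex_counts),
    determine_genetic_sex(config$sex_counts$nX, config$sex_counts$nY))
  report$authentication$mt_contamination <- run_stage(
    "mt_contamination", !is.null(config$mt_pileup),
    estimate_mt_contamination(load_df(config$mt_pileup),
                              error_rate = config$mt_error_rate %||% 0.01))
  report$authentication$x_contamination <- run_stage(
    "x_contamination",
    !is.null(config$x_polymorphic) && !is.null(config$x_monomorphic),
    estimate_x_contamination(load_df(config$x_polymorphic),
                             load_df(config$x_monomorphic)))

  # --- qc ------------------------------------------------------------------
  report$qc$library_metrics <- run_stage(
    "library_metrics", !is.null(config$library_counts),
    with(config$library_counts,
         compute_library_metrics(n_fragments, mapped_before, mapped_after)))
  depths <- config$depths
  if (is.character(depths)) depths <- read.delim(depths)$depth
  report$qc$coverage <- run_stage(
    "coverage", !is.null(depths), compute_coverage_summary(depths))

  variants <- NULL
  if (!is.null(config$variants)) {
    variants <- if (is.character(config$variants)) read_variant_vcf(config$variants)
                else config$variants
  }
  report$qc$variant_set <- run_stage(
    "variant_set", !is.null(variants), summarize_variant_set(variants))

  # --- prioritization -------------------------------------------------------
  pcfg <- config$prioritization_config %||% prioritization_config()
  pri <- run_stage("prioritization", !is.null(variants), {
    ann <- annotated_pipeline(variants, pcfg)
    prd <- predicted_pipeline(variants, pcfg)
    ci <- clinical_intersection(ann, config$severity_lookup)
    rare_clin <- ann$retained[ann$retained$id %in% ci$rare_clinical_ids, ,
                              drop = FALSE]
    list(n_annotated = nrow(ann$retained),
         n_predicted = nrow(prd$retained),
         intersection = ci[c("n_clinvar", "n_hgmd", "n_common_to_both",
                             "n_rare_clinical", "severity_filtered")],
         candidates = recessive_candidates(rare_clin),
         modifier = modifier_scan(variants, config = pcfg)[
           c("rare_by_gene", "n_common")],
         annotated_ids = ann$retained$id,
         predicted_ids = prd$retained$id)
  })
  report$prioritization <- pri %||% list()
  if (is.null(variants)) report$skipped <- unique(c(report$skipped, "prioritization"))

  # --- phase ----------------------------------------------------------------
  panel <- NULL
  if (!is.null(config$panel)) {
    panel <- if (is.character(config$panel)) read_panel_vcf(config$panel)
             else config$panel
  }
  report$phase <- run_stage(
    "phase", !is.null(panel) && !is.null(config$anchor) && !is.null(config$query),
    {
      block <- find_anchor_block(panel, config$anchor,
                                 threshold = config$phase_threshold %||% 0.98)
      call <- infer_configuration(block, config$query, panel,
                                  config$sample_genotypes %||%
                                    list(anchor = "het", query = "het"),
                                  freqs = config$variant_freqs)
      list(block = list(interval = block$interval,
                        n_member_sites = length(block$member_sites),
                        n_carriers = block$n_carriers),
           call = call)
    }) %||% list()
  if (is.null(panel)) report$skipped <- unique(c(report$skipped, "phase"))

  class(report) <- "analysis_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report as JSON plus a flat TSV of headline numbers
#'
#' @param report an `analysis_report`
#' @param dir output directory (created if needed)
#' @return the JSON path, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report_numbers(report)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(slim, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  flat <- unlist(slim)
  write.table(data.frame(metric = names(flat), value = unname(flat)),
              file.path(dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}

# Flatten the report to plain named numbers/strings for serialization.
report_numbers <- function(report) {
  a <- report$authentication
  out <- list(provenance = report$provenance,
              skipped = as.list(report$skipped),
              errors = report$errors)
  if (!is.null(a$damage_profile))
    out$authentication$ct_5p_position1 <- unname(a$damage_profile$five_prime_ct[1])
  if (!is.null(a$fragment_lengths)) {
    out$authentication$fragment_mean <- a$fragment_lengths$mean
    out$authentication$fragment_median <- a$fragment_lengths$median
  }
  if (!is.null(a$sex_call))
    out$authentication[c("ry", "ry_se", "sex_classification")] <-
      a$sex_call[c("ry", "se", "classification")]
  for (m in c("mt_contamination", "x_contamination"))
    if (!is.null(a[[m]]))
      out$authentication[paste0(m, c("", "_se"))] <-
        a[[m]][c("estimate", "stderr")]
  q <- report$qc
  if (!is.null(q$library_metrics))
    out$qc[c("human_percent", "duplicate_percent")] <-
      q$library_metrics[c("human_percent", "duplicate_percent")]
  if (!is.null(q$coverage))
    out$qc[c("mean_coverage", "pct_ge_10x", "genotypability", "fold80")] <-
      q$coverage[c("mean_coverage", "pct_ge_10x", "genotypability", "fold80")]
  if (!is.null(q$variant_set))
    out$qc[c("n_variants", "pct_hom", "pct_het", "titv")] <-
      q$variant_set[c("n_variants", "pct_hom", "pct_het", "titv")]
  p <- report$prioritization
  if (length(p)) {
    out$prioritization <- p[c("n_annotated", "n_predicted", "intersection")]
    out$prioritization$n_candidates <- length(p$candidates)
    out$prioritization$modifier <- p$modifier
  }
  ph <- report$phase
  if (length(ph)) {
    out$phase <- list(configuration = ph$call$configuration,
                      spanning = ph$call$spanning,
                      carrier_query_allele_fraction =
                        ph$call$carrier_query_allele_fraction,
                      block_start = unname(ph$block$interval["start"]),
                      block_end = unname(ph$block$interval["end"]))
    if (!is.null(ph$call$freq_evidence))
      out$phase$cooccurrence_probability <-
        ph$call$freq_evidence$cooccurrence_probability
  }
  out
}

#' Generate a complete demo fixture bundle
#'
#' One call generates every input the pipeline consumes — damaged reads
#' (SAM) over a random reference (FASTA), target BED, per-base depths,
#' sex-chromosome counts, mitochondrial and X pileups, an annotated
#' variant VCF with a planted compound-het pair, and a phased panel VCF
#' with a planted trans query — plus the ground-truth JSON, and returns a
#' `run_pipeline()`-ready config.
#'
#' @param seed integer seed; all sub-generator seeds derive from it
#' @param dir output directory (default: a fresh tempdir subdirectory)
#' @return list with `config` (for [run_pipeline()]), `truth`, `dir`
#' @export
make_demo_dataset <- function(seed = 1, dir = tempfile("relicdx_demo_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  sub <- function(k) (seed * 97L + k) %% .Machine$integer.max

  ref <- with_seed(sub(1L), setNames(
    paste(sample(c("A", "C", "G", "T"), 40000, replace = TRUE), collapse = ""),
    "chrA"))
  ref_path <- write_reference_fasta(ref, file.path(dir, "reference.fasta"))

  dmg <- damage_model_config(terminal_ct_rate = 0.25, decay = 0.5,
                             mean_fragment_length = 90, seed = sub(2L))
  frags <- simulate_adna_fragments(dmg, ref, n = 3000)
  sam_path <- write_sam(frags$alignments, ref, file.path(dir, "reads.sam"))

  sexc <- simulate_sexed_alignment_counts("XY", 20000, seed = sub(3L))
  mt <- simulate_mt_pileup(0.005, depth = 100, n_diagnostic_sites = 30,
                           error_rate = 0.01, seed = sub(4L))
  mt_path <- write_pileup_tsv(mt$pileup, file.path(dir, "mt_pileup.tsv"))
  xp <- simulate_x_pileup(0.002, n_polymorphic = 400, n_monomorphic = 400,
                          depth = 30, seed = sub(5L))
  xp_path <- write_pileup_tsv(xp$polymorphic, file.path(dir, "x_polymorphic.tsv"))
  xm_path <- write_pileup_tsv(xp$monomorphic, file.path(dir, "x_monomorphic.tsv"))

  depths <- with_seed(sub(6L), rpois(20000, 30))
  depth_path <- file.path(dir, "depths.tsv")
  write.table(data.frame(depth = depths), depth_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines("chrA\t0\t20000\ttarget", file.path(dir, "targets.bed"))

  vt <- simulate_variant_table(variant_table_config(n_variants = 500,
                                                    seed = sub(7L)))
  vcf_path <- write_variant_vcf(vt$variants, file.path(dir, "variants.vcf"))

  pan <- simulate_haplotype_panel(panel_config(n_haplotypes = 200,
                                               planted_configuration = "trans",
                                               seed = sub(8L)))
  panel_path <- write_panel_vcf(pan$panel, file.path(dir, "panel.vcf"))

  truth <- list(fragments = list(n = nrow(frags$truth),
                                 n_contaminant = sum(frags$truth$contaminant),
                                 damage = dmg[c("terminal_ct_rate", "decay",
                                                "udg_mode")]),
                sex = sexc$sex,
                mt_contamination = mt$truth$true_contamination,
                x_contamination = xp$truth$true_contamination,
                variants = vt$truth,
                phase = pan$truth[c("configuration", "n_carriers")])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  config <- list(seed = seed,
                 alignments = sam_path, reference = ref_path,
                 sex_counts = sexc[c("nX", "nY")],
                 mt_pileup = mt_path, mt_error_rate = 0.01,
                 x_polymorphic = xp_path, x_monomorphic = xm_path,
                 library_counts = list(n_fragments = 7924124,
                                       mapped_before = 1856551,
                                       mapped_after = 1533864),
                 depths = depth_path,
                 variants = vcf_path,
                 panel = panel_path,
                 anchor = list(pos = pan$anchor$pos, allele = 1L),
                 query = list(pos = pan$query$pos, allele = 1L),
                 sample_genotypes = pan$sample_genotypes,
                 variant_freqs = list(anchor = 0.03, query = 9e-06),
                 phase_threshold = 0.98)
  list(config = config, truth = truth, dir = dir)
}

#' Plot a terminal damage profile
#'
#' Base-graphics plot of the 5' C>T and 3' G>A frequencies by distance
#' from the fragment end.
#'
#' @param profile a `damage_profile`
#' @param ... passed to [graphics::plot()]
#' @return the profile, invisibly
#' @export
plot_damage_profile <- function(profile, ...) {
  stopifnot(inherits(profile, "damage_profile"))
  w <- profile$window
  ylim <- range(0, profile$five_prime_ct, profile$three_prime_ga, na.rm = TRUE)
  graphics::plot(seq_len(w), profile$five_prime_ct, type = "b", col = "red",
                 pch = 16, xlab = "distance from fragment end (bp)",
                 ylab = "substitution frequency", ylim = ylim, ...)
  graphics::lines(seq_len(w), profile$three_prime_ga, type = "b",
                  col = "blue", pch = 17)
  graphics::legend("topright", c("5' C>T", "3' G>A"), col = c("red", "blue"),
                   pch = c(16, 17), bty = "n")
  invisible(profile)
}
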