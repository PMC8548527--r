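#' Simulate a phased haplotype panel with a planted anchor/query pair
#'
#' Builds a panel of phased haplotypes as mosaics of a small set of founder
#' haplotypes with Poisson-distributed recombination breakpoints. The
#' anchor allele lives on one founder lineage only, so its carriers share
#' an identical surrounding block; the query variant position lies inside
#' that block but its alternative allele is absent from every panel
#' haplotype (trans configuration) or planted onto the carrier haplotypes
#' (cis). A proband record heterozygous for both variants carries the
#' planted phase as truth.
#'
#' @param config a [panel_config()]
#' @return list with `panel` (a `haplotype_panel`), `anchor` and `query`
#'   (lists: site index, position, alleles), `sample_genotypes` (both
#'   `"het"`) and `truth` (planted configuration and carrier rows)
#' @export
simulate_haplotype_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, {
    n_hap <- config$n_haplotypes
    n_sites <- config$n_sites
    n_f <- config$n_founders

    positions <- sort(sample.int(config$region_span - 2L, n_sites)) + 1L
    anchor_site <- as.integer(ceiling(n_sites / 2))
    query_site <- anchor_site + 1L

    # founder alleles; founder 1 is the anchor lineage
    site_freq <- runif(n_sites, 0.05, 0.95)
    founders <- matrix(0L, n_f, n_sites)
    for (f in seq_len(n_f))
      founders[f, ] <- as.integer(runif(n_sites) < site_freq)
    founders[, anchor_site] <- 0L
    founders[1L, anchor_site] <- 1L
    founders[, query_site] <- 0L  # query allele absent from all founders

    n_carriers <- max(1L, as.integer(round(config$anchor_frequency * n_hap)))
    carriers <- sample.int(n_hap, n_carriers)

    hap <- matrix(0L, n_hap, n_sites)
    for (h in seq_len(n_hap)) {
      n_bp <- rpois(1L, config$recomb_rate)
      bp <- sort(runif(n_bp, 1, config$region_span))
      seg <- findInterval(positions, bp) + 1L  # segment index per site
      n_seg <- max(seg)
      is_carrier <- h %in% carriers
      anchor_seg <- seg[anchor_site]
      # carriers copy the anchor lineage in the anchor segment;
      # non-carriers must not
      choices <- vapply(seq_len(n_seg), function(s) {
        if (is_carrier && s == anchor_seg) return(1L)
        if (!is_carrier && s == anchor_seg)
          return(1L + sample.int(n_f - 1L, 1L))
        sample.int(n_f, 1L)
      }, integer(1))
      hap[h, ] <- founders[cbind(choices[seg], seq_len(n_sites))]
    }
    if (config$planted_configuration == "cis")
      hap[carriers, query_site] <- 1L

    panel <- haplotype_panel(
      positions = positions,
      alleles = hap,
      sample_labels = sprintf("hap%04d", seq_len(n_hap)),
      region = list(chrom = "chr17",
                    start = 1L, end = config$region_span))

    list(panel = panel,
         anchor = list(site = anchor_site, pos = positions[anchor_site],
                       allele = 1L),
         query = list(site = query_site, pos = positions[query_site],
                      allele = 1L),
         sample_genotypes = list(anchor = "het", query = "het"),
         truth = list(configuration = config$planted_configuration,
                      carriers = sort(carriers),
                      n_carriers = n_carriers))
  })
}

#' Construct a phased haplotype panel
#'
#' @param positions strictly increasing integer genomic coordinates
#' @param alleles integer matrix, haplotypes x sites, coded 0 (ref) /
#'   1 (alt); `NA` = missing
#' @param sample_labels haplotype labels (two consecutive haplotypes form
#'   one individual)
#' @param region list with `chrom`, `start`, `end`
#' @return an object of class `haplotype_panel`
#' @export
haplotype_panel <- function(positions, alleles, sample_labels = NULL,
                            region = NULL) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stopf("panel positions must be strictly increasing")
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != length(positions))
    stopf("alleles matrix has %d columns but %d positions",
          ncol(alleles), length(positions))
  if (is.null(sample_labels))
    sample_labels <- sprintf("hap%04d", seq_len(nrow(alleles)))
  if (is.null(region))
    region <- list(chrom = "chr1", start = min(positions), end = max(positions))
  structure(list(positions = positions, alleles = alleles,
                 sample_labels = sample_labels, region = region),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d sites (%s:%d-%d)\n",
              nrow(x$alleles), length(x$positions),
              x$region$chrom, x$region$start, x$region$end))
  invisible(x)
}
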