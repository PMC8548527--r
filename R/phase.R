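#' Find the concordant haplotype block around an anchor allele
#'
#' Takes the panel haplotypes carrying the anchor allele and extends
#' site-by-site left and right from the anchor: a candidate site joins the
#' block when the fraction of carriers matching the carrier-modal allele at
#' that site is at least `threshold`; extension in a direction stops at the
#' first failure. Concordance is measured against the carrier-modal allele
#' (not the panel-major allele): the block is the interval over which the
#' anchor is "consistently inherited together" with its neighbours.
#'
#' @param panel a [haplotype_panel()]
#' @param anchor list with either `site` (column index) or `pos`, plus
#'   `allele` (default 1, the alternative allele)
#' @param threshold minimum carrier concordance per site, in (0.5, 1]
#' @param unit `"haplotype"` (default): concordance over carrier
#'   haplotypes; `"individual"`: over carrier individuals (consecutive
#'   haplotype pairs), an individual concordant when all of its carrier
#'   haplotypes match the modal allele
#' @return an `anchor_block`: list with `anchor_site`, `member_sites`,
#'   `interval` (min/max member positions), `concordance` (per member
#'   site), `n_carriers`, `threshold`, `unit`
#' @export
find_anchor_block <- function(panel, anchor, threshold = 0.98,
                              unit = c("haplotype", "individual")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  unit <- match.arg(unit)
  if (threshold <= 0.5 || threshold > 1)
    stopf("`threshold` must be in (0.5, 1]")
  a_site <- anchor_site_index(panel, anchor)
  allele <- if (is.null(anchor$allele)) 1L else anchor$allele
  carriers <- which(panel$alleles[, a_site] == allele)
  if (length(carriers) == 0L) stopf("anchor has no carrier haplotypes")

  conc <- site_concordance(panel, carriers, unit)
  n_sites <- length(panel$positions)
  ok <- conc >= threshold
  lo <- a_site
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- a_site
  while (hi < n_sites && ok[hi + 1L]) hi <- hi + 1L
  member <- lo:hi

  structure(list(anchor_site = a_site,
                 anchor = anchor,
                 member_sites = member,
                 interval = c(start = panel$positions[lo],
                              end = panel$positions[hi]),
                 concordance = setNames(conc[member],
                                        panel$positions[member]),
                 n_carriers = length(carriers),
                 carriers = carriers,
                 threshold = threshold,
                 unit = unit),
            class = "anchor_block")
}

# Fraction of carriers (haplotypes or individuals) matching the
# carrier-modal allele at every site.
site_concordance <- function(panel, carriers, unit = "haplotype") {
  sub <- panel$alleles[carriers, , drop = FALSE]
  n1 <- colSums(sub == 1L, na.rm = TRUE)
  n0 <- colSums(sub == 0L, na.rm = TRUE)
  modal <- ifelse(n1 >= n0, 1L, 0L)
  if (unit == "haplotype") {
    match_count <- ifelse(modal == 1L, n1, n0)
    return(match_count / nrow(sub))
  }
  # individual mode: consecutive haplotype pairs form individuals; an
  # individual is concordant when all its carrier haplotypes match
  ind <- (carriers + 1L) %/% 2L
  vapply(seq_len(ncol(sub)), function(s) {
    m <- sub[, s] == modal[s]
    ok_ind <- tapply(m, ind, all)
    mean(ok_ind, na.rm = TRUE)
  }, numeric(1))
}

anchor_site_index <- function(panel, anchor) {
  if (!is.null(anchor$site)) {
    s <- as.integer(anchor$site)
    if (s < 1L || s > length(panel$positions)) stopf("anchor site out of range")
    return(s)
  }
  if (!is.null(anchor$pos)) {
    s <- match(as.integer(anchor$pos), panel$positions)
    if (is.na(s)) stopf("anchor position %s not a panel site", anchor$pos)
    return(s)
  }
  stopf("anchor needs `site` or `pos`")
}

#' Infer the cis/trans configuration of a panel-absent query variant
#'
#' Given the anchor-carrier block, tests whether the block spans the query
#' position, and reads the query allele off the carrier haplotypes: if the
#' block spans the query and the carrier query-allele fraction is at most
#' `1 - threshold`, the carrier haplotype is inferred to carry the
#' reference at the query site, so in a proband heterozygous for both
#' variants the two alternative alleles must lie on opposite chromosomes
#' (trans); a fraction of at least `threshold` implies cis. Anything else,
#' or a non-spanning block, is indeterminate. Population-frequency
#' co-occurrence evidence is attached either way when frequencies are
#' supplied.
#'
#' @param block an `anchor_block` from [find_anchor_block()]
#' @param query list with `site` or `pos`, plus `allele` (default 1)
#' @param panel the [haplotype_panel()] the block was found in
#' @param sample_genotypes list with `anchor` and `query` genotypes; both
#'   must be `"het"` (otherwise the configuration question is undefined)
#' @param freqs optional list/vector with `anchor` and `query` population
#'   frequencies for [frequency_cooccurrence()]
#' @return a `phase_call`: list with `configuration` ("cis", "trans" or
#'   "indeterminate"), `spanning`, `carrier_query_allele_fraction`,
#'   `freq_evidence`
#' @export
infer_configuration <- function(block, query, panel, sample_genotypes,
                                freqs = NULL) {
  stopifnot(inherits(block, "anchor_block"), inherits(panel, "haplotype_panel"))
  if (!identical(sample_genotypes$anchor, "het") ||
      !identical(sample_genotypes$query, "het"))
    stopf("sample must be heterozygous for both anchor and query; configuration undefined otherwise")

  qpos <- if (!is.null(query$pos)) as.integer(query$pos)
          else panel$positions[as.integer(query$site)]
  if (qpos < panel$region$start || qpos > panel$region$end) {
    warning("query position outside panel region")
    return(new_phase_call("indeterminate", FALSE, NA_real_, freqs))
  }
  spanning <- qpos >= block$interval["start"] && qpos <= block$interval["end"]

  q_site <- match(qpos, panel$positions)
  q_allele <- if (is.null(query$allele)) 1L else query$allele
  frac <- if (is.na(q_site)) 0 else {
    qa <- panel$alleles[block$carriers, q_site]
    mean(qa == q_allele, na.rm = TRUE)
  }

  configuration <- if (spanning && !is.na(frac) && frac <= 1 - block$threshold) {
    "trans"
  } else if (spanning && !is.na(frac) && frac >= block$threshold) {
    "cis"
  } else {
    "indeterminate"
  }
  new_phase_call(configuration, spanning, frac, freqs)
}

new_phase_call <- function(configuration, spanning, frac, freqs) {
  fe <- if (!is.null(freqs))
    frequency_cooccurrence(freqs$anchor, freqs$query) else NULL
  structure(list(configuration = configuration,
                 spanning = spanning,
                 carrier_query_allele_fraction = frac,
                 freq_anchor = if (!is.null(freqs)) freqs$anchor else NA_real_,
                 freq_query = if (!is.null(freqs)) freqs$query else NA_real_,
                 freq_evidence = fe),
            class = "phase_call")
}

#' @export
print.phase_call <- function(x, ...) {
  cat(sprintf("phase: %s (spanning = %s, carrier query-allele fraction = %s)\n",
              x$configuration, x$spanning,
              format(x$carrier_query_allele_fraction)))
  if (!is.null(x$freq_evidence))
    cat(sprintf("  frequency evidence: product %.3g (%s)\n",
                x$freq_evidence$cooccurrence_probability,
                x$freq_evidence$support))
  invisible(x)
}

#' Population-frequency co-occurrence evidence for a variant pair
#'
#' Under independence, the probability that one haplotype carries both
#' alleles is the product of their population frequencies. When both
#' variants are nonetheless observed in one individual and this product is
#' below `cutoff`, co-occurrence on the same chromosome is implausible and
#' the evidence qualitatively supports a trans configuration.
#'
#' @param freq_anchor,freq_query population allele frequencies in [0, 1];
#'   at least one must be non-missing
#' @param cutoff product below which the evidence supports trans
#' @return list with `cooccurrence_probability` and `support`
#'   ("supports-trans", "no-support" or "no-evidence")
#' @export
frequency_cooccurrence <- function(freq_anchor, freq_query, cutoff = 1e-05) {
  if ((is.null(freq_anchor) || is.na(freq_anchor)) &&
      (is.null(freq_query) || is.na(freq_query)))
    return(list(cooccurrence_probability = NA_real_, support = "no-evidence"))
  fa <- if (is.null(freq_anchor) || is.na(freq_anchor)) 1 else freq_anchor
  fq <- if (is.null(freq_query) || is.na(freq_query)) 1 else freq_query
  check_prob(fa, "freq_anchor"); check_prob(fq, "freq_query")
  p <- fa * fq
  list(cooccurrence_probability = p,
       support = if (p < cutoff) "supports-trans" else "no-support")
}
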