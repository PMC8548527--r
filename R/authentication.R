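#' Compute a terminal misincorporation (deamination) profile
#'
#' For each position i from the 5' end, reports the frequency of reads
#' showing T where the reference has C; symmetrically G read as A counted
#' from the 3' end. These are the canonical ancient-DNA damage signatures:
#' post-mortem cytosine deamination inflates C>T at the 5' terminus and is
#' read as G>A at the 3' terminus, decaying inward. Positions with zero
#' opportunities (no reference C, resp. G, at that offset) are reported as
#' `NA`, never as zero.
#'
#' @param alignments data.frame with columns `chrom`, `pos` (1-based
#'   leftmost), `seq` (full-length match; reads with indels are not
#'   supported and are skipped with a message), or a SAM/BAM file path
#'   readable by Rsamtools.
#' @param reference named character vector or `Biostrings::DNAStringSet`
#' @param window number of positions profiled from each end (>= 1)
#' @return a `damage_profile`: list with `five_prime_ct`, `three_prime_ga`
#'   (frequency vectors of length `window` with attached opportunity
#'   counts), `other_subst` (background substitution frequency at
#'   non-C/non-G reference bases), `n_fragments`, `window`
#' @export
compute_misincorporation_profile <- function(alignments, reference, window = 25) {
  if (window < 1) stopf("`window` must be >= 1")
  aln <- as_alignments(alignments)
  ref <- as_reference(reference)
  if (nrow(aln) == 0L) stopf("no aligned reads")

  bad_chrom <- !(aln$chrom %in% names(ref))
  lens <- nchar(aln$seq)
  out_of_range <- !bad_chrom & (aln$pos < 1L | aln$pos + lens - 1L > nchar(ref)[aln$chrom])
  skip <- bad_chrom | out_of_range
  if (any(skip)) {
    message(sprintf("relicdx: skipping %d reads without reference context", sum(skip)))
    aln <- aln[!skip, , drop = FALSE]
    lens <- lens[!skip]
  }
  if (nrow(aln) == 0L) stopf("no aligned reads with reference context")

  refseq <- substring(ref[aln$chrom], aln$pos, aln$pos + lens - 1L)
  rchar <- strsplit(paste(refseq, collapse = ""), "", fixed = TRUE)[[1]]
  schar <- strsplit(paste(aln$seq, collapse = ""), "", fixed = TRUE)[[1]]
  pos5 <- sequence(lens)
  pos3 <- sequence(lens, from = lens, by = -1L)

  tab <- function(sel, pos) tabulate(pos[sel & pos <= window], nbins = window)
  opp5 <- tab(rchar == "C", pos5)
  mis5 <- tab(rchar == "C" & schar == "T", pos5)
  opp3 <- tab(rchar == "G", pos3)
  mis3 <- tab(rchar == "G" & schar == "A", pos3)

  freq <- function(mis, opp) {
    f <- ifelse(opp > 0L, mis / opp, NA_real_)
    attr(f, "mismatches") <- mis
    attr(f, "opportunities") <- opp
    f
  }
  bg_opp <- sum(rchar %in% c("A", "T"))
  bg_mis <- sum(rchar %in% c("A", "T") & schar != rchar)

  structure(list(five_prime_ct = freq(mis5, opp5),
                 three_prime_ga = freq(mis3, opp3),
                 other_subst = if (bg_opp > 0) bg_mis / bg_opp else NA_real_,
                 n_fragments = nrow(aln),
                 window = as.integer(window)),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("damage_profile over %d fragments (window %d)\n",
              x$n_fragments, x$window))
  cat(sprintf("  5' C>T pos 1-3: %s\n",
              paste(format(round(x$five_prime_ct[1:min(3, x$window)], 4)),
                    collapse = " ")))
  cat(sprintf("  3' G>A pos 1-3: %s\n",
              paste(format(round(x$three_prime_ga[1:min(3, x$window)], 4)),
                    collapse = " ")))
  invisible(x)
}

#' Summarize aligned fragment lengths
#'
#' @param alignments as in [compute_misincorporation_profile()]; lengths
#'   are the aligned fragment spans.
#' @param bin_width histogram bin width in bp
#' @return a `fragment_length_summary`: list with `mean`, `median`,
#'   `histogram` (counts per bin), `n`
#' @export
summarize_fragment_lengths <- function(alignments, bin_width = 5) {
  aln <- as_alignments(alignments)
  if (nrow(aln) == 0L) stopf("no alignments")
  lens <- nchar(aln$seq)
  breaks <- seq(0, max(lens) + bin_width, by = bin_width)
  h <- table(cut(lens, breaks, right = TRUE))
  structure(list(mean = mean(lens), median = median(lens),
                 histogram = setNames(as.integer(h), names(h)),
                 n = length(lens)),
            class = "fragment_length_summary")
}

#' Determine genetic sex from sex-chromosome alignment counts
#'
#' Computes the Ry statistic, the fraction of sex-chromosome alignments
#' hitting the Y: `ry = nY / (nX + nY)`, with standard error
#' `sqrt(ry (1 - ry) / (nX + nY))`. Classification uses the published Ry
#' cutoffs with a 95% confidence guard: `ry + 1.96 se < 0.016` is
#' consistent with XX, `ry - 1.96 se > 0.075` consistent with XY,
#' otherwise indeterminate.
#'
#' @param nX,nY alignment counts on X and Y (already filtered to mapping
#'   quality >= 30)
#' @param min_count minimum `nX + nY` for a confident call
#' @param xx_threshold,xy_threshold classification cutoffs on Ry
#' @return a `sex_call`: list with `nX`, `nY`, `ry`, `se`, `classification`
#' @export
determine_genetic_sex <- function(nX, nY, min_count = 100,
                                  xx_threshold = 0.016, xy_threshold = 0.075) {
  if (nX < 0 || nY < 0) stopf("counts must be non-negative")
  n <- nX + nY
  ry <- if (n > 0) nY / n else NA_real_
  se <- if (n > 0) sqrt(ry * (1 - ry) / n) else NA_real_
  if (n < min_count) {
    warning(sprintf("only %d sex-chromosome alignments (< %d): call is indeterminate",
                    n, min_count))
    cls <- "indeterminate"
  } else if (ry + 1.96 * se < xx_threshold) {
    cls <- "consistent-with-XX"
  } else if (ry - 1.96 * se > xy_threshold) {
    cls <- "consistent-with-XY"
  } else {
    cls <- "indeterminate"
  }
  structure(list(nX = nX, nY = nY, ry = ry, se = se, classification = cls),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("Ry = %.4f +/- %.4f (nX = %d, nY = %d): %s\n",
              x$ry, x$se, x$nX, x$nY, x$classification))
  invisible(x)
}

# Accept a data.frame of alignments or a SAM/BAM path.
as_alignments <- function(x) {
  if (is.data.frame(x)) {
    need <- c("chrom", "pos", "seq")
    if (!all(need %in% names(x)))
      stopf("alignments data.frame needs columns %s", paste(need, collapse = ", "))
    return(x)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_sam(x))
  stopf("alignments must be a data.frame or an existing SAM/BAM path")
}
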