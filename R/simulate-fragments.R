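#' Simulate aligned ancient-DNA fragments with terminal deamination damage
#'
#' Draws fragments from a reference, applies the configured damage model
#' (C>T near the 5' end, G>A near the 3' end, exponentially decaying
#' inward), and mixes in a fraction of undamaged modern contaminant
#' fragments. Returns SAM-convention alignment records together with a
#' truth table recording, per read, the contaminant status, the chromosome
#' of origin and the number of damage events introduced.
#'
#' Endogenous fragment lengths are log-normal with arithmetic mean
#' `mean_fragment_length` and log-sd `length_dispersion`. At 5' position i
#' a reference C becomes T with probability `terminal_ct_rate * decay^(i-1)`
#' (symmetrically G>A at 3' position i); in partial-UDG mode only position
#' 1 from each end can be damaged.
#'
#' @param config a [damage_model_config()]
#' @param reference named character vector or `Biostrings::DNAStringSet`
#' @param n number of fragments (>= 1)
#' @return list with `alignments` (data.frame: qname, chrom, pos, length,
#'   seq) and `truth` (data.frame: qname, chrom, contaminant,
#'   n_damage_ct, n_damage_ga, length)
#' @export
simulate_adna_fragments <- function(config, reference, n) {
  stopifnot(inherits(config, "damage_model_config"))
  ref <- as_reference(reference)
  if (n < 1) stopf("`n` must be >= 1")
  n <- as.integer(n)

  with_seed(config$seed, {
    sdlog <- config$length_dispersion
    meanlog <- log(config$mean_fragment_length) - sdlog^2 / 2
    lens <- pmax(15L, as.integer(round(rlnorm(n, meanlog, sdlog))))
    chrom_lens <- nchar(ref)
    lens <- pmin(lens, max(chrom_lens))

    # fragment origin weighted by chromosome length among chromosomes that
    # can hold the fragment
    chrom_idx <- sample.int(length(ref), n, replace = TRUE,
                            prob = chrom_lens / sum(chrom_lens))
    too_long <- lens > chrom_lens[chrom_idx]
    lens[too_long] <- chrom_lens[chrom_idx][too_long]
    starts <- 1L + as.integer(floor(runif(n) * (chrom_lens[chrom_idx] - lens + 1L)))

    seqs <- substring(ref[chrom_idx], starts, starts + lens - 1L)
    contaminant <- runif(n) < config$contamination_fraction

    # flatten to one character vector; per-base distance from each end
    chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
    pos5 <- sequence(lens)
    pos3 <- sequence(lens, from = lens, by = -1L)
    read_of <- rep.int(seq_len(n), lens)

    rate <- config$terminal_ct_rate
    if (config$udg_mode == "partial") {
      p5 <- ifelse(pos5 == 1L, rate, 0)
      p3 <- ifelse(pos3 == 1L, rate, 0)
    } else {
      p5 <- rate * config$decay^(pos5 - 1L)
      p3 <- rate * config$decay^(pos3 - 1L)
    }
    endo <- !contaminant[read_of]
    hit_ct <- endo & chars == "C" & runif(length(chars)) < p5
    hit_ga <- endo & chars == "G" & runif(length(chars)) < p3
    chars[hit_ct] <- "T"
    chars[hit_ga] <- "A"

    damaged <- substring(paste(chars, collapse = ""),
                         cumsum(lens) - lens + 1L, cumsum(lens))
    qname <- sprintf("frag%06d", seq_len(n))
    alignments <- data.frame(qname = qname,
                             chrom = names(ref)[chrom_idx],
                             pos = starts,
                             length = lens,
                             seq = damaged,
                             stringsAsFactors = FALSE)
    truth <- data.frame(qname = qname,
                        chrom = names(ref)[chrom_idx],
                        contaminant = contaminant,
                        n_damage_ct = as.integer(tabulate(read_of[hit_ct], n)),
                        n_damage_ga = as.integer(tabulate(read_of[hit_ga], n)),
                        length = lens,
                        stringsAsFactors = FALSE)
    list(alignments = alignments, truth = truth)
  })
}

#' Simulate X/Y alignment counts for a given karyotype
#'
#' Allocates sex-chromosome alignments between X and Y consistent with the
#' requested karyotype: for XY, each read hits the Y with probability equal
#' to the relative mappable length of the Y (default 0.09); for XX, Y hits
#' occur only through mismapping (default rate 0.002).
#'
#' @param sex `"XY"` or `"XX"`
#' @param n_sex_chromosome_reads total reads on X+Y (>= 1)
#' @param seed integer seed
#' @param male_y_share expected Y fraction of sex-chromosome alignments in
#'   an XY individual
#' @param mismap_rate probability an X read of an XX individual is
#'   mismapped to the Y
#' @return list with integer counts `nX`, `nY` and the truth `sex`
#' @export
simulate_sexed_alignment_counts <- function(sex, n_sex_chromosome_reads,
                                            seed = NULL,
                                            male_y_share = 0.09,
                                            mismap_rate = 0.002) {
  if (!sex %in% c("XY", "XX")) stopf("unknown sex label '%s'", sex)
  if (n_sex_chromosome_reads < 1) stopf("`n_sex_chromosome_reads` must be >= 1")
  n <- as.integer(n_sex_chromosome_reads)
  with_seed(seed, {
    p <- if (sex == "XY") male_y_share else mismap_rate
    nY <- rbinom(1L, n, p)
    list(nX = n - nY, nY = nY, sex = sex)
  })
}

#' Simulate a mitochondrial pileup under a two-source contamination model
#'
#' At each diagnostic site (where the endogenous consensus and the
#' contaminant allele differ), each read base derives from the contaminant
#' with probability `true_contamination`, then is flipped to a uniformly
#' chosen other base with probability `error_rate`.
#'
#' @param true_contamination contaminant proportion in [0, 1]
#' @param depth reads per site (>= 1)
#' @param n_diagnostic_sites number of diagnostic sites
#' @param error_rate per-base sequencing error probability
#' @param seed integer seed
#' @return list with `pileup` (data.frame: chrom, pos, endogenous,
#'   contaminant, bases — the bases column a string of length `depth`) and
#'   `truth` (per-site count of contaminant-derived reads plus the
#'   generating parameters)
#' @export
simulate_mt_pileup <- function(true_contamination, depth, n_diagnostic_sites = 50,
                               error_rate = 0.01, seed = NULL) {
  check_prob(true_contamination, "true_contamination")
  check_prob(error_rate, "error_rate")
  if (depth < 1) stopf("`depth` must be >= 1")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    endo <- sample(bases, n_diagnostic_sites, replace = TRUE)
    cont <- vapply(endo, function(b) sample(setdiff(bases, b), 1L), "")
    n_cont <- integer(n_diagnostic_sites)
    pile <- character(n_diagnostic_sites)
    for (s in seq_len(n_diagnostic_sites)) {
      from_cont <- runif(depth) < true_contamination
      b <- ifelse(from_cont, cont[s], endo[s])
      err <- runif(depth) < error_rate
      if (any(err))
        b[err] <- vapply(b[err], function(x) sample(setdiff(bases, x), 1L), "")
      n_cont[s] <- sum(from_cont)
      pile[s] <- paste(b, collapse = "")
    }
    list(pileup = data.frame(chrom = "chrM", pos = seq_len(n_diagnostic_sites) * 100L,
                             endogenous = endo, contaminant = cont,
                             bases = pile, stringsAsFactors = FALSE),
         truth = list(true_contamination = true_contamination,
                      error_rate = error_rate, depth = depth,
                      n_contaminant_reads = n_cont))
  })
}

#' Simulate male X-chromosome pileups at polymorphic and monomorphic sites
#'
#' A male sample is hemizygous on the X, so any minor-allele signal at
#' polymorphic sites beyond the sequencing-error baseline (measured at
#' flanking monomorphic sites) indicates contamination. Contaminant reads
#' carry the alternative allele at polymorphic sites.
#'
#' @param true_contamination contaminant proportion
#' @param n_polymorphic,n_monomorphic site counts
#' @param depth reads per site
#' @param error_rate per-base error probability (flip to one of the three
#'   other bases)
#' @param seed integer seed
#' @return list with `polymorphic` and `monomorphic` data.frames
#'   (site, n_match, n_mismatch) and `truth`
#' @export
simulate_x_pileup <- function(true_contamination, n_polymorphic = 1344,
                              n_monomorphic = 1344, depth = 30,
                              error_rate = 0.005, seed = NULL) {
  check_prob(true_contamination, "true_contamination")
  with_seed(seed, {
    sim_sites <- function(n_sites, p_source_mismatch) {
      k <- n_sites * depth
      alt_source <- matrix(runif(k) < p_source_mismatch, depth, n_sites)
      err <- matrix(runif(k) < error_rate, depth, n_sites)
      # an error turns a matching base into a mismatch; on an alt-source
      # base it returns to the reference 1/3 of the time
      back <- err & alt_source & matrix(runif(k) < 1 / 3, depth, n_sites)
      mism <- (alt_source & !back) | (!alt_source & err)
      n_mm <- colSums(mism)
      data.frame(site = seq_len(n_sites), n_match = depth - n_mm,
                 n_mismatch = n_mm)
    }
    list(polymorphic = sim_sites(n_polymorphic, true_contamination),
         monomorphic = sim_sites(n_monomorphic, 0),
         truth = list(true_contamination = true_contamination,
                      error_rate = error_rate, depth = depth))
  })
}
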