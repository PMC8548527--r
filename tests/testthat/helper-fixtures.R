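# Shared fixtures and independent oracles.

random_reference <- function(len = 50000, seed = 99, name = "chr1") {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""), name)
}

# Alignment data.frame from explicit sequences placed on a reference of As
# (so there are no C/G damage opportunities unless stated).
aln_df <- function(seqs, chrom = "chr1", pos = 1L) {
  data.frame(qname = sprintf("r%03d", seq_along(seqs)),
             chrom = rep_len(chrom, length(seqs)),
             pos = rep_len(pos, length(seqs)),
             seq = seqs, stringsAsFactors = FALSE)
}

# Independent brute-force oracle for the anchor block: test every
# contiguous site interval containing the anchor for the per-site
# concordance property and return the maximal passing interval. Its
# concordance computation is its own loop, not site_concordance().
oracle_anchor_block <- function(panel, anchor_site, allele = 1L,
                                threshold = 0.98) {
  carriers <- which(panel$alleles[, anchor_site] == allele)
  n_sites <- length(panel$positions)
  conc <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    a <- panel$alleles[carriers, s]
    n1 <- sum(a == 1L); n0 <- sum(a == 0L)
    modal <- if (n1 >= n0) 1L else 0L
    conc[s] <- sum(a == modal) / length(carriers)
  }
  best <- c(anchor_site, anchor_site)
  for (i in seq_len(anchor_site)) {
    for (j in anchor_site:n_sites) {
      if (all(conc[i:j] >= threshold) &&
          (j - i) > (best[2] - best[1])) best <- c(i, j)
    }
  }
  best[1]:best[2]
}

# Random small panel with at least one anchor carrier.
random_small_panel <- function(seed) {
  set.seed(seed)
  n_hap <- sample(4:20, 1)
  n_sites <- sample(5:50, 1)
  alleles <- matrix(rbinom(n_hap * n_sites, 1L,
                           runif(1, 0.1, 0.9)), n_hap, n_sites)
  anchor_site <- sample(n_sites, 1)
  if (all(alleles[, anchor_site] == 0L))
    alleles[sample(n_hap, 1), anchor_site] <- 1L
  positions <- sort(sample.int(10 * n_sites, n_sites))
  list(panel = haplotype_panel(positions, alleles),
       anchor_site = anchor_site)
}

# Independent per-read grid-likelihood oracle for the mt contamination
# estimator: loops over individual read bases, no per-site count
# aggregation.
oracle_mt_grid <- function(pileup, error_rate, grid_step = 0.001) {
  pileup <- pileup[pileup$endogenous != pileup$contaminant, , drop = FALSE]
  grid <- seq(0, 1, by = grid_step)
  ll <- sapply(grid, function(c) {
    tot <- 0
    for (s in seq_len(nrow(pileup))) {
      for (b in strsplit(pileup$bases[s], "")[[1]]) {
        pe <- if (b == pileup$endogenous[s]) 1 - error_rate else error_rate / 3
        pc <- if (b == pileup$contaminant[s]) 1 - error_rate else error_rate / 3
        p <- (1 - c) * pe + c * pc
        tot <- tot + log(max(p, .Machine$double.xmin))
      }
    }
    tot
  })
  grid[which.max(ll)]
}
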