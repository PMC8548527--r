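# File-format frontends. Reading of the standard formats goes through
# Rsamtools (SAM/BAM), Biostrings (FASTA) and vcfR (VCF); the small
# plain-text writers below emit the package's own simulated data.

#' Write alignments as SAM
#'
#' @param alignments data.frame with `qname`, `chrom`, `pos`, `seq`
#' @param reference named character vector or DNAStringSet (for the
#'   `@SQ` header lines)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sam <- function(alignments, reference, path) {
  ref <- as_reference(reference)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)))
  body <- sprintf("%s\t0\t%s\t%d\t37\t%dM\t*\t0\t0\t%s\t*",
                  alignments$qname, alignments$chrom,
                  as.integer(alignments$pos),
                  nchar(alignments$seq), alignments$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM/BAM alignments into the package's data.frame convention
#'
#' Uses Rsamtools; reads with indel/clip CIGARs are skipped with a
#' message (the damage profiler assumes full-length matches).
#'
#' @param path SAM or BAM file
#' @return data.frame with `qname`, `chrom`, `pos`, `seq`
#' @export
read_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "seq", "cigar"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos) & grepl("^[0-9]+M$", x$cigar)
  n_skip <- sum(!is.na(x$pos)) - sum(keep)
  if (n_skip > 0)
    message(sprintf("relicdx: skipping %d reads with non-M CIGARs", n_skip))
  data.frame(qname = x$qname[keep],
             chrom = as.character(x$rname)[keep],
             pos = x$pos[keep],
             seq = as.character(x$seq)[keep],
             stringsAsFactors = FALSE)
}

#' Write a reference as FASTA
#' @param reference named character vector or DNAStringSet
#' @param path output path
#' @return `path`, invisibly
#' @export
write_reference_fasta <- function(reference, path) {
  ref <- as_reference(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  invisible(path)
}

#' Read a FASTA reference
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as.character(x)
}

#' Write an annotated variant table as VCF (with a TSV sidecar mirror)
#'
#' Annotations go into INFO keys `GENE`, `EFFECT`, `REGION`, `CLNSIG`,
#' `HGMD_CLASS`, `AF_1000G`, `AF_GNOMAD`, `AF_ESP`, `AF_INTERNAL`,
#' `AF_FG`, `PRED_*`; genotype into the single sample column.
#'
#' @param variants data.frame in the [simulate_variant_table()] layout
#' @param path output VCF path (the sidecar is `<path>.tsv`)
#' @return `path`, invisibly
#' @export
write_variant_vcf <- function(variants, path) {
  info_keys <- c(GENE = "gene", EFFECT = "effect", REGION = "region",
                 CLNSIG = "clinvar_class", HGMD_CLASS = "hgmd_class",
                 AF_1000G = "af_1000g", AF_GNOMAD = "af_gnomad",
                 AF_ESP = "af_esp", AF_INTERNAL = "internal_freq",
                 AF_FG = "fg_freq",
                 PRED_SIFT = "pred_sift", PRED_POLYPHEN2 = "pred_polyphen2",
                 PRED_MUTATIONTASTER = "pred_mutationtaster",
                 PRED_MUTATIONASSESSOR = "pred_mutationassessor",
                 PRED_FATHMM = "pred_fathmm")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
                   names(info_keys), info_keys),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  enc <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "."
    gsub("[;= ]", "_", x)
  }
  info <- do.call(paste, c(lapply(seq_along(info_keys), function(i) {
    sprintf("%s=%s", names(info_keys)[i], enc(variants[[info_keys[i]]]))
  }), sep = ";"))
  gt <- ifelse(variants$genotype == "hom", "1/1", "0/1")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                  variants$chrom, as.integer(variants$pos), variants$id,
                  variants$ref, variants$alt, info, gt)
  writeLines(c(hdr, body), path)
  write.table(variants, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an annotated variant VCF back into the table layout
#'
#' @param path VCF written by [write_variant_vcf()] (or any VCF carrying
#'   the same INFO keys)
#' @return data.frame in the [simulate_variant_table()] layout
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  info1 <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    x[x == "."] <- NA
    x
  }
  num1 <- function(key) suppressWarnings(as.numeric(info1(key)))
  data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             genotype = ifelse(gt[, 1] %in% c("1/1", "1|1"), "hom", "het"),
             gene = info1("GENE"), effect = info1("EFFECT"),
             region = info1("REGION"),
             clinvar_class = gsub("_", " ", info1("CLNSIG")),
             hgmd_class = info1("HGMD_CLASS"),
             af_1000g = num1("AF_1000G"), af_gnomad = num1("AF_GNOMAD"),
             af_esp = num1("AF_ESP"), internal_freq = num1("AF_INTERNAL"),
             fg_freq = num1("AF_FG"),
             pred_sift = info1("PRED_SIFT"),
             pred_polyphen2 = info1("PRED_POLYPHEN2"),
             pred_mutationtaster = info1("PRED_MUTATIONTASTER"),
             pred_mutationassessor = info1("PRED_MUTATIONASSESSOR"),
             pred_fathmm = info1("PRED_FATHMM"),
             stringsAsFactors = FALSE)
}

#' Write a phased haplotype panel as VCF
#'
#' Haplotype pairs (1,2), (3,4), ... become diploid samples with
#' pipe-separated phased genotypes.
#'
#' @param panel a [haplotype_panel()]
#' @param path output VCF path
#' @return `path`, invisibly
#' @export
write_panel_vcf <- function(panel, path) {
  n_hap <- nrow(panel$alleles)
  if (n_hap %% 2L != 0L) stopf("panel must have an even number of haplotypes")
  samples <- sprintf("ind%04d", seq_len(n_hap / 2L))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", panel$region$chrom,
                   panel$region$end),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  a1 <- panel$alleles[seq(1L, n_hap, 2L), , drop = FALSE]
  a2 <- panel$alleles[seq(2L, n_hap, 2L), , drop = FALSE]
  body <- vapply(seq_along(panel$positions), function(s) {
    gts <- paste0(a1[, s], "|", a2[, s])
    paste(c(panel$region$chrom, panel$positions[s],
            sprintf("site%05d", s), "A", "G", ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' @param path VCF with phased GT fields (pipe separator)
#' @return a [haplotype_panel()]
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gt, fixed = TRUE)))
    stopf("panel VCF contains unphased genotypes")
  parts <- strsplit(gt, "|", fixed = TRUE)
  h1 <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  h2 <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  n_sites <- nrow(gt); n_ind <- ncol(gt)
  alleles <- matrix(0L, 2L * n_ind, n_sites)
  alleles[seq(1L, 2L * n_ind, 2L), ] <- t(matrix(h1, n_sites, n_ind))
  alleles[seq(2L, 2L * n_ind, 2L), ] <- t(matrix(h2, n_sites, n_ind))
  labels <- as.vector(rbind(paste0(colnames(gt), "_1"),
                            paste0(colnames(gt), "_2")))
  haplotype_panel(positions = as.integer(fix$POS), alleles = alleles,
                  sample_labels = labels,
                  region = list(chrom = fix$CHROM[1],
                                start = min(as.integer(fix$POS)),
                                end = max(as.integer(fix$POS))))
}

#' Write / read a pileup TSV
#'
#' Mitochondrial pileups serialize as a TSV with columns chrom, pos,
#' endogenous, contaminant, bases.
#'
#' @param pileup data.frame
#' @param path TSV path
#' @return `path` (write) or the data.frame (read)
#' @export
write_pileup_tsv <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character") |>
    (\(d) { for (c in intersect(c("pos", "n_match", "n_mismatch", "site"), names(d)))
              d[[c]] <- as.integer(d[[c]]); d })()
}
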