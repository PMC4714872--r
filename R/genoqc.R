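# Input parsing and genotype-level quality control.
#
# The QC thresholds default to the values used for the resequencing panel:
# minimum mapping quality 30, minimum genotype quality 30, read depth within
# [4, 300].  Calls failing any threshold become missing.

#' Read a phenotype/sample sheet (TSV)
#'
#' @param path TSV with columns sample, species, clade, dennis, ray, group.
#' @return a [phenotype_table()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  phenotype_table(df)
}

#' Read a gapped haplotype alignment (FASTA)
#'
#' Sequences must be equal length over the alphabet A,C,G,T,-,N (case
#' insensitive); haplotype names follow `<sample>_h1` / `<sample>_h2`.
#'
#' @param path FASTA file.
#' @param offset 0-based scaffold coordinate of the first alignment column.
#' @return a [phased_alignment()].
#' @export
read_phased_fasta <- function(path, offset = 0L) {
  dn <- ape::read.FASTA(path)
  lens <- lengths(dn)
  if (length(unique(lens)) != 1)
    stopf("alignment has ragged sequence lengths (%s)",
          paste(range(lens), collapse = "-"))
  ch <- toupper(do.call(rbind, as.character(dn)))
  bad <- setdiff(unique(as.vector(ch)), ALN_LEVELS)
  if (length(bad)) {
    # ambiguity codes and anything non-standard are treated as missing
    ch[ch %in% bad] <- "N"
  }
  rownames(ch) <- names(dn)
  phased_alignment(ch, ids = names(dn),
                   coord = offset + 0:(ncol(ch) - 1L))
}

#' Read diploid genotype calls from a VCF
#'
#' Extracts GT, per-genotype DP and GQ, and the per-site INFO MQ field.
#' Positions are converted to the internal 0-based convention.  Genotypes
#' with half-missing alleles are scored fully missing.
#'
#' @param path VCF 4.2 file.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  pos <- as.integer(fix[, "POS"]) - 1L
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  mq <- as.numeric(vcfR::extract.info(v, element = "MQ"))
  samples <- colnames(gt)
  ns <- length(pos)
  alleles <- lapply(seq_len(ns), function(i) {
    a <- c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1]])
    a[a != "."]
  })
  split_gt <- function(which_allele) {
    idx <- matrix(NA_integer_, nrow = ns, ncol = length(samples))
    parts <- strsplit(as.vector(gt), "[/|]")
    pick <- vapply(parts, function(p) {
      if (length(p) < which_allele) return(NA_character_)
      p[which_allele]
    }, character(1))
    pick[pick == "."] <- NA
    matrix(as.integer(pick), nrow = ns) + 1L
  }
  i1 <- split_gt(1); i2 <- split_gt(2)
  a1 <- matrix(NA_character_, ns, length(samples))
  a2 <- matrix(NA_character_, ns, length(samples))
  for (i in seq_len(ns)) {
    a1[i, ] <- alleles[[i]][i1[i, ]]
    a2[i, ] <- alleles[[i]][i2[i, ]]
  }
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA; a2[half] <- NA
  dp[is.na(dp)] <- 0
  gq[is.na(gq)] <- 0
  genotype_matrix(pos = pos, a1 = a1, a2 = a2, dp = dp, gq = gq, mq = mq,
                  samples = samples)
}

#' Read the analysis input triple
#'
#' Reads genotype calls (VCF), the phased haplotype alignment (FASTA) and
#' the sample sheet (TSV), and checks id consistency: every VCF sample and
#' every haplotype's sample must appear in the sheet.
#'
#' @param vcf_path,fasta_path,sheet_path input files.
#' @param offset 0-based scaffold coordinate of the first alignment column.
#' @return list with `geno`, `alignment`, `pheno`.
#' @export
read_inputs <- function(vcf_path, fasta_path, sheet_path, offset = 0L) {
  pheno <- read_sample_sheet(sheet_path)
  alignment <- read_phased_fasta(fasta_path, offset = offset)
  geno <- read_genotype_vcf(vcf_path)
  bad <- setdiff(geno$samples, pheno$sample)
  if (length(bad)) stopf("VCF sample(s) absent from sample sheet: %s",
                         paste(bad, collapse = ", "))
  bad <- setdiff(unique(hap_samples(alignment$ids)), pheno$sample)
  if (length(bad)) stopf("alignment sample(s) absent from sample sheet: %s",
                         paste(bad, collapse = ", "))
  list(geno = geno, alignment = alignment, pheno = pheno)
}

#' Apply genotype-level quality filters
#'
#' Any call at a site with mapping quality below `min_mq`, or with genotype
#' quality below `min_gq`, or with read depth outside `[min_dp, max_dp]`, is
#' scored missing.  All other calls are unchanged.  A masking report (counts
#' per criterion, with precedence mq > dp_low > dp_high > gq so counts are
#' additive across disjoint criteria) is attached as the `qc_report`
#' attribute.
#'
#' @param geno a [genotype_matrix()].
#' @param min_mq,min_gq,min_dp,max_dp thresholds (defaults 30, 30, 4, 300).
#' @return a new, masked [genotype_matrix()].
#' @export
apply_qc <- function(geno, min_mq = 30, min_gq = 30, min_dp = 4, max_dp = 300) {
  if (min_dp > max_dp) stopf("min_dp must be <= max_dp")
  if (any(c(min_mq, min_gq, min_dp) < 0)) stopf("thresholds must be non-negative")
  present <- !is.na(geno$a1)
  f_mq <- present & (geno$mq < min_mq)          # recycled per column
  f_dp_lo <- present & !f_mq & (geno$dp < min_dp)
  f_dp_hi <- present & !f_mq & !f_dp_lo & (geno$dp > max_dp)
  f_gq <- present & !f_mq & !f_dp_lo & !f_dp_hi & (geno$gq < min_gq)
  mask <- f_mq | f_dp_lo | f_dp_hi | f_gq
  out <- geno
  out$a1[mask] <- NA
  out$a2[mask] <- NA
  attr(out, "qc_report") <- list(
    mq = sum(f_mq), dp_low = sum(f_dp_lo), dp_high = sum(f_dp_hi),
    gq = sum(f_gq), total_masked = sum(mask),
    thresholds = c(min_mq = min_mq, min_gq = min_gq,
                   min_dp = min_dp, max_dp = max_dp))
  out
}

#' Masking report of a QC'd genotype matrix
#'
#' @param geno output of [apply_qc()].
#' @return list of per-criterion masked-call counts.
#' @export
qc_report <- function(geno) {
  rep <- attr(geno, "qc_report")
  if (is.null(rep)) stopf("no QC has been applied to this matrix")
  rep
}

#' Write a masking report as TSV
#'
#' @param geno output of [apply_qc()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(geno, path) {
  rep <- qc_report(geno)
  df <- data.frame(criterion = c("mq", "dp_low", "dp_high", "gq", "total_masked"),
                   masked_calls = c(rep$mq, rep$dp_low, rep$dp_high, rep$gq,
                                    rep$total_masked))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Informative sites of a genotype matrix
#'
#' A site is informative when at least two distinct alleles are observed
#' among non-missing calls and the fraction of samples with a non-missing
#' call is at least `min_call_rate`.
#'
#' @param geno a [genotype_matrix()] (after QC).
#' @param min_call_rate minimum fraction of called samples (default 0.5).
#' @param samples optional sample subset over which to evaluate.
#' @return integer vector of site indices into `geno$pos`.
#' @export
informative_sites <- function(geno, min_call_rate = 0.5, samples = NULL) {
  a1 <- geno$a1; a2 <- geno$a2
  if (!is.null(samples)) {
    bad <- setdiff(samples, geno$samples)
    if (length(bad)) stopf("unknown sample(s): %s", paste(bad, collapse = ", "))
    a1 <- a1[, samples, drop = FALSE]
    a2 <- a2[, samples, drop = FALSE]
  }
  called <- !is.na(a1)
  rate <- rowMeans(called)
  n_allele <- integer(nrow(a1))
  for (b in c("A", "C", "G", "T")) {
    n_allele <- n_allele +
      as.integer(rowSums(a1 == b, na.rm = TRUE) + rowSums(a2 == b, na.rm = TRUE) > 0)
  }
  which(n_allele >= 2 & rate >= min_call_rate)
}
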