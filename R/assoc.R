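# Genotype-by-phenotype association scan.
#
# Per informative site, alleles (two per diploid call) are tabulated by
# binary phenotype and tested with a 1-df Pearson chi-squared statistic
# without continuity correction (the fast case-control allelic contrast).
# Genome-wide control is Bonferroni over the number of sites actually
# tested.

#' Allele-count table for one site
#'
#' Counts alleles (two per non-missing diploid call) split by binary
#' phenotype.  Multi-allelic sites are reduced to their two most frequent
#' alleles (ties broken alphabetically); other alleles and missing calls
#' contribute nothing.
#'
#' @param geno a [genotype_matrix()].
#' @param site site index into `geno$pos`.
#' @param phen named logical vector (TRUE = case); names are sample ids.
#'   Samples with `NA` phenotype are excluded.
#' @return 2x2 integer matrix (rows: case/control; columns: the two alleles),
#'   or `NULL` if fewer than two alleles are observed (monomorphic signal).
#' @export
allele_table <- function(geno, site, phen) {
  phen <- phen[!is.na(phen)]
  use <- intersect(names(phen), geno$samples)
  a <- c(geno$a1[site, use], geno$a2[site, use])
  ph <- rep(phen[use], 2)
  keep <- !is.na(a)
  a <- a[keep]; ph <- ph[keep]
  if (!length(a)) return(NULL)
  tab <- sort(table(a), decreasing = TRUE)
  if (length(tab) < 2) return(NULL)
  top2 <- names(tab)[order(-as.numeric(tab), names(tab))][1:2]
  keep <- a %in% top2
  a <- factor(a[keep], levels = top2)
  ph <- factor(ifelse(ph[keep], "case", "control"), levels = c("case", "control"))
  tb <- table(ph, a)
  matrix(as.integer(tb), 2, 2, dimnames = dimnames(tb))
}

#' 1-df Pearson chi-squared test on a 2x2 table
#'
#' Statistic = sum (O - E)^2 / E without continuity correction; p-value from
#' the upper tail of the 1-df chi-squared distribution.  Degenerate tables
#' (any zero margin) return statistic 0, p = 1.
#'
#' @param tab 2x2 count matrix (or `NULL`, treated as degenerate).
#' @return list with `statistic` and `p`.
#' @export
chi_square_1df <- function(tab) {
  if (is.null(tab)) return(list(statistic = 0, p = 1))
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stopf("need a 2x2 table")
  rm <- rowSums(tab); cm <- colSums(tab); n <- sum(tab)
  if (any(rm == 0) || any(cm == 0)) return(list(statistic = 0, p = 1))
  e <- outer(rm, cm) / n
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_sites number of tests.
#' @return the threshold on the -log10(p) scale: `-log10(alpha / n_sites)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_sites) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (n_sites < 1) stopf("n_sites must be >= 1")
  -log10(alpha / n_sites)
}

#' Per-site association scan
#'
#' Runs the allelic chi-squared contrast at every informative site and flags
#' sites exceeding the Bonferroni threshold computed from the number of
#' sites actually tested.  A genotypic Cochran-Armitage trend variant
#' (scores 0/1/2 copies of the minor allele) is available behind
#' `method = "trend"`; the allelic contrast is the default.
#'
#' @param geno a [genotype_matrix()] (after QC).
#' @param phen named logical phenotype vector (TRUE = case).
#' @param alpha family-wise error rate (default 0.05).
#' @param min_call_rate informative-site call-rate floor.
#' @param method `"allelic"` (default) or `"trend"`.
#' @return an `assoc_track` data.frame (pos, allele counts, statistic, p,
#'   neglog10p, flagged) with attributes `threshold`, `alpha`, `n_tested`.
#' @export
assoc_scan <- function(geno, phen, alpha = 0.05, min_call_rate = 0.5,
                       method = c("allelic", "trend")) {
  method <- match.arg(method)
  phen <- phen[!is.na(phen)]
  use <- intersect(names(phen), geno$samples)
  if (length(unique(phen[use])) < 2)
    stopf("phenotype vector has a single class among genotyped samples")
  if (min(table(phen[use])) < 2)
    stopf("need at least 2 samples per phenotype class")
  sites <- informative_sites(geno, min_call_rate = min_call_rate, samples = use)
  n_t <- length(sites)
  if (n_t == 0) {
    out <- data.frame(pos = integer(), n_case_a = integer(), n_case_b = integer(),
                      n_ctrl_a = integer(), n_ctrl_b = integer(),
                      statistic = numeric(), p = numeric(),
                      neglog10p = numeric(), flagged = logical())
    attr(out, "threshold") <- NA_real_
    attr(out, "alpha") <- alpha
    attr(out, "n_tested") <- 0L
    class(out) <- c("assoc_track", "data.frame")
    return(out)
  }
  res <- matrix(0, nrow = n_t, ncol = 6)
  for (k in seq_len(n_t)) {
    tab <- allele_table(geno, sites[k], phen[use])
    ts <- chi_square_1df(tab)
    if (method == "trend" && !is.null(tab)) {
      ts <- trend_test(geno, sites[k], phen[use], colnames(tab))
    }
    cnt <- if (is.null(tab)) c(0, 0, 0, 0) else as.vector(t(tab))
    res[k, ] <- c(cnt, ts$statistic, ts$p)
  }
  thr <- bonferroni_threshold(alpha, n_t)
  neglog <- -log10(pmax(res[, 6], .Machine$double.xmin))
  out <- data.frame(pos = geno$pos[sites],
                    n_case_a = res[, 1], n_case_b = res[, 2],
                    n_ctrl_a = res[, 3], n_ctrl_b = res[, 4],
                    statistic = res[, 5], p = res[, 6],
                    neglog10p = neglog, flagged = neglog > thr)
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- n_t
  class(out) <- c("assoc_track", "data.frame")
  out
}

# Cochran-Armitage trend test over genotype copy numbers (0/1/2 of allele b).
trend_test <- function(geno, site, phen, alleles) {
  use <- names(phen)
  g <- (geno$a1[site, use] == alleles[2]) + (geno$a2[site, use] == alleles[2])
  keep <- !is.na(g)
  g <- g[keep]; y <- as.numeric(phen[keep])
  n <- length(g)
  if (n < 2 || stats::var(g) == 0 || stats::var(y) == 0)
    return(list(statistic = 0, p = 1))
  r <- stats::cor(g, y)
  stat <- n * r^2
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' @export
print.assoc_track <- function(x, ...) {
  cat(sprintf("assoc_track: %d sites tested, threshold -log10(p) = %.3f, %d flagged\n",
              attr(x, "n_tested"), attr(x, "threshold"), sum(x$flagged)))
  invisible(x)
}

#' Write an association track as TSV (and flagged sites as BED)
#'
#' @param track an `assoc_track`.
#' @param path TSV output path.
#' @param bed_path optional BED (0-based half-open) of flagged sites.
#' @return the TSV path, invisibly.
#' @export
write_assoc_track <- function(track, path, bed_path = NULL) {
  df <- as.data.frame(track)
  df$pos <- df$pos + 1L   # human/VCF coordinates in the TSV
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    flagged <- track$pos[track$flagged]
    if (length(flagged)) {
      bed <- data.frame(chrom = "region1", start = flagged, end = flagged + 1L,
                        name = sprintf("assoc_%d", seq_along(flagged)))
      utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      file.create(bed_path)
    }
  }
  invisible(path)
}
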