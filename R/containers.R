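# Core data containers shared by all analysis stages.
#
# Coordinates are 0-based half-open internally; conversion to 1-based (VCF,
# human reports) or BED (0-based half-open, unchanged) happens at the I/O
# boundary only.

ALN_LEVELS <- c("A", "C", "G", "T", "-", "N")
ALN_GAP <- 5L
ALN_N <- 6L

#' Phased haplotype alignment
#'
#' A gapped multiple alignment of phased haplotypes over a coordinate-anchored
#' region.  Sequences are stored as an integer matrix (rows = haplotypes,
#' columns = alignment columns) with codes 1-4 = A,C,G,T, 5 = gap, 6 = N.
#' Haplotype ids follow the `<sample>_h1` / `<sample>_h2` convention.
#'
#' @param seq integer matrix of base codes, or a character matrix over
#'   `A,C,G,T,-,N` which is converted.
#' @param ids haplotype identifiers (row names).
#' @param coord optional integer vector mapping alignment columns to 0-based
#'   scaffold positions; must be strictly increasing.  Defaults to
#'   `0:(ncol-1)`.
#' @return an object of class `phased_alignment`.
#' @export
phased_alignment <- function(seq, ids = rownames(seq), coord = NULL) {
  if (is.character(seq)) {
    m <- match(toupper(seq), ALN_LEVELS)
    if (anyNA(m)) stopf("alignment contains symbols outside {A,C,G,T,-,N}")
    seq <- matrix(as.integer(m), nrow = nrow(seq))
  }
  if (is.null(ids)) stopf("haplotype ids are required")
  if (length(ids) != nrow(seq)) stopf("ids do not match alignment rows")
  if (is.null(coord)) coord <- 0:(ncol(seq) - 1L)
  if (length(coord) != ncol(seq)) stopf("coordinate map length != alignment width")
  if (any(diff(coord) <= 0)) stopf("coordinate map must be strictly increasing")
  rownames(seq) <- ids
  structure(list(seq = seq, ids = ids, coord = as.integer(coord)),
            class = "phased_alignment")
}

#' @export
print.phased_alignment <- function(x, ...) {
  cat(sprintf("phased_alignment: %d haplotypes x %d columns (span %d-%d)\n",
              nrow(x$seq), ncol(x$seq), x$coord[1], x$coord[length(x$coord)] + 1L))
  invisible(x)
}

# Sample id of each haplotype ("s_h1" -> "s").
hap_samples <- function(ids) sub("_h[12]$", "", ids)

# Column indices of an alignment falling in a 0-based half-open interval
# (or the union of a list of such intervals).
aln_columns <- function(aln, interval = NULL) {
  if (is.null(interval)) return(seq_along(aln$coord))
  if (is.list(interval)) {
    hit <- rep(FALSE, length(aln$coord))
    for (iv in interval) hit <- hit | (aln$coord >= iv[1] & aln$coord < iv[2])
    return(which(hit))
  }
  which(aln$coord >= interval[1] & aln$coord < interval[2])
}

# Character matrix view (for I/O and tests).
aln_chars <- function(aln, rows = NULL) {
  s <- if (is.null(rows)) aln$seq else aln$seq[rows, , drop = FALSE]
  matrix(ALN_LEVELS[s], nrow = nrow(s), dimnames = list(rownames(s), NULL))
}

#' Diploid genotype matrix with per-call quality annotations
#'
#' Per-site diploid calls with read depth (DP), genotype quality (GQ) and a
#' per-site mapping quality (MQ).  Missing calls are `NA` in both allele
#' matrices.
#'
#' @param pos 0-based site positions (strictly increasing).
#' @param a1,a2 character matrices (sites x samples) of allele letters, `NA`
#'   for missing.
#' @param dp,gq numeric matrices (sites x samples).
#' @param mq numeric vector, one mapping quality per site.
#' @param samples sample identifiers (column names).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(pos, a1, a2, dp, gq, mq, samples = colnames(a1)) {
  pos <- as.integer(pos)
  if (any(diff(pos) <= 0)) stopf("site positions must be strictly increasing")
  dims <- dim(a1)
  for (m in list(a2, dp, gq)) {
    if (!identical(dim(m), dims)) stopf("genotype matrices must share dimensions")
  }
  if (length(mq) != nrow(a1)) stopf("mq must have one value per site")
  if (length(pos) != nrow(a1)) stopf("pos must have one value per site")
  if (is.null(samples)) stopf("sample ids are required")
  if (any(dp < 0, na.rm = TRUE)) stopf("DP must be non-negative")
  # a call is two observed alleles or fully missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stopf("half-missing genotype calls are not allowed")
  colnames(a1) <- colnames(a2) <- colnames(dp) <- colnames(gq) <- samples
  structure(list(pos = pos, a1 = a1, a2 = a2, dp = dp, gq = gq, mq = mq,
                 samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("genotype_matrix: %d sites x %d samples (%.1f%% missing calls)\n",
              length(x$pos), length(x$samples), 100 * miss))
  rep <- attr(x, "qc_report")
  if (!is.null(rep)) {
    cat("  QC masking:", paste(names(rep), unlist(rep), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

n_sites <- function(geno) length(geno$pos)

# Controlled vocabulary for analysis groups in the sample sheet.
GROUP_LEVELS <- c("outgroup", "silvaniform", "dennis_ray", "dennis_only",
                  "ray_only", "postman")

#' Validate a phenotype/sample table
#'
#' The sample sheet carries one row per individual: `sample`, `species`,
#' `clade`, the binary module phenotypes `dennis` and `ray`
#' (`present`/`absent`/`unknown`) and an analysis `group` drawn from a
#' controlled vocabulary (outgroup, silvaniform, dennis_ray, dennis_only,
#' ray_only, postman).
#'
#' @param df a data.frame with the columns above.
#' @return the validated data.frame, classed `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("sample", "species", "clade", "dennis", "ray", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stopf("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  for (ph in c("dennis", "ray")) {
    badp <- setdiff(unique(df[[ph]]), c("present", "absent", "unknown"))
    if (length(badp)) stopf("invalid %s phenotype value(s): %s", ph, paste(badp, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Binary phenotype vector for one module
#'
#' @param pheno a `phenotype_table`.
#' @param module `"dennis"` or `"ray"`.
#' @param samples optional subset/order of samples.
#' @return named logical vector (`TRUE` = present, `NA` = unknown).
#' @export
phenotype_vector <- function(pheno, module = c("dennis", "ray"), samples = NULL) {
  module <- match.arg(module)
  v <- pheno[[module]]
  out <- ifelse(v == "present", TRUE, ifelse(v == "absent", FALSE, NA))
  names(out) <- pheno$sample
  if (!is.null(samples)) {
    missing <- setdiff(samples, pheno$sample)
    if (length(missing)) stopf("samples absent from sheet: %s", paste(missing, collapse = ", "))
    out <- out[samples]
  }
  out
}

#' Module interval
#'
#' A half-open genomic interval delineating an associated region, with its
#' supporting evidence.
#'
#' @param start,end 0-based half-open bounds.
#' @param count supporting fixed-site count.
#' @param evidence free-text provenance for each boundary.
#' @return an object of class `module_interval`.
#' @export
module_interval <- function(start, end, count = NA_integer_, evidence = list()) {
  if (start >= end) stopf("module interval requires start < end")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 count = count, evidence = evidence),
            class = "module_interval")
}

#' @export
print.module_interval <- function(x, ...) {
  hv <- interval0_to_human(c(x$start, x$end))
  cat(sprintf("module_interval: [%s, %s) (1-based %s-%s), %s fixed sites\n",
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(hv[1], big.mark = ","), format(hv[2], big.mark = ","),
              x$count))
  if (length(x$evidence)) {
    for (nm in names(x$evidence)) cat("  ", nm, ": ", x$evidence[[nm]], "\n", sep = "")
  }
  invisible(x)
}
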