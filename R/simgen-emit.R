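# Diploid genotype emission with a coverage/quality model, and file writers.

#' Emit diploid genotype calls from a simulated alignment
#'
#' Haplotypes are paired `<sample>_h1` + `<sample>_h2` into diploids.  Every
#' alignment column segregating for at least two bases becomes a VCF-style
#' site; per-genotype read depth is Poisson, genotype quality and per-site
#' mapping quality are Gaussian (clamped), and configured fractions of calls
#' and sites are forced below the QC thresholds (DP < 4, DP > 300, GQ < 30,
#' MQ < 30) to exercise the masking stage.  Alleles falling in gap runs
#' become missing calls.
#'
#' @param alignment a [phased_alignment()] from [mutate_and_emit()].
#' @param cfg the `sim_config`.
#' @param truth the matching `sim_truth` (supplies the phenotype table).
#' @return list with `geno` (a [genotype_matrix()]) and `pheno`
#'   (a [phenotype_table()]).
#' @export
emit_genotypes <- function(alignment, cfg, truth) {
  ids <- alignment$ids
  samples <- unique(hap_samples(ids))
  h1 <- paste0(samples, "_h1")
  h2 <- paste0(samples, "_h2")
  missing <- setdiff(c(h1, h2), ids)
  if (length(missing))
    stopf("diploid pairing error: unpaired haplotype(s) %s",
          paste(missing, collapse = ", "))

  S <- alignment$seq
  base_count <- lapply(1:4, function(b) colSums(S == b) > 0)
  n_alleles <- Reduce(`+`, base_count)
  sites <- which(n_alleles >= 2)
  pos <- alignment$coord[sites]

  chr1 <- aln_chars(alignment, h1)[, sites, drop = FALSE]
  chr2 <- aln_chars(alignment, h2)[, sites, drop = FALSE]
  chr1[!(chr1 %in% c("A", "C", "G", "T"))] <- NA
  chr2[!(chr2 %in% c("A", "C", "G", "T"))] <- NA
  # a call is two observed alleles or missing: half-calls are dropped
  half <- xor(is.na(chr1), is.na(chr2))
  chr1[half] <- NA
  chr2[half] <- NA
  a1 <- t(chr1); a2 <- t(chr2)   # sites x samples
  colnames(a1) <- colnames(a2) <- samples

  cm <- cfg$coverage_model
  ns <- length(sites); nsam <- length(samples)
  with_seed(substream_seed(cfg$seed, "emit"), {
    dp <- matrix(stats::rpois(ns * nsam, cm$mean_dp), nrow = ns)
    gq <- matrix(pmin(99, pmax(0, round(stats::rnorm(ns * nsam, cm$gq_mean, cm$gq_sd)))),
                 nrow = ns)
    mq <- pmin(60, pmax(0, round(stats::rnorm(ns, cm$mq_mean, cm$mq_sd), 2)))
    if (cm$low_call_frac > 0) {
      k <- round(cm$low_call_frac * ns * nsam)
      if (k > 0) {
        idx <- sample.int(ns * nsam, k)
        mode <- sample(3L, k, replace = TRUE)
        dp[idx[mode == 1]] <- sample(0:3, sum(mode == 1), replace = TRUE)
        dp[idx[mode == 2]] <- sample(301:400, sum(mode == 2), replace = TRUE)
        gq[idx[mode == 3]] <- sample(0:29, sum(mode == 3), replace = TRUE)
      }
    }
    if (cm$low_site_frac > 0) {
      ks <- round(cm$low_site_frac * ns)
      if (ks > 0) mq[sample.int(ns, ks)] <- round(stats::runif(ks, 10, 29.9), 2)
    }
    if (cfg$phase_scramble) {
      pheno_tab <- truth_phenotypes(truth)
      hom <- pheno_tab$sample[
        apply(truth$classes[paste0(pheno_tab$sample, "_h1"), , drop = FALSE] ==
                truth$classes[paste0(pheno_tab$sample, "_h2"), , drop = FALSE],
              1, all)]
      for (s in intersect(hom, samples)) {
        flip <- stats::runif(ns) < 0.5
        tmp <- a1[flip, s]
        a1[flip, s] <- a2[flip, s]
        a2[flip, s] <- tmp
      }
    }
  })

  geno <- genotype_matrix(pos = pos, a1 = a1, a2 = a2, dp = dp, gq = gq,
                          mq = mq, samples = samples)
  list(geno = geno, pheno = truth_phenotypes(truth))
}

#' Run the full generator
#'
#' Convenience wrapper: genealogies, mutation/indel placement, genotype
#' emission.  Deterministic given `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @return list with `config`, `genealogies`, `alignment`, `truth`, `geno`,
#'   `pheno`.
#' @export
simulate_dataset <- function(cfg) {
  gen <- simulate_genealogies(cfg)
  me <- mutate_and_emit(gen, cfg)
  eg <- emit_genotypes(me$alignment, cfg, me$truth)
  list(config = cfg, genealogies = gen, alignment = me$alignment,
       truth = me$truth, geno = eg$geno, pheno = eg$pheno)
}

# ---- writers --------------------------------------------------------------

#' Write a gapped haplotype alignment as FASTA
#'
#' @param alignment a [phased_alignment()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_phased_fasta <- function(alignment, path) {
  ch <- aln_chars(alignment)
  lines <- character(2L * nrow(ch))
  lines[c(TRUE, FALSE)] <- paste0(">", alignment$ids)
  lines[c(FALSE, TRUE)] <- apply(ch, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits `GT:DP:GQ` per genotype and a per-site `MQ` INFO field.  Positions
#' are converted from the internal 0-based convention to 1-based VCF
#' coordinates.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file.
#' @param chrom contig name.
#' @param contig_length contig length for the header (default: past-the-end
#'   of the last site).
#' @return the path, invisibly.
#' @export
write_vcf <- function(geno, path, chrom = "region1", contig_length = NULL) {
  ns <- length(geno$pos)
  contig_length <- contig_length %||% (max(geno$pos) + 1L)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=redmodules",
    sprintf("##contig=<ID=%s,length=%d>", chrom, contig_length),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t"))
  body <- character(ns)
  for (i in seq_len(ns)) {
    obs <- c(geno$a1[i, ], geno$a2[i, ])
    tab <- sort(table(obs[!is.na(obs)]), decreasing = TRUE)
    alleles <- names(tab)
    ref <- alleles[1]
    alt <- if (length(alleles) > 1) paste(alleles[-1], collapse = ",") else "."
    i1 <- match(geno$a1[i, ], alleles) - 1L
    i2 <- match(geno$a2[i, ], alleles) - 1L
    gt <- ifelse(is.na(i1), "./.", paste0(i1, "|", i2))
    cells <- paste0(gt, ":", geno$dp[i, ], ":", geno$gq[i, ])
    body[i] <- paste(c(chrom, geno$pos[i] + 1L, ".", ref, alt, ".", "PASS",
                       sprintf("MQ=%.2f", geno$mq[i]), "GT:DP:GQ", cells),
                     collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a phenotype/sample sheet as TSV
#'
#' @param pheno a [phenotype_table()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sample_sheet <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Module intervals, per-haplotype allele classes, event times, recombinant
#' breakpoints, block boundaries and block genealogies (as Newick strings
#' with branch lengths in Ma).
#'
#' @param truth a `sim_truth`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  gen <- truth$genealogies
  out <- list(
    modules = lapply(truth$modules, function(iv) list(start = iv[1], end = iv[2])),
    classes = cbind(data.frame(hap = rownames(truth$classes),
                               stringsAsFactors = FALSE),
                    as.data.frame(truth$classes)),
    events = truth$events,
    recombinants = truth$recombinants,
    blocks = gen$blocks,
    block_trees = vapply(gen$trees, ape::write.tree, character(1)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a simulation configuration as YAML
#'
#' @param cfg a `sim_config`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits the gapped haplotype FASTA, the VCF, the sample sheet TSV, the truth
#' JSON and the configuration YAML.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "haplotypes.fasta"),
    vcf = file.path(dir, "genotypes.vcf"),
    sheet = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml"))
  write_phased_fasta(sim$alignment, paths["fasta"])
  write_vcf(sim$geno, paths["vcf"], contig_length = sim$config$region_length)
  write_sample_sheet(sim$pheno, paths["sheet"])
  write_truth_json(sim$truth, paths["truth"])
  write_config_yaml(sim$config, paths["config"])
  invisible(paths)
}
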