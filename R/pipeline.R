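# End-to-end orchestration: simulate (or read) -> QC -> association ->
# fixed-difference scan -> haplotype painting/breakpoints -> trees,
# divergence tables and dated events -> report.

#' Build a pipeline run configuration
#'
#' All stage parameters default to the values of the published analysis
#' where one exists (QC thresholds 30/30/4/300; 5 kb windows at 1 kb steps;
#' alpha 0.05; calibration node age 3.96 Ma).  Unknown keys raise an error
#' naming the key.
#'
#' @param ... overrides for: `sim` (a [sim_config()]; default
#'   [default_sim_config()] with `seed`), `inputs` (optional list with
#'   `vcf`, `fasta`, `sheet` paths; replaces simulation), `recipient_clade`,
#'   `min_mq`, `min_gq`, `min_dp`, `max_dp`, `alpha`, `min_call_rate`,
#'   `window`, `step`, `min_calls`, `min_run`, `min_indel_len`,
#'   `bootstrap_B`, `t_cal`, `seed`, `log_level`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    sim = NULL, inputs = NULL, recipient_clade = "melpomene",
    min_mq = 30, min_gq = 30, min_dp = 4, max_dp = 300,
    alpha = 0.05, min_call_rate = 0.5,
    window = 5000, step = 1000, min_calls = 2,
    min_run = 3, min_indel_len = 30,
    bootstrap_B = 100, t_cal = 3.96,
    seed = 1L, log_level = "info")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) stopf("unknown configuration key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, ov)
  if (is.null(cfg$sim) && is.null(cfg$inputs))
    cfg$sim <- default_sim_config(seed = cfg$seed)
  structure(cfg, class = "run_config")
}

# Haplotype ids of a set of samples.
haps_of <- function(samples) as.vector(t(outer(samples, c("_h1", "_h2"), paste0)))

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing every output file plus a
#' JSON and a human-readable summary report into `out_dir`.  Reports carry a
#' provenance header (package version, seed, configuration hash) and are
#' byte-identical across reruns with the same configuration.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of in-memory stage results (`dataset`, `qc`,
#'   `assoc`, `fixscan`, `breakpoints`, `phylo`, `report`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_lines <- character()
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    if (identical(config$log_level, "info")) message(line)
  }
  stage <- "input"
  result <- tryCatch({
    # ---- input ----
    if (!is.null(config$inputs)) {
      note(stage, "reading genotype/alignment/sheet inputs")
      dat <- read_inputs(config$inputs$vcf, config$inputs$fasta,
                         config$inputs$sheet)
      dat$truth <- NULL
      region <- c(min(dat$alignment$coord),
                  max(dat$alignment$coord) + 1L)
      modules_truth <- NULL
    } else {
      note(stage, sprintf("simulating dataset (seed %d)", config$sim$seed))
      sim <- simulate_dataset(config$sim)
      write_sim_dataset(sim, file.path(out_dir, "data"))
      dat <- list(geno = sim$geno, alignment = sim$alignment,
                  pheno = sim$pheno, truth = sim$truth)
      region <- c(0L, config$sim$region_length)
      modules_truth <- config$sim$modules
    }
    pheno <- dat$pheno

    # ---- qc ----
    stage <- "qc"
    geno <- apply_qc(dat$geno, min_mq = config$min_mq, min_gq = config$min_gq,
                     min_dp = config$min_dp, max_dp = config$max_dp)
    write_qc_report(geno, file.path(out_dir, "qc_masking.tsv"))
    note(stage, sprintf("masked %d calls", qc_report(geno)$total_masked))

    # ---- association ----
    stage <- "assoc"
    rc <- pheno$sample[pheno$clade == config$recipient_clade]
    tracks <- list()
    for (m in c("dennis", "ray")) {
      phv <- phenotype_vector(pheno, m, samples = rc)
      tracks[[m]] <- assoc_scan(geno, phv, alpha = config$alpha,
                                min_call_rate = config$min_call_rate)
      write_assoc_track(tracks[[m]],
                        file.path(out_dir, sprintf("assoc_%s.tsv", m)),
                        file.path(out_dir, sprintf("assoc_%s_significant.bed", m)))
      note(stage, sprintf("%s: %d sites tested, %d flagged (threshold %.2f)",
                          m, attr(tracks[[m]], "n_tested"),
                          sum(tracks[[m]]$flagged), attr(tracks[[m]], "threshold")))
    }

    # ---- fixed differences ----
    stage <- "fixscan"
    in_rc <- pheno$clade == config$recipient_clade
    contrast_groups <- list(
      dennis = list(a = pheno$sample[in_rc & pheno$group %in% c("dennis_ray", "dennis_only")],
                    b = pheno$sample[in_rc & pheno$group %in% c("postman", "ray_only")]),
      ray = list(a = pheno$sample[in_rc & pheno$group %in% c("dennis_ray", "ray_only")],
                 b = pheno$sample[in_rc & pheno$group %in% c("postman", "dennis_only")]))
    fixed <- list(); fixtracks <- list(); minimal <- list()
    for (m in names(contrast_groups)) {
      cg <- contrast_groups[[m]]
      fixed[[m]] <- fixed_differences(dat$alignment, haps_of(cg$a),
                                      haps_of(cg$b), min_calls = config$min_calls)
      fixtracks[[m]] <- window_counts(fixed[[m]], region,
                                      window = config$window, step = config$step)
      minimal[[m]] <- minimal_region(fixed[[m]])
      write_fixscan(fixtracks[[m]],
                    sites_bed = file.path(out_dir, sprintf("fixed_%s.bed", m)),
                    track_tsv = file.path(out_dir, sprintf("fixed_%s_windows.tsv", m)),
                    region_bed = file.path(out_dir, sprintf("minimal_%s.bed", m)))
      note(stage, sprintf("%s: %d fixed differences", m, length(fixed[[m]])))
    }
    disjoint <- nonoverlap_check(fixtracks$dennis, fixtracks$ray)

    # ---- haplotype painting & breakpoints ----
    stage <- "haploclass"
    exemplars <- list(
      dennis_ray = haps_of(pheno$sample[in_rc & pheno$group == "dennis_ray"]),
      postman = haps_of(pheno$sample[in_rc & pheno$group == "postman"]),
      outgroup = haps_of(pheno$sample[pheno$group == "outgroup"]))
    diag <- learn_diagnostics(dat$alignment, exemplars,
                              min_indel_len = config$min_indel_len)
    classifications <- classify_haplotypes(dat$alignment, diag,
                                           min_run = config$min_run)
    write_paintings_bed(classifications, file.path(out_dir, "paintings.bed"))
    calls <- call_breakpoints(classifications, pheno, fixed,
                              present_class = list(dennis = "dennis_ray",
                                                   ray = "dennis_ray"),
                              region = region,
                              samples = pheno$sample[in_rc])
    refined <- lapply(calls, function(x) x$interval)
    for (m in names(calls)) {
      if (length(calls[[m]]$conflicts))
        stopf("contradictory recombinants for module %s:\n%s", m,
              paste(calls[[m]]$conflicts, collapse = "\n"))
      if (!is.null(refined[[m]]))
        note(stage, sprintf("%s refined to [%d, %d)", m,
                            refined[[m]]$start, refined[[m]]$end))
    }
    bp_rows <- do.call(rbind, lapply(names(classifications), function(h) {
      bp <- classifications[[h]]$breakpoints
      if (!nrow(bp)) return(NULL)
      cbind(data.frame(hap = h), bp)
    }))
    if (!is.null(bp_rows))
      utils::write.table(bp_rows, file.path(out_dir, "breakpoints.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    # ---- phylogenetics & dating ----
    stage <- "phylo"
    reg_or_min <- function(m) {
      if (!is.null(refined[[m]])) c(refined[[m]]$start, refined[[m]]$end)
      else if (!is.null(minimal[[m]])) c(minimal[[m]]$start, minimal[[m]]$end)
      else NULL
    }
    dennis_iv <- reg_or_min("dennis"); ray_iv <- reg_or_min("ray")
    flank_iv <- c(region[1], if (!is.null(dennis_iv)) dennis_iv[1] else region[2])
    donor_haps <- haps_of(pheno$sample[pheno$clade != config$recipient_clade &
                                         pheno$group != "outgroup"])
    recip_haps <- haps_of(pheno$sample[in_rc])
    outgroup_haps <- exemplars$outgroup
    silv_haps <- haps_of(pheno$sample[pheno$group == "silvaniform"])
    dennis_car_rc <- haps_of(pheno$sample[in_rc & pheno$dennis == "present"])
    ray_car_rc <- haps_of(pheno$sample[in_rc & pheno$ray == "present"])
    donor_dennis <- haps_of(pheno$sample[!in_rc & pheno$dennis == "present"])
    donor_ray <- haps_of(pheno$sample[!in_rc & pheno$ray == "present"])
    postman_haps <- haps_of(pheno$sample[pheno$group == "postman"])

    div_groups <- function(m) {
      car <- if (m == "dennis") c("dennis_ray", "dennis_only") else
        c("dennis_ray", "ray_only")
      list(outgroup = outgroup_haps,
           silvaniform = silv_haps,
           carrier = haps_of(pheno$sample[pheno$group %in% car]),
           postman = postman_haps)
    }
    div_tables <- list()
    trees <- list()
    assign_res <- list()
    for (m in c("dennis", "ray")) {
      iv <- if (m == "dennis") dennis_iv else ray_iv
      if (is.null(iv)) next
      div_tables[[m]] <- group_divergence(dat$alignment, div_groups(m),
                                          region = iv, region_label = m)
      pd <- p_distance_matrix(dat$alignment, region = iv)
      trees[[m]] <- nj_tree(pd)
      ape::write.tree(trees[[m]], file.path(out_dir, sprintf("tree_%s.nwk", m)))
      focal <- if (m == "dennis") dennis_car_rc else
        unique(c(ray_car_rc, donor_ray))
      # for the module whose functional allele is native to the donor
      # species, that species' alleles anchor the donor reference; for the
      # recipient-origin module they are introgressed copies and are focal
      refs_donor <- if (m == "dennis") donor_haps else silv_haps
      assign_res[[m]] <- clade_assignment(
        trees[[m]], setdiff(focal, refs_donor),
        refs = list(donor = refs_donor, recipient = postman_haps),
        outgroup = outgroup_haps[1])
    }
    div_tables$flank <- group_divergence(dat$alignment, div_groups("dennis"),
                                         region = flank_iv,
                                         region_label = "flank")
    for (m in names(div_tables)) {
      utils::write.table(round(unclass(div_tables[[m]]), 1),
                         file.path(out_dir, sprintf("divergence_%s.tsv", m)),
                         sep = "\t", quote = FALSE, col.names = NA)
    }

    clock <- calibrate_clock(dat$alignment,
                             clade_a = donor_haps, clade_b = recip_haps,
                             t_cal = config$t_cal, region = flank_iv,
                             B = config$bootstrap_B,
                             seed = substream_seed(config$seed, "clock"))
    dated <- list()
    date_ev <- function(a, b, iv, tag) {
      if (is.null(iv) || !length(a) || !length(b)) return(NULL)
      date_divergence(dat$alignment, a, b, clock, region = iv,
                      seed = substream_seed(config$seed, paste0("date:", tag)))
    }
    # Event vocabulary: A = module-1 introgression donor -> recipient,
    # B = module-2 allele origin within the recipient,
    # D = module-2 introgression back into the donor species.
    dated$A_dennis_donor_to_recipient <-
      date_ev(donor_dennis, dennis_car_rc, dennis_iv, "A")
    dated$B_ray_origin_within_recipient <-
      date_ev(ray_car_rc, postman_haps, ray_iv, "B")
    dated$D_ray_into_donor_species <-
      date_ev(donor_ray, ray_car_rc, ray_iv, "D")
    dating_json <- lapply(Filter(Negate(is.null), dated), function(d)
      list(age_ma = d$age, interval_ma = d$interval, divergence = d$divergence))
    jsonlite::write_json(
      c(list(calibration = list(t_cal_ma = clock$t_cal, rate_per_ma = clock$rate,
                                rate_interval = clock$interval)),
        dating_json),
      file.path(out_dir, "dating.json"), auto_unbox = TRUE, digits = NA)

    # ---- report ----
    stage <- "report"
    report <- list(
      provenance = list(
        package = "redmodules",
        version = as.character(utils::packageVersion("redmodules")),
        seed = config$seed,
        config_hash = content_hash(unclass(config))),
      qc = qc_report(geno)[c("mq", "dp_low", "dp_high", "gq", "total_masked")],
      association = lapply(tracks, function(tr) list(
        n_tested = attr(tr, "n_tested"),
        threshold_neglog10p = attr(tr, "threshold"),
        n_flagged = sum(tr$flagged))),
      fixed_differences = lapply(fixed, length),
      minimal_regions = lapply(minimal, function(mr) if (is.null(mr)) NULL else
        list(start_1based = mr$start + 1, end_1based = mr$end,
             n_fixed = mr$count)),
      refined_modules = lapply(calls, function(x) if (is.null(x$interval)) NULL else
        list(start_1based = x$interval$start + 1, end_1based = x$interval$end,
             length_bp = x$interval$end - x$interval$start,
             evidence = x$interval$evidence)),
      modules_disjoint = list(sites = disjoint$sites_disjoint,
                              regions = disjoint$regions_disjoint),
      clade_assignment = lapply(assign_res, function(a) as.list(table(a))),
      divergence_percent = lapply(div_tables, function(t) {
        y <- unclass(t); attributes(y)[c("region_label", "deletion")] <- NULL
        as.data.frame(round(y, 2))
      }),
      dated_events_ma = dating_json,
      truth = if (!is.null(dat$truth)) list(
        modules = lapply(modules_truth, function(iv)
          list(start_1based = iv[1] + 1, end_1based = iv[2])),
        events = dat$truth$events) else NULL)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(format_report_txt(report), file.path(out_dir, "report.txt"))
    writeLines(log_lines, logf)
    list(dataset = dat, qc = geno, assoc = tracks,
         fixscan = list(fixed = fixed, tracks = fixtracks, minimal = minimal,
                        disjoint = disjoint),
         breakpoints = calls, classifications = classifications,
         phylo = list(trees = trees, divergence = div_tables, clock = clock,
                      dated = dated, assignment = assign_res),
         report = report, out_dir = out_dir)
  }, error = function(e) {
    writeLines(c(log_lines, sprintf("[%s] FAILED: %s", stage, conditionMessage(e))),
               logf)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(result)
}

# Human-readable summary.
format_report_txt <- function(r) {
  out <- c(
    sprintf("redmodules %s run (seed %s, config %s)", r$provenance$version,
            r$provenance$seed, r$provenance$config_hash),
    "",
    sprintf("QC: %d calls masked (mq %d, dp_low %d, dp_high %d, gq %d)",
            r$qc$total_masked, r$qc$mq, r$qc$dp_low, r$qc$dp_high, r$qc$gq),
    "")
  for (m in names(r$association)) {
    a <- r$association[[m]]
    out <- c(out, sprintf(
      "association %-6s: %d sites tested, threshold -log10 p = %.2f, %d flagged",
      m, a$n_tested, a$threshold_neglog10p, a$n_flagged))
  }
  out <- c(out, "")
  for (m in names(r$refined_modules)) {
    rm_ <- r$refined_modules[[m]]
    if (is.null(rm_)) next
    out <- c(out, sprintf("module %-6s: %s-%s (1-based, %.1f kb)", m,
                          format(rm_$start_1based, big.mark = ","),
                          format(rm_$end_1based, big.mark = ","),
                          rm_$length_bp / 1000),
             sprintf("  start: %s", rm_$evidence$start),
             sprintf("  end:   %s", rm_$evidence$end))
  }
  out <- c(out, sprintf("fixed-site sets disjoint: %s; minimal regions disjoint: %s",
                        r$modules_disjoint$sites, r$modules_disjoint$regions), "")
  for (m in names(r$clade_assignment)) {
    tabs <- unlist(r$clade_assignment[[m]])
    out <- c(out, sprintf("clade assignment (%s alleles): %s", m,
                          paste(names(tabs), tabs, sep = "=", collapse = ", ")))
  }
  out <- c(out, "")
  for (ev in names(r$dated_events_ma)) {
    d <- r$dated_events_ma[[ev]]
    out <- c(out, sprintf("event %s: %.2f Ma (bootstrap %.2f-%.2f)",
                          ev, d$age_ma, d$interval_ma[1], d$interval_ma[2]))
  }
  out
}

#' Generate miniature committed-size fixtures
#'
#' Writes the deterministic tiny dataset (20 haplotypes over 10 kb,
#' including a recombinant race) used by unit tests: FASTA, VCF, sample
#' sheet, truth JSON and config YAML.
#'
#' @param seed master seed.
#' @param dir output directory.
#' @return named vector of file paths, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir) {
  sim <- simulate_dataset(tiny_sim_config(seed))
  write_sim_dataset(sim, dir)
}
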