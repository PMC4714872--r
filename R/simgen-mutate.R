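# Sequence evolution on block genealogies and ground-truth bookkeeping.

#' Drop mutations on block genealogies and emit the haplotype alignment
#'
#' Substitutions are Poisson on each branch (rate = mutation_rate x branch
#' length in Ma x block length) under Jukes-Cantor from a random ancestral
#' sequence per block.  Class-diagnostic indels are then applied as fixed gap
#' runs so each allele class carries its configured indel architecture.
#'
#' @param gen a `block_genealogies` from [simulate_genealogies()].
#' @param cfg the `sim_config` used to generate `gen`.
#' @return a list with `alignment` (a [phased_alignment()]) and `truth`
#'   (a `sim_truth`: per-haplotype allele class per module, true module
#'   intervals, event times, recombinant breakpoints and the genealogies).
#' @export
mutate_and_emit <- function(gen, cfg) {
  hap_tab <- gen$hap_table
  n <- nrow(hap_tab)
  L <- cfg$region_length
  aln <- matrix(0L, nrow = n, ncol = L)
  mu <- cfg$mutation_rate

  for (b in seq_len(nrow(gen$blocks))) {
    blk <- gen$blocks[b, ]
    Lb <- blk$end - blk$start
    cols <- (blk$start + 1L):blk$end
    tr <- gen$trees[[b]]
    with_seed(substream_seed(cfg$seed, sprintf("mutate:%d", b)), {
      anc <- sample.int(4L, Lb, replace = TRUE)
      edge <- tr$edge
      elen <- tr$edge.length
      kids <- split(seq_len(nrow(edge)), edge[, 1])
      root <- n + 1L
      seqs <- vector("list", 2L * n - 1L)
      seqs[[root]] <- anc
      stack <- root
      while (length(stack)) {
        nd <- stack[length(stack)]
        stack <- stack[-length(stack)]
        s0 <- seqs[[nd]]
        for (r in kids[[as.character(nd)]]) {
          ch <- edge[r, 2]
          s <- s0
          nm <- stats::rpois(1, mu * elen[r] * Lb)
          if (nm > 0) {
            pos <- sample.int(Lb, nm, replace = TRUE)
            shift <- sample.int(3L, nm, replace = TRUE)
            for (i in seq_len(nm)) {
              s[pos[i]] <- ((s[pos[i]] - 1L + shift[i]) %% 4L) + 1L
            }
          }
          if (ch <= n) {
            aln[ch, cols] <- s
          } else {
            seqs[[ch]] <- s
            stack <- c(stack, ch)
          }
        }
        seqs[nd] <- list(NULL)
      }
    })
  }

  classes <- hap_module_classes(cfg, hap_tab)
  for (isp in cfg$indel_specs) {
    cls <- classes[, isp$module]
    rows <- which(cls %in% isp$gap_in)
    if (length(rows)) aln[rows, (isp$start + 1L):isp$end] <- ALN_GAP
  }

  alignment <- phased_alignment(aln, ids = hap_tab$hap)
  recs <- if (length(cfg$recombinant_specs)) {
    do.call(rbind, lapply(cfg$recombinant_specs, function(r)
      data.frame(hap = r$hap, breakpoint = r$breakpoint,
                 left_like = r$left_like, right_like = r$right_like,
                 stringsAsFactors = FALSE)))
  } else data.frame(hap = character(), breakpoint = integer(),
                    left_like = character(), right_like = character())
  events <- if (length(cfg$introgression_events)) {
    do.call(rbind, lapply(cfg$introgression_events, function(ev) {
      mod <- names(cfg$modules)[vapply(cfg$modules, function(iv)
        all(iv == ev$interval), logical(1))]
      data.frame(name = ev$name, time = ev$time, donor = ev$donor,
                 recipient = ev$recipient, module = mod,
                 fraction = ev$fraction, stringsAsFactors = FALSE)
    }))
  } else data.frame()
  truth <- structure(list(classes = classes, modules = cfg$modules,
                          events = events, recombinants = recs,
                          hap_table = hap_tab, genealogies = gen,
                          config = cfg),
                     class = "sim_truth")
  list(alignment = alignment, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d haplotypes, modules: %s\n", nrow(x$classes),
              paste(sprintf("%s [%d,%d)", names(x$modules),
                            vapply(x$modules, `[`, numeric(1), 1),
                            vapply(x$modules, `[`, numeric(1), 2)),
                    collapse = ", ")))
  if (nrow(x$events)) {
    cat("events:\n"); print(x$events)
  }
  invisible(x)
}

#' Phenotypes implied by simulated allele classes
#'
#' Applies the single-locus dominance rule: a module phenotype is present iff
#' at least one of the individual's two haplotypes carries that module's
#' functional allele class.  Analysis groups follow the controlled
#' vocabulary: `outgroup`, `silvaniform` (donor clade, no module),
#' `dennis_ray`, `dennis_only`, `ray_only`, `postman`.
#'
#' @param truth a `sim_truth` (modules must be named `dennis` and `ray`).
#' @return a [phenotype_table()].
#' @export
truth_phenotypes <- function(truth) {
  if (!all(c("dennis", "ray") %in% names(truth$modules)))
    stopf("phenotype table requires modules named dennis and ray")
  cfg <- truth$config
  clade_of <- stats::setNames(cfg$populations$clade, cfg$populations$name)
  species_of <- stats::setNames(cfg$populations$species, cfg$populations$name)
  ht <- truth$hap_table
  samples <- unique(ht$sample)
  rows <- lapply(samples, function(s) {
    haps <- ht$hap[ht$sample == s]
    pop <- ht$pop[ht$sample == s][1]
    d <- any(truth$classes[haps, "dennis"] == "dennis")
    r <- any(truth$classes[haps, "ray"] == "ray")
    clade <- clade_of[[pop]]
    group <- if (clade == "outgroup") "outgroup"
      else if (d && r) "dennis_ray"
      else if (d) "dennis_only"
      else if (r) "ray_only"
      else if (clade == cfg$recipient_clade) "postman"
      else "silvaniform"
    data.frame(sample = s, species = species_of[[pop]], clade = clade,
               dennis = if (d) "present" else "absent",
               ray = if (r) "present" else "absent",
               group = group, stringsAsFactors = FALSE)
  })
  phenotype_table(do.call(rbind, rows))
}
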