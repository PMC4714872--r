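# Simulation scenario configuration.
#
# The generator produces phased haplotypes over a region containing two
# adjacent cis-regulatory modules, under a structured coalescent with a deep
# donor/recipient species split, interval-restricted introgression of each
# module at its own time, and declared within-species recombinant haplotypes
# carrying only one module.
#
# Introgression semantics: a locally fixed, non-recombining introgressed
# allele class is represented as its own deme.  Carrier lineages occupy that
# deme from the present backwards and the deme merges into the donor
# population's deme for that interval at the event time.  This is what makes
# carrier-vs-noncarrier fixed differences possible: lineages of the two
# allele classes cannot coalesce more recently than the event.

#' Construct a simulation configuration
#'
#' @param region_length region size in bp.
#' @param modules named list of two disjoint 0-based half-open intervals,
#'   e.g. `list(dennis = c(30000, 37000), ray = c(40000, 77000))`.
#' @param populations data.frame with columns `name`, `species`, `clade`,
#'   `Ne` (diploid individuals) and `n_hap` (sampled haplotypes; may be 0 for
#'   ghost populations).
#' @param splits data.frame with columns `pop`, `into`, `time` (Ma): each row
#'   merges a population into another, oldest merges building the species
#'   tree; exactly one population never merges (the root).
#' @param mutation_rate substitutions per site per Ma.
#' @param generation_scale generation time in Ma; the pairwise coalescence
#'   scale of a population is `2 * Ne * generation_scale` Ma.
#' @param introgression_events list of events, each a list with `name`,
#'   `time` (Ma), `donor`, `recipient` (population names), `interval`
#'   (must coincide with a module interval) and `fraction` in (0, 1] of
#'   recipient lineages carried.
#' @param recombinant_specs list of per-haplotype mosaics: each a list with
#'   `hap` (haplotype id), `breakpoint` (bp, strictly inside the region but
#'   not inside a module), `left_like`, `right_like` (population names whose
#'   allele the haplotype carries on each side).
#' @param native_modules named list: population -> character vector of module
#'   names for which that population's native allele is the
#'   phenotype-conferring class (e.g. the donor-species source population).
#' @param recipient_clade clade label of the recipient species complex.
#' @param indel_specs list of diagnostic indels, each a list with `module`,
#'   `start`, `end` (0-based, inside the module) and `gap_in` (character
#'   vector of allele-class labels showing a gap there).
#' @param coverage_model list with `mean_dp`, `gq_mean`, `gq_sd`, `mq_mean`,
#'   `mq_sd`, `low_call_frac` (fraction of genotype calls forced below QC
#'   thresholds) and `low_site_frac` (fraction of sites given failing MQ).
#' @param phase_scramble if TRUE, phase is scrambled within
#'   phenotype-homozygous individuals when genotypes are emitted.
#' @param seed master seed; all stages derive sub-stream seeds from it.
#' @return an object of class `sim_config`.
#' @seealso [default_sim_config()], [tiny_sim_config()], [simulate_dataset()]
#' @export
sim_config <- function(region_length, modules, populations, splits,
                       mutation_rate, generation_scale,
                       introgression_events = list(),
                       recombinant_specs = list(),
                       native_modules = list(),
                       recipient_clade,
                       indel_specs = list(),
                       coverage_model = list(),
                       phase_scramble = FALSE,
                       seed = 1L) {
  cm <- utils::modifyList(
    list(mean_dp = 30, gq_mean = 80, gq_sd = 8, mq_mean = 50, mq_sd = 4,
         low_call_frac = 0.02, low_site_frac = 0.005),
    coverage_model)
  cfg <- structure(list(
    region_length = as.integer(region_length),
    modules = modules,
    populations = as.data.frame(populations, stringsAsFactors = FALSE),
    splits = as.data.frame(splits, stringsAsFactors = FALSE),
    mutation_rate = mutation_rate,
    generation_scale = generation_scale,
    introgression_events = introgression_events,
    recombinant_specs = recombinant_specs,
    native_modules = native_modules,
    recipient_clade = recipient_clade,
    indel_specs = indel_specs,
    coverage_model = cm,
    phase_scramble = isTRUE(phase_scramble),
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %s bp region, %d populations, %d sampled haplotypes, seed %d\n",
              format(x$region_length, big.mark = ","), nrow(x$populations),
              sum(x$populations$n_hap), x$seed))
  for (m in names(x$modules)) {
    iv <- x$modules[[m]]
    cat(sprintf("  module %-8s [%s, %s)  (%.1f kb)\n", m,
                format(iv[1], big.mark = ","), format(iv[2], big.mark = ","),
                (iv[2] - iv[1]) / 1000))
  }
  for (ev in x$introgression_events) {
    cat(sprintf("  event %-22s %s -> %s at %.2f Ma (fraction %.2f)\n",
                ev$name, ev$donor, ev$recipient, ev$time, ev$fraction))
  }
  invisible(x)
}

#' Validate a simulation configuration
#'
#' Checks module geometry, the species-tree merge forest, introgression
#' events (time younger than the donor/recipient split, fraction in (0,1]),
#' recombinant breakpoints (inside the region, outside modules) and indel
#' placements.  Errors name the offending entry.
#'
#' @param cfg a `sim_config`.
#' @return invisibly TRUE.
#' @export
validate_sim_config <- function(cfg) {
  L <- cfg$region_length
  if (L <= 0) stopf("region_length must be positive")
  mods <- cfg$modules
  if (length(mods) < 1) stopf("at least one module interval required")
  for (m in names(mods)) {
    iv <- mods[[m]]
    if (iv[1] >= iv[2]) stopf("module %s: empty interval", m)
    if (iv[1] < 0 || iv[2] > L) stopf("module %s outside region", m)
  }
  if (length(mods) >= 2) {
    nm <- names(mods)
    for (i in seq_along(mods)) for (j in seq_along(mods)) {
      if (i < j && overlaps(mods[[i]], mods[[j]]))
        stopf("modules %s and %s overlap", nm[i], nm[j])
    }
  }
  pops <- cfg$populations
  need <- c("name", "species", "clade", "Ne", "n_hap")
  miss <- setdiff(need, names(pops))
  if (length(miss)) stopf("populations table lacks: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(pops$name)) stopf("duplicate population names")
  if (any(pops$Ne <= 0)) stopf("Ne must be positive")
  if (any(pops$n_hap < 0)) stopf("n_hap must be non-negative")
  sp <- cfg$splits
  if (!all(c("pop", "into", "time") %in% names(sp))) stopf("splits needs pop/into/time")
  unknown <- setdiff(c(sp$pop, sp$into), pops$name)
  if (length(unknown)) stopf("splits reference unknown population(s): %s",
                             paste(unique(unknown), collapse = ", "))
  if (anyDuplicated(sp$pop)) stopf("a population may merge only once")
  if (any(sp$time < 0)) stopf("split times must be >= 0")
  roots <- setdiff(pops$name, sp$pop)
  if (length(roots) != 1) stopf("merge forest must have exactly one root (found: %s)",
                                paste(roots, collapse = ", "))
  # every population must reach the root (no cycles, no disconnection)
  for (p in pops$name) {
    seen <- character()
    cur <- p
    while (cur != roots) {
      if (cur %in% seen) stopf("cycle in splits at population %s", cur)
      seen <- c(seen, cur)
      nxt <- sp$into[sp$pop == cur]
      if (!length(nxt)) stopf("population %s never reaches the root", cur)
      cur <- nxt
    }
  }
  if (cfg$mutation_rate < 0) stopf("mutation_rate must be >= 0")
  if (cfg$generation_scale <= 0) stopf("generation_scale must be positive")
  for (ev in cfg$introgression_events) {
    nm <- ev$name %||% "<unnamed>"
    if (is.null(ev$time) || ev$time < 0) stopf("event %s: time must be >= 0", nm)
    if (!(ev$donor %in% pops$name)) stopf("event %s: unknown donor %s", nm, ev$donor)
    if (!(ev$recipient %in% pops$name)) stopf("event %s: unknown recipient %s", nm, ev$recipient)
    if (is.null(ev$fraction) || ev$fraction <= 0 || ev$fraction > 1)
      stopf("event %s: fraction must be in (0, 1]", nm)
    mmatch <- which(vapply(mods, function(iv) all(iv == ev$interval), logical(1)))
    if (!length(mmatch))
      stopf("event %s: interval must coincide with a module interval", nm)
    jt <- pop_join_time(cfg, ev$donor, ev$recipient)
    if (ev$time >= jt)
      stopf("event %s: time %.2f not younger than donor/recipient split %.2f",
            nm, ev$time, jt)
  }
  haps <- sim_hap_table(cfg)$hap
  for (rs in cfg$recombinant_specs) {
    if (!(rs$hap %in% haps)) stopf("recombinant spec: unknown haplotype %s", rs$hap)
    if (rs$breakpoint <= 0 || rs$breakpoint >= L)
      stopf("recombinant %s: breakpoint must be strictly inside the region", rs$hap)
    for (m in names(mods)) {
      if (rs$breakpoint > mods[[m]][1] && rs$breakpoint < mods[[m]][2])
        stopf("recombinant %s: breakpoint inside module %s", rs$hap, m)
    }
    for (side in c("left_like", "right_like")) {
      if (!(rs[[side]] %in% pops$name)) stopf("recombinant %s: unknown population %s",
                                              rs$hap, rs[[side]])
    }
  }
  for (isp in cfg$indel_specs) {
    if (!(isp$module %in% names(mods))) stopf("indel spec: unknown module %s", isp$module)
    iv <- mods[[isp$module]]
    if (isp$start < iv[1] || isp$end > iv[2] || isp$start >= isp$end)
      stopf("indel spec in module %s: interval [%d,%d) not inside module",
            isp$module, isp$start, isp$end)
  }
  for (nm in names(cfg$native_modules)) {
    if (!(nm %in% pops$name)) stopf("native_modules: unknown population %s", nm)
    bad <- setdiff(cfg$native_modules[[nm]], names(mods))
    if (length(bad)) stopf("native_modules for %s: unknown module(s) %s",
                           nm, paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Time at which two populations' lineages first share a deme under the
# species-tree merge schedule.
pop_join_time <- function(cfg, a, b) {
  path <- function(p) {
    out <- data.frame(pop = p, time = 0)
    cur <- p
    repeat {
      row <- cfg$splits[cfg$splits$pop == cur, ]
      if (!nrow(row)) break
      out <- rbind(out, data.frame(pop = row$into, time = row$time))
      cur <- row$into
    }
    out
  }
  pa <- path(a); pb <- path(b)
  common <- intersect(pa$pop, pb$pop)
  if (!length(common)) return(Inf)
  max(min(pa$time[pa$pop %in% common]), min(pb$time[pb$pop %in% common]))
}

#' Sampled haplotype table for a configuration
#'
#' @param cfg a `sim_config`.
#' @return data.frame with columns `hap`, `sample`, `pop` listing every
#'   sampled haplotype (two per individual, `_h1`/`_h2`).
#' @export
sim_hap_table <- function(cfg) {
  out <- list()
  for (i in seq_len(nrow(cfg$populations))) {
    p <- cfg$populations[i, ]
    if (p$n_hap == 0) next
    if (p$n_hap %% 2 != 0)
      stopf("population %s: n_hap must be even for diploid pairing", p$name)
    n_ind <- p$n_hap / 2
    samples <- sprintf("%s_%02d", p$name, seq_len(n_ind))
    out[[p$name]] <- data.frame(
      hap = as.vector(t(outer(samples, c("_h1", "_h2"), paste0))),
      sample = rep(samples, each = 2),
      pop = p$name, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# ---- scenario compilation -------------------------------------------------

# Resolve, per haplotype and module, the population whose allele it carries
# (recombinant haplotypes borrow a population on each side of their
# breakpoint).
effective_pop <- function(cfg, hap_tab, module_iv) {
  eff <- hap_tab$pop
  names(eff) <- hap_tab$hap
  for (rs in cfg$recombinant_specs) {
    # a module lies entirely on one side of the breakpoint (validated)
    side <- if (module_iv[2] <= rs$breakpoint) rs$left_like else rs$right_like
    eff[rs$hap] <- side
  }
  eff
}

# Carrier haplotypes of an introgression event: the designated fraction of
# the recipient population's own haplotypes (seeded, deterministic), plus any
# recombinant-borrowed haplotypes whose effective population for the event's
# module is the recipient (they carry the allele by declaration).
event_carriers <- function(cfg, hap_tab) {
  mods <- cfg$modules
  out <- list()
  for (ev in cfg$introgression_events) {
    mod <- names(mods)[vapply(mods, function(iv) all(iv == ev$interval), logical(1))]
    eff <- effective_pop(cfg, hap_tab, mods[[mod]])
    own <- hap_tab$hap[hap_tab$pop == ev$recipient]
    if (ev$fraction >= 1) {
      des <- own
    } else {
      k <- ceiling(ev$fraction * length(own))
      des <- with_seed(substream_seed(cfg$seed, paste0("carriers:", ev$name)),
                       sort(sample(own, k)))
    }
    borrowed <- setdiff(names(eff)[eff == ev$recipient], own)
    out[[ev$name]] <- list(module = mod, haps = union(des, borrowed))
  }
  out
}

# Allele class of every haplotype at every module.  Class labels: the module
# name for the phenotype-conferring allele; "absent" for the recipient-clade
# non-carrier allele; "outgroup" for outgroup-clade alleles; otherwise the
# clade label (e.g. "silvaniform").
hap_module_classes <- function(cfg, hap_tab = sim_hap_table(cfg)) {
  carriers <- event_carriers(cfg, hap_tab)
  clade_of <- stats::setNames(cfg$populations$clade, cfg$populations$name)
  out <- matrix(NA_character_, nrow = nrow(hap_tab), ncol = length(cfg$modules),
                dimnames = list(hap_tab$hap, names(cfg$modules)))
  for (m in names(cfg$modules)) {
    eff <- effective_pop(cfg, hap_tab, cfg$modules[[m]])
    cls <- rep(NA_character_, length(eff))
    carrier_haps <- unique(unlist(lapply(carriers, function(cc)
      if (cc$module == m) cc$haps else character())))
    native_pops <- names(cfg$native_modules)[vapply(cfg$native_modules,
                                                    function(v) m %in% v, logical(1))]
    is_carrier <- hap_tab$hap %in% carrier_haps | eff %in% native_pops
    cls[is_carrier] <- m
    rest <- !is_carrier
    cls[rest & clade_of[eff] == cfg$recipient_clade] <- "absent"
    cls[rest & clade_of[eff] == "outgroup"] <- "outgroup"
    still <- is.na(cls)
    cls[still] <- clade_of[eff[still]]
    out[, m] <- cls
  }
  out
}

# ---- default scenarios ----------------------------------------------------

#' Default module-shuffling scenario
#'
#' The study conditions: a 100 kb region carrying a 7 kb forewing-patch
#' ("dennis") module and a 37 kb hindwing-ray ("ray") module; an outgroup, a
#' donor (silvaniform) clade containing the source species, and a recipient
#' (melpomene) clade splitting from the donor clade at 3.96 Ma; introgression
#' of the dennis module from the donor species into the recipient at 1.95 Ma;
#' origin of the ray allele within the recipient clade at 1.85 Ma (modelled
#' via an unsampled ghost lineage); introgression of the ray module back into
#' the donor species at 0.66 Ma; and two within-species recombinant races
#' each carrying only one module (112 sampled haplotypes in total).
#'
#' Population sizes use Ne = 1.6-2.0 million with four generations per year
#' (`generation_scale = 2.5e-7` Ma), giving within-species pairwise
#' coalescence scales of 0.8-1.0 Ma; the mutation rate of 0.005
#' substitutions/site/Ma then reproduces the observed order of within-clade
#' (~1%) and cross-clade (~4%) divergences.
#'
#' @param seed master seed.
#' @return a `sim_config`.
#' @export
default_sim_config <- function(seed = 1L) {
  # melpo_anc is the bottlenecked melpomene stem (ghost, no samples):
  # single-origin alleles joining the stem coalesce into recipient
  # diversity well before the deep split, as the observed unambiguous
  # clustering of module alleles requires
  pops <- data.frame(
    name    = c("outgroup", "silvaniform", "elevatus", "melpo_dr", "melpo_pm",
                "meriana", "contigua", "ray_anc", "melpo_anc"),
    species = c("aoede", "silvaniform", "elevatus", "melpomene", "melpomene",
                "melpomene", "timareta", "melpomene", "melpomene"),
    clade   = c("outgroup", "silvaniform", "silvaniform", "melpomene",
                "melpomene", "melpomene", "melpomene", "melpomene",
                "melpomene"),
    Ne      = c(2e6, 1.6e6, 4e5, 1.6e6, 1.6e6, 1.6e6, 1.6e6, 1.6e6, 8e5),
    n_hap   = c(8, 20, 12, 32, 32, 4, 4, 0, 0),
    stringsAsFactors = FALSE)
  splits <- data.frame(
    pop  = c("meriana", "contigua", "melpo_dr", "melpo_pm", "ray_anc",
             "elevatus", "melpo_anc", "silvaniform"),
    into = c("melpo_dr", "melpo_dr", "melpo_pm", "melpo_anc", "melpo_anc",
             "silvaniform", "silvaniform", "outgroup"),
    time = c(0.005, 0.005, 0.01, 1.0, 1.9, 3.0, 3.96, 8.0),
    stringsAsFactors = FALSE)
  modules <- list(dennis = c(30000L, 37000L), ray = c(40000L, 77000L))
  events <- list(
    list(name = "dennis_into_melpomene", time = 1.95, donor = "elevatus",
         recipient = "melpo_dr", interval = modules$dennis, fraction = 1),
    list(name = "ray_origin_melpomene", time = 1.85, donor = "ray_anc",
         recipient = "melpo_dr", interval = modules$ray, fraction = 1),
    list(name = "ray_into_elevatus", time = 0.66, donor = "melpo_dr",
         recipient = "elevatus", interval = modules$ray, fraction = 1))
  # meriana: dennis-only race (one fixed recombination event); contigua:
  # ray-only race.  All haplotypes of each race share the race's breakpoint.
  recs <- c(
    lapply(sprintf("meriana_%02d_h%d", rep(1:2, each = 2), rep(1:2, 2)),
           function(h) list(hap = h, breakpoint = 38200L,
                            left_like = "melpo_dr", right_like = "melpo_pm")),
    lapply(sprintf("contigua_%02d_h%d", rep(1:2, each = 2), rep(1:2, 2)),
           function(h) list(hap = h, breakpoint = 38800L,
                            left_like = "melpo_pm", right_like = "melpo_dr")))
  indels <- list(
    list(module = "dennis", start = 31000L, end = 31400L, gap_in = "outgroup"),
    list(module = "dennis", start = 33500L, end = 33620L, gap_in = c("absent", "outgroup")),
    list(module = "dennis", start = 35200L, end = 35280L, gap_in = c("dennis", "silvaniform")),
    list(module = "ray", start = 50000L, end = 50500L, gap_in = "outgroup"),
    list(module = "ray", start = 55000L, end = 55150L, gap_in = c("absent", "outgroup")),
    list(module = "ray", start = 60000L, end = 60090L, gap_in = "ray"))
  sim_config(
    region_length = 100000L, modules = modules, populations = pops,
    splits = splits, mutation_rate = 0.005, generation_scale = 2.5e-7,
    introgression_events = events, recombinant_specs = recs,
    native_modules = list(elevatus = "dennis"),
    recipient_clade = "melpomene", indel_specs = indels, seed = seed)
}

#' Miniature scenario for unit tests and fixtures
#'
#' Same topology and event times as [default_sim_config()] scaled to a 10 kb
#' region and 20 haplotypes, with a higher mutation rate so diagnostic-site
#' density per kb stays comparable.
#'
#' @param seed master seed.
#' @return a `sim_config`.
#' @export
tiny_sim_config <- function(seed = 1L) {
  pops <- data.frame(
    name    = c("outgroup", "silvaniform", "elevatus", "melpo_dr", "melpo_pm",
                "meriana", "ray_anc", "melpo_anc"),
    species = c("aoede", "silvaniform", "elevatus", "melpomene", "melpomene",
                "melpomene", "melpomene", "melpomene"),
    clade   = c("outgroup", "silvaniform", "silvaniform", "melpomene",
                "melpomene", "melpomene", "melpomene", "melpomene"),
    Ne      = c(2e6, 1.6e6, 4e5, 1.6e6, 1.6e6, 1.6e6, 1.6e6, 8e5),
    n_hap   = c(2, 2, 2, 6, 6, 2, 0, 0),
    stringsAsFactors = FALSE)
  splits <- data.frame(
    pop  = c("meriana", "melpo_dr", "melpo_pm", "ray_anc", "elevatus",
             "melpo_anc", "silvaniform"),
    into = c("melpo_dr", "melpo_pm", "melpo_anc", "melpo_anc", "silvaniform",
             "silvaniform", "outgroup"),
    time = c(0.005, 0.01, 1.0, 1.9, 3.0, 3.96, 8.0),
    stringsAsFactors = FALSE)
  modules <- list(dennis = c(2000L, 3500L), ray = c(4500L, 7500L))
  events <- list(
    list(name = "dennis_into_melpomene", time = 1.95, donor = "elevatus",
         recipient = "melpo_dr", interval = modules$dennis, fraction = 1),
    list(name = "ray_origin_melpomene", time = 1.85, donor = "ray_anc",
         recipient = "melpo_dr", interval = modules$ray, fraction = 1),
    list(name = "ray_into_elevatus", time = 0.66, donor = "melpo_dr",
         recipient = "elevatus", interval = modules$ray, fraction = 1))
  recs <- lapply(c("meriana_01_h1", "meriana_01_h2"),
                 function(h) list(hap = h, breakpoint = 4000L,
                                  left_like = "melpo_dr", right_like = "melpo_pm"))
  indels <- list(
    list(module = "dennis", start = 2400L, end = 2460L, gap_in = c("absent", "outgroup")),
    list(module = "dennis", start = 3000L, end = 3040L, gap_in = c("dennis", "silvaniform")),
    list(module = "ray", start = 5000L, end = 5100L, gap_in = "outgroup"),
    list(module = "ray", start = 5500L, end = 5560L, gap_in = c("absent", "outgroup")),
    list(module = "ray", start = 6000L, end = 6050L, gap_in = "ray"))
  sim_config(
    region_length = 10000L, modules = modules, populations = pops,
    splits = splits, mutation_rate = 0.02, generation_scale = 2.5e-7,
    introgression_events = events, recombinant_specs = recs,
    native_modules = list(elevatus = "dennis"),
    recipient_clade = "melpomene", indel_specs = indels, seed = seed)
}
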