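# Block-wise structured coalescent.
#
# Recombination happens only at module boundaries and declared breakpoints:
# the region is cut into non-recombining blocks, and each block gets its own
# genealogy from a structured Kingman coalescent over demes (populations plus
# allele-class demes created by introgression events), with demes merging at
# the configured split/event times.  Node ages are in Ma throughout.

# Non-recombining blocks: delimited by module boundaries and declared
# recombinant breakpoints.
block_table <- function(cfg) {
  cuts <- c(0L, cfg$region_length,
            unlist(cfg$modules, use.names = FALSE),
            vapply(cfg$recombinant_specs, function(r) as.integer(r$breakpoint),
                   integer(1)))
  cuts <- sort(unique(as.integer(cuts)))
  out <- data.frame(start = cuts[-length(cuts)], end = cuts[-1],
                    module = NA_character_, stringsAsFactors = FALSE)
  for (m in names(cfg$modules)) {
    iv <- cfg$modules[[m]]
    out$module[out$start >= iv[1] & out$end <= iv[2]] <- m
  }
  out
}

# The deme holding a population's own lineages for a given module: its event
# deme if the population is the recipient of an event on that module
# (the transferred allele descends from the carrier class), else the
# population itself.
deme_for_pop <- function(cfg, pop, module) {
  if (!is.na(module)) {
    for (ev in cfg$introgression_events) {
      mod <- names(cfg$modules)[vapply(cfg$modules, function(iv)
        all(iv == ev$interval), logical(1))]
      if (identical(mod, module) && ev$recipient == pop)
        return(paste0("ev:", ev$name))
    }
  }
  pop
}

# Deme plan for one block: starting deme per haplotype and the merge
# schedule (species splits plus event-deme merges relevant to the block).
block_deme_plan <- function(cfg, hap_tab, block, carriers) {
  bp_side <- function(rs) if (block$end <= rs$breakpoint) rs$left_like else rs$right_like
  eff <- stats::setNames(hap_tab$pop, hap_tab$hap)
  for (rs in cfg$recombinant_specs) eff[rs$hap] <- bp_side(rs)

  start_deme <- eff
  if (!is.na(block$module)) {
    for (nm in names(carriers)) {
      cc <- carriers[[nm]]
      if (cc$module == block$module) {
        hit <- intersect(cc$haps, hap_tab$hap)
        start_deme[hit] <- paste0("ev:", nm)
      }
    }
  }

  merges <- cfg$splits[, c("pop", "into", "time")]
  names(merges) <- c("from", "to", "time")
  merges$founder <- logical(nrow(merges))
  if (!is.na(block$module)) {
    for (ev in cfg$introgression_events) {
      mod <- names(cfg$modules)[vapply(cfg$modules, function(iv)
        all(iv == ev$interval), logical(1))]
      if (identical(mod, block$module)) {
        # single-origin allele class: remaining carrier lineages coalesce
        # into the founder haplotype at the event time, and the founder is
        # what transfers into the donor deme
        merges <- rbind(merges, data.frame(
          from = paste0("ev:", ev$name),
          to = deme_for_pop(cfg, ev$donor, block$module),
          time = ev$time, founder = TRUE, stringsAsFactors = FALSE))
      }
    }
  }
  merges <- merges[order(merges$time), , drop = FALSE]

  ne_t <- stats::setNames(2 * cfg$populations$Ne * cfg$generation_scale,
                          cfg$populations$name)
  for (ev in cfg$introgression_events) {
    ne_t[paste0("ev:", ev$name)] <- ne_t[ev$recipient]
  }
  list(start_deme = start_deme, merges = merges, ne_t = ne_t)
}

# One Kingman coalescent run over the deme plan.  RNG must be seeded by the
# caller.  Returns an ape::phylo with edge lengths in Ma and a "node_ages"
# attribute (ages in Ma, tips first).
sim_block_tree <- function(hap_ids, start_deme, ne_t, merges) {
  n <- length(hap_ids)
  if (n < 2) stopf("need at least 2 haplotypes")
  active_node <- seq_len(n)
  active_deme <- unname(start_deme[hap_ids])
  ages <- numeric(n - 1)
  kids <- matrix(0L, nrow = n - 1, ncol = 2)
  alias <- character(0)
  resolve <- function(d) { while (d %in% names(alias)) d <- alias[[d]]; d }
  t <- 0
  k_int <- 0L
  m_idx <- 1L
  while (length(active_node) > 1) {
    tab <- table(active_deme)
    tab <- tab[tab >= 2]
    rates <- as.numeric(tab) * (as.numeric(tab) - 1) / 2 / ne_t[names(tab)]
    total <- sum(rates)
    t_merge <- if (m_idx <= nrow(merges)) merges$time[m_idx] else Inf
    dt <- if (total > 0) stats::rexp(1, total) else Inf
    if (t + dt < t_merge) {
      t <- t + dt
      d <- if (length(rates) == 1) names(tab) else
        sample(names(tab), 1, prob = rates)
      idx <- which(active_deme == d)
      pair <- if (length(idx) == 2) idx else sample(idx, 2)
      k_int <- k_int + 1L
      ages[k_int] <- t
      kids[k_int, ] <- active_node[pair]
      active_node <- c(active_node[-pair], n + k_int)
      active_deme <- c(active_deme[-pair], d)
    } else {
      if (is.infinite(t_merge)) {
        stopf("unresolvable configuration: lineages stranded in deme(s) %s",
              paste(unique(active_deme), collapse = ", "))
      }
      t <- t_merge
      while (m_idx <= nrow(merges) && merges$time[m_idx] <= t + 1e-12) {
        from <- merges$from[m_idx]
        to <- resolve(merges$to[m_idx])
        if (isTRUE(merges$founder[m_idx])) {
          # coalesce the allele class into its founder at the event time
          while (sum(active_deme == from) > 1) {
            idx <- which(active_deme == from)
            pair <- if (length(idx) == 2) idx else sample(idx, 2)
            k_int <- k_int + 1L
            ages[k_int] <- t
            kids[k_int, ] <- active_node[pair]
            active_node <- c(active_node[-pair], n + k_int)
            active_deme <- c(active_deme[-pair], from)
          }
        }
        if (from != to) {
          alias[[from]] <- to
          active_deme[active_deme == from] <- to
        }
        m_idx <- m_idx + 1L
      }
    }
  }
  # renumber: internal k (ages ascending) -> ape node 2n - k, so root = n+1
  renum <- function(x) ifelse(x <= n, x, 2L * n - (x - n))
  node_age <- function(x) ifelse(x <= n, 0, ages[x - n])
  edge <- matrix(0L, nrow = 2 * (n - 1), ncol = 2)
  elen <- numeric(2 * (n - 1))
  r <- 1L
  for (k in seq_len(n - 1)) {
    for (ci in 1:2) {
      ch <- kids[k, ci]
      edge[r, ] <- c(renum(n + k), renum(ch))
      elen[r] <- ages[k] - node_age(ch)
      r <- r + 1L
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = hap_ids, Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  node_ages <- numeric(2 * n - 1)
  node_ages[n + seq_len(n - 1)] <- ages[rev(seq_len(n - 1))]
  attr(tr, "node_ages") <- node_ages
  tr
}

#' Simulate block genealogies under a module-shuffling scenario
#'
#' Cuts the region into non-recombining blocks (module boundaries plus
#' declared recombinant breakpoints) and draws one rooted genealogy per block
#' from the structured coalescent: Kingman coalescence within demes at rate
#' scaled by Ne, demes merging at the configured species splits, and
#' introgression-event allele-class demes merging into the donor at the event
#' time for blocks inside the event interval.  Deterministic given the
#' configuration seed.
#'
#' @param cfg a `sim_config`.
#' @return an object of class `block_genealogies`: a block table, one
#'   `ape::phylo` per block (edge lengths and node ages in Ma), and the
#'   haplotype table.
#' @export
simulate_genealogies <- function(cfg) {
  validate_sim_config(cfg)
  hap_tab <- sim_hap_table(cfg)
  blocks <- block_table(cfg)
  carriers <- event_carriers(cfg, hap_tab)
  trees <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    plan <- block_deme_plan(cfg, hap_tab, blocks[b, ], carriers)
    trees[[b]] <- with_seed(
      substream_seed(cfg$seed, sprintf("genealogy:%d", b)),
      sim_block_tree(hap_tab$hap, plan$start_deme, plan$ne_t, plan$merges))
  }
  structure(list(blocks = blocks, trees = trees, hap_table = hap_tab,
                 config = cfg),
            class = "block_genealogies")
}

#' @export
print.block_genealogies <- function(x, ...) {
  cat(sprintf("block_genealogies: %d blocks, %d haplotypes\n",
              nrow(x$blocks), nrow(x$hap_table)))
  print(x$blocks)
  invisible(x)
}

#' Pairwise coalescence ages of a block genealogy
#'
#' @param tree an `ape::phylo` with a `node_ages` attribute (as produced by
#'   [simulate_genealogies()]).
#' @return symmetric matrix of pairwise MRCA ages in Ma (zero diagonal),
#'   tips in `tip.label` order.
#' @export
pairwise_coal_ages <- function(tree) {
  ages <- attr(tree, "node_ages")
  if (is.null(ages)) stopf("tree lacks node ages")
  m <- ape::mrca(tree)
  out <- matrix(ages[m], nrow = nrow(m), dimnames = dimnames(m))
  diag(out) <- 0
  out
}

#' Realized mean cross-group coalescence time over a region
#'
#' Block-length-weighted mean, over all pairs (a in A, b in B), of the MRCA
#' age of a and b, restricted to blocks overlapping `region`.  This is the
#' generator's ground-truth divergence time for a pair of allele groups, the
#' quantity a correctly calibrated strict clock estimates.
#'
#' @param gen a `block_genealogies`.
#' @param ids_a,ids_b haplotype id sets.
#' @param region 0-based half-open interval (default: whole region).
#' @return mean coalescence time in Ma.
#' @export
mean_cross_coal_time <- function(gen, ids_a, ids_b, region = NULL) {
  if (length(intersect(ids_a, ids_b))) stopf("groups must be disjoint")
  tot <- 0; wsum <- 0
  for (b in seq_len(nrow(gen$blocks))) {
    blk <- gen$blocks[b, ]
    if (!is.null(region)) {
      ov <- min(blk$end, region[2]) - max(blk$start, region[1])
      if (ov <= 0) next
    } else ov <- blk$end - blk$start
    ca <- pairwise_coal_ages(gen$trees[[b]])
    tot <- tot + ov * mean(ca[ids_a, ids_b])
    wsum <- wsum + ov
  }
  if (wsum == 0) stopf("region overlaps no block")
  tot / wsum
}
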