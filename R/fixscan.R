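# Fixed nucleotide differences between sample groups, sliding-window
# summaries, and minimal-region delineation.

#' Fixed nucleotide differences between two groups
#'
#' A site is a fixed difference when all non-missing alleles in group A share
#' one state, all non-missing alleles in group B share a different single
#' state, and each group has at least `min_calls` callable members at the
#' site.  In genotype mode both alleles of every diploid must agree (a
#' heterozygote breaks fixation); in alignment mode each haplotype
#' contributes one state and columns containing gaps in either group are
#' skipped (indel architecture is handled elsewhere).
#'
#' @param x a [genotype_matrix()] (groups are sample ids) or a
#'   [phased_alignment()] (groups are haplotype ids).
#' @param group_a,group_b disjoint id sets.
#' @param min_calls minimum callable members per group per site (default 2).
#' @return integer vector of 0-based positions of fixed differences.
#' @export
fixed_differences <- function(x, group_a, group_b, min_calls = 2) {
  if (length(intersect(group_a, group_b)))
    stopf("groups overlap: %s", paste(intersect(group_a, group_b), collapse = ", "))
  UseMethod("fixed_differences")
}

#' @export
fixed_differences.genotype_matrix <- function(x, group_a, group_b, min_calls = 2) {
  for (g in list(group_a, group_b)) {
    bad <- setdiff(g, x$samples)
    if (length(bad)) stopf("unknown sample(s): %s", paste(bad, collapse = ", "))
  }
  state_of <- function(ids) {
    a1 <- x$a1[, ids, drop = FALSE]
    a2 <- x$a2[, ids, drop = FALSE]
    called <- !is.na(a1)
    hom <- called & (a1 == a2)
    # per-site single state if every called member is the same homozygote
    n_called <- rowSums(called)
    all_hom <- rowSums(hom) == n_called & n_called > 0
    state <- rep(NA_character_, nrow(a1))
    uniq <- rep(FALSE, nrow(a1))
    for (b in c("A", "C", "G", "T")) {
      is_b <- rowSums(hom & a1 == b) == n_called & n_called > 0
      state[all_hom & is_b] <- b
    }
    list(state = state, n = n_called)
  }
  sa <- state_of(group_a)
  sb <- state_of(group_b)
  ok <- sa$n >= min_calls & sb$n >= min_calls &
    !is.na(sa$state) & !is.na(sb$state) & sa$state != sb$state
  x$pos[ok]
}

#' @export
fixed_differences.phased_alignment <- function(x, group_a, group_b, min_calls = 2) {
  for (g in list(group_a, group_b)) {
    bad <- setdiff(g, x$ids)
    if (length(bad)) stopf("unknown haplotype(s): %s", paste(bad, collapse = ", "))
  }
  sa <- x$seq[group_a, , drop = FALSE]
  sb <- x$seq[group_b, , drop = FALSE]
  gap_col <- colSums(sa == ALN_GAP) + colSums(sb == ALN_GAP) > 0
  state_of <- function(s) {
    called <- s >= 1L & s <= 4L
    n <- colSums(called)
    state <- rep(NA_integer_, ncol(s))
    for (b in 1:4) {
      is_b <- colSums(called & s == b) == n & n > 0
      state[is_b] <- b
    }
    list(state = state, n = n)
  }
  za <- state_of(sa)
  zb <- state_of(sb)
  ok <- !gap_col & za$n >= min_calls & zb$n >= min_calls &
    !is.na(za$state) & !is.na(zb$state) & za$state != zb$state
  x$coord[ok]
}

#' Sliding-window counts of fixed sites
#'
#' Windows start at `region[1] + k * step` and span `window` bp (half-open);
#' trailing windows truncated by the region end are emitted and flagged.
#' Defaults are a 5 kb window moving in 1 kb steps.
#'
#' @param positions 0-based fixed-site positions.
#' @param region 0-based half-open region interval.
#' @param window,step window and step length in bp (`window >= step >= 1`).
#' @return a `fixed_diff_track` data.frame (start, end, count, truncated)
#'   with the positions and parameters attached as attributes.
#' @export
window_counts <- function(positions, region, window = 5000, step = 1000) {
  if (step < 1 || window < step) stopf("need window >= step >= 1")
  starts <- seq(region[1], region[2] - 1, by = step)
  ends <- pmin(starts + window, region[2])
  count <- vapply(seq_along(starts), function(i)
    sum(positions >= starts[i] & positions < ends[i]), integer(1))
  out <- data.frame(start = starts, end = ends, count = count,
                    truncated = (starts + window) > region[2])
  attr(out, "positions") <- sort(positions)
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "region") <- region
  class(out) <- c("fixed_diff_track", "data.frame")
  out
}

#' @export
print.fixed_diff_track <- function(x, ...) {
  cat(sprintf("fixed_diff_track: %d fixed sites, %d windows (%d bp / %d bp step)\n",
              length(attr(x, "positions")), nrow(x),
              attr(x, "window"), attr(x, "step")))
  invisible(x)
}

#' Minimal region spanned by fixed differences
#'
#' The smallest half-open interval containing every fixed-site position.
#'
#' @param positions 0-based fixed-site positions (non-empty).
#' @return a [module_interval()], or `NULL` when no positions are given
#'   (no-region signal).
#' @export
minimal_region <- function(positions) {
  if (!length(positions)) return(NULL)
  module_interval(min(positions), max(positions) + 1L,
                  count = length(positions),
                  evidence = list(start = "outermost fixed site",
                                  end = "outermost fixed site"))
}

#' Disjointness report for two fixed-difference comparisons
#'
#' @param track_a,track_b two `fixed_diff_track` objects on the same region
#'   (or plain position vectors).
#' @return list: `sites_disjoint`, `overlapping_positions`,
#'   `regions_disjoint`, and the two minimal regions.
#' @export
nonoverlap_check <- function(track_a, track_b) {
  pa <- if (inherits(track_a, "fixed_diff_track")) attr(track_a, "positions") else track_a
  pb <- if (inherits(track_b, "fixed_diff_track")) attr(track_b, "positions") else track_b
  ov <- intersect(pa, pb)
  ra <- minimal_region(pa)
  rb <- minimal_region(pb)
  reg_disjoint <- if (is.null(ra) || is.null(rb)) TRUE else
    !overlaps(c(ra$start, ra$end), c(rb$start, rb$end))
  list(sites_disjoint = length(ov) == 0,
       overlapping_positions = sort(ov),
       regions_disjoint = reg_disjoint,
       region_a = ra, region_b = rb)
}

#' Write fixed sites (BED), window track (TSV) and minimal region (BED)
#'
#' BED output is 0-based half-open; the window TSV carries 0-based window
#' starts (wiggle-compatible step/span in the header comment).
#'
#' @param track a `fixed_diff_track`.
#' @param sites_bed,track_tsv,region_bed output paths (`NULL` to skip).
#' @param chrom contig name used in BED lines.
#' @return invisibly, the list of written paths.
#' @export
write_fixscan <- function(track, sites_bed = NULL, track_tsv = NULL,
                          region_bed = NULL, chrom = "region1") {
  pos <- attr(track, "positions")
  if (!is.null(sites_bed)) {
    if (length(pos)) {
      bed <- data.frame(chrom = chrom, start = pos, end = pos + 1L)
      utils::write.table(bed, sites_bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      file.create(sites_bed)
    }
  }
  if (!is.null(track_tsv)) {
    con <- file(track_tsv, "w")
    writeLines(sprintf("# fixedStep window=%d step=%d", attr(track, "window"),
                       attr(track, "step")), con)
    utils::write.table(as.data.frame(track), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(region_bed)) {
    mr <- minimal_region(pos)
    if (!is.null(mr)) {
      bed <- data.frame(chrom = chrom, start = mr$start, end = mr$end,
                        name = "minimal_region")
      utils::write.table(bed, region_bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(list(sites_bed = sites_bed, track_tsv = track_tsv,
                 region_bed = region_bed))
}
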