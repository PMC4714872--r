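# Haplotype allele-class painting and recombination-breakpoint calling.
#
# Allele classes (e.g. an outgroup form, a donor/carrier form and a
# non-carrier form of the whole region) are learned from exemplar
# haplotypes as diagnostic columns (each class internally fixed, >= 2
# classes differing; gap states participate, so fixed indel architecture is
# diagnostic too).  Haplotypes are then painted by majority runs of
# concordant diagnostic votes, and class switches become recombination
# breakpoints with the bracketing informative columns as uncertainty.

#' Learn diagnostic columns and indel architecture from exemplars
#'
#' @param alignment a [phased_alignment()].
#' @param exemplars named list: class label -> haplotype ids (>= 2 each).
#' @param min_indel_len minimum gap-run length (bp) recorded as an indel
#'   architecture feature (default 30).
#' @return a `diagnostic_set`: diagnostic column indices/coordinates, the
#'   class-state matrix, and the indel architecture table
#'   (start, end, classes_gap).
#' @export
learn_diagnostics <- function(alignment, exemplars, min_indel_len = 30) {
  if (length(exemplars) < 2) stopf("need at least 2 classes")
  for (cl in names(exemplars)) {
    ids <- exemplars[[cl]]
    if (length(ids) < 2) stopf("class %s has fewer than 2 exemplars", cl)
    bad <- setdiff(ids, alignment$ids)
    if (length(bad)) stopf("class %s: unknown haplotype(s) %s", cl,
                           paste(bad, collapse = ", "))
  }
  classes <- names(exemplars)
  L <- ncol(alignment$seq)
  states <- matrix(NA_integer_, nrow = length(classes), ncol = L,
                   dimnames = list(classes, NULL))
  for (cl in classes) {
    s <- alignment$seq[exemplars[[cl]], , drop = FALSE]
    s[s == ALN_N] <- NA_integer_
    mx <- apply(s, 2, function(col) {
      u <- unique(col[!is.na(col)])
      if (length(u) == 1) u else NA_integer_
    })
    states[cl, ] <- mx
  }
  all_fixed <- colSums(is.na(states)) == 0
  n_distinct <- apply(states, 2, function(x) length(unique(x[!is.na(x)])))
  diag_cols <- which(all_fixed & n_distinct >= 2)

  # indel architecture: maximal runs of columns with a constant gap-presence
  # pattern (each class either fully gapped or fully ungapped; base-level
  # polymorphism within a class does not interrupt a gap feature)
  gap_key <- rep(NA_real_, L)
  gp <- matrix(FALSE, nrow = length(classes), ncol = L,
               dimnames = list(classes, NULL))
  gap_ok <- rep(TRUE, L)
  for (cl in classes) {
    s <- alignment$seq[exemplars[[cl]], , drop = FALSE]
    n_gap <- colSums(s == ALN_GAP)
    gp[cl, ] <- n_gap == nrow(s)
    gap_ok <- gap_ok & (n_gap == 0 | n_gap == nrow(s))
  }
  key_vals <- colSums(gp * 2^(seq_along(classes) - 1))
  gap_key[gap_ok] <- key_vals[gap_ok]
  r <- rle(ifelse(is.na(gap_key), -1, gap_key))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0 & r$lengths >= min_indel_len
  indels <- data.frame(start = integer(), end = integer(),
                       classes_gap = character(), stringsAsFactors = FALSE)
  if (any(keep)) {
    dec <- function(v) paste(classes[bitwAnd(as.integer(v),
                                             2^(seq_along(classes) - 1)) > 0],
                             collapse = ",")
    indels <- data.frame(
      start = alignment$coord[starts[keep]],
      end = alignment$coord[ends[keep]] + 1L,
      classes_gap = vapply(r$values[keep], dec, character(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(columns = diag_cols,
                 coords = alignment$coord[diag_cols],
                 states = states[, diag_cols, drop = FALSE],
                 classes = classes,
                 indels = indels),
            class = "diagnostic_set")
}

#' @export
print.diagnostic_set <- function(x, ...) {
  cat(sprintf("diagnostic_set: %d classes (%s), %d diagnostic columns, %d indel features\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$columns), nrow(x$indels)))
  invisible(x)
}

#' Paint one haplotype by allele class
#'
#' Each diagnostic column votes for the class(es) whose expected state the
#' haplotype matches; columns matching no class or more than one class are
#' unscored.  Maximal runs of at least `min_run` concordant votes become
#' segments; shorter discordant runs are absorbed into the flanking segment
#' and logged as votes against; spans before the first / after the last
#' scored column are marked `unknown`.  A switch between two anchored
#' classes is a breakpoint, reported as the midpoint between the bracketing
#' concordant columns.
#'
#' @param alignment a [phased_alignment()].
#' @param hap haplotype id.
#' @param diagnostics a `diagnostic_set`.
#' @param min_run minimum concordant run length to anchor a segment
#'   (default 3, to resist recurrent mutation).
#' @return a `seg_classification`: `segments` (start, end, class, votes_for,
#'   votes_against) tiling the alignment span, and `breakpoints` (left_col,
#'   right_col, midpoint, from_class, to_class), coordinates 0-based
#'   half-open.
#' @export
classify_haplotype <- function(alignment, hap, diagnostics, min_run = 3) {
  if (!(hap %in% alignment$ids)) stopf("unknown haplotype %s", hap)
  span <- c(alignment$coord[1], alignment$coord[length(alignment$coord)] + 1L)
  empty <- function() {
    structure(list(
      hap = hap,
      segments = data.frame(start = span[1], end = span[2], class = "unknown",
                            votes_for = 0L, votes_against = 0L,
                            stringsAsFactors = FALSE),
      breakpoints = data.frame(left_col = integer(), right_col = integer(),
                               midpoint = integer(), from_class = character(),
                               to_class = character(), stringsAsFactors = FALSE),
      absorbed = 0L), class = "seg_classification")
  }
  if (!length(diagnostics$columns)) return(empty())
  code <- alignment$seq[hap, diagnostics$columns]
  hits <- diagnostics$states == rep(code, each = length(diagnostics$classes))
  n_hit <- colSums(hits)
  label <- rep(NA_character_, length(code))
  one <- which(n_hit == 1 & code != ALN_N)
  label[one] <- diagnostics$classes[apply(hits[, one, drop = FALSE], 2, which)]
  scored <- which(!is.na(label))
  if (!length(scored)) return(empty())

  ls <- label[scored]
  r <- rle(ls)
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  anchor <- which(r$lengths >= min_run)
  if (!length(anchor)) return(empty())

  # merge consecutive anchors of the same class; count absorbed discordants
  segs <- list()
  cur <- list(class = r$values[anchor[1]], si_first = rstart[anchor[1]],
              si_last = rend[anchor[1]])
  absorbed <- 0L
  if (length(anchor) > 1) {
    for (ai in anchor[-1]) {
      if (r$values[ai] == cur$class) {
        cur$si_last <- rend[ai]
      } else {
        segs[[length(segs) + 1L]] <- cur
        cur <- list(class = r$values[ai], si_first = rstart[ai],
                    si_last = rend[ai])
      }
    }
  }
  segs[[length(segs) + 1L]] <- cur
  absorbed <- sum(r$lengths[-anchor])

  col_coord <- function(si) diagnostics$coords[scored[si]]

  n_seg <- length(segs)
  bps <- data.frame(left_col = integer(), right_col = integer(),
                    midpoint = integer(), from_class = character(),
                    to_class = character(), stringsAsFactors = FALSE)
  bounds <- numeric(n_seg + 1)
  bounds[1] <- span[1]
  bounds[n_seg + 1] <- span[2]
  if (n_seg > 1) {
    for (k in seq_len(n_seg - 1)) {
      lcol <- col_coord(segs[[k]]$si_last)
      rcol <- col_coord(segs[[k + 1]]$si_first)
      mid <- floor((lcol + rcol) / 2)
      bounds[k + 1] <- mid
      bps <- rbind(bps, data.frame(
        left_col = lcol, right_col = rcol, midpoint = mid,
        from_class = segs[[k]]$class, to_class = segs[[k + 1]]$class,
        stringsAsFactors = FALSE))
    }
  }
  seg_df <- do.call(rbind, lapply(seq_len(n_seg), function(k) {
    s <- bounds[k]; e <- bounds[k + 1]
    in_seg <- which(diagnostics$coords[scored] >= s &
                      diagnostics$coords[scored] < e)
    data.frame(start = s, end = e, class = segs[[k]]$class,
               votes_for = sum(ls[in_seg] == segs[[k]]$class),
               votes_against = sum(ls[in_seg] != segs[[k]]$class),
               stringsAsFactors = FALSE)
  }))
  # leading/trailing spans outside any scored column stay part of the first/
  # last segment span here; mark them unknown when they carry no votes
  first_col <- col_coord(segs[[1]]$si_first)
  last_col <- col_coord(segs[[n_seg]]$si_last)
  lead <- first_col - span[1]
  trail <- span[2] - (last_col + 1L)
  out_segs <- seg_df
  if (lead > 0) {
    out_segs$start[1] <- first_col
    out_segs <- rbind(data.frame(start = span[1], end = first_col,
                                 class = "unknown", votes_for = 0L,
                                 votes_against = 0L), out_segs)
  }
  if (trail > 0) {
    out_segs$end[nrow(out_segs)] <- last_col + 1L
    out_segs <- rbind(out_segs,
                      data.frame(start = last_col + 1L, end = span[2],
                                 class = "unknown", votes_for = 0L,
                                 votes_against = 0L))
  }
  structure(list(hap = hap, segments = out_segs, breakpoints = bps,
                 absorbed = absorbed),
            class = "seg_classification")
}

#' @export
print.seg_classification <- function(x, ...) {
  cat(sprintf("seg_classification for %s: %d segment(s), %d breakpoint(s)\n",
              x$hap, nrow(x$segments), nrow(x$breakpoints)))
  print(x$segments)
  invisible(x)
}

#' Paint many haplotypes
#'
#' @param alignment a [phased_alignment()].
#' @param diagnostics a `diagnostic_set`.
#' @param ids haplotypes to classify (default: all).
#' @param min_run see [classify_haplotype()].
#' @return named list of `seg_classification` objects.
#' @export
classify_haplotypes <- function(alignment, diagnostics, ids = alignment$ids,
                                min_run = 3) {
  stats::setNames(lapply(ids, classify_haplotype, alignment = alignment,
                         diagnostics = diagnostics, min_run = min_run), ids)
}

#' Refine module boundaries from recombinant haplotypes
#'
#' For each module, every phenotype-positive individual must carry the
#' functional allele class across the module's fixed-site extent on at least
#' one haplotype (single-locus dominance).  The module therefore lies within
#' the intersection of those carrier haplotypes' pure class segments: a
#' boundary supported by a recombinant is placed at its breakpoint midpoint
#' (uncertainty = the bracketing diagnostic columns), and a boundary with no
#' recombinant evidence falls back to the outermost phenotype-associated
#' fixed site (the "rapid loss of associated variants" rule).  Individuals
#' heterozygous for a module contribute through their carrier haplotype
#' only; samples whose haplotypes cannot be scored across the module are
#' uninformative.  Carriers whose pure segment excludes fixed associated
#' sites contradict the comparison and are reported as conflicts, with no
#' silent resolution (no interval is returned for a conflicted module).
#'
#' @param classifications named list of `seg_classification` (from
#'   [classify_haplotypes()]).
#' @param pheno a [phenotype_table()].
#' @param fixed_sites named list: module -> 0-based fixed-site positions
#'   (from [fixed_differences()] for that module's contrast).
#' @param present_class named list: module -> class label marking the
#'   functional (phenotype-conferring) allele form.
#' @param region 0-based half-open interval of the analysed region.
#' @param samples optional sample subset whose haplotypes may contribute
#'   boundary evidence.  Typically the recipient-clade samples: carriers in
#'   other species hold introgressed copies that accumulate their own
#'   mutations after transfer, so they violate strict class concordance
#'   without being recombinant.
#' @return a `breakpoint_calls` object: per module a refined
#'   [module_interval()] (or `NULL` if conflicted/no signal), boundary
#'   evidence, and any conflicts.
#' @export
call_breakpoints <- function(classifications, pheno, fixed_sites,
                             present_class, region, samples = NULL) {
  haps <- names(classifications)
  if (!is.null(samples)) {
    haps <- haps[hap_samples(haps) %in% samples]
  }
  samples_of <- hap_samples(haps)
  out <- list()
  for (m in names(fixed_sites)) {
    f <- fixed_sites[[m]]
    if (!length(f)) {
      out[[m]] <- list(interval = NULL, conflicts = character(),
                       note = "no fixed differences")
      next
    }
    fmin <- min(f); fmax <- max(f) + 1L
    pcl <- present_class[[m]]
    pres <- phenotype_vector(pheno, m)
    conflicts <- character()
    lefts <- data.frame(pos = region[1], hap = NA_character_,
                        bracket_l = NA_integer_, bracket_r = NA_integer_)
    rights <- data.frame(pos = region[2], hap = NA_character_,
                         bracket_l = NA_integer_, bracket_r = NA_integer_)
    used <- character()
    for (s in intersect(names(pres)[!is.na(pres) & pres], unique(samples_of))) {
      s_haps <- haps[samples_of == s]
      for (h in s_haps) {
        cl <- classifications[[h]]
        segs <- cl$segments
        bp <- cl$breakpoints
        for (k in which(segs$class == pcl)) {
          # only a class switch constrains; edges bounded by unknown spans
          # or the region ends carry no evidence and coverage extends
          # through them.  Switch positions are uncertain within their
          # bracketing diagnostic columns, so coverage of the fixed-site
          # extent is judged at bracket resolution: the segment is
          # consistent unless concordant opposite-class votes fall strictly
          # inside the extent.
          bl <- bp[bp$midpoint == segs$start[k], , drop = FALSE]
          br <- bp[bp$midpoint == segs$end[k], , drop = FALSE]
          out_s <- if (nrow(bl)) bl$left_col[1] else region[1]
          out_e <- if (nrow(br)) br$right_col[1] + 1L else region[2]
          if (out_s >= fmax || out_e <= fmin) next  # elsewhere in the region
          ok_left <- !nrow(bl) || bl$left_col[1] < fmin
          ok_right <- !nrow(br) || br$right_col[1] >= fmax
          if (ok_left && ok_right) {
            used <- c(used, h)
            if (nrow(bl)) lefts <- rbind(lefts, data.frame(
              pos = segs$start[k], hap = h,
              bracket_l = bl$left_col[1], bracket_r = bl$right_col[1]))
            if (nrow(br)) rights <- rbind(rights, data.frame(
              pos = segs$end[k], hap = h,
              bracket_l = br$left_col[1], bracket_r = br$right_col[1]))
          } else {
            conflicts <- c(conflicts, sprintf(
              "%s: %s switch inside the fixed-site extent [%d,%d) of module %s",
              h, pcl, fmin, fmax, m))
          }
        }
      }
    }
    if (length(conflicts)) {
      out[[m]] <- list(interval = NULL, conflicts = conflicts)
      next
    }
    li <- lefts[which.max(lefts$pos), ]
    ri <- rights[which.min(rights$pos), ]
    # breakpoint midpoints are clamped so the interval always contains the
    # fixed-site extent (the midpoint may sit just inside it when the
    # bracket straddles the outermost fixed site)
    left_pos <- if (li$pos > region[1]) min(li$pos, fmin) else fmin
    right_pos <- if (ri$pos < region[2]) max(ri$pos, fmax) else fmax
    ev <- list(
      start = if (li$pos > region[1])
        sprintf("recombination breakpoint in %s (bracket %d-%d)", li$hap,
                li$bracket_l, li$bracket_r)
      else "outermost phenotype-associated fixed site (rapid-loss fallback)",
      end = if (ri$pos < region[2])
        sprintf("recombination breakpoint in %s (bracket %d-%d)", ri$hap,
                ri$bracket_l, ri$bracket_r)
      else "outermost phenotype-associated fixed site (rapid-loss fallback)")
    out[[m]] <- list(
      interval = module_interval(left_pos, right_pos, count = length(f),
                                 evidence = ev),
      conflicts = character(),
      boundary = list(left = li, right = ri),
      carriers_used = unique(used))
  }
  structure(out, class = "breakpoint_calls")
}

#' @export
print.breakpoint_calls <- function(x, ...) {
  for (m in names(x)) {
    cat("module ", m, ":\n", sep = "")
    if (length(x[[m]]$conflicts)) {
      cat("  CONFLICT:\n")
      for (cc in x[[m]]$conflicts) cat("   ", cc, "\n")
    } else if (is.null(x[[m]]$interval)) {
      cat("  ", x[[m]]$note %||% "no interval", "\n")
    } else {
      print(x[[m]]$interval)
    }
  }
  invisible(x)
}

#' Write per-haplotype class paintings as BED
#'
#' One BED line per segment, class in the name field.
#'
#' @param classifications named list of `seg_classification`.
#' @param path output BED path.
#' @param chrom contig name.
#' @return the path, invisibly.
#' @export
write_paintings_bed <- function(classifications, path, chrom = "region1") {
  rows <- do.call(rbind, lapply(classifications, function(cl) {
    data.frame(chrom = chrom, start = cl$segments$start, end = cl$segments$end,
               name = paste0(cl$hap, ":", cl$segments$class))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
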