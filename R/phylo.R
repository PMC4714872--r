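# Pairwise p-distances, neighbor-joining trees, group divergence tables and
# outgroup-rooted clade assignment.

#' Pairwise p-distance matrix
#'
#' Fraction of differing sites among pairwise-complete columns (both states
#' in A,C,G,T; gaps and N excluded pairwise — MEGA-style pairwise deletion).
#' Complete deletion (drop any column with a missing state in any selected
#' haplotype) is available by flag.
#'
#' @param alignment a [phased_alignment()].
#' @param region optional 0-based half-open interval restricting columns.
#' @param ids optional haplotype subset.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return a `p_distance` object: `d` (symmetric distance matrix, `NaN`
#'   where no columns are comparable) and `n` (compared-site counts).
#' @export
p_distance_matrix <- function(alignment, region = NULL, ids = NULL,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  ids <- ids %||% alignment$ids
  bad <- setdiff(ids, alignment$ids)
  if (length(bad)) stopf("unknown haplotype(s): %s", paste(bad, collapse = ", "))
  cols <- aln_columns(alignment, region)
  if (!length(cols)) stopf("region selects no alignment columns")
  s <- alignment$seq[ids, cols, drop = FALSE]
  valid <- s >= 1L & s <= 4L
  if (deletion == "complete") {
    keep <- colSums(valid) == nrow(s)
    s <- s[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  vd <- valid * 1
  V <- tcrossprod(vd)
  M <- matrix(0, nrow(s), nrow(s))
  for (b in 1:4) {
    ind <- (s == b) * 1
    M <- M + tcrossprod(ind)
  }
  D <- V - M
  d <- D / V
  diag(d) <- 0
  dimnames(d) <- dimnames(V) <- list(ids, ids)
  structure(list(d = d, n = V), class = "p_distance")
}

#' p-distance for one pair of haplotypes
#'
#' @param alignment a [phased_alignment()].
#' @param pair two haplotype ids.
#' @param region optional 0-based half-open interval.
#' @return list with `distance` (NaN when no comparable columns: the
#'   undefined-distance signal) and `compared` (column count).
#' @export
p_distance <- function(alignment, pair, region = NULL) {
  if (length(pair) != 2 || pair[1] == pair[2]) stopf("need two distinct haplotypes")
  pd <- p_distance_matrix(alignment, region = region, ids = pair)
  list(distance = pd$d[1, 2], compared = pd$n[1, 2])
}

#' Group divergence table
#'
#' Mean pairwise p-distance within (diagonal) and between (off-diagonal)
#' groups, expressed as percent.  Within-group entries use intra-group pairs
#' only; singleton groups have an undefined diagonal but still contribute
#' off-diagonals.
#'
#' @param alignment a [phased_alignment()].
#' @param groups named list: group label -> haplotype ids.
#' @param region optional 0-based half-open interval.
#' @param region_label free-text label stored with the table.
#' @return a `group_divergence` matrix (percent).
#' @export
group_divergence <- function(alignment, groups, region = NULL,
                             region_label = NA_character_) {
  ids <- unique(unlist(groups))
  pd <- p_distance_matrix(alignment, region = region, ids = ids)
  g <- names(groups)
  out <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) for (j in i:length(g)) {
    a <- groups[[i]]; b <- groups[[j]]
    if (i == j) {
      if (length(a) < 2) next
      sub <- pd$d[a, a]
      val <- mean(sub[upper.tri(sub)])
    } else {
      val <- mean(pd$d[a, b])
    }
    out[i, j] <- out[j, i] <- 100 * val
  }
  attr(out, "region_label") <- region_label
  attr(out, "deletion") <- "pairwise"
  class(out) <- c("group_divergence", "matrix")
  out
}

#' @export
print.group_divergence <- function(x, ...) {
  lbl <- attr(x, "region_label")
  cat(sprintf("group divergence (%%), %s, pairwise deletion:\n",
              if (is.na(lbl)) "unlabelled region" else lbl))
  y <- unclass(x)
  attr(y, "region_label") <- NULL
  attr(y, "deletion") <- NULL
  print(round(y, 1))
  invisible(x)
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard neighbor-joining agglomeration (via ape); negative branch
#' lengths are clamped to zero and logged in the `clamped_edges` attribute.
#'
#' @param pd a `p_distance` object or a symmetric distance matrix.
#' @return an unrooted `ape::phylo`.
#' @export
nj_tree <- function(pd) {
  d <- if (inherits(pd, "p_distance")) pd$d else as.matrix(pd)
  if (nrow(d) < 3) stopf("need at least 3 haplotypes")
  bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad)) {
    pairs <- apply(bad, 1, function(ij)
      paste(rownames(d)[ij[1]], colnames(d)[ij[2]], sep = "/"))
    stopf("undefined distances for pair(s): %s", paste(pairs, collapse = ", "))
  }
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  if (length(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped_edges") <- length(neg)
  tr
}

#' Assign focal haplotypes to reference clades on a rooted tree
#'
#' The tree is rooted at the declared outgroup; each focal leaf is labelled
#' by the reference set represented in its smallest enclosing ancestral
#' clade that contains any reference leaves — if exactly one reference set
#' is represented there, the focal gets that label, otherwise
#' `"unresolved"`.  Leaves that are neither focal nor reference (nor
#' outgroup) are ignored while walking.
#'
#' @param tree an `ape::phylo`.
#' @param focal focal leaf ids.
#' @param refs named list of disjoint, non-empty reference leaf sets.
#' @param outgroup leaf id(s) to root at.
#' @return named character vector: focal leaf -> reference label or
#'   `"unresolved"`.
#' @export
clade_assignment <- function(tree, focal, refs, outgroup) {
  if (!all(outgroup %in% tree$tip.label)) stopf("outgroup absent from tree")
  for (nm in names(refs)) {
    if (!length(refs[[nm]])) stopf("reference set %s is empty", nm)
  }
  allr <- unlist(refs)
  if (anyDuplicated(allr)) stopf("reference sets must be disjoint")
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  n <- length(tr$tip.label)
  parent <- integer(n + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  # tip sets per node, accumulated children-first
  tipsets <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) tipsets[[i]] <- i
  po <- ape::postorder(tr)
  for (e in po) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  ref_of_tip <- rep(NA_character_, n)
  for (nm in names(refs)) {
    ref_of_tip[match(refs[[nm]], tr$tip.label)] <- nm
  }
  out <- stats::setNames(rep("unresolved", length(focal)), focal)
  root_node <- n + 1L
  for (f in focal) {
    node <- match(f, tr$tip.label)
    if (is.na(node)) stopf("focal leaf %s absent from tree", f)
    lab <- "unresolved"
    while (node != root_node) {
      node <- parent[node]
      rr <- unique(ref_of_tip[tipsets[[node]][tipsets[[node]] <= n]])
      rr <- rr[!is.na(rr)]
      if (length(rr) == 1) { lab <- rr; break }
      if (length(rr) > 1) { lab <- "unresolved"; break }
      if (node == root_node) break
    }
    out[f] <- lab
  }
  out
}
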