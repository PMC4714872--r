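# Diagnostic learning, haplotype painting and breakpoint calling.

# Hand-built alignment: two classes with exemplars, controllable diagnostic
# columns.
toy_classes <- function() {
  L <- 120
  base <- matrix("A", nrow = 7, ncol = L)
  rownames(base) <- c("y_01_h1", "y_01_h2", "y_02_h1",
                      "z_01_h1", "z_01_h2", "z_02_h1", "q_01_h1")
  diag_cols <- c(10, 30, 50, 70)
  for (j in diag_cols) base[4:6, j] <- "G"      # Z differs at 4 columns
  base[1, 90] <- "C"                            # polymorphic within Y
  base
}

test_that("diagnostic columns are class-fixed and distinguishing", {
  ch <- toy_classes()
  aln <- phased_alignment(ch, ids = rownames(ch))
  diag <- learn_diagnostics(aln, list(
    Y = rownames(ch)[1:3], Z = rownames(ch)[4:6]))
  expect_equal(diag$coords, c(10, 30, 50, 70) - 1L)
  expect_error(learn_diagnostics(aln, list(Y = rownames(ch)[1:3],
                                           Z = rownames(ch)[4])),
               "fewer than 2")
})

test_that("a pure haplotype paints as a single class segment", {
  ch <- toy_classes()
  aln <- phased_alignment(ch, ids = rownames(ch))
  diag <- learn_diagnostics(aln, list(Y = rownames(ch)[1:3],
                                      Z = rownames(ch)[4:6]))
  cl <- classify_haplotype(aln, "q_01_h1", diag)  # identical to Y states
  segs <- cl$segments[cl$segments$class != "unknown", ]
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$class, "Y")
  expect_identical(nrow(cl$breakpoints), 0L)
})

test_that("a constructed mosaic switches exactly between its bracket columns", {
  L <- 600
  ch <- matrix("A", nrow = 5, ncol = L)
  rownames(ch) <- c("y_01_h1", "y_01_h2", "z_01_h1", "z_01_h2", "m_01_h1")
  diag_cols <- seq(5, 500, by = 5)              # 100 diagnostic columns
  for (j in diag_cols) ch[3:4, j] <- "T"
  # mosaic: Y states at diagnostic columns 1..40, Z at 41..100
  ch[5, diag_cols[41:100]] <- "T"
  aln <- phased_alignment(ch, ids = rownames(ch))
  diag <- learn_diagnostics(aln, list(Y = rownames(ch)[1:2],
                                      Z = rownames(ch)[3:4]))
  cl <- classify_haplotype(aln, "m_01_h1", diag)
  expect_identical(cl$segments$class[cl$segments$class != "unknown"],
                   c("Y", "Z"))
  expect_identical(nrow(cl$breakpoints), 1L)
  bp <- cl$breakpoints
  expect_identical(bp$left_col, diag$coords[40])
  expect_identical(bp$right_col, diag$coords[41])
  expect_identical(bp$midpoint, floor((diag$coords[40] + diag$coords[41]) / 2))
  # segments tile the alignment span without overlap
  segs <- cl$segments
  expect_identical(segs$start[-1], segs$end[-nrow(segs)])
  expect_equal(segs$start[1], aln$coord[1])
  expect_equal(segs$end[nrow(segs)], aln$coord[length(aln$coord)] + 1L)
})

test_that("short discordant runs are absorbed and logged", {
  L <- 600
  ch <- matrix("A", nrow = 5, ncol = L)
  rownames(ch) <- c("y_01_h1", "y_01_h2", "z_01_h1", "z_01_h2", "m_01_h1")
  diag_cols <- seq(5, 500, by = 5)
  for (j in diag_cols) ch[3:4, j] <- "T"
  ch[5, diag_cols[50]] <- "T"                  # single discordant vote
  aln <- phased_alignment(ch, ids = rownames(ch))
  diag <- learn_diagnostics(aln, list(Y = rownames(ch)[1:2],
                                      Z = rownames(ch)[3:4]))
  cl <- classify_haplotype(aln, "m_01_h1", diag, min_run = 3)
  expect_identical(nrow(cl$breakpoints), 0L)
  expect_identical(cl$absorbed, 1L)
  seg <- cl$segments[cl$segments$class == "Y", ]
  expect_identical(seg$votes_against, 1L)
})

test_that("classification is invariant to haplotype input order", {
  sim <- get_tiny_sim(1)
  ph <- sim$pheno
  exem <- list(
    dennis_ray = haps_for(ph$sample[ph$group == "dennis_ray" &
                                      ph$clade == "melpomene"]),
    postman = haps_for(ph$sample[ph$group == "postman"]),
    outgroup = haps_for(ph$sample[ph$group == "outgroup"]))
  diag <- learn_diagnostics(sim$alignment, exem)
  ids <- sim$alignment$ids
  c1 <- classify_haplotypes(sim$alignment, diag, ids = ids)
  c2 <- classify_haplotypes(sim$alignment, diag, ids = rev(ids))
  for (h in ids) expect_identical(c1[[h]], c2[[h]])
})

test_that("simulated indel architecture is re-learned exactly", {
  sim <- get_tiny_sim(1)
  ph <- sim$pheno
  exem <- list(
    dennis_ray = haps_for(ph$sample[ph$group == "dennis_ray" &
                                      ph$clade == "melpomene"]),
    postman = haps_for(ph$sample[ph$group == "postman"]),
    outgroup = haps_for(ph$sample[ph$group == "outgroup"]))
  diag <- learn_diagnostics(sim$alignment, exem)
  cfg_indels <- sim$config$indel_specs
  # translate configured class labels to exemplar class labels
  gap_classes <- function(gap_in) {
    out <- character()
    if (any(gap_in %in% c("dennis", "ray"))) out <- c(out, "dennis_ray")
    if ("absent" %in% gap_in) out <- c(out, "postman")
    if ("outgroup" %in% gap_in) out <- c(out, "outgroup")
    paste(sort(out), collapse = ",")
  }
  for (isp in cfg_indels) {
    hit <- diag$indels[diag$indels$start == isp$start &
                         diag$indels$end == isp$end, ]
    expect_identical(nrow(hit), 1L)
    got <- paste(sort(strsplit(hit$classes_gap, ",")[[1]]), collapse = ",")
    expect_identical(got, gap_classes(isp$gap_in))
  }
})

test_that("simulated recombinant breakpoints fall inside their called bracket", {
  for (seed in 1:5) {
    sim <- get_tiny_sim(seed)
    ph <- sim$pheno
    exem <- list(
      dennis_ray = haps_for(ph$sample[ph$group == "dennis_ray" &
                                        ph$clade == "melpomene"]),
      postman = haps_for(ph$sample[ph$group == "postman"]))
    diag <- learn_diagnostics(sim$alignment, exem)
    cl <- classify_haplotype(sim$alignment, "meriana_01_h1", diag)
    bp <- cl$breakpoints[cl$breakpoints$from_class == "dennis_ray" &
                           cl$breakpoints$to_class == "postman", ]
    expect_identical(nrow(bp), 1L)
    truth_bp <- sim$truth$recombinants$breakpoint[
      sim$truth$recombinants$hap == "meriana_01_h1"]
    expect_lte(bp$left_col, truth_bp)
    expect_gte(bp$right_col, truth_bp)
  }
})

test_that("boundaries fall back to the fixed-site extent without recombinants", {
  sim <- get_tiny_sim(1)
  ph <- sim$pheno
  rc <- ph$clade == "melpomene"
  exem <- list(
    dennis_ray = haps_for(ph$sample[rc & ph$group == "dennis_ray"]),
    postman = haps_for(ph$sample[ph$group == "postman"]))
  diag <- learn_diagnostics(sim$alignment, exem)
  pure <- c(exem$dennis_ray, exem$postman)
  cls <- classify_haplotypes(sim$alignment, diag, ids = pure)
  fixed <- list(dennis = fixed_differences(
    sim$alignment, exem$dennis_ray, exem$postman))
  fixed$dennis <- fixed$dennis[fixed$dennis >= 2000 & fixed$dennis < 3500]
  ph_pure <- phenotype_table(ph[ph$sample %in% hap_samples_test(pure), ])
  calls <- call_breakpoints(cls, ph_pure, fixed,
                            present_class = list(dennis = "dennis_ray"),
                            region = c(0L, 10000L))
  iv <- calls$dennis$interval
  expect_identical(iv$start, as.numeric(min(fixed$dennis)))
  expect_identical(iv$end, as.numeric(max(fixed$dennis) + 1))
  expect_match(iv$evidence$start, "fixed site")
})

test_that("heterozygous recombinants inform only their carrier module", {
  sim <- get_tiny_sim(1)
  ph <- sim$pheno
  rc <- ph$clade == "melpomene"
  exem <- list(
    dennis_ray = haps_for(ph$sample[rc & ph$group == "dennis_ray"]),
    postman = haps_for(ph$sample[ph$group == "postman"]))
  diag <- learn_diagnostics(sim$alignment, exem)
  ids <- c(exem$dennis_ray, exem$postman, "meriana_01_h1", "meriana_01_h2")
  cls <- classify_haplotypes(sim$alignment, diag, ids = ids)
  # make meriana_01 an artificial heterozygote: h2 replaced by a pure
  # postman painting
  cls[["meriana_01_h2"]] <- cls[[exem$postman[1]]]
  cls[["meriana_01_h2"]]$hap <- "meriana_01_h2"
  fixed <- list(
    dennis = fixed_differences(sim$alignment, exem$dennis_ray, exem$postman))
  fixed$dennis <- fixed$dennis[fixed$dennis >= 2000 & fixed$dennis < 3500]
  ph_use <- phenotype_table(ph[ph$sample %in% hap_samples_test(ids), ])
  calls <- call_breakpoints(cls, ph_use, fixed,
                            present_class = list(dennis = "dennis_ray"),
                            region = c(0L, 10000L))
  expect_true("meriana_01_h1" %in% calls$dennis$carriers_used)
  expect_false("meriana_01_h2" %in% calls$dennis$carriers_used)
  # the recombinant's switch refines the dennis end
  expect_match(calls$dennis$interval$evidence$end, "meriana_01_h1")
})

test_that("contradictory recombinants are reported, not resolved", {
  sim <- get_tiny_sim(1)
  ph <- sim$pheno
  rc <- ph$clade == "melpomene"
  exem <- list(
    dennis_ray = haps_for(ph$sample[rc & ph$group == "dennis_ray"]),
    postman = haps_for(ph$sample[ph$group == "postman"]))
  diag <- learn_diagnostics(sim$alignment, exem)
  ids <- c(exem$dennis_ray, exem$postman)
  cls <- classify_haplotypes(sim$alignment, diag, ids = ids)
  # fabricate a carrier whose present-class segment stops inside the
  # fixed-site extent (a breakpoint where none is possible)
  fake <- cls[[exem$dennis_ray[1]]]
  fake$segments <- data.frame(
    start = c(0, 3000), end = c(3000, 10000),
    class = c("dennis_ray", "postman"),
    votes_for = c(10L, 10L), votes_against = c(0L, 0L))
  fake$breakpoints <- data.frame(left_col = 2990L, right_col = 3010L,
                                 midpoint = 3000L,
                                 from_class = "dennis_ray",
                                 to_class = "postman")
  cls[[exem$dennis_ray[1]]] <- fake
  fixed <- list(
    dennis = fixed_differences(sim$alignment, exem$dennis_ray, exem$postman))
  fixed$dennis <- fixed$dennis[fixed$dennis >= 2000 & fixed$dennis < 3500]
  ph_use <- phenotype_table(ph[ph$sample %in% hap_samples_test(ids), ])
  calls <- call_breakpoints(cls, ph_use, fixed,
                            present_class = list(dennis = "dennis_ray"),
                            region = c(0L, 10000L))
  expect_null(calls$dennis$interval)
  expect_gt(length(calls$dennis$conflicts), 0)
})
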