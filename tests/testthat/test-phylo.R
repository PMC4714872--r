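# p-distances, NJ trees, clade assignment, group divergence and the
# calibrated strict clock.

test_that("p-distance handles identity, simple counts and missing data", {
  ch <- rbind(a_01_h1 = strsplit(strrep("ACGT", 25), "")[[1]],
              a_01_h2 = strsplit(strrep("ACGT", 25), "")[[1]])
  aln <- phased_alignment(ch, ids = rownames(ch))
  expect_equal(p_distance(aln, c("a_01_h1", "a_01_h2"))$distance, 0)

  ch2 <- ch
  ch2[2, c(3, 50, 97)] <- c("T", "A", "C")
  aln2 <- phased_alignment(ch2, ids = rownames(ch2))
  pd <- p_distance(aln2, c("a_01_h1", "a_01_h2"))
  expect_equal(pd$distance, 0.03)
  expect_equal(unname(pd$compared), 100)

  ch3 <- ch2
  ch3[1, 1:10] <- "-"; ch3[2, 8:12] <- "N"
  aln3 <- phased_alignment(ch3, ids = rownames(ch3))
  expect_equal(unname(p_distance(aln3, rownames(ch3))$compared), 88)
  # no comparable columns -> undefined-distance signal
  ch4 <- rbind(b_01_h1 = c("A", "C"), b_01_h2 = c("-", "N"))
  expect_true(is.nan(p_distance(phased_alignment(ch4, ids = rownames(ch4)),
                                rownames(ch4))$distance))
})

test_that("p-distances equal brute force and the ape oracle", {
  aln <- random_alignment(12, 400, p_gap = 0.07, seed = 13)
  pd <- p_distance_matrix(aln)
  # brute force, column by column, on many random pairs
  set.seed(14)
  for (k in 1:500) {
    ij <- sample(12, 2)
    x <- ALN_LEVELS_TEST[aln$seq[ij[1], ]]
    y <- ALN_LEVELS_TEST[aln$seq[ij[2], ]]
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    expect_equal(pd$d[ij[1], ij[2]], sum(x[ok] != y[ok]) / sum(ok))
    expect_equal(unname(pd$n[ij[1], ij[2]]), sum(ok))
  }
  # independent implementation: ape's raw pairwise-deletion distance
  ch <- matrix(tolower(ALN_LEVELS_TEST[aln$seq]), nrow = nrow(aln$seq),
               dimnames = list(aln$ids, NULL))
  dd <- ape::dist.dna(ape::as.DNAbin(ch), model = "raw",
                      pairwise.deletion = TRUE)
  expect_equal(unname(pd$d[lower.tri(pd$d)]), unname(as.vector(dd)),
               tolerance = 1e-12)
})

test_that("group divergence matches hand-computed means", {
  ch <- rbind(
    g1_01_h1 = rep("A", 100),
    g1_01_h2 = c(rep("A", 98), "C", "C"),          # d = 0.02 to g1_01_h1
    g2_01_h1 = c(rep("G", 10), rep("A", 90)),
    g2_01_h2 = c(rep("G", 12), rep("A", 88)))
  aln <- phased_alignment(ch, ids = rownames(ch))
  groups <- list(g1 = rownames(ch)[1:2], g2 = rownames(ch)[3:4])
  gd <- group_divergence(aln, groups)
  expect_equal(gd["g1", "g1"], 2)
  expect_equal(gd["g2", "g2"], 2)
  # cross pairs: 10, 12, 8(?), hand-enumerated below
  cross <- c(sum(ch[1, ] != ch[3, ]), sum(ch[1, ] != ch[4, ]),
             sum(ch[2, ] != ch[3, ]), sum(ch[2, ] != ch[4, ]))
  expect_equal(gd["g1", "g2"], mean(cross))
  # identical groups give zeros
  gd0 <- group_divergence(aln, list(a = rownames(ch)[1], b = rownames(ch)[1:2]))
  expect_true(is.na(gd0["a", "a"]))                # singleton diagonal
  # order invariance
  gd_rev <- group_divergence(aln, list(g2 = rev(groups$g2), g1 = rev(groups$g1)))
  expect_equal(gd_rev["g1", "g2"], gd["g1", "g2"])
})

test_that("neighbor-joining recovers 3-leaf lengths and additive trees", {
  d <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d["x", "y"] <- d["y", "x"] <- 0.10
  d["x", "z"] <- d["z", "x"] <- 0.16
  d["y", "z"] <- d["z", "y"] <- 0.18
  tr <- nj_tree(d)
  # closed form: edge to x = (dxy + dxz - dyz) / 2, etc.
  el <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(el["x"]), (0.10 + 0.16 - 0.18) / 2)
  expect_equal(unname(el["y"]), (0.10 + 0.18 - 0.16) / 2)
  expect_equal(unname(el["z"]), (0.16 + 0.18 - 0.10) / 2)

  set.seed(31)
  for (i in 1:5) {
    true <- ape::rtree(6)
    true$edge.length <- true$edge.length + 0.05
    dd <- cophenetic(true)
    rec <- nj_tree(dd[true$tip.label, true$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("nj on ultrametric coalescent ages reproduces the genealogy", {
  sim <- get_tiny_sim(1)
  tr_true <- sim$genealogies$trees[[1]]
  d <- 2 * pairwise_coal_ages(tr_true)
  rec <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr_true), ape::unroot(rec)), 0,
               ignore_attr = TRUE)
})

test_that("undefined distances abort tree building with the pairs named", {
  d <- matrix(0.1, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(d) <- 0
  d["x", "y"] <- d["y", "x"] <- NaN
  expect_error(nj_tree(d), "x/y")
})

test_that("clade assignment follows the smallest enclosing reference clade", {
  tr <- ape::read.tree(text = "(((f1:1,(d1:1,d2:1):1):1,(r1:1,r2:1):1):1,og:1);")
  got <- clade_assignment(tr, "f1", refs = list(donor = c("d1", "d2"),
                                                recipient = c("r1", "r2")),
                          outgroup = "og")
  expect_identical(unname(got), "donor")
  # focal sister to the whole ingroup is unresolved
  tr2 <- ape::read.tree(text = "((f1:1,((d1:1,d2:1):1,(r1:1,r2:1):1):1):1,og:1);")
  got2 <- clade_assignment(tr2, "f1", refs = list(donor = c("d1", "d2"),
                                                  recipient = c("r1", "r2")),
                           outgroup = "og")
  expect_identical(unname(got2), "unresolved")
  expect_error(clade_assignment(tr, "f1", list(donor = "d1"), "missing_tip"),
               "outgroup")
})

test_that("clock calibration follows the arithmetic and scaling laws", {
  # two clades, 10,000 comparable columns, cross-divergence 0.0792
  L <- 10000
  ch <- matrix("A", 4, L)
  rownames(ch) <- c("a_01_h1", "a_01_h2", "b_01_h1", "b_01_h2")
  ch[3:4, seq_len(792)] <- "G"
  aln <- phased_alignment(ch, ids = rownames(ch))
  cl <- calibrate_clock(aln, c("a_01_h1", "a_01_h2"), c("b_01_h1", "b_01_h2"),
                        t_cal = 3.96, B = 50, seed = 3, correction = "none")
  expect_equal(cl$rate, 0.0792 / (2 * 3.96))
  expect_equal(cl$rate, 0.01)
  cl2 <- calibrate_clock(aln, c("a_01_h1", "a_01_h2"), c("b_01_h1", "b_01_h2"),
                         t_cal = 2 * 3.96, B = 50, seed = 3, correction = "none")
  expect_equal(cl2$rate, cl$rate / 2)
  expect_true(cl$interval[1] <= cl$rate && cl$rate <= cl$interval[2])
  # the default applies the Jukes-Cantor multiple-hit correction
  cl_jc <- calibrate_clock(aln, c("a_01_h1", "a_01_h2"), c("b_01_h1", "b_01_h2"),
                           t_cal = 3.96, B = 50, seed = 3)
  expect_equal(cl_jc$rate, -0.75 * log(1 - 4 * 0.0792 / 3) / (2 * 3.96))
  # zero divergence cannot calibrate
  ch0 <- matrix("A", 4, 100, dimnames = list(rownames(ch), NULL))
  expect_error(calibrate_clock(phased_alignment(ch0, ids = rownames(ch0)),
                               c("a_01_h1", "a_01_h2"),
                               c("b_01_h1", "b_01_h2"), 3.96),
               "zero cross-clade")
})

test_that("dating is self-consistent, handles zero divergence, and is scale-free", {
  build <- function(n_cal, n_target) {
    ch <- matrix("A", 8, 10000)
    rownames(ch) <- c("a_01_h1", "a_01_h2", "b_01_h1", "b_01_h2",
                      "c_01_h1", "c_01_h2", "d_01_h1", "d_01_h2")
    ch[3:4, seq_len(n_cal)] <- "G"            # a-b cross divergence
    ch[7:8, 2000 + seq_len(n_target)] <- "G"  # c-d cross divergence
    phased_alignment(ch, ids = rownames(ch))
  }
  A <- c("a_01_h1", "a_01_h2"); B <- c("b_01_h1", "b_01_h2")
  C <- c("c_01_h1", "c_01_h2"); D <- c("d_01_h1", "d_01_h2")
  aln <- build(792, 300)
  clock <- calibrate_clock(aln, A, B, t_cal = 3.96, B = 40, seed = 5)
  # calibration clades date to exactly t_cal (any correction)
  self <- date_divergence(aln, A, B, clock, seed = 6)
  expect_equal(self$age, 3.96, tolerance = 1e-12)
  # zero cross-clade distance dates to zero (A and C are identical here)
  expect_equal(date_divergence(aln, A, C, clock, seed = 6)$age, 0)
  # scale-free on raw distances: doubling every divergence leaves ages fixed
  clock <- calibrate_clock(aln, A, B, t_cal = 3.96, B = 40, seed = 5,
                           correction = "none")
  aln2 <- build(2 * 792, 2 * 300)
  clock2 <- calibrate_clock(aln2, A, B, t_cal = 3.96, B = 40, seed = 5,
                            correction = "none")
  expect_equal(clock2$rate, 2 * clock$rate)
  t1 <- date_divergence(aln, C, D, clock, seed = 7)
  t2 <- date_divergence(aln2, C, D, clock2, seed = 7)
  expect_equal(t2$divergence / t1$divergence, 2, tolerance = 1e-12)
  expect_equal(t1$age, t2$age, tolerance = 1e-12)
})
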