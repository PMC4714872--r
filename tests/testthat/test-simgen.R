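# Structured-coalescent generator: configuration validation, coalescent
# behaviour, mutation model, truth bookkeeping and determinism.

test_that("configuration validation names the offending entry", {
  cfg <- tiny_sim_config(1)
  bad <- cfg
  bad$modules$ray <- c(3000L, 7500L)   # overlaps dennis [2000, 3500)
  expect_error(validate_sim_config(bad), "overlap")

  bad <- cfg
  bad$recombinant_specs[[1]]$breakpoint <- 2500L  # inside dennis module
  expect_error(validate_sim_config(bad), "inside module dennis")

  bad <- cfg
  bad$introgression_events[[1]]$fraction <- 1.5
  expect_error(validate_sim_config(bad), "fraction")

  bad <- cfg
  bad$introgression_events[[1]]$time <- 5  # older than 3.96 split
  expect_error(validate_sim_config(bad), "not younger")

  bad <- cfg
  bad$introgression_events[[1]]$donor <- "nosuchpop"
  expect_error(validate_sim_config(bad), "nosuchpop")

  bad <- cfg
  bad$splits <- cfg$splits[-2, ]  # melpo_dr never reaches the root
  expect_error(validate_sim_config(bad), "root")
})

test_that("coalescence collapses towards zero in the small-Ne limit", {
  pops <- pop_row("p", 2, Ne = 1)   # pairwise scale 2*1*2.5e-7 Ma
  cfg <- bare_config(pops, seed = 5)
  gen <- simulate_genealogies(cfg)
  ages <- attr(gen$trees[[1]], "node_ages")
  expect_lt(max(ages), 1e-4)
})

test_that("cross-population coalescence never predates the split", {
  pops <- rbind(pop_row("a", 4), pop_row("b", 4))
  splits <- data.frame(pop = "a", into = "b", time = 3.96)
  cfg <- bare_config(pops, splits, seed = 3)
  for (s in 1:5) {
    cfg$seed <- s
    gen <- simulate_genealogies(cfg)
    ca <- pairwise_coal_ages(gen$trees[[1]])
    cross <- ca[haps_for(c("a_01", "a_02")), haps_for(c("b_01", "b_02"))]
    expect_true(all(cross >= 3.96))
  }
})

test_that("pairwise coalescence time matches the Kingman expectation", {
  # E[T2] = 2 Ne g = 0.5 Ma for Ne = 1e6, g = 2.5e-7
  pops <- pop_row("p", 2, Ne = 1e6)
  cfg <- bare_config(pops, region = 10L)
  ages <- vapply(1:10000, function(s) {
    cfg$seed <- s
    max(attr(simulate_genealogies(cfg)$trees[[1]], "node_ages"))
  }, numeric(1))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 0.5), 3 * se)
})

test_that("pairwise differences follow the Jukes-Cantor expectation", {
  pops <- pop_row("p", 2, Ne = 1e6)
  L <- 1000L
  cfg <- bare_config(pops, region = L, mutation_rate = 0.005, seed = 42)
  gen <- simulate_genealogies(cfg)
  t_path <- 2 * max(attr(gen$trees[[1]], "node_ages"))
  # exact JC expectation for the fraction of differing sites on a path t
  p_exp <- 0.75 * (1 - exp(-4 / 3 * cfg$mutation_rate * t_path))
  diffs <- vapply(1:1000, function(s) {
    cfg2 <- cfg; cfg2$seed <- s
    a <- mutate_and_emit(gen, cfg2)$alignment$seq
    sum(a[1, ] != a[2, ])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - L * p_exp), 3.2 * se)
})

test_that("zero mutation rate leaves haplotypes identical up to indels", {
  cfg <- tiny_sim_config(2)
  cfg$mutation_rate <- 0
  sim <- mutate_and_emit(simulate_genealogies(cfg), cfg)
  s <- sim$alignment$seq
  base_cols <- colSums(s == 5L) == 0   # columns without any gap
  for (i in 2:nrow(s)) expect_identical(s[i, base_cols], s[1, base_cols])
  expect_gt(sum(s == 5L), 0)           # indel architecture still present
})

test_that("expected pairwise differences increase with mutation rate", {
  res <- sapply(1:4, function(s) {
    lo <- tiny_sim_config(s); lo$mutation_rate <- 0.005
    hi <- tiny_sim_config(s); hi$mutation_rate <- 0.02
    gen <- simulate_genealogies(lo)  # identical genealogies for both rates
    n_lo <- sum(mutate_and_emit(gen, lo)$alignment$seq[1, ] !=
                  mutate_and_emit(gen, lo)$alignment$seq[3, ])
    n_hi <- sum(mutate_and_emit(gen, hi)$alignment$seq[1, ] !=
                  mutate_and_emit(gen, hi)$alignment$seq[3, ])
    c(lo = n_lo, hi = n_hi)
  })
  expect_true(all(res["hi", ] > res["lo", ]))
})

test_that("introgressed lineages coalesce across species more recently than the split", {
  sim <- get_tiny_sim(1)
  gen <- sim$genealogies
  blocks <- gen$blocks
  dennis_block <- which(blocks$module == "dennis")[1]
  flank_block <- which(is.na(blocks$module))[1]
  ca_d <- pairwise_coal_ages(gen$trees[[dennis_block]])
  ca_f <- pairwise_coal_ages(gen$trees[[flank_block]])
  mel <- haps_for(c("melpo_dr_01", "melpo_dr_02"))
  elev <- haps_for("elevatus_01")
  pm <- haps_for(c("melpo_pm_01", "melpo_pm_02"))
  # introgressed module: donor/recipient carrier alleles coalesce after the
  # 1.95 Ma event but before the 3.96 Ma species split
  expect_true(all(ca_d[mel, elev] >= 1.95))
  expect_true(any(ca_d[mel, elev] < 3.96))
  # non-carriers and flank lineages respect the species split
  expect_true(all(ca_d[pm, elev] >= 3.96))
  expect_true(all(ca_f[c(mel, pm), elev] >= 3.96))
})

test_that("truth classes are complete and round-trip to phenotypes", {
  sim <- get_tiny_sim(1)
  cls <- sim$truth$classes
  expect_false(anyNA(cls))                       # one class per module
  expect_identical(sim$truth$modules, sim$config$modules)
  ph <- sim$pheno
  for (s in ph$sample) {
    haps <- paste0(s, c("_h1", "_h2"))
    expect_identical(ph$dennis[ph$sample == s],
                     if (any(cls[haps, "dennis"] == "dennis")) "present" else "absent")
    expect_identical(ph$ray[ph$sample == s],
                     if (any(cls[haps, "ray"] == "ray")) "present" else "absent")
  }
  # homozygous recipient-class individual expresses neither module
  expect_identical(ph$dennis[ph$sample == "melpo_pm_01"], "absent")
  # the recombinant race carries dennis only
  expect_identical(ph$group[ph$sample == "meriana_01"], "dennis_only")
})

test_that("recombinant haplotypes match the class consensus on each side", {
  sim <- get_tiny_sim(1)
  aln <- sim$alignment
  diag <- learn_diagnostics(aln, list(
    carrier = haps_for(c("melpo_dr_01", "melpo_dr_02", "melpo_dr_03")),
    noncarrier = haps_for(c("melpo_pm_01", "melpo_pm_02", "melpo_pm_03"))))
  bp <- 4000
  rec <- aln$seq["meriana_01_h1", diag$columns]
  left <- diag$coords < bp
  # private mutations on the recombinant's own branches may touch a few
  # diagnostic columns; concordance must nonetheless be near-perfect
  expect_gt(mean(rec[left] == diag$states["carrier", ][left]), 0.9)
  expect_gt(mean(rec[!left] == diag$states["noncarrier", ][!left]), 0.9)
  expect_lt(mean(rec[left] == diag$states["noncarrier", ][left]), 0.5)

  # with mutation off, the only diagnostics are the indel architecture and
  # the match is exact by construction
  cfg0 <- tiny_sim_config(3)
  cfg0$mutation_rate <- 0
  sim0 <- mutate_and_emit(simulate_genealogies(cfg0), cfg0)
  diag0 <- learn_diagnostics(sim0$alignment, list(
    carrier = haps_for(c("melpo_dr_01", "melpo_dr_02", "melpo_dr_03")),
    noncarrier = haps_for(c("melpo_pm_01", "melpo_pm_02", "melpo_pm_03"))))
  rec0 <- sim0$alignment$seq["meriana_01_h1", diag0$columns]
  left0 <- diag0$coords < bp
  expect_identical(rec0[left0], unname(diag0$states["carrier", left0]))
  expect_identical(rec0[!left0], unname(diag0$states["noncarrier", !left0]))
})

test_that("generator output is byte-identical under a fixed seed", {
  a <- simulate_dataset(tiny_sim_config(9))
  b <- simulate_dataset(tiny_sim_config(9))
  expect_identical(a$alignment$seq, b$alignment$seq)
  expect_identical(a$geno, b$geno)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim_dataset(a, d1); write_sim_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  c3 <- simulate_dataset(tiny_sim_config(10))
  expect_false(identical(a$alignment$seq, c3$alignment$seq))
})

test_that("unpaired haplotypes trigger a pairing error", {
  sim <- get_tiny_sim(1)
  aln <- sim$alignment
  odd <- phased_alignment(aln$seq[1:3, , drop = FALSE], ids = aln$ids[1:3])
  expect_error(emit_genotypes(odd, sim$config, sim$truth), "pairing")
})

test_that("a clean coverage model passes QC untouched", {
  cfg <- tiny_sim_config(4)
  cfg$coverage_model$low_call_frac <- 0
  cfg$coverage_model$low_site_frac <- 0
  sim <- simulate_dataset(cfg)
  masked <- qc_report(apply_qc(sim$geno))$total_masked
  expect_identical(masked, 0L)
})
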