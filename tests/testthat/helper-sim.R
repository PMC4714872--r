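# Shared fixtures built in code.  Simulated datasets are memoised per seed
# so several test files can reuse them without recomputation.

.sim_cache <- new.env(parent = emptyenv())

get_tiny_sim <- function(seed = 1L) {
  key <- paste0("tiny", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(tiny_sim_config(seed))
  .sim_cache[[key]]
}

get_default_sim <- function(seed = 1L) {
  key <- paste0("default", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(default_sim_config(seed))
  .sim_cache[[key]]
}

# A minimal single-region configuration for coalescent unit tests: one or
# two populations, one module spanning the whole region, no events.
bare_config <- function(pops, splits = NULL, region = 1000L,
                        mutation_rate = 0, seed = 1L,
                        generation_scale = 2.5e-7) {
  if (is.null(splits))
    splits <- data.frame(pop = character(), into = character(),
                         time = numeric())
  sim_config(region_length = region,
             modules = list(m1 = c(0L, region)),
             populations = pops, splits = splits,
             mutation_rate = mutation_rate,
             generation_scale = generation_scale,
             recipient_clade = pops$clade[1], seed = seed)
}

pop_row <- function(name, n_hap, Ne = 1e6, clade = "a", species = name) {
  data.frame(name = name, species = species, clade = clade, Ne = Ne,
             n_hap = n_hap, stringsAsFactors = FALSE)
}

# Haplotype ids for a set of samples.
haps_for <- function(samples) as.vector(t(outer(samples, c("_h1", "_h2"), paste0)))

# Build a small genotype_matrix from a matrix of genotype strings like
# "A/G" ("." = missing), with uniform good-quality annotations by default.
toy_geno <- function(gt, pos = seq_len(nrow(gt)) * 10L, dp = 30, gq = 80,
                     mq = 50) {
  ns <- nrow(gt); nsam <- ncol(gt)
  a1 <- matrix(NA_character_, ns, nsam)
  a2 <- matrix(NA_character_, ns, nsam)
  ok <- gt != "."
  a1[ok] <- substr(gt[ok], 1, 1)
  a2[ok] <- substr(gt[ok], 3, 3)
  samples <- colnames(gt) %||% sprintf("s%02d", seq_len(nsam))
  genotype_matrix(pos = pos, a1 = a1, a2 = a2,
                  dp = matrix(dp, ns, nsam), gq = matrix(gq, ns, nsam),
                  mq = rep(mq, length.out = ns), samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Alignment integer codes used by phased_alignment.
ALN_LEVELS_TEST <- c("A", "C", "G", "T", "-", "N")

# Random gapped toy alignment (character level) for scan oracles.
random_alignment <- function(n_hap, L, p_gap = 0, seed = 1) {
  set.seed(seed)
  ch <- matrix(sample(c("A", "C", "G", "T"), n_hap * L, replace = TRUE),
               nrow = n_hap)
  if (p_gap > 0) ch[matrix(runif(n_hap * L) < p_gap, n_hap)] <- "-"
  rownames(ch) <- sprintf("s%02d_h%d", rep(seq_len(ceiling(n_hap / 2)), each = 2),
                          rep(1:2, length.out = n_hap))
  phased_alignment(ch, ids = rownames(ch))
}

# Sample id of a haplotype id.
hap_samples_test <- function(ids) sub("_h[12]$", "", ids)
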