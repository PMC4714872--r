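# redmodules

Mapping and dating of red wing-pattern cis-regulatory modules from
population genomic data.

## The problem

Red wing-pattern elements in *Heliconius* butterflies — the forewing
"dennis" patch and the hindwing "ray" streaks — are controlled by discrete
cis-regulatory modules in the non-coding region downstream of the
transcription factor *optix*. These modules have moved between species by
adaptive introgression and have been shuffled within species by
recombination, so different module combinations produce different mimicry
phenotypes. Localising each module, assigning its alleles to a clade of
origin, and dating its movement between lineages together reconstruct how a
novel phenotype was assembled.

`redmodules` implements that inference chain for phenotype-labelled
multi-sample data (a VCF of diploid genotype calls, a phased gapped
haplotype alignment, and a sample sheet), plus a structured-coalescent
generator that produces all three inputs under a known module-shuffling
scenario with full ground truth, so every stage is testable without any
external data.

## The methods

* **Genotype QC** — calls with mapping quality < 30, genotype quality < 30,
  or read depth outside [4, 300] are scored missing.
* **Association scan** — per informative site, alleles (two per diploid)
  are tabulated against the binary phenotype and tested with the 1-df
  Pearson chi-squared statistic X² = Σ(O−E)²/E (no continuity correction);
  genome-wide control is Bonferroni, threshold −log₁₀(α/m) for m tested
  sites (α = 0.05).
* **Fixed-difference scan** — sites at which two phenotype groups are fixed
  for different states, summarised in 5 kb windows sliding at 1 kb, with
  the minimal region spanned by the fixed sites.
* **Haplotype painting** — allele classes learned as diagnostic columns
  (each class internally fixed, classes differing; indel architecture
  included), haplotypes segmented by runs of concordant votes, class
  switches called as recombination breakpoints with bracketing-column
  uncertainty; breakpoints refine module boundaries (ends without
  recombinant evidence fall back to the outermost associated site).
* **Phylogenetics** — pairwise p-distances with pairwise deletion,
  neighbor-joining trees, outgroup-rooted clade assignment of focal
  alleles, and Table-style group divergence matrices (mean pairwise %).
* **Clock dating** — a strict clock calibrated at a node of known age
  T_cal: r = D_cal/(2 T_cal) from the Jukes–Cantor-corrected cross-clade
  divergence; a clade pair then dates to T = D/(2r), with site-bootstrap
  intervals (labelled bootstrap, not credible intervals).

## Worked example

```r
library(redmodules)
res <- run_pipeline(run_config(seed = 1), out_dir = "run1")
cat(readLines("run1/report.txt"), sep = "\n")
```

```
redmodules 0.1.0 run (seed 1, config 09c60da4)

QC: 27351 calls masked (mq 5488, dp_low 7237, dp_high 7329, gq 7297)

association dennis: 4557 sites tested, threshold -log10 p = 4.96, 506 flagged
association ray   : 4557 sites tested, threshold -log10 p = 4.96, 1123 flagged

module dennis: 30,019-38,854 (1-based, 8.8 kb)
  start: outermost phenotype-associated fixed site (rapid-loss fallback)
  end:   recombination breakpoint in meriana_01_h1 (bracket 36887-40822)
module ray   : 38,520-76,980 (1-based, 38.5 kb)
  start: recombination breakpoint in contigua_01_h1 (bracket 36973-40065)
  end:   outermost phenotype-associated fixed site (rapid-loss fallback)
fixed-site sets disjoint: TRUE; minimal regions disjoint: TRUE

clade assignment (dennis alleles): donor=36
clade assignment (ray alleles): recipient=48

event A_dennis_donor_to_recipient: 2.00 Ma (bootstrap 1.78-2.30)
event B_ray_origin_within_recipient: 1.44 Ma (bootstrap 1.36-1.54)
event D_ray_into_donor_species: 0.96 Ma (bootstrap 0.88-1.05)
```

Reading the report: the default scenario plants a 7 kb module at 30–37 kb
and a 37 kb module at 40–77 kb of a 100 kb region. The fixed-difference
scans confine each module's associated sites to its true interval (minimal
regions 6.96 kb and 36.9 kb) and the two site sets are disjoint; the
recombinant dennis-only and ray-only races bound the inner module edges at
their breakpoints, the outer edges fall back to the outermost associated
site. All 36 dennis alleles of the recipient clade join the donor
(silvaniform) clade and all 48 ray alleles join the recipient clade, and
the dated events recover the simulated history (dennis introgression at
1.95 Ma dated 2.00 Ma; dated divergences exceed their event times by the
within-class coalescent offset, and calibrating at the species-split
parameter deflates ages by the ancestral coalescent offset — both discussed
in the methods vignette).

Per-stage functions (`simulate_dataset()`, `read_inputs()`, `apply_qc()`,
`assoc_scan()`, `fixed_differences()`, `learn_diagnostics()`,
`classify_haplotypes()`, `call_breakpoints()`, `p_distance_matrix()`,
`nj_tree()`, `clade_assignment()`, `calibrate_clock()`,
`date_divergence()`) expose every step individually; see their help pages.

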