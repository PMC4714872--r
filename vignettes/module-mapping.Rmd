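---
title: "Localising and dating cis-regulatory modules with redmodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localising and dating cis-regulatory modules with redmodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`redmodules` reconstructs the history of two adjacent cis-regulatory
modules that control discrete red wing-pattern elements ("dennis" and
"ray") in the *Heliconius melpomene* species group: where each module lies
on the scaffold, which allele class each haplotype carries, which clade
each allele class descends from, and when the modules moved between
lineages. This vignette describes the models behind each stage, the
simulation scenario used to validate them, the tunable parameters, and the
limits of what the validation shows.

## The inference chain

### Genotype quality control

Diploid calls are masked to missing when the site's mapping quality is
below 30, the call's genotype quality is below 30, or its read depth falls
outside [4, 300] — the thresholds used for the original resequencing
panel. Masking is idempotent and the report counts each call once, with
precedence mapping quality > low depth > high depth > genotype quality, so
counts are additive when criteria are applied in stages. An *informative*
site (the unit of the association scan and of the Bonferroni correction) is
polymorphic among non-missing calls with a call rate of at least 50%; the
source analysis did not define the term, so both the definition and the
call-rate floor are configurable.

### Association scan

At each informative site the two alleles of every phenotyped diploid are
tabulated against the binary phenotype and tested with the 1-df Pearson
chi-squared statistic without continuity correction. This is the fast
allelic case-control contrast; it treats the 2n alleles as independent,
which is the same approximation the original scan made, and like that scan
it applies no correction for population structure (a deliberate
reproduction: with several species in the panel, background association is
expected and visible genome-wide). The implemented statistic is the Pearson
form; a score-test variant would differ by a factor n/(n−1), immaterial at
these sample sizes, and a genotypic Cochran–Armitage trend variant is
available behind `method = "trend"`. Significance is Bonferroni-controlled
at `-log10(alpha / m)` with m the number of sites actually tested and
alpha = 0.05 — the back-derivation of the published genome-wide threshold.

### Fixed differences and minimal regions

A site is a fixed difference between two sample groups when all non-missing
alleles are one state in the first group and a different single state in
the second. In genotype mode both alleles of a diploid must agree (one
heterozygote breaks fixation); in alignment mode each haplotype contributes
one state and columns containing gaps in either group are skipped, since
indel variation is handled by the painting stage. Sites with fewer than
`min_calls = 2` callable members in either group are skipped rather than
counted — the source method is silent on missing data, and skipping is the
conservative choice. Counts are summarised in 5 kb windows sliding at 1 kb,
and the minimal region is the smallest half-open interval spanning all
fixed sites of a comparison. The contrast groups are phenotype-based within
the recipient clade (module-present vs module-absent), which makes the
recombinant single-module races the discriminating samples: each appears on
a different side of the two contrasts, so the two modules' fixed-site sets
separate.

### Haplotype painting and breakpoint refinement

Whole-region allele forms (an outgroup form, a carrier form and a
non-carrier form) are learned from exemplar haplotypes as *diagnostic
columns*: columns at which every class is internally fixed and at least two
classes differ. Gap states participate, so the fixed indel architecture of
each class is diagnostic; gap runs of at least `min_indel_len = 30` bp with
a constant gap-presence pattern are additionally reported as indel
features (base-level polymorphism within a class does not interrupt a gap
feature). A haplotype is painted by voting: each diagnostic column matching
exactly one class votes for it; maximal runs of at least `min_run = 3`
concordant votes anchor segments (resisting recurrent mutation), shorter
discordant runs are absorbed and logged, and a switch between anchored
classes is a breakpoint, reported as the midpoint between the bracketing
concordant columns with the bracket as its uncertainty.

Module boundaries are then refined by dominance logic: every
phenotype-positive individual must carry the functional allele class across
the module's fixed-site extent on at least one haplotype, so the module
lies within the intersection of the carrier haplotypes' pure class
segments. A boundary supported by a recombinant is placed at its breakpoint
midpoint (clamped so the interval always contains the fixed-site extent);
a boundary with no recombinant evidence falls back to the outermost
phenotype-associated fixed site — our operationalisation of delineation by
"rapid loss" of associated variants, flagged as such in the output, since
no numeric criterion exists for it. Only recipient-clade haplotypes
contribute boundary evidence: carriers in other species hold introgressed
copies that accumulate their own mutations after transfer and therefore
violate strict class concordance without being recombinant. Segments whose
switch would fall strictly inside the fixed-site extent are contradictory
and are reported as conflicts with no interval returned; heterozygous
individuals contribute through their scorable carrier haplotype only, and
samples whose haplotypes cannot be scored across a module are
uninformative for it.

### Distances, trees and clade assignment

Pairwise p-distances use pairwise deletion (both states must be bases;
complete deletion is available by flag), matching the default of the
distance software used for the published divergence tables; whether those
tables excluded gapped columns globally is not recoverable, so the deletion
mode is recorded in the output metadata. Group divergence tables are mean
pairwise percent, within groups on the diagonal. Trees are neighbor-joining
on these distances — a deliberate, declared substitution for
maximum-likelihood search, chosen for determinism at desk scale; claims are
therefore topology-level only. Negative NJ branch lengths are clamped to
zero and counted. A focal allele is assigned to the reference clade
represented in its smallest enclosing ancestral clade containing any
reference leaves on the outgroup-rooted tree, or `unresolved` when both
references are represented there. For the module whose functional allele is
native to the donor species, that species' alleles anchor the donor
reference; for the recipient-origin module they are introgressed copies and
are treated as focal.

### Calibrated strict clock

The divergence rate per lineage pair is r = D_cal / (2 T_cal), where T_cal
is the age of a calibration node (default 3.96 Ma, the donor/recipient
clade split) and D_cal the cross-clade divergence over flanking sequence
unaffected by introgression. A clade pair of interest then dates to
T = D / (2 r). Divergences are pooled site-count estimators — the summed
differing pair-site comparisons over summed valid comparisons — which makes
dating the calibration clades return T_cal *exactly* and lets the site
bootstrap (B = 100 column resamples, seeded) reuse per-column counts.
Proportions are Jukes–Cantor corrected before the clock arithmetic
(`correction = "JC"`, with `"none"` available): at ~4% divergence the raw
proportion under-estimates the substitution load by ~3%, more than the
width of the bootstrap interval. Intervals are bootstrap percentile
intervals and are labelled as such — they quantify site-sampling
(mutational) noise conditional on the genealogy, not genealogical
uncertainty, and are therefore narrower than a full Bayesian credible
interval would be.

Two systematic offsets matter when reading dated events, and both are
visible in the simulation study. First, a dated divergence is an allele
*coalescence*, which exceeds the underlying transfer event by the waiting
time to common ancestry within the donor class. Second, if T_cal is
interpreted as the *population split* time while the calibration distance
is an allele divergence, r is inflated by the ancestral coalescent offset
and all subsequent dates deflate by the same factor (~10-15% under the
default scenario). The estimator-recovery tests therefore calibrate with
the realized calibration-node divergence from the generator's ground
truth; the pipeline report calibrates at the conventional 3.96 Ma, which is
what an empirical analysis would do.

## The synthetic scenario

The generator is the package's ground-truth instrument: a block-wise
structured coalescent over a 100 kb region carrying a 7 kb module at
[30000, 37000) and a 37 kb module at [40000, 77000), with recombination
*only* at module boundaries and declared breakpoints — mirroring the
treatment of the region as a few discrete haplotype blocks. The default
scenario samples 112 haplotypes: an outgroup (8), a donor silvaniform clade
(20) containing the donor species (12), and a recipient clade with 16
dennis-ray individuals, 16 postman individuals, and two recombinant races
of 2 individuals each — a dennis-only race (all four haplotypes sharing one
fixed recombination at 38.2 kb) and a ray-only race (one recombination at
38.8 kb).

Demography, all times in Ma: recipient and donor clades split at 3.96 (the
calibration node), the donor species splits within its clade at 3.0, the
outgroup roots at 8.0. Morph pools within the recipient species merge at
0.01 — morphs are near-panmictic outside the pattern loci, and an older
split would let whole flank blocks drift to spurious reciprocal monophyly.
A ghost bottlenecked stem population (Ne 8e5) carries the recipient lineage
from 1.0 back to the deep split. Effective sizes are Ne = 1.6-2.0 million
for extant panmictic pools and 4e5 for the narrow-range donor species, with
four generations per year (`generation_scale = 2.5e-7` Ma), giving pairwise
coalescence scales 2·Ne·g of 0.2-1.0 Ma. The mutation rate is 0.005
substitutions/site/Ma under Jukes–Cantor — chosen, with the sizes above, to
reproduce the observed orders of within-clade (~1%) and cross-clade (~4%)
divergence. Jukes–Cantor rather than a richer model is deliberate: the
analysis statistics are model-free counts and JC keeps the generator
closed-form testable.

Introgression events are interval-restricted and realised as allele-class
demes: the carrier lineages of a module occupy a dedicated deme from the
present backwards; at the event time any remaining class lineages coalesce
into the founder haplotype (module alleles are single-origin — an
adaptively introgressed or novel regulatory allele descends from one
haplotype), and the founder transfers into the donor's deme for that
interval. This structure is what maintains carrier-vs-noncarrier fixed
differences: class lineages cannot coalesce across classes more recently
than the event. The default events are the dennis module from the donor
species into the recipient at 1.95, the ray allele originating within the
recipient at 1.85 (modelled as transfer from an unsampled ghost lineage
that merges back at 1.9), and the ray module into the donor species at
0.66. Phenotypes follow single-locus dominance (D/d, R/r): a module is
expressed iff at least one haplotype carries its functional class —
consistent with heterozygous recombinants expressing the pattern. Each
class also carries a configured architecture of diagnostic indels, emitted
as fixed gap runs.

Genotype emission pairs haplotypes into diploids and draws DP ~ Poisson(30),
GQ ~ round N(80, 8) clamped to [0, 99], and per-site MQ ~ N(50, 4), with 2%
of calls forced below a QC threshold and 0.5% of sites given failing MQ, so
the masking stage is exercised. Phasing is emitted as known; a config
switch scrambles phase within phenotype-homozygous individuals, mirroring
arbitrary phase assignment in the source data.

What the generator does *not* emulate: background (intra-block)
recombination, gene flow after the splits other than the declared events,
selection beyond its implicit role in the single-origin/fixation
assumptions, indel evolution beyond the fixed diagnostic architecture,
alignment error, and read-level artefacts beyond the parametric DP/GQ/MQ
model. Passing tests therefore show that the chain recovers truth under
clean, block-structured histories; they do not bound its behaviour under
pervasive recombination or alignment noise.

## Numerical and design choices

* Coordinates are 0-based half-open internally; VCF I/O converts to
  1-based at the boundary, BED output stays 0-based half-open, and human
  reports are 1-based inclusive.
* One master seed fans out to per-stage sub-streams by a stable hash, so
  any stage can be rerun in isolation; identical configuration and seed
  give byte-identical outputs, and reports carry version, seed and a
  configuration hash (no timestamps).
* Breakpoint point estimates are bracket midpoints with the full bracket
  reported; ties and degenerate inputs (monomorphic sites, zero-margin
  tables, empty fixed-site sets, all-ambiguous haplotypes) return explicit
  degenerate results (p = 1, no-region, unknown-only) rather than errors.
* Multi-allelic sites are reduced to their two most frequent alleles, ties
  broken alphabetically.
* The clock's pooled divergence weights every pair-site comparison
  equally (robust to uneven missingness and exactly self-consistent);
  group divergence tables instead use mean-of-pairs, matching how the
  published tables were computed. The two estimators agree when
  missingness is uniform.
* The donor-species effective size (4e5) is set small enough that a
  transferred founder lineage reliably coalesces into donor-clade
  diversity before the deep split; with a large donor Ne the founder
  occasionally drifts past the split, a genealogy in which the module's
  clade of origin is genuinely unrecoverable — the observed data show
  unambiguous donor-clade nesting, so the default scenario is built to be
  in that regime.

## Validation scale

The test suite validates each operation against independent oracles (brute
force enumeration for tables, fixed sites and windows; hand computation and
`chisq.test`/`dist.dna` cross-checks; closed-form Kingman and Jukes–Cantor
expectations for the generator) and the full chain against ground truth on
simulation: 20 default-scale replicates for module recovery and 50 shared
default-scale replicates for clade assignment, clock recovery and the
divergence-pattern property, with 10,000 two-lineage runs for the
coalescent mean and 1,000 mutation replicates for the Poisson/JC check.
These sizes keep the whole suite within a few minutes on one core while
giving the proportion-based properties binomial noise well below their
margins.

## Known limitations

Classification assumes the learned classes cover the haplotypes being
painted: a hybrid from an unmodelled lineage paints as `unknown`/ambiguous
rather than being flagged specially. Boundary refinement trusts phenotype
labels; a mislabelled sample surfaces as a conflict report. The clock
assumes rate constancy across the region and lineages, and its intervals
exclude genealogical noise (see above). NJ topology claims degrade below
roughly five diagnostic sites per kb — at the default mutation rate and
module sizes the signal is far above this, but short, young modules would
need likelihood methods.
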