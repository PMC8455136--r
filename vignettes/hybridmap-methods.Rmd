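---
title: "Methods: block genotyping and sex-specific map construction in a three-strain double cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block genotyping and sex-specific map construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridmap)
```

## The cross and what it measures

`hybridmap` analyses F2 progeny of a *double cross* between three
inbred nematode strains: CA (the reference strain), WA, and LR.  CA is
crossed to WA to obtain F1 hybrid males and to LR to obtain F1 hybrid
hermaphrodites; the two F1 types are then mated.  Each F2 hermaphrodite
therefore inherits one recombinant chromatid from a CA/WA spermatocyte
meiosis and one from a CA/LR oocyte meiosis.  The design phases itself:
WA alleles can only have arrived through sperm and LR alleles only
through ova, so the four possible block genotypes (CA/CA, CA/WA, CA/LR,
WA/LR) map bijectively onto (paternal, maternal) haplotype pairs, and
genotype transitions along a chromosome locate crossovers (COs) in the
male or hermaphrodite F1 parent.  Males are XO: the male F1 carries a
single X that cannot recombine, so there is no male map for the X.

The pipeline is: select strain-diagnostic sites from parental
genotypes, genotype each F2 in 100 kb blocks from allele-depth
fractions, filter blocks, phase, build per-parent Marey maps, and test
for segregation distortion.  A meiosis simulator generates complete
synthetic inputs so every stage is exercised end-to-end with known
ground truth.

## The simulator

**Parental panel.** Sites are placed per chromosome as a Poisson process
with density `sites_per_Mb` (default 8900/Mb, the density implied by a
~1.4 M-site panel over a 156.7 Mb genome; ~890 sites per 100 kb block).
Each site is biallelic, homozygous in all three strains, and diagnostic
for exactly one uniformly chosen strain.  Parental depths are Poisson
with strain means 86x (CA, LR) and 61x (WA).

**Meiosis.** A bivalent is modeled as four chromatids (two sisters per
homolog).  With the default obligate model each meiosis receives exactly
one CO (plus a second with probability `double_co_rate`, default 0.006,
the order of magnitude of the rare observed doubles); the non-obligate
mode draws a Poisson count.  CO positions follow a piecewise-uniform
density with weight `arm_weight` (default 3) on the distal thirds and 1
on the center, reflecting arm-enriched recombination; regions listed in
`suppressed_regions` get zero density (the obligate CO relocates to the
remaining mass, as expected if a CO-promoting signal acts from one
chromosome end).  Each CO involves one chromatid of each homolog,
chosen uniformly.  The transmitted chromatid is a molecule traced
through the bivalent: every CO it is involved in crosses it to the
other homolog, so its ancestry flips at each involvement.  This yields
the two laws the analysis relies on: with a single obligate CO, half of
transmitted chromatids are nonrecombinant, and the expected map length
is 50 cM per CO per meiosis (verified in the tests at 0, 1, and 2
COs/meiosis).

**Cohort.** Each F2 receives a paternal CA/WA gamete (X transmitted
intact; the strain of the male X is configurable and defaults to CA,
since the direction of the P0 cross producing the F1 males is an open
choice) and a maternal CA/LR gamete.  Emulating marker-validated cross
progeny, an F2 must carry a WA haplotype somewhere; candidates without
one are redrawn.  On small synthetic genomes this conditioning is not
negligible (with a single autosome it excludes a quarter of paternal
chromatids); tests that need exact Mendelian ratios therefore place a
WA male X, which satisfies the validation for free.  Viability
selection, when configured, accepts an F2 carrying the disfavored
strain at the locus (of the stated parental origin) with probability
`relative_viability`, by rejection sampling with a bounded retry
budget.

**Reads.** Depth at a site is Poisson(`coverage`/2) per inherited
haplotype (default coverage 5x); each read reports its haplotype's
allele, flipped with probability `error_rate` (default 0.005, a typical
short-read substitution scale).  Total read counts are conserved
between draw and report.

## Site selection

A site is cross-informative iff all three parents are homozygous, each
parent's depth lies within its strain's mean ± 3 SD window (computed
genome-wide, matching the single printed window per strain), exactly
two alleles segregate, and exactly one strain carries the minority
allele.  Rejections are typed (`missing`, `het`, `depth`,
`not_biallelic`, `not_diagnostic`); a missing genotype is its own
class rather than being folded into `depth`.  With three homozygous
parents and two alleles the allele split is always 2:1, so
`not_diagnostic` is defensive only.

## Block genotyping

Within a 100 kb block, reads carrying the diagnostic allele of strain X
at X-diagnostic sites are summed into `depth_X`; reads carrying shared
alleles count for no strain (only then does a CA/CA block drive
`f_CA` to 1, consistent with the 0.95 rule).  The fractions are
**site-normalised**: `f_X` is `depth_X / n_sites_X` renormalised to sum
to 1.  The per-strain diagnostic-site count in a block is itself noisy
(Poisson placement) and, in real panels, systematically unequal across
strains; raw total-depth fractions inherit that noise undiminished by
sequencing depth (at 30x, error 0, ~22% of true heterozygous blocks
fail the balance rule), whereas normalised fractions converge with read
depth.  With equal site counts the two definitions coincide.

Calls: `CA/CA` iff `f_CA > 0.95`; `CA/LR` iff `f_WA < 0.05` and
`|f_CA − f_LR| ≤ 0.10`; `CA/WA` and `WA/LR` by symmetry.  The balance
inequality is deliberately "≤": a true heterozygote has both carrier
fractions near 0.5, so requiring them to be *close* accepts exactly the
heterozygote cluster; the opposite direction (available as
`classifier_thresholds(balance = "beyond")`) would reject every
balanced heterozygote while homozygotes are already captured by the
0.95 rule.  The rule set is mutually exclusive (verified by grid search
over the fraction simplex at step 0.001).  Any call requires at least
`min_classified_reads` (default 20) diagnostic reads — an added gate
the fraction rules do not imply; set it to 0 for the bare rules.  On
the X, calls incompatible with the intact male X strain become
`no_call(incompatible_X)`.  Blocks with fewer than 100 diagnostic
sites, more than 30% uncalled F2, or segregation distortion p ≤ 0.001
are excluded from mapping.

## Phasing and maps

Called genotypes decompose into per-parent strain labels; a CO is
called at each strain change between consecutive called blocks, its
interval running from the end of the left called block to the start of
the right one (missing blocks widen the interval; the midpoint is the
point estimate).  Terminal missing blocks generate no COs, and no
smoothing is applied — every transition counts; chromatids with more
than 3 COs are flagged suspect but retained.

The map treats each kept block as a locus at its midpoint.  Because a
block containing a CO has intermediate fractions and is typically
uncalled at 5x, the recombination fraction of the interval between
adjacent bins is estimated from transitions between consecutive
*called* bins: each transition is assigned to the interval containing
its breakpoint midpoint, and the denominator of an interval is the
number of chromatids with called bins on both sides.  This reduces to
plain adjacent-bin discordance under complete data and guarantees that
summed interval counts equal the total transition count from phasing
(asserted in the tests).  Map distance accumulates as cM = 100·m(r)
summed over intervals with the morgan identity m(r) = r by default —
appropriate because per-interval r over 100 kb bins is far below 0.1 —
with Haldane and Kosambi selectable; for these dense bins the choice
moves totals by at most a few percent.  Intervals with no informative
chromatid contribute 0 cM and are flagged.  r above 0.5 is capped with
a warning.  Physical bin order is taken as marker order (an assembled
reference is assumed); no de novo marker ordering is attempted.

## Distortion diagnostics

Each block's called genotype counts are tested against the cross's
Mendelian expectation (1:1:1:1 on autosomes, df 3; 1:1 over the two
admissible classes on the X, df 1) with Pearson's chi-square, no
continuity correction — with ~93 called F2 the expected counts exceed
20, where the asymptotic reference is standard.  The filter runs before
map building, but distortion *reporting* (inheritance bias, gradients)
uses the unfiltered call matrix: a chromosome that distorts coherently
would otherwise remove its own evidence through the filter.

Inheritance bias is the favored:disfavored count ratio among
nonrecombinant chromatids of one chromosome and parent; under
single-locus viability selection with relative viability v the expected
ratio is 1/v (recovered in the tests for v of 1, 0.5, and 0.125).  The
distortion gradient regresses per-bin favored-haplotype frequency on
physical position; significance comes from a permutation test (bin
labels permuted, two-sided on |slope|, seeded).  The permutation null
assumes exchangeable bins: it is calibrated for independent bin noise
(asserted in the tests), but along-chromosome linkage correlates
neighbouring bins, so on real profiles the p-value is anticonservative
and should be read as descriptive; the slope's *sign* (pointing toward
the selected end) is the robust signal.

## Numerical and design notes

- **Coordinates** are 0-based half-open everywhere except VCF (1-based,
  stated in file headers).  Blocks assign sites by half-open interval,
  so position 100,000 belongs to the second block.
- **Determinism**: all randomness flows through R's generator; every
  simulation entry point takes a seed, `run_pipeline()` seeds once, and
  the run manifest records it.  Identical seeds give identical files.
- **Edge truncation**: a CO inside the outermost block of a chromosome
  end may lack a flanking called block and is then invisible to any
  marker-based caller.  At the default geometry this removes a few
  percent of COs, which is the main reason simulated map lengths sit
  1–3 cM below the 50 cM expectation; oracle tests therefore assert
  exact CO-count recovery for chromatids whose true breakpoints lie at
  least one block from the ends, and breakpoint accuracy (within one
  block) for all recovered COs.
- **Problem sizes**: the package default genome is the six-chromosome
  2n = 12 karyotype (I–V plus X, chromosome I longest, 156.7 Mb total)
  scaled to 20% physical length.  Genetic-map expectations are
  invariant to physical scale, so the scaled genome reproduces the same
  map lengths, nonrecombinant fractions, and filter behaviour at a
  fraction of the simulation cost; `ppa_chromosomes(scale = 1)` gives
  the full-size genome (1567 hundred-kb blocks).
- **What the simulator does not model**: alignment and variant-calling
  artifacts, mapping bias between divergent strains, indels, depth
  overdispersion beyond Poisson, gene conversion, and chromatid
  interference.  Passing tests demonstrate the statistical machinery is
  correct under the stated generative model, not that real libraries
  are free of these effects.

## Reproducing a run

```{r, eval = FALSE}
cfg <- pipeline_config(
  chromosomes = ppa_chromosomes(scale = 0.2),
  co_male = co_model(1, obligate = TRUE, arm_weight = 3),
  co_herm = co_model(1, obligate = TRUE, arm_weight = 3),
  n_f2 = 93, coverage = 5, error_rate = 0.005,
  seed = 1, out_dir = "hybridmap_out")
res <- run_pipeline(cfg)
res$map$summary          # total cM per chromosome per parent
res$tally$per_parent     # nonrecombinant chromatid fractions
```
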