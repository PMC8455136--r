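# hybridmap

Sex-specific recombination maps from low-coverage sequencing of F2
progeny of a three-strain nematode double cross.

## The problem

Measuring meiotic recombination separately in spermatocytes and
oocytes of the same species normally requires two crosses. A *double
cross* does it in one: a reference strain (CA) is crossed to two
divergent strains (WA, LR) to produce F1 hybrid males (CA/WA) and F1
hybrid hermaphrodites (CA/LR), which are then mated. Every F2 carries
one chromatid recombined in male meiosis and one recombined in
hermaphrodite meiosis — and because WA alleles can only arrive through
sperm and LR alleles only through ova, the cross phases itself. With
only ~5× shotgun coverage per F2, single-site genotypes are hopeless;
instead, genotypes are called in 100 kb blocks from the relative
depths of strain-diagnostic alleles.

`hybridmap` implements the full analysis for R:

1. **Informative sites** — select biallelic sites homozygous in all
   three parents, with depth inside mean ± 3 SD per strain, where one
   strain carries a private allele.
2. **Block genotyper** — per F2 and 100 kb block, form site-normalised
   depth fractions `f_CA + f_WA + f_LR = 1` and call `CA/CA` iff
   `f_CA > 0.95`, `CA/LR` iff `f_WA < 0.05` and `|f_CA − f_LR| ≤ 0.1`
   (symmetrically for `CA/WA`, `WA/LR`); filter blocks with < 100
   sites, > 30% uncalled F2, or segregation distortion (p ≤ 0.001).
3. **Phasing** — decompose each genotype into (paternal, maternal)
   strain labels and call crossovers at label transitions between
   called blocks.
4. **Maps** — per-chromosome, per-parent Marey maps: interval
   recombination fractions r from phased chromatids, cumulative
   cM = 100·m(r) (morgan/haldane/kosambi), arm vs. center rates. The
   male X is transmitted intact, so the X has a maternal map only.
5. **Distortion** — per-block chi-square against the 1:1:1:1 (autosome)
   or 1:1 (X) expectation, nonrecombinant inheritance-bias ratios, and
   permutation trend tests for distortion gradients along chromosomes.
6. **Simulator** — a parameterised meiosis model (obligate single
   crossover per bivalent, arm-weighted placement, optional suppressed
   regions and viability selection, XX/XO sex chromosomes, Poisson read
   sampling with errors) that generates every input from scratch, with
   ground truth for oracle testing.

Key expectations encoded and tested: one obligate CO per chromosome per
meiosis gives ~50 cM maps and ~half nonrecombinant chromatids; a
selected locus with relative viability v gives a 1/v inheritance ratio
among nonrecombinant chromatids; a CO-suppressed arm gives a flat Marey
segment while the obligate CO keeps total length near 50 cM.

## Worked example

Simulate the study design (93 F2, obligate single CO, 5× coverage) on
the six-chromosome karyotype at 10% physical scale and run the whole
pipeline:

```r
library(hybridmap)
cfg <- pipeline_config(
  chromosomes = ppa_chromosomes(scale = 0.1),
  co_male = co_model(1, obligate = TRUE, double_co_rate = 0),
  co_herm = co_model(1, obligate = TRUE, double_co_rate = 0),
  seed = 1)
res <- run_pipeline(cfg)
res$map$summary
```

```
sites: 138095/139303 cross-informative
blocks: 160/160 kept (dropped: too_few_sites=0, too_many_uncalled=0, distorted=0)
     chrom   parent n_bins total_cm
 1:   chrI paternal     37 51.74678
 2:   chrI maternal     37 46.33272
 3:  chrII paternal     28 43.12840
 ...
11:   chrX maternal     17 41.94717
```

Eleven maps (5 autosomes × 2 parents, maternal X only), each close to
the 50 cM expected from one obligate crossover per meiosis — the few-cM
shortfall reflects crossovers inside the terminal blocks, which no
marker-based caller can flank. Chromatid-level summaries show the
companion law, about half of chromatids nonrecombinant per parent:

```r
res$tally$per_parent[, 1:4]
#>      parent n_chromatids n_nonrecombinant fraction_nonrecombinant
#> 1: maternal          558              298               0.5340502
#> 2: paternal          465              237               0.5096774
```

`run_pipeline()` with `out_dir` set writes all artifacts (parental VCF,
site TSV/BED, depth TSV, truth JSON, call/filter/chromatid/Marey TSVs,
and a manifest with the seed and funnel counts). A thin command-line
wrapper lives at `inst/scripts/run_pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package="hybridmap"))')" \
  --config config.yaml --seed 1 --out mapping_run/
```

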