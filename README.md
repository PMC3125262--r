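# xspecnorm

Normalization and centering of cross-species (heterologous) array
hybridization data using universally diverged control probes.

## The problem

Hybridizing genomic DNA from a non-model species onto a short-oligonucleotide
tiling array designed for a related model organism can, in principle, reveal
which probes — and which genes — are conserved enough to reuse. But the
standard array normalizations (quantile normalization, per-array scaling to a
common mean) assume every chip shares an intensity distribution. A
heterologous chip violates that assumption: most of its probes bind only
non-specifically, so forcing its distribution onto a homologous chip's
inflates non-specific signal into the false appearance of homology.

`xspecnorm` is for researchers running such cross-species gDNA
hybridizations on arrays that carry control probes from distant taxa (plant
and bacterial features on a nematode chip, for example). Those controls are
equivalently dissimilar to every test species, so their signal is
non-specific by construction and can calibrate each chip's baseline.

## The method

Per species *s*, over control probes *c*, with ΔG37 the nearest-neighbor
duplex free energy of a probe bound to its exact complement (kcal/mol,
unified parameter set):

    ln(i_c,s) = alpha_s + beta_s * dG37(c) + e,    e ~ N(0, sigma^2)

fitted by OLS; then every probe *p* is adjusted and centered:

    AI_p,s = ln(i_p,s) - beta_s * dG37(p) - shift_s
    shift_s = median_c [ ln(i_c,s) - beta_s * dG37(c) ]

so the median control probe sits at AI = 0 in every species. AI ≈ 0 means
non-specific baseline; AI > 0 suggests specific binding. No distributional
assumption is made about the target probes.

Around that core the package provides the conventional aCGH pipeline it is
compared against (quantile normalization, scaling to a common mean of 500,
50-bp smoothing), evaluation procedures (per-gene conserved-sequence t tests
with Bonferroni control, deletion ratio-track scans, probe-identity
specificity curves at matched true-positive counts, genome k-mer
frequencies), and a seeded synthetic hybridization generator that makes
every claim testable offline.

## Worked example

Simulate a two-species experiment — a reference species the probes were
tiled from and a diverged relative in which 15% of genes are conserved —
then normalize and call conserved genes:

```r
library(xspecnorm)

sim <- generate_dataset(sim_config(
  n_target_probes = 1200, n_control_probes = 400,
  divergence_per_site = 0.15, conserved_fraction = 0.15, seed = 31))

norm <- normalize_experiment(sim$intensities, sim$chips, sim$probes)
norm$fits
#>   species chip_id alpha   beta se_beta resid_sd shift n_controls
#> 1     ref    <NA>  4.81 -0.156 0.00597    0.345  4.81        400
#> 2     het    <NA>  5.07 -0.148 0.00623    0.360  5.08        400
```

Both chips recover the generative thermodynamic slope (−0.15 log-intensity
units per kcal/mol): each extra kcal/mol of duplex stability raises
non-specific log signal by ~0.15. The intercept and shift differ chip to
chip — exactly the variation the per-species calibration absorbs.

```r
res <- conserved_gene_test(norm$ai[norm$ai$species == "het", ], sim$probes)
head(res[res$significant, ], 5)
#>    gene_id n_exon_probes mean_ai t_stat    p_raw significant
#> 14   g0014             8    1.95   24.7 2.30e-08        TRUE
#> 16   g0016             8    2.06   20.9 7.14e-08        TRUE
#> 17   g0017             8    2.02   16.0 4.62e-07        TRUE
#> 20   g0020             8    1.91   11.0 5.74e-06        TRUE
#> 21   g0021             8    2.00   19.0 1.38e-07        TRUE
```

Conserved genes surface with mean AI near the planted +2.0 log-unit binding
gain and huge t statistics; 21 of 100 genes are called at family-wise 0.05
(all 18 truly conserved genes, plus 3 partially diverged genes whose
residual identity still supports binding).

A thin command-line interface wrapping these functions is installed at
`system.file("cli", "xspecnorm", package = "xspecnorm")`, with subcommands
`thermo`, `normalize`, `baseline`, `conserved`, `deletions`, `specificity`,
`kmerfreq`, `simulate`, and `run` (the last drives a whole pipeline from a
YAML config and writes a JSON manifest).

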