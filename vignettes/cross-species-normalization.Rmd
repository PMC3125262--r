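---
title: "Normalizing heterologous array hybridization with diverged control probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing heterologous array hybridization with diverged control probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xspecnorm)
```

## The problem

Hybridizing genomic DNA of a non-model species onto a short-oligonucleotide
tiling array designed for a related model organism is an attractive way to
borrow genome-enabled tools: probes whose sequence is conserved in the test
species should light up, diverged probes should not. The difficulty is that
the standard normalizations of array analysis — quantile normalization,
per-array scaling to a common mean — assume every chip draws its intensities
from the same distribution. A heterologous chip does not: most of its probes
bind only non-specifically, so its raw distribution sits lower and has a
different shape than a homologous chip's. Forcing the distributions to agree
re-labels non-specific binding as signal and manufactures the false
appearance of homology.

`xspecnorm` implements an alternative that makes no distributional
assumption. Commercial arrays carry control probes drawn from distant taxa
(on the *C. elegans* tiling array, plant and bacterial sequences). These
controls are *equivalently dissimilar* to every species one would hybridize:
whatever signal they show is non-specific by construction. They therefore
trace out, chip by chip, the relationship between probe thermodynamics and
non-specific signal, and that relationship can be removed from every probe.

## The model

For each species $s$, over its control probes $c$:

$$\ln(i_{c,s}) = \alpha_s + \beta_s\,\Delta G_{37}(c) + e, \qquad
e \sim N(0, \sigma_s^2)$$

where $i$ is the background-subtracted intensity and $\Delta G_{37}$ is the
nearest-neighbor free energy of the probe bound to its exact complement at
37&nbsp;°C (kcal/mol; more negative = stronger binding). The fit is ordinary
least squares on the natural-log scale ([fit_control_model()]). Every probe
$p$ is then adjusted and centered:

$$\mathrm{AI}_{p,s} = \ln(i_{p,s}) - \beta_s\,\Delta G_{37}(p) - \mathrm{shift}_s,
\qquad \mathrm{shift}_s = \operatorname{median}_c\!\left[\ln(i_{c,s}) -
\beta_s\,\Delta G_{37}(c)\right].$$

The phase shift pins the median control probe at AI $= 0$ in every species,
so AI is comparable across chips without equating their distributions:
AI $\approx 0$ is the non-specific baseline, AI $> 0$ suggests specific
binding. Two centerings coexist here and are deliberately distinct: the OLS
residuals are exactly decorrelated from $\Delta G_{37}$ (slope zero), while
the reported AI is median-centered — the median of the slope-adjusted
values, not of the raw log intensities, because only the slope-adjusted
median guarantees that controls center on zero *after* the thermodynamic
adjustment.

```{r fit-example}
dg <- delta_g37(setNames(
  c("ACGTACGTACGTACGTACGTACGTA", "GGGCCGGGCCGGGCCGGGCCGGGCC",
    "ATATATATATATATATATATATATA", "TTGACCTTGACCTTGACCTTGACCT"),
  paste0("c", 1:4)))
round(dg, 2)
```

### Thermodynamic parameters

`delta_g37()` uses the unified nearest-neighbor $\Delta G^\circ_{37}$ set at
1&nbsp;M NaCl: ten unique Watson–Crick stacking energies (expanded to all 16
dinucleotide steps by strand symmetry), a duplex initiation term, and a
terminal A·T penalty per A/T end. The shipped default
(`inst/extdata/nn_unified_dg37.tsv`, loadable via `read_nn_params()`)
**includes** the initiation and terminal terms. Whether to include them is
immaterial to the normalization — they shift $\Delta G_{37}$ affinely, and
any affine change is absorbed by the fitted $\alpha$ and $\beta$ — but the
choice is fixed and documented so that reported $\Delta G_{37}$ values are
reproducible. For the same reason no salt or temperature correction is
applied. Self-folding and probe dimerization are not modeled; the covariate
is duplex formation free energy alone.

### Numerical conventions

* **Median**: the midpoint of the two central order statistics for even
  counts (`stats::median`). The exact-zero centering invariant depends on
  this: with an odd control count the median control AI is exactly 0; with
  an even count it is 0 to floating precision.
* **Replicate handling**: the model carries a species index but no chip
  index, so replicate chips are combined per probe on the log scale
  (geometric mean, [collapse_replicates()]) *before* fitting. A
  `per_chip = TRUE` mode fits and adjusts each chip separately and averages
  the per-chip AI ([combine_replicates()]); it exists to expose chip-to-chip
  variation, which the control-vs-$\Delta G$ relationship otherwise absorbs.
* **Error model**: OLS, matching the model's normality assumption. A
  Theil–Sen option (`method = "theil-sen"`) is available for contaminated
  control sets but is not the default.
* **Degenerate inputs**: fewer than 3 distinct $\Delta G$ values,
  non-positive intensities, or probes without a $\Delta G$ value are
  rejected with the offending probe named.

## The conventional baseline

[baseline_normalize()] reproduces the aCGH-style pipeline the method is
compared against: quantile normalization across chips, per-array scaling to
a common mean of 500 intensity units, and positional smoothing over a 50-bp
bandwidth, in that order. It exists to measure its own artifacts, which the
test suite asserts directly:

* after scaling, the low-mean (heterologous) chip receives the larger
  multiplier, inflating non-specific signal;
* smoothing bleeds a high-intensity probe into near-zero neighbors,
  inflating low-intensity probes.

Tie handling in quantile normalization (tied values receive the mean of the
order statistics they span) follows `limma::normalizeQuantiles(ties =
TRUE)`, which backs the implementation. The smoother is a windowed mean over
probes within ± bandwidth/2 bp — the conventional workflow describes its
smoother only as "wavelet-based" without an algorithm, so the default here
is the variant with an exact brute-force oracle; a translation-invariant
Haar soft-threshold alternative (`method = "haar"`) is provided and shows
the same flanking-inflation artifact.

## Evaluation procedures

**Conserved genes.** A gene is "conserved" when the mean AI of its exon
probes is significantly greater than zero: one-sample, one-sided t test per
gene, Bonferroni-corrected over the genes tested at family-wise 0.05
([conserved_gene_test()]). One-sided is the default because the question is
directional (above the non-specific baseline); a two-sided flag exists.
Genes with fewer than two exon probes are excluded and reported, not
errors. Zero-variance genes get $t = 0$ when their mean is 0 (never
significant) and $t = \pm\infty$ otherwise.

**Deletions.** [ratio_track()] back-transforms AI differences to ratios,
$\exp(\mathrm{AI}_{test} - \mathrm{AI}_{ref})$, centered at 1.0.
[deletion_scan()] reports maximal runs of at least `min_run` probes whose
running-median ratio (window `window_probes`, shrinking at chromosome ends)
falls below `ratio_threshold`. Defaults — window 5, threshold 0.5, run
length 10 — were chosen by simulation to recover 3-kb deletions at 35-bp
probe spacing with no false intervals on null tracks (50/50 recovered at
≥ 80% overlap, 0 null calls in the acceptance checks); the original
confirmation of such dips was visual, so the scan is this package's
formalization rather than a published algorithm. Intervals are half-open,
`[first probe start, last probe start + 1)`.

**Identity and specificity.** [probe_identity()] counts, per probe span,
alignment columns where reference and ortholog carry the identical
nucleotide; gap columns count as mismatch (how gapped columns were scored
historically is unstated — this is the documented choice). Classes follow
the <22 / 23–24 / 25 convention: `true` = 25/25, `semi-true` = 23–24,
`false` ≤ 22. A count of exactly 22 belongs to no published class and is
classed `false`; the boundary (`semi_min`) is configurable.
[align_orthologs()] provides global affine-gap alignment (match +1,
mismatch −1, a length-$L$ gap costs $5 + (L-1)$), backed by
`Biostrings::pairwiseAlignment` and validated against exhaustive
enumeration on short sequences. [threshold_accumulation()] counts class
members above each ratio threshold, and [matched_tp_mismatch()] compares
two normalizations fairly: because their ratio scales are not equivalent,
thresholds are matched by true-positive count (the ratio of the k-th
best-ranked perfect-match probe), and the mismatch-to-perfect ratio is
averaged over a sensitivity grid (5–50% of perfect-match probes). This is
the package's figure of merit for "fewer false accumulations at equal true
positives".

**k-mer frequency.** [kmer_frequency()] counts exact occurrences of each
probe (plus reverse complement — labeled gDNA is double-stranded; a
single-strand mode exists), overlaps included, ambiguous genome positions
never matching.

## The synthetic generator

[generate_dataset()] emits experiments with the statistical structure the
model assumes, so every claim is testable without external downloads. Per
chip:

$$\ln(i_p) = \alpha_{true} + \beta_{true}\,\Delta G_{37}(p) +
\mathrm{effect} \cdot g(\mathrm{identity}_p) \cdot \mathrm{copies}_p +
N(0, \sigma)$$

with $g = 0$ below `identity_floor` (default 0.8, i.e. 20/25) rising
linearly to 1 at perfect identity. Defaults: $\alpha_{true} = 5$,
$\beta_{true} = -0.15$ (log-intensity per kcal/mol, the sign and rough
magnitude a stabilizing $\Delta G$ relationship implies), $\sigma = 0.5$,
effect 2.0 log units, 25-mer probes every 35 bp, two chips per species,
genome GC 0.36 (nematode-like), controls at GC 0.5 with $g \equiv 0$
(equivalently dissimilar by construction). The heterologous genome is
derived by per-site substitutions, small indels, and planted deletions,
with a configurable fraction of genes protected from divergence; the truth
alignment is retained, so per-probe identity is recomputable and probes
overlapping deletions lose identity — and hence signal — through the same
scoring that [probe_identity()] applies.

Deliberate simplifications, and hence what passing tests do *not* show
about real data: the identity-to-affinity map $g$ is a modeling knob, not a
measurement (the method's own conclusion is that intensity correlates
poorly with identity, so no particular map is defended); noise is
homoskedastic log-normal with no scanner saturation, spatial artifacts, or
probe-specific affinity beyond $\Delta G_{37}$; copy number multiplies the
specific term on the log scale; genomes are i.i.d.-composition, not real
nematode sequence. The generator shows the method behaves as designed when
its assumptions hold — it cannot show the assumptions hold on any
particular real dataset.

## Validation scale

The shipped checks run at desk scale, chosen to keep the full suite in
minutes while leaving comfortable statistical margins: 1,000-probe control
sets over 200 replicates for calibration recovery (CI coverage within
[90%, 99%], mean absolute slope error < 0.005); 100-kb chromosomes at 35-bp
spacing with one 3-kb planted deletion over 50 seeds (plus 50 null tracks);
1,000-gene null families over 200 replicates for FWER; 3,000 target probes
at 10% per-site divergence — an identity spectrum spanning < 22 through 25
of 25 — for the specificity comparison; 2,000 probes for the copy-number
relationship. `scripts/acceptance.R` recomputes all of these from scratch
at any seed.

## Known limitations

* Controls must truly be equivalently dissimilar; contamination of control
  features with sequences conserved in the test species biases the
  baseline upward.
* A single $\Delta G_{37}$ covariate cannot capture self-folding, probe
  dimerization, or position-of-mismatch effects; the residual spread it
  leaves is absorbed into $\sigma_s$.
* AI values are comparable across species only in location (median control
  = 0); scale differences between chips are not equalized — by design, since
  equalizing them is the artifact the method avoids.
* The deletion scan is a formalized convenience; its defaults target
  3-kb-scale events at tiling-array spacing and will miss events shorter
  than `min_run` probes.
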