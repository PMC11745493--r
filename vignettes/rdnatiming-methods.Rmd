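---
title: "Methods: quantifying replication timing, licensing and firing at a collapsed rDNA array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying replication timing, licensing and firing at a collapsed rDNA array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnatiming)
```

## The problem

Budding yeast carries ~150 tandem copies of a 9.1 kb rDNA repeat — almost
1.4 Mb of chromosome XII. Each repeat holds one origin of replication
(rARS), licensed in G1 by loading an MCM2-7 double-hexamer next to a
well-positioned +1 nucleosome. Transcription of the Sir2-repressed C-pro
noncoding RNA can push a loaded helicase ~150 bp rightward into a
nucleosome-depleted region, and these displaced helicases fire earlier than
their nondisplaced neighbours. The package quantifies this biology from
fragment-interval sequencing data: relative replication timing from sorted
G1/S libraries (S-seq), fragment-size-resolved MCM footprints from
MCM2-ChEC, origin firing from the differential disappearance of those
footprints across a hydroxyurea (HU) time course, nucleosome occupancy from
MNase-seq, EdU origin activity, and the band-intensity and qPCR arithmetic
used for licensing and array-size estimates.

Because reads from a tandem array cannot be assigned to individual repeats,
the genome model is a *collapsed reference*: all N physical repeats map onto
`collapsed_copies = 2` reference repeats, and N manifests only as read depth.
That makes the expected rDNA share of G1 reads

$$\mathrm{frac} = \frac{N\,\ell}{N\,\ell + U},$$

with repeat length $\ell$ = 9100 bp and unique genome length $U$ = 12.1 Mb,
about 10% at N = 150 — which is precisely how `copies_from_fraction()`
estimates array size from sequencing alone.

## The timing statistic

`trel_profile()` computes, per genomic bin $b$,

$$r_b = \frac{S_b / S_\mathrm{tot}}{G_b / G_\mathrm{tot}}, \qquad
T_{\mathrm{rel},b} = \frac{r_b}{\mathrm{median}_b(r_b)}.$$

Dividing S by G1 depth cancels copy number (essential for a locus whose
copy number varies between strains); dividing by the genome-wide *median*
anchors the average locus at 1 while staying robust to the rDNA's own
outlying depth. A locus replicated in a fraction $f$ of sorted S-phase
cells is present in $1+f$ copies on average, so with a genome-median
replicated fraction of 0.5 the expected region value is
$(1+f)/(1.5)$ — 0.90 at $f = 0.35$ (late, wild-type-like) and 1.21 at
$f = 0.815$ (early, as in *sir2*). Defaults: 1 kb bins, bins with fewer
than 20 G1 midpoints undefined, bins partially overlapping a query region
excluded from `region_trel()`. No smoothing is applied.

## Firing from footprint disappearance

A loaded double-hexamer protects a ~65 bp fragment; its ChEC footprint
vanishes when the origin fires and the helicases leave with the forks.
`decay_table()` therefore measures, per window and timepoint, the retained
fraction $R(t)$ of 51–100 bp midpoint counts relative to G1, after
max-total depth scaling (`scale_to_max_total()`: every library scaled up
to the deepest). Under first-order kinetics $R(t) = e^{-\lambda t}$, and
`fit_firing_rate()` uses the zero-intercept least-squares closed form
$\hat\lambda = -\sum_t t \ln R(t) / \sum_t t^2$.

The simulator's default rates in 200 mM HU are $\lambda_d = 0.02$/min for
displaced and $\lambda_n = 0.002$/min for nondisplaced rDNA helicases
(so displaced retention at 90 min is $e^{-1.8} \approx 0.17$, a
near-complete loss, while nondisplaced signal barely moves), 0.02/min for
genomic early origins and 5e-4/min for checkpoint-inhibited late origins.
The rates themselves are modelling choices — only their ordering is
empirically anchored — and every one is overridable through
`genotype_params()`.

At the rDNA the replication fork barrier (RFB) sits ~1.5 kb right of the
MCM sites, so fired helicase signal reappears in the 300 bp immediately
left of the RFB (`rfb_accumulation()`); MCM-window loss equals RFB-window
gain, a bookkeeping identity the test suite checks to within three
standard errors.

## What the generator emulates — and what it does not

`simulate_chec_timecourse()`, `simulate_sseq()`, `simulate_mnase()`,
`simulate_edu()` and `simulate_licensing_assay()` sample fragments
directly from mixture weights rather than simulating individual cells:
equivalent in distribution and far cheaper. Key design choices:

* **Conservation.** Signal never vanishes from the mixture, it moves.
  Fired rDNA helicase weight transfers to the RFB deposit; weight lost
  from genomic origin footprints and from MCM-conditioned
  nucleosome-adjacent fragments transfers to a genome-wide dispersed pool
  (physically, helicases travelling with forks whose ChEC signal spreads
  below peak scale). Total library composition is therefore stable across
  the time course, which is what makes retained fractions under max-total
  scaling interpretable as survival probabilities.
* **Geometry.** Footprint lengths are normal(65, 4) clipped to 51–100 bp;
  nucleosomal fragments normal(165, 10) clipped to 151–200 bp; footprint
  midpoints jitter with sd 3 bp; sonicated (S-seq/EdU) fragments are
  uniform 150–450 bp. Fork speed in HU is 50 bp/min — a ~1 kb/min
  unperturbed fork slowed ~20-fold, rounded.
* **Genotypes.** Licensing probability L = 0.75 (inside the measured
  60–85% range). Displaced fraction p_d = 0.10 in wild type (the paper-
  scale data show only "a small fraction", so this is a declared
  placeholder), 0.70 in *sir2*, +0.10 with *fun30* (increased C-pro
  transcription). *fun30* quarters the displaced firing rate and doubles
  +2/+3 nucleosome emission (0.25/0.35 to 0.50/0.70, capped at 1).
  Weak early origins (28 of the 111 early origins) fire at 0.5 the early
  rate in *sir2*; co-deleting *FUN30* damps rDNA firing and partially
  restores them, encoded as scale 0.8 — without that intermediate value
  the observed wild type > *sir2 fun30* > *sir2* ordering of weak-early
  activity could not arise from the parameter table at all.
* **Seeding.** One master seed; each assay (and each ChEC timepoint)
  draws from an arithmetically derived 31-bit substream, so a
  `simulation_spec` reproduces libraries byte-for-byte.

The generator does *not* emulate sequence content, mapping artifacts, PCR
duplicates, read errors, cell-cycle asynchrony beyond the G1/HU design, or
repeat-to-repeat heterogeneity within an array. Passing tests therefore
demonstrate that the analysis stages are correct against the declared
locus model, not that they are robust to alignment pathologies of real
tandem-repeat data.

## Numerical conventions

* Coordinates are 0-based half-open internally; exported TSV/bedGraph
  coordinates follow each format's convention (the size-coordinate matrix
  writes 1-based coordinates, matching its source-data layout).
* A fragment's position is its midpoint, `floor((start + end)/2)` — even
  lengths round down — and a fragment belongs to a window iff its midpoint
  lies in the half-open window. Size classes are inclusive on both ends.
* `call_peaks()` smooths with a discrete Gaussian kernel (bandwidth 10 bp,
  support ±4 bandwidths), takes the leftmost point of any plateau as the
  local maximum, requires 5% of the maximum height, and greedily enforces
  a 100 bp minimum separation in decreasing height order with ties broken
  leftmost. These defaults always resolve two equal peaks 150 bp apart —
  the displaced/nondisplaced spacing — while merging sub-separation
  shoulders.
* Degenerate inputs fail loudly: empty libraries, windows with zero G1
  counts (flagged, not dropped), a zero +1 normalization reference,
  identical qPCR standards, clipped licensing fractions (warned and
  flagged).
* "Student's t-test" means the pooled-variance two-sample two-tailed t
  throughout, with Welch available via `var_equal = FALSE`; EdU drop
  comparisons are unpaired on per-origin drop vectors by default with a
  paired option.

## Problem sizes

Desk-scale defaults were chosen so every stage is measurable with
comfortable statistical margins: S-seq anchors use 2×10^6 fragments per
library (rDNA Trel standard error ~0.003 against a ±0.02 acceptance band),
ChEC/MNase stages use 1–3×10^5 fragments, and rate-recovery checks run ten
seeds at 2×10^5 fragments per timepoint. The full test suite completes in
roughly two minutes on one core.

## Worked example

```{r, eval = FALSE}
model <- default_genome_model(150)
spec <- simulation_spec(model, genotype_preset("sir2"),
                        n_fragments = 2e5, seed = 1)

# timing
ss <- simulate_sseq(spec, replication_track(model, 5000, f_rdna = 0.815))
rdna_trel(trel_profile(ss$g1, ss$s, model, 5000), model)

# firing kinetics
tc <- simulate_chec_timecourse(spec)
tab <- decay_table(tc, rdna_mcm_windows(model))
fit_firing_rate(tab, "displaced")
displaced_vs_nondisplaced(tab)
```

## Known limitations

* The Trel normalization convention (total-scaled S/G1 ratio over its
  genome-wide median) is a declared reconstruction: it reproduces the
  published anchor values and range, but the published pipeline's exact
  bin size, filters and normalizer are not recoverable from the text.
* ChEC time-course depth normalization adopts the max-total rule stated
  for EdU; no assay-specific alternative is documented.
* The exponential firing model is a summary device; the data constrain
  monotone loss and rate orderings, not the kinetic law.
* Absolute EdU medians depend on sequencing depth; only comparisons
  between genotypes (drops, rank orders) are meaningful at desk scale.
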