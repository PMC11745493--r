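# rdnatiming

Quantitative analysis of DNA replication at a tandemly repeated rDNA locus,
for researchers working with fragment-interval sequencing assays (S-seq,
ChEC-seq, MNase-seq, EdU-seq) in budding yeast or similar systems with a
collapsed repeat reference.

The rDNA array (~150 × 9.1 kb on chrXII) licenses one origin per repeat in
G1 by loading an MCM2-7 double-hexamer; a derepressed noncoding transcript
can push the loaded helicase ~150 bp rightward into a nucleosome-depleted
region where it fires earlier. The package implements the quantitative
framework for measuring this:

* **Relative replication timing.** Per bin, r_b = (S_b/S_tot)/(G_b/G_tot),
  normalized by its genome-wide median: Trel = r_b / median(r). Average
  loci score 1; early regions range up to ~1.4, late down to ~0.8.
* **Copy number from sequencing.** The G1 rDNA read fraction equals
  N·ℓ/(N·ℓ + U) on a collapsed reference, inverted by
  `copies_from_fraction()`.
* **Fragment-size-resolved footprinting.** 51–100 bp fragments mark MCM
  double-hexamer footprints (~65 bp mode), 151–200 bp fragments mark
  nucleosomes; `call_peaks()` resolves helicase complexes only 150 bp
  apart.
* **Firing inference.** Retained footprint fraction R(t) across a
  hydroxyurea time course (max-total depth scaling, G1 reference), with
  the zero-intercept exponential rate λ = −Σ t·ln R / Σ t², plus
  accounting of reciprocal signal accumulation at the replication fork
  barrier.
* **EdU origin activity, licensing and qPCR arithmetic.** 5 kb origin
  windows, per-class medians of log10 signal and drop comparisons;
  Southern-band depletion → licensed fraction; two-point log-linear qPCR
  calibration → copies; per-copy C-pro expression.
* **A synthetic-data generator** (`simulate_*`) that emulates the locus
  model — genotype effects of *sir2* and *fun30* included — so every stage
  is verifiable at desk scale without external data.

## Worked example

```r
library(rdnatiming)

model <- default_genome_model(150)        # 12.1 Mb unique + collapsed array
spec  <- simulation_spec(model, genotype_preset("sir2"),
                         n_fragments = 2e5, seed = 3)

# S-seq timing: an early-replicating rDNA (replicated fraction 0.815
# against a genome median of 0.5)
ss   <- simulate_sseq(spec, replication_track(model, 5000, f_rdna = 0.815))
prof <- trel_profile(ss$g1, ss$s, model, bin_size = 5000)
rdna_trel(prof, model)
#> [1] 1.209803

# ChEC time course in HU: displaced helicases fire faster
tc  <- simulate_chec_timecourse(spec)
tab <- decay_table(tc, rdna_mcm_windows(model))
displaced_vs_nondisplaced(tab)
#>   timepoint retained_displaced retained_nondisplaced difference
#> 1         0          1.0000000             1.0000000  0.0000000
#> 2        15          0.7373876             0.9744377  0.2370501
#> 3        30          0.5497114             0.9404173  0.3907059
#> 4        45          0.4048866             0.9107199  0.5058333
#> 5        60          0.2969258             0.8840925  0.5871667
#> 6        90          0.1659552             0.8456864  0.6797312
fit_firing_rate(tab, "displaced")
#> firing_estimate: displaced | lambda = 0.02005 /min | rms residual 0.00674
```

The rDNA Trel of ~1.21 is the early-replicating signature of a *sir2*
locus (a wild-type-like locus at replicated fraction 0.35 scores ~0.90);
the fitted λ of 0.020/min against 0.002/min for the nondisplaced window
quantifies the faster activation of displaced helicase complexes, and the
retained-fraction table shows the displaced footprint decaying to ~17% by
90 min while the nondisplaced one persists.

A thin CLI wrapper drives the same functions from a YAML config:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/rdna-pipeline.R",
                                      package = "rdnatiming"))') \
    simulate --genotype sir2 --seed 1 --outdir out/
```

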