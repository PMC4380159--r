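# spikelin

Spike-in linearity benchmarking for RNA-seq library preparation protocols.

## The problem

Low-input and "single-cell" RNA-seq protocols pre-amplify minute amounts of
cDNA before library construction. Amplification can distort quantification in
sequence-dependent, potentially non-linear ways, so the question a protocol
benchmark must answer is not *"does protocol X report the same FPKM as
protocol Y"* (absolute levels are generally not comparable across protocols)
but *"when the true concentration of a transcript changes k-fold, does the
measured abundance change k-fold?"*

A two-species mixture design answers it directly: whole RNA of a **spike
species** (e.g. *D. virilis*) is mixed into a **background species**
(e.g. *D. melanogaster*) at known fractions
Q<sub>j</sub> ∈ {0, 5, 10, 20 %}, one library per fraction. Every
spike-species gene is then a natural dose-response probe spanning the full
~10<sup>5</sup>-fold dynamic range of real transcript abundances.

`spikelin` is for anyone running such a benchmark: it takes HTSeq-count
style per-gene count files and a design table and produces the per-gene and
per-protocol linearity statistics, an ideal-protocol null model to compare
against, and a decomposition of replicate noise that isolates the
pre-amplification step.

## The statistics at its core

With A<sub>ij</sub> the count of gene *i* in library *j* (libraries first
subsampled to equal depth by multivariate hypergeometric draws), each gene
is rescaled onto the fraction axis by a weighted no-intercept projection:

```
Â_ij = A_ij ÷ ( Σ_j Q_j A_ij / Σ_j Q_j² )
```

The divisor is the least-squares slope of A on Q through the origin, so a
perfectly linear gene has Â<sub>ij</sub> = Q<sub>j</sub> exactly. For every
spike gene with ≥ 20 fragments in the highest-fraction library, `spikelin`
fits an independent ordinary least-squares line
Â<sub>ij</sub> = m<sub>i</sub>·Q<sub>j</sub> + b<sub>i</sub> and the Pearson
correlation r<sub>i</sub>; per protocol it reports the distributions of
(m, b, r), one-sample t tests of the slopes against 1 and the intercepts
against 0, and the interquartile range of the slopes.

Two companion analyses put those numbers in context:

* **Counting-noise null** — an ideal protocol in which the only variability
  is the multinomial sampling of a finite number of reads. Replicated
  simulations give null distributions of mean r and slope IQR; observed
  metrics are placed on them as the percentage of replicates strictly
  exceeding them.
* **Intrinsic/extrinsic noise** — for two runs of the same mixture series,
  gene *i* contributes a point (m<sub>1i</sub>, m<sub>2i</sub>);
  η<sub>ext</sub> = sd(m₁ + m₂) measures variation shared by the runs (along
  the diagonal), η<sub>int</sub> = sd(m₁ − m₂) the variation specific to
  each (perpendicular to it). Runs re-prepared from the same pre-amplified
  cDNA pools share the pre-amplification biases, so their η<sub>int</sub>
  isolates the post-amplification noise.

Utility functions cover the wet-lab bookkeeping around the design: library
molarity from concentration, volume and fragment size
(Y fmol = C·10⁻⁹·V·10¹⁵ / 608.9 / S) and equimolar pooling volumes.

## Worked example

The synthetic generator produces complete mixture experiments with known
truth, so the whole pipeline can be exercised without sequencing data. Here
a "low-volume" protocol with a lognormal pre-amplification bias
(`bias_sd = 0.2`) is fitted and compared with the counting-noise null:

```r
library(spikelin)

cfg <- generator_config(n_background_genes = 3000, n_spike_genes = 1000,
                        levels = c(0, 0.05, 0.10, 0.20), depth = 1e6,
                        bias_sd = 0.2, seed = 5)
tab <- generate_experiment(cfg, preamp_id = "batch1", protocol = "lowvol")
fit <- spikelin(tab, min_count = 20)
summary(fit)
#> Per-protocol distribution of per-gene fit parameters
#> (ideal linear response: slope 1, intercept 0, r 1)
#>
#>  protocol   n          slope         intercept             r iqr_slope
#>    lowvol 423 0.999 ± 0.0795 9.64e-05 ± 0.0119 0.977 ± 0.031     0.107

base <- base_probs_from_reference(tab)
sc <- sim_config(base$probs, base$species, levels = cfg$levels,
                 depth = 1e6, n_reps = 100, seed = 5)
obs <- summary(fit)
run_ensemble(sc, observed = list(mean_r = obs$mean_r,
                                 iqr_slope = obs$iqr_slope))
#> Counting-noise null ensemble: 100 replicates ( 0 failed )
#>   mean_slope     1.0012 ± 0.0017
#>   mean_intercept -0.0002 ± 0.0003
#>   mean_r         0.9937 ± 0.0005
#>   iqr_slope      0.0346 ± 0.0022
#>   percent of replicates above observed:
#>     mean_r         100.0%
#>     iqr_slope      0.0%
```

Reading the output: the biased protocol still has mean slope ≈ 1 and mean
intercept ≈ 0 — amplification bias does not destroy linearity *on average*
— but its per-gene correlations (0.977) fall below every one of 100 null
replicates and its slope IQR (0.107) exceeds all of them: the protocol adds
real gene-specific noise beyond counting noise.

The pre-amplification share of that noise is visible in paired runs:

```r
r1 <- spikelin(generate_experiment(cfg, "batch1", run_seed = 1))$fits
r2 <- spikelin(generate_experiment(cfg, "batch1", run_seed = 2))$fits
r3 <- spikelin(generate_experiment(cfg, "batch2", run_seed = 3))$fits
decompose_noise(r1, r2)   # same pre-amplified pools
#>   eta_int = sd(m1 - m2) = 0.0423
#>   eta_ext = sd(m1 + m2) = 0.0997
decompose_noise(r1, r3)   # independent pre-amplifications
#>   eta_int = sd(m1 - m2) = 0.0750
#>   eta_ext = sd(m1 + m2) = 0.0761
```

Sharing the pre-amplification nearly halves the intrinsic noise (0.042 vs
0.075) while inflating the shared (extrinsic) component — the signature of
a bias introduced at the pre-amplification step.

End-to-end runs over count files on disk go through `run_pipeline()`, which
reads a design CSV, subsamples to the lowest library depth, fits, summarizes
and writes everything as TSV plus a manifest.

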