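---
title: "Assessing per-gene linearity of RNA-seq protocols with two-species spike-ins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing per-gene linearity of RNA-seq protocols with two-species spike-ins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikelin)
```

## The measurement model

A two-species mixture experiment prepares one library per known spike
fraction $Q_j$ (whole spike-species RNA mixed into background-species RNA;
the package's default series is $Q \in \{0, 0.05, 0.10, 0.20\}$, expressed
throughout as fractions, not percent). After mapping and per-gene counting,
the data are a gene $\times$ library matrix of counts $A_{ij}$. Three
modelling assumptions underlie the analysis:

1. **Counts, not rates.** $A_{ij}$ is the raw fragment count after all
   libraries have been subsampled to a common depth. At equal depth raw
   counts are directly comparable across libraries and no length or
   depth normalization (FPKM/TPM) is needed — or wanted, since those
   transformations would change the noise model.
2. **Proportional truth.** The true concentration of spike gene $i$ in
   library $j$ is proportional to $Q_j$, because the same spike RNA pool
   is diluted as a whole. Background genes are *not* constant across
   libraries (their share grows as the spike shrinks), which is why the
   linearity analysis is restricted to spike-species genes.
3. **Per-gene scale nuisance.** Each gene's absolute abundance is
   arbitrary (it depends on expression level, length, mappability), so
   the analysis must be invariant to a per-gene positive scale factor.

The scale nuisance is removed by projecting each gene onto the fraction
axis:

$$\hat A_{ij} \;=\; A_{ij} \div \frac{\sum_j Q_j A_{ij}}{\sum_j Q_j^2}.$$

The divisor $s_i$ is the no-intercept least-squares slope of $A_i$ on
$Q$, so the projection identity $\sum_j Q_j \hat A_{ij} / \sum_j Q_j^2 = 1$
holds exactly for every gene with $s_i > 0$, and a gene that responds
perfectly linearly satisfies $\hat A_{ij} = Q_j$. Genes with $s_i = 0$
(no reads in any positive-fraction library) have no defined scale; they
are carried through flagged `excluded` so that data loss stays auditable,
never dropped silently. Because $\hat A$ is $A$ times a per-gene positive
constant, the per-gene Pearson correlation with $Q$ is unchanged by the
normalization — only slopes and intercepts are placed on the common scale.

For each spike gene with at least `min_count` fragments in the
highest-fraction library (default 20 — genes below that are too noisy for
a meaningful 4-point regression), `spikelin()` fits ordinary least
squares $\hat A_{ij} = m_i Q_j + b_i$ and the Pearson $r_i$. A protocol
summary reports means and sample standard deviations of $(m, b, r)$,
one-sample $t$ tests of the slopes against 1 and intercepts against 0,
and the interquartile range of the slopes. The $t$ statistics are
reported plainly: a small $p$ is evidence *against* mean slope 1, and
with hundreds of genes the tests are sensitive to deviations far smaller
than any practical concern, so the summary should be read jointly with
the effect sizes.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_count` | 20 | fragments | inclusion filter in the highest-$Q$ library; inclusive |
| `target_depth` | min library depth | reads | common depth for subsampling |
| `levels` | 0, 0.01, 0.05, 0.10, 0.20 | fraction | generator mixture series (the 1% level mirrors extended designs; any $\ge 3$ distinct levels can be fitted) |
| `depth` | 2.5e6 | reads/library | generator and null-model depth; the scale typical after subsampling a multiplexed lane to its shallowest library |
| `dynamic_range` | 1e5 | fold | span of synthetic expression |
| `bias_sd` | 0 | log-scale sd | pre-amplification bias magnitude; 0 = ideal protocol |
| `n_reps` | 1000 | — | null-ensemble replicates (tests and the acceptance script use 20 to keep runs short) |

## The counting-noise null

An ideal protocol has no preparation bias at all: every library is one
multinomial draw of `depth` reads over genes. Base probabilities describe
the highest-fraction library; they may come from the synthetic generator
or, via `base_probs_from_reference()`, from any real reference library's
count vector. A lower level $\ell$ is derived by scaling every spike
gene's probability by $\ell / \ell_{max}$ and assigning the freed mass
*evenly* — the same absolute increment — to each background gene. The
even (rather than proportional) redistribution is a deliberate, literal
modelling choice; at spike fractions $\le$ 20% the two differ negligibly
for the spike genes under study, and only the spike genes enter the fits.

`run_ensemble()` applies the identical normalize–filter–fit–summarize
pipeline to every replicate and records mean slope, mean intercept, mean
$r$ and slope IQR. Observed metrics are ranked by *strict-greater*
counting: the reported percentage is the share of replicates strictly
exceeding the observed value, so "0%" means the observation beats the
whole ensemble. Replicates that fail (e.g. no gene passes the filter at
very low depth) are recorded and skipped rather than aborting the run.

One property of the pipeline is worth knowing when reading ensemble
summaries: the null's mean per-gene slope sits very slightly above 1 at
finite depth (about $+10^{-3}$ at 2.5 M reads; the acceptance script
computes it). The filter conditions on the *observed* reference-library
count, so genes near the threshold are retained preferentially when that
count fluctuates upward, and the same fluctuation carries the largest
regression weight. The bias shrinks with depth and with the filter
threshold's distance from typical counts; it is a property of the
estimator itself, present for real data and null alike, and therefore
does not affect protocol-versus-null comparisons.

## Intrinsic and extrinsic noise of paired runs

Low-input protocols pre-amplify the cDNA once per sample; libraries can
then be re-prepared (e.g. with different tagmentation dilutions) from the
same amplified pools. For two such runs, per-gene slopes are matched by
gene identifier after each run's own filter, and

$$\eta_{int} = \mathrm{sd}(m_1 - m_2), \qquad
  \eta_{ext} = \mathrm{sd}(m_1 + m_2),$$

with the sample ($n-1$) convention throughout, so that
$\mathrm{var}(m_1-m_2) + \mathrm{var}(m_1+m_2) =
2\,\mathrm{var}(m_1) + 2\,\mathrm{var}(m_2)$ holds as an exact identity.
Biases shared by the two runs cancel in $m_1 - m_2$: if the runs share a
pre-amplification batch, $\eta_{int}$ excludes the pre-amplification
noise, and comparing it with the $\eta_{int}$ of a cross-batch pairing
estimates that step's contribution.

## What the synthetic generator emulates — and what it does not

`generate_experiment()` produces count tables with the statistical
structure the analysis assumes: a log-uniform expression profile spanning
`dynamic_range` (chosen over a lognormal for its explicit, heavy-tailed
span; the spike genes then densely cover the whole abundance range),
spike mass exactly equal to the top mixture level, the even-redistribution
mixture rule, and multinomial sequencing. Pre-amplification bias is
modelled minimally: one lognormal$(0, \texttt{bias\_sd})$ factor per gene
*and per mixture level*, drawn once per `preamp_id` batch and shared by
every run generated under that batch label, then renormalized. The
per-level draw matters: a bias constant across all levels of a gene is a
pure per-gene scale factor and cancels exactly under the normalization —
it would be invisible to every downstream statistic. A per-level bias
instead perturbs slopes, and its cancellation in same-batch pairs is what
gives the intrinsic/extrinsic contrast. Optional Dirichlet-multinomial
overdispersion adds extra-multinomial noise independent of batches.

Deliberately not modelled: sequence-content effects (GC, priming
hexamers), mapping ambiguity between the two genomes, PCR duplication and
library-complexity saturation, and any enrichment-cycle effects on shared
pools. Passing tests on synthetic data therefore demonstrate that the
*statistical machinery* is correct under the stated model, not that any
particular real protocol is linear; with real data the same code answers
that question empirically.

Seeds are split deterministically into independent streams (profile,
per-batch bias, per-run draws), so varying one component never perturbs
another, and every function that consumes randomness restores the
caller's RNG state.

## Numerical and design choices

* Subsampling to equal depth is a multivariate hypergeometric draw on
  each count vector — statistically identical to uniformly subsampling
  mapped reads and recounting — implemented as sequential conditional
  `rhyper` draws, exact and $O(\text{genes})$ per library.
* Standard deviations and IQRs: sample ($n-1$) convention; quartiles by
  linear interpolation (`quantile` type 7).
* Two-protocol comparison of per-gene correlations uses Welch's $t$ (no
  variance-equality assumption is defensible across protocols). Groups
  with zero variance are flagged degenerate rather than producing
  divide-by-zero statistics; genes with undefined $r$ (flat response) are
  excluded from mean $r$ but counted and reported.
* HTSeq `__`-prefixed summary counters are parsed and preserved but never
  enter depth or analysis.
* The molar-mass constant 608.9 g/mol per bp is used verbatim in the
  yield formula, matching the fluorometric-quantification convention the
  formula was defined with.
* Test and acceptance problem sizes: property tests run 1,000 random
  cases; the simulation-recovery check uses 6,000 background + 2,000
  spike genes at 2.5 M reads and 20 replicates; the paired-run noise
  check uses 50 seeded experiments at `bias_sd = 0.2`. These sizes give
  sub-minute runs while leaving Monte-Carlo error well below the effects
  being checked.

## Known limitations

* The analysis assumes the spike series was physically accurate; pipetting
  error in the mixture fractions enters as an unmodelled $x$-axis error.
* Only spike-species genes are assessed; background genes serve as
  carrier mass.
* The mean-slope selection bias described above is inherent to filtering
  on an observed count; at the default depth it is ~0.1% and immaterial
  for protocol comparison, but exact unbiasedness should not be asserted
  from ensemble means.
* Absolute abundances are never compared across protocols; the package
  makes no attempt at between-protocol calibration.
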