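---
title: "Methods: flow-conservation modelling of ribosome profiling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-conservation modelling of ribosome profiling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboflow)
library(dplyr)
```

## The model

Ribosome profiling reports, at codon resolution, where translating
ribosomes sit at steady state. `riboflow` treats the observed footprint
count $d_{mk}$ at codon $k$ of message $m$ as a sparse sample from the
steady-state ribosome occupancy. Under flow conservation — ribosomes that
initiate also terminate, with no drop-off — the protein synthesis rate
(flux) $J_m$ is the same at every position, and

$$ J_m \propto \frac{d_{mk}}{\mu_{mk}}, $$

where $\mu_{mk}$ is the dwell time of the ribosome on that codon: slow
codons are occupied longer and accumulate proportionally more footprints.
Because a single dataset cannot support a free parameter per position, the
model shares one dwell $\mu_m^c$ across all occurrences of codon $c$ on
message $m$, and ties these softly to a global codon dwell $\mu^c$:

$$
\min \;
\sum_m \sum_{k \in k'_m} \left( \log d'_{mk} - \log \mu_m^{c(m,k)} \right)^2
\; + \; C \sum_c \sum_m w_m^c \left( \log \mu_m^c - \log \mu^c \right)^2 .
$$

The weight $w_m^c$ is the number of occurrences of $c$ on $m$ divided by
its occurrences overall, so genes that use a codon heavily get a larger
vote in the global estimate; the minimiser of the penalty alone is the
weighted geometric mean of the per-gene dwells. $C$ (default 100) balances
the two terms; fitted dwells are empirically stable over $C \in [1, 10^4]$
(this is asserted in the test suite).

Squared error on log counts is used as the data term. Its per-codon
minimiser is a (weighted) geometric mean, which is robust to the heavy
upper tail of footprint counts; a Poisson quasi-likelihood data term
($\sum \mu - d' \log \mu$) is available via `loss = "poisson"` for users
who prefer a count likelihood. The two give highly correlated global
dwells on simulated data.

### Count transformation

Counts receive a pseudo-count of 1 (so zeros survive the logarithm), are
flow-normalised by the fixed per-gene flux, and all values are multiplied
by one global factor chosen so that the smallest transformed count is
exactly 1 — anchoring the scale so log-residuals are non-negative at the
floor. The training region $k'_m$ excludes the first 100 codons (the first
25% for genes under 100 codons): the 5' region has atypical occupancy, and
if it did not, excluding it would not change the estimates. The stop codon
carries no parameter. The target mean of the initial log dwells is
recomputed from each dataset as $\log(\textrm{mean } d')$ rather than
hard-coded, so the procedure transfers across datasets of any depth.

Two count axes leave the transformation:

* `dprime` — pseudo-counted, flow-normalised, globally scaled: the
  training axis for dwell estimation.
* `dscaled` — pseudo-counted and globally scaled only: the count axis on
  which final fluxes and outlier expectations live. Flow-normalising here
  would cancel the very flux differences the model is meant to estimate.

### Optimisation

With fluxes fixed, the objective separates across codons, and under the
log-Gaussian loss each codon block has an exact closed form: with
$\beta_m = \log \mu_m^c$, $y$ the log transformed counts, $S_m$ and $n_m$
their per-gene sums and counts,

$$ \beta_m = \frac{S_m + C w_m b}{n_m + C w_m}, \qquad
   b = \frac{\sum_m w_m \beta_m}{\sum_m w_m}, $$

which reduces to one linear equation in $b$. Coordinate descent over
codons (fixed lexicographic order, for determinism) therefore converges in
a single sweep; the loop still runs the standard stopping rules (parameter
change $< 5\times10^{-5}$ or objective change $< 10^{-5}$) so the Poisson
variant, solved per codon by L-BFGS in log space, uses the same machinery.
The objective trace is recorded and asserted non-increasing. The
initialisation (baseline dwells, recentred in log space, plus a seeded
uniform perturbation of $\pm 0.01$) is immaterial for the closed-form path
but kept so all variants share one contract: identical seeds give
bit-identical fits.

Final fluxes are the dwell-corrected mean counts over the full gene body,
$J_m = \sum_k (d_{mk}/\mu_m^{c(m,k)})/L_m$ on the `dscaled` axis, with the
global dwell standing in wherever a gene lacks a per-gene parameter
(positions before codon 100, or genes whose restricted region is empty —
e.g. exactly 100 codons long — which are excluded from training but still
receive a flux). A consequence of the min-to-1 anchoring is that the
absolute dwell scale shifts slightly with sequencing depth; relative
dwells, normalised rates (`codon_rates()`, slowest codon = 1) and flux
ratios are the meaningful outputs.

## Pausing outliers

A position pauses if its observed count exceeds the model expectation
$J_m \mu_m^c$ by more than its noise scale:
$\Delta_{mk} = (d'_{mk} - J_m\mu_m^c)/s_{mk}$. The scale $s_{mk}$ is the
sample standard deviation (ddof 1, appropriate for the small cells the
binning rule guarantees) of scaled counts within an abundance-bin ×
codon cell; genes are binned into 32 abundance quantiles (abundance =
mean footprint count $D_m$), automatically reduced to the largest number
of bins at which every cell keeps at least three counts and a nonzero
standard deviation. Slow outliers have $\Delta > T$; non-outliers have
$-1 < \Delta < 1$. Candidate *fast* outliers are excluded from
comparisons: a position with far fewer counts than expected is more
plausibly an A-site misattribution from an adjacent slow position than a
genuinely fast codon.

A candidate feature (structure track, positional covariate, ...) is called
significant only when (a) its Pearson and Spearman correlations with
$\Delta$ among slow outliers share a sign and have $p < 0.05$ at every
threshold $T \in \{0, 0.5, 1, 1.5, 2, 2.5\}$, (b) the per-codon
correlation is significant for at least 30 codons, and (c) the sign
matches the slow-versus-non-outlier difference of feature means. The
built-in positional features are distance from the 5' end, relative
position, and distance from the 3' end; biological features arrive as
user-supplied tracks.

## Translation efficiency

$TE_m = J_m / M_m$ with $M_m$ the mRNA abundance, on the intersection of
genes valid in both samples. Mutant-versus-wild-type comparisons rank
genes by $|\log(TE_{mut}/TE_{wt})|$ (the log is symmetric in up- and
down-regulation; the default takes the top 200), count reduced
versus increased genes, and assess the imbalance by permuting the mutant
TE values (1,000 times by default) and recomputing the difference. Both
the one-sided p-value (fraction of permutations with difference at least
the observed) and the count of permutations below the observed difference
are reported.

One caveat is worth stating plainly: permuting mutant values tests
*exchangeability* of mutant TE across genes. When mutant and wild-type
TEs are nearly equal gene by gene — exactly the situation in which the
test is interesting — the permuted log-ratios are dominated by the
wild-type spread rather than by measurement noise, and the permutation
distribution no longer matches the observed statistic's distribution
(under a paired null it is measurably narrower: permutation cycles
cancel). Calibration therefore holds under the exchangeability null (we
verify type-I error at $\alpha = 0.05$ over 500 replicates), while under
a paired null the test can be anti-conservative; conclusions from it
should be treated as descriptive. (In practice, on near-identical
samples the permuted differences typically dwarf the observed one and
the test reads as conservative.)

## The Kozak-motif TE regression

Log TE (z-scored — TE is strictly positive and right-skewed, and the
reported error magnitudes only make sense on a standardised response) is
regressed on standardised gene features plus a learnable start-context
feature

$$ f^k = \frac{1}{1 + \exp(x \cdot g)}, $$

where $g$ one-hot encodes the 9 non-AUG positions ($-6..-1$, $+4..+6$) of
the 12-nt context and $x$ holds 36 weights, penalised by
$\lambda_1 \lVert w \rVert_1 + \lambda_2(\lVert w \rVert_2^2 +
\lVert x \rVert_2^2)$. Fitting alternates an exact coordinate-descent
elastic-net solve for $w$ (the intercept unpenalised) with BFGS steps on
the smooth objective for $x$, until the relative objective change falls
below $10^{-5}$ or 100 alternations. $x$ starts at small seeded random
values: at $x = 0$ the feature is constant, its weight is zero, and the
$x$-gradient vanishes — a saddle the perturbation escapes.

Because $(x, w_k)$ and $(-x, -w_k)$ fit identically (the sigmoid flips,
the intercept absorbs the shift), each split's solution is canonicalised
to $w_k \le 0$, which makes favourable bases carry the most positive
weights. The motif is averaged over `n_splits` random train/test splits
(default 100; tests and examples use fewer and say so) and exported as a
PWM by shifting each position's four weights so the minimum is zero and
normalising to sum 1 — the dominant PWM base is then the favourable one.
Hyperparameters are selected by 5-fold cross-validation on a grid
($10^{-3}..10$ crossed, user-overridable) on the first split and reused
across splits to keep desk-scale runtimes; `cv_per_split = TRUE` restores
the full procedure. The null model refits on permuted training TE with
the same penalties; its test error on standardised TE is ~1 by
construction, which the tests assert. A fixed (e.g. consensus) motif is
evaluated by freezing $x$ — rescaled so each position's weight sum
matches the learned motif's — and learning only $w$ over the same splits.

## DMS structure windows

Raw DMS counts (modification of accessible A/C bases) are normalised in
consecutive 150-nt windows: the divisor is the minimum count among the
top 5% of A/C positions (by rank, boundary ties included), values divide
by it and the top set is capped at exactly 1, giving reactivities in
$[0,1]$. A window is masked when fewer than 10 A/C nucleotides are
available to define the top 5%, or when the divisor is zero. We read the
"fewer than 10 in the top 5%" rule as a coverage filter: the top-5% set
of a full window holds only ~4 positions, so requiring the *set itself*
to have 10 members would mask essentially every window with distinct
counts, leaving the rest of the pipeline nothing to analyse. Masking is
deterministic and logged per window.

Sliding 40-nt windows (stride 1 — "sliding" is read literally) aligned to
the start codon are averaged per gene, normalised by the gene's mean
window value, then averaged across genes at each of the 280 default
positions (30 upstream, 250 downstream). TE correlations per window are
Spearman, Bonferroni-corrected by the number of windows. The energy dip is
the first position at or downstream of the start codon that is minimal
within a centred 90-nt span (truncated at the scan origin; ties go to the
smallest coordinate).

## The synthetic world

The generator inverts the model: $d_{mk} \sim
\textrm{Poisson}(\textrm{depth} \cdot J_m \cdot \mu_m^c \cdot
\textrm{fold}_{mk})$. Its defaults are fixed once and shared by the tests:

| quantity | default | why |
|---|---|---|
| genes × length | 200 × ~300 codons | the recovery-test scale |
| depth | 20 counts/codon | moderate coverage; dwells and fluxes have mean 1 so depth is the genome-wide mean count |
| global dwell spread | lognormal, sdlog 0.4 | a severalfold rate range between fastest and slowest codons, as observed in codon-rate estimates |
| per-gene dwell spread | lognormal, sdlog 0.2 | mirrors the soft-constraint structure of the model |
| flux spread | lognormal, sdlog 0.5 | severalfold variation in synthesis rates |
| mRNA abundance | lognormal, sdlog 1 | wide, as in expression data |
| pause sites | 2/gene, fold 10, uniform placement | sparse strong pauses when requested |

Poisson observation noise is the default (matching the model's likelihood
family); lengths are discretised lognormal (sdlog 0.3, floor 60). What the
generator does **not** emulate: ribosome queueing/collisions, drop-off,
ligation and sequence biases in library preparation, codon
autocorrelation along real transcripts, or UTR-dependent initiation. A
green recovery test therefore establishes that the estimator inverts its
own generative family at realistic depth — not that real libraries are
free of the biases the model ignores.

A TE generator plants a Kozak effect (`simulate_te_dataset`): log TE =
linear features + effect × $f^k$(context; planted motif) + Gaussian
noise, with the planted motif supplied favourable-positive and negated
inside the sigmoid so consensus contexts gain the effect. A DMS generator
(`simulate_dms_counts`) gives A/C positions Poisson counts proportional
to accessibility × depth with a 5% background on G/T, so structure bands
planted at known coordinates test dip localisation end to end.

## Numerical and design notes

* Coordinates are 0-based codon indices (half-open ranges); sequences are
  stored as DNA, with U normalised to T on input.
* A-site assignment: reads of 28–31 nt; offsets 15/16/17 nt for reads
  starting on the first/last/middle nucleotide of a codon. Multi-mapping
  across overlapping genes is assumed resolved upstream (one gene per
  read); duplicate gene ids are an error, not last-wins, since silent
  overwrites hide corruption.
* The flux is computed in a single pass (fix $J = D_m$, fit dwells,
  recompute $J$ once); the fit object retains everything needed to iterate
  externally if desired.
* Numeric tables are written at 17 significant digits and parsed by
  strtod, so write–read round trips are bit-exact.
* Degenerate inputs: genes with all-zero counts must be filtered before
  transformation (the flux normaliser would be 0); a dataset in which some
  codon has constant counts in every binning admits no valid noise scale
  and `fit_noise_bins()` errors rather than returning zero scales.
* Known limitations: no drop-off or interference modelling; per-position
  dwell variants are sensitive to initialisation (their global dwells are
  still stable); the outlier false-positive rate is higher outside the
  restricted region, where per-gene dwells are extrapolated rather than
  fitted.
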