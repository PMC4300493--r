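# riboflow

Statistical inference of translation dynamics from ribosome profiling
(ribo-seq) data.

Ribosome profiling counts ribosome-protected mRNA fragments at codon
resolution, but turning those counts into biology is non-trivial: a codon
can carry many footprints because the gene is highly translated *or*
because the ribosome dwells there for a long time. `riboflow` separates
the two under a steady-state **flow-conservation model**: if ribosomes do
not drop off, the protein synthesis rate (flux) `J_m` of message `m` is
constant along the message, and the observed count `d_mk` at codon `k` is
proportional to `J_m · μ_mk`, where `μ_mk` is the ribosome dwell time.
The package estimates per-gene per-codon dwell times `μ_m^c`, softly tied
to global codon dwells `μ^c`, by minimising

```
Σ_m Σ_{k∈k'} ( log d'_mk − log μ_m^{c(m,k)} )²
   + C · Σ_c Σ_m w_m^c ( log μ_m^c − log μ^c )²
```

over pseudo-counted, flow-normalised counts `d'` (first 100 codons of
each gene excluded from training), then recomputes fluxes as
dwell-corrected mean counts, `J_m = Σ_k (d_mk/μ_mk)/L_m`. From there it
derives:

* **translation efficiency** `TE_m = J_m / M_m` (flux over mRNA
  abundance), with mutant-vs-wild-type comparison tools (top-deviating
  gene counts, per-codon TE correlations, a permutation test);
* **pausing outliers** — positions where elongation is slower than the
  codon predicts, `Δ_mk = (d'_mk − J_m μ_m^c)/s_mk`, with abundance-binned
  noise scales and a stringent feature-significance evaluator;
* a **TE regression with a learnable Kozak motif** — elastic net over gene
  features plus a sigmoid start-context feature `f^k = 1/(1+exp(x·g))`
  whose 36 weights are learned and exported as a PWM;
* **DMS structure-probing analyses** — reactivity normalisation in 150-nt
  windows, sliding 40-nt window profiles aligned to the start codon, TE
  correlations with Bonferroni correction, and energy-dip detection;
* a **synthetic-data generator** with full ground truth (dwells, fluxes,
  pause sites, planted motifs, structure bands) so every estimator is
  testable by parameter recovery.

It is intended for computational biologists analysing ribo-seq count
tables (the package consumes aligned A-site positions or per-codon
counts; it does not align reads).

## Worked example

Simulate a dataset with known truth, fit the model, and inspect recovery:

```r
library(riboflow)
library(dplyr)

sim <- simulate_ribo_dataset(n_genes = 200, mean_len = 300, depth = 20,
                             seed = 42)
fit <- fit_flow_model(sim$profiles, C = 100, seed = 1)
fit
#> <flow_fit> per_gene_codon/log_gaussian, C = 100
#>   genes: 200; codons: 61; sweeps: 2
#>   objective: 2352.795

head(tidy(fit), 3)   # global dwells and min-normalised rates
#> # A tibble: 3 × 3
#>   codon    mu  rate
#>   <chr> <dbl> <dbl>
#> 1 AAA    47.7  1
#> 2 AAC    23.4  2.04
#> 3 AAG    18.8  2.54

cor(inner_join(fit$dwell_global, sim$truth$mu_global, by = "codon") %>%
      select(mu.x, mu.y), method = "spearman")[1, 2]
#> 0.997   # fitted vs true codon dwells
cor(inner_join(fit$flows, sim$truth$J, by = "gene_id") %>%
      select(J.x, J.y))[1, 2]
#> 0.995   # fitted vs true fluxes

te <- compute_te(fit, sim$abundance)
head(te, 3)
#> # A tibble: 3 × 2
#>   gene_id    te
#>   <chr>   <dbl>
#> 1 g0001   35.3
#> 2 g0002    5.44
#> 3 g0003   26.4

deltas <- classify_outliers(outlier_deltas(fit), T = 1)
sum(deltas$class == "slow")
#> 6248    # positions slower than the model expects, of 61504
```

The codon with dwell 47.7 is the dataset's slowest (`rate = 1` after
min-normalisation); a rate of 2.5 means elongation off that codon is 2.5×
faster than off the slowest one. `TE` is on the arbitrary-but-consistent
scale of flux over abundance; ratios between genes or samples are the
meaningful quantity.

Real data enter through `read_cds_fasta()`, `read_counts_table()` and
`read_abundance_table()`, are quality-filtered by `filter_genes()`
(AUG start, no internal stops, mRNA coverage, nonzero footprints) and
assembled by `prepare_profiles()`; `assign_asite()` converts aligned read
positions to A-site codons (28–31-nt reads, phase-dependent 15/16/17-nt
offsets). See the methods vignette (`vignettes/riboflow-methods.Rmd`) for
the model, its assumptions, and every tunable parameter. A thin CLI over
these functions is installed at `inst/scripts/riboflow.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's core computation from
scratch — simulating a ground-truthed dataset, fitting the
flow-conservation model, and deriving rates, fluxes, TE and outliers —
and writes a JSON results file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

`--seed` controls every source of randomness; identical seeds give
identical results.
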