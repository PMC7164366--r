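# clockdate

Bayesian divergence-time estimation for multi-gene coding data under
relaxed molecular clocks, with the Hessian-based approximate likelihood
that makes phylogenomic-scale dating tractable. The package re-implements,
as tested and reusable components, the complete workflow of a modern
dating study:

* **quality control** of coding alignments — pseudogene screening
  (internal stop codons, frameshift indels), exon-missingness filters,
  representative-individual selection, exon-to-gene concatenation;
* **rate partitioning** — per-gene relative rates from two-sequence HKY85
  maximum-likelihood distances, contiguous rate bins (3/6/10-partition
  schemes), codon-position splitting, and clocklikeness ranking for
  reduced-dataset experiments;
* **priors** — birth–death node-age kernel conditional on the root age
  (λ = μ = 1, ρ = 0.1 gives the familiar near-uniform density), hard/soft
  fossil calibrations with continuity-matched tails, and strict /
  independent-lognormal / autocorrelated (geometric Brownian motion) clock
  priors with Γ(2, 20) and Γ(2, 2) hyperpriors;
* **likelihood** — exact HKY85+Γ pruning (compiled, pattern-compressed),
  branch-length MLEs, and the quadratic surface
  ℓ(b) ≈ ℓ(b̂) + gᵀ(b − b̂) + ½(b − b̂)ᵀH(b − b̂) on unrooted branches;
* **MCMC** — Metropolis–Hastings over node ages, branch rates, and
  hyperparameters, with burn-in step-size tuning, a likelihood-invariant
  age/rate rescaling move, power-posterior support, Tracer-compatible
  traces, ESS, and posterior summaries;
* **model selection** — stepping-stone marginal likelihoods with standard
  errors and posterior model probabilities over {STR, IR, AR};
* **diagnostics** — infinite-sites regressions (95% CI width against
  posterior mean age) and complete-vs-reduced dataset comparisons;
* **synthetic data** — timetrees from the birth–death kernel, branch rates
  under all three clocks, HKY85+Γ coding alignments with codon-position
  effects, and pseudogene/missingness corruption with a ground-truth log.

Ages are in Ma everywhere; rates are per site per 100 Myr (so the
Γ(2, 20) prior mean 0.1 is a typical slow mammalian 10⁻³/site/Myr).

## Worked example

Posterior clock-model probabilities from published stepping-stone log
marginal likelihoods (1 gene, 20 species), under equal model priors:

```r
library(clockdate)
tab <- clock_model_logml_table()
rows <- tab[tab$data_label == "1g_20s", ]
round(model_posterior_probs(setNames(rows$log_ml, rows$model)), 3)
#>    AR    IR   STR
#> 0.993 0.007 0.000
```

The autocorrelated-rates model wins decisively: its log marginal
likelihood (−4176.4) beats the independent-rates model by ~5 log units and
the strict clock by ~18, which the softmax turns into Pr(AR) = 0.993.

A miniature end-to-end dating run on synthetic data:

```r
cfg <- pipeline_config(out_dir = "run1", n_taxa = 8, n_genes = 12,
                       n_codons = 100, n_iter = 6000, sample_every = 5)
res <- run_pipeline(cfg)
head(res$summary[!is.na(res$summary$node), c("parameter", "mean", "q2.5", "q97.5")])
#>   parameter     mean      q2.5    q97.5
#> 1       t_9 36.85459 33.669615 39.73596
#> 2      t_10 34.98176 32.262912 38.68167
#> 3      t_11 34.00313 30.544053 36.83122
#> 4      t_12 26.95550 22.885993 31.41555
#> 5      t_13 17.67307 14.046636 22.02466
#> 6      t_14 12.77472  9.453915 16.76521
```

Each row is an internal node: posterior mean age and equal-tail 95%
credibility interval in Ma (here the true root age was 36.4 Ma and every
true node age falls inside its interval). `run_pipeline()` writes the QC
report, gene rate table, partition files, per-partition likelihood
surfaces, traces, the dated Newick tree, and the infinite-sites fit into
`out_dir`, all stamped with the configuration hash and seed; re-running
with an unchanged configuration skips completed stages byte-identically.

The `analysis/` directory holds the same workflow as a sequence of
narrative scripts (`01_simulate.R` … `06_diagnostics.R`), each writing its
tables under `results/`.

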