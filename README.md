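# emtstate

Colon cancer cell lines harbor, next to their dominant epithelial
population (CD44^hi/EpCAM^hi), a small quasi-mesenchymal subpopulation
(CD44^hi/EpCAM^lo) that is motile, invasive and metastasis-prone. Sorted
pure cultures of either state drift back to the same mixed composition,
which means the two states interconvert stochastically and sit in a
dynamic equilibrium. `emtstate` is an R package for the quantitative side
of this biology, aimed at researchers analyzing cell-state plasticity in
FACS time courses, single-cell RNA-seq, and bulk tumor cohorts.

It provides three connected toolsets:

1. **Two-state dynamics** — the linear growth/switching model

   dH/dt = (g_hi − k_HL)·H + k_LH·L,  dL/dt = (g_lo − k_LH)·L + k_HL·H,
   g = ln2/T,

   solved exactly (`simulate_deterministic`), its closed-form stable
   equilibrium lo-fraction (`equilibrium_lo_fraction`), rate calibration
   from published summaries (`calibrate_rates`, `cell_line_fixture`),
   two-stage least-squares fitting of doubling times and transition rates
   from time courses (`fit_doubling_times`, `fit_transition_rates`), a
   per-cell stochastic simulator (`simulate_stochastic`), and
   deterministic subclone competition (`simulate_clonal_competition`).

2. **EMT scoring** — library-size normalization, z-score gene-set scoring,
   the EMT (= M − E) and partial-EMT (= min(E, M)) statistics with
   deterministic EMT-axis ranking (`emt_pemt`), windowed expression trends
   along the axis (`smooth_trend`), hybrid-cell flagging (`hybrid_cells`),
   and k-means gene programs (`gene_program_clusters`).

3. **Signatures & survival** — meta-gene tracks (`metagene`,
   `correlate_tracks`), derivation of a tumor-cell-intrinsic signature by
   correlating genes (Pearson r > 0.3, strict) with a reference signature
   inside the epithelial compartment (`derive_epithelial_signature`),
   mes-like cell annotation (`annotate_mes_like`), patient grouping by
   k-means or tertiles, and Kaplan–Meier/log-rank comparisons
   (`km_logrank`).

Synthetic-data generators (`generate_facs_timecourse`,
`generate_sc_counts`, `generate_cohort`) emulate each experiment with
known ground truth, so the full pipeline installs, runs and validates
itself without external downloads. `run_end_to_end()` chains everything
into one reproducible report.

## Worked example

The HCT116 fixture is calibrated at call time from four published
summary values — doubling times 1.00/1.09 days, a lo-to-hi vs hi-to-lo
transition ratio of 8.1, and a 5.0% equilibrium EpCAM^lo fraction:

```r
library(emtstate)

fx <- cell_line_fixture("HCT116")
fx
#> Two-state model parameters
#>   doubling times: T_hi = 1 d, T_lo = 1.09 d
#>   transition rates: k_HL = 0.00498814 /d, k_LH = 0.0404039 /d (ratio 8.1)
#>   per-day switch probabilities: hi->lo 0.00497572, lo->hi 0.0395986
```

A pure EpCAM^hi culture relaxes to the 5% equilibrium, and fitting the
model back to noiseless trajectories from both pure starts recovers the
8.1-fold rate asymmetry:

```r
tail(simulate_deterministic(fx, c(hi = 1, lo = 0), c(0, 150))$fraction_lo, 1)
#> [1] 0.04999998

tc_hi <- simulate_deterministic(fx, c(hi = 1, lo = 0), c(0, 3, 7, 14, 21, 28))
tc_lo <- simulate_deterministic(fx, c(hi = 0, lo = 1), c(0, 3, 7, 14, 21, 28))
fit <- fit_transition_rates(tc_hi, tc_lo, fx$T_hi, fx$T_lo)
fit$ratio
#> [1] 8.1
```

On simulated single cells the EMT score tracks the latent
epithelial→mesenchymal axis, and a SPARC-like midpeak gene peaks between
the extremes:

```r
sim  <- generate_sc_counts(sc_sim_config(seed = 7))
norm <- normalize_counts(sim$counts)
sc   <- emt_pemt(score_gene_set(norm, sim$gene_sets$epithelial),
                 score_gene_set(norm, sim$gene_sets$mesenchymal))
cor(sc$EMT, sim$cells$t_true, method = "spearman")
#> [1] 0.979358

trend <- smooth_trend(norm, sim$gene_sets$midpeak[1], sc$rank)
which.max(trend$smoothed) / nrow(sc)   # argmax position on the axis
#> [1] 0.4983333
```

On the synthetic cohort, the tumor-cell signature derived inside the
epithelial compartment recovers the planted program, and the high
meta-gene tertile shows the worst survival:

```r
coh <- generate_cohort(cohort_sim_config(seed = 7))
sig <- derive_epithelial_signature(coh$sc$values, coh$sc$cells$compartment,
                                   coh$gene_sets$reference)
mean(coh$gene_sets$planted %in% sig$members)   # recall of planted genes
#> [1] 1

groups <- expression_groups_tertiles(metagene(coh$bulk, sig$members))
surv <- coh$survival; surv$group <- groups[surv$sample_id]
km <- km_logrank(surv)
c(chisq = km$chisq, p = km$p)
#>        chisq            p
#> 2.049093e+01 3.551815e-05
```

Median survival drops from 18.6 months (low group) to 5.4 months (high
group) in this simulation — the planted hazard effect, recovered end to
end through signature derivation, meta-gene scoring and grouping.

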