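# crossnet

Multi-tissue transcriptome analysis for intervention studies: differential
expression, direction-aware treatment-reversal statistics, tissue-specific
co-expression modules with cross-tissue module correlation, gene-set
enrichment, and flux-balance-based metabolic reaction-activity scoring — with
a bundled synthetic multi-tissue data generator so every stage can be
validated by parameter recovery, no downloads required.

## Who this is for

Systems-biology analysts working with designs like: rats drink
sucrose-sweetened water, subsets additionally receive a JNK-inhibitor
treatment at one of two doses, and liver, visceral adipose, skeletal muscle
and brain are RNA-sequenced from the *same animals*. The questions the
package answers:

1. **Which genes does the intervention move, and does the treatment move them
   back?** Per-gene NB Wald contrasts (median-of-ratios normalization, BH
   adjustment, DEGs at adjusted p < 0.01), then *suppressed* =
   intervention-up ∩ treatment-down and *restored* = intervention-down ∩
   treatment-up, with upper-tail hypergeometric overlap p-values and Jaccard
   similarity, plus cross-tissue log₂FC concordance of shared DEGs
   (sign agreement and Spearman ρ).
2. **Which co-expression modules exist, and which talk across tissues?**
   Spearman networks (edges = top decile of positively correlated gene pairs
   passing FDR < 0.05), Leiden modules (modularity objective, modules < 30
   genes discarded), module eigengenes (first principal component of the
   gene-standardized module matrix), module–DEG enrichment, and inter-tissue
   eigengene correlation matched by animal with BH control.
3. **How does predicted metabolic activity shift?** A reaction
   potential-activity score on stoichiometric models: per reaction, maximize
   flux under S·v = 0, then minimize expression-derived penalties
   (penalty = 1/(1+expr), GPR rules resolved with AND = min, OR = sum) while
   sustaining ≥ 95% of maximal flux; score = −log(optimal penalty).
   Differential activity via Wilcoxon + Cohen's d, with subsystem partitions
   and treatment-reversal fractions.

## Worked example

Simulate a two-tissue study (10 animals per group; 14% of genes perturbed by
sucrose, 60% of those reverted by the first treatment dose), run the sucrose
and treatment contrasts, and account for reversal:

```r
library(crossnet)

sim <- simulate_study(sim_config(tissues = c("Liver", "vWAT"),
                                 n_genes_per_tissue = 1000,
                                 n_animals_per_group = 10, seed = 2024))
ds  <- sim$datasets$Liver
suc <- nb_wald_contrast(ds, c("sucrose", "control"), alpha = 0.01)
d1  <- nb_wald_contrast(ds, c("D1", "sucrose"),      alpha = 0.01)
suc$degs
#> deg_sets: 50 up, 54 down (padj < 0.01, 1000 genes tested)
reversal_report(suc$degs, d1$degs)
#> reversal_report (background n = 1000 )
#>   suppressed: 30 of 50 intervention-up (60%), hypergeometric p = 9.24e-42
#>   restored:   29 of 54 intervention-down (53.7%), hypergeometric p = 1.03e-37
```

Reading it: of 104 sucrose DEGs detected (140 were planted; the rest sit
below the power of n = 10 at this effect-size distribution), 59 are
significantly moved in the opposite direction by the treatment — the
direction-aware estimate of the planted 60% reversal rate — and both overlaps
are far beyond chance for a 1000-gene universe.

The whole workflow (simulate → DE → reversal → networks/modules → enrichment
→ metabolic scoring → report) runs as one call:

```r
report <- run_pipeline(run_config(sim = sim_config(seed = 1),
                                  out_dir = "crossnet_out"))
report          # prints DEG counts/percentages, reversal percentages,
                # module sizes, significant cross-tissue pairs, reaction
                # activity summaries, and per-stage provenance
```

Every intermediate lands as TSV/JSON under `out_dir`; rerunning with
`resume = TRUE` reloads finished stages and recomputes only what is missing
or downstream of a change. A thin command-line wrapper with the same stages
as subcommands lives at `inst/scripts/crossnet.R`.

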