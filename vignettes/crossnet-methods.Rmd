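---
title: "Methods: multi-tissue co-expression, reversal statistics and reaction activity"
author: "crossnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue co-expression, reversal statistics and reaction activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnet)
```

crossnet analyses multi-tissue bulk RNA-seq intervention studies of the kind
where animals receive a dietary intervention (here: sucrose-sweetened water)
with or without a drug treatment at one or two doses, and several tissues are
profiled from the same animals. The package asks three questions of such a
design: which genes does the intervention move and does the treatment move
them back; which co-expression modules exist per tissue and which module pairs
are correlated *across* tissues in the same animals; and how does predicted
metabolic reaction activity shift between groups. Every stage is exercised
end-to-end on a bundled synthetic data generator with known ground truth, so
the statistical machinery is validated by parameter recovery rather than by
eyeballing.

## The synthetic study generator

`simulate_study()` emulates a four-group design (`control`, `sucrose`, and
`sucrose` plus a treatment at doses `D1` and `D2`; default 10 animals per
group, after a study enrolling 11 per group with some dropout at sequencing)
across four tissues sharing animal IDs. The generative model, per tissue:

* Baseline means are log-normal (`baseline_meanlog = log(100)`,
  `baseline_sdlog = 1`), giving the heavy-tailed abundance distribution of
  bulk RNA-seq.
* Counts are negative binomial with the dispersion trend
  $\phi = a_0/\mu + a_1$ ($a_0 = 1$, $a_1 = 0.05$): Poisson-dominated at low
  counts, a ~22% biological CV floor at high counts, typical of laboratory
  rodent cohorts.
* A fraction `frac_sucrose_deg` (default 0.14, matching the share of the
  transcriptome the intervention moved in the most responsive tissue) of
  genes is differentially expressed under sucrose, half up and half down,
  with $|\log_2 \mathrm{FC}| = \max\{N(\mu_{\mathrm{lfc}},
  \sigma_{\mathrm{lfc}}), 0.25\}$ — location/scale are the tunable knobs, the
  0.25 floor keeps "planted DEG" meaningful.
* Reversal: a fraction of planted DEGs (defaults 0.6 for `D1`, 0.3 for `D2`)
  returns fully to the control baseline under treatment; the rest retain the
  sucrose effect. Full return-to-baseline is deliberate: the downstream
  statistic only observes signed significance, so partial reversal would
  conflate effect size with the reversal rate.
* Modules: disjoint gene blocks receive a per-animal latent factor acting as
  a multiplicative $2^{\lambda f}$ perturbation (`module_loading`
  $\lambda = 0.5$ by default). Selected module pairs in *different* tissues
  share a common standardized factor mixed to a target correlation
  (`cross_module_corr`), joined by animal ID — the generative analogue of
  inter-tissue crosstalk.
* Library sizes are log-normal (`libsize_log_sd = 0.2`) and multiply all
  means before sampling.

What the generator does **not** emulate: batch effects, gene length biases
beyond TPM bookkeeping, isoform structure, count outliers, or dropout of
individual animals. Passing recovery tests therefore demonstrates that the
statistics read back what the model plants, not that real data satisfy the
model; on real data the DESeq2-grade machinery the package deliberately
simplifies (below) will behave differently in the tails.

A fixed `seed` fixes every output bit; all downstream stages take and log
their own seeds and thresholds.

## Differential expression

`nb_wald_contrast()` is a deliberately simplified stand-in for the DESeq2
analysis a real study would run. Counts are normalized with median-of-ratios
size factors (`size_factors()`: reference = per-gene geometric mean over
genes positive in all samples). Per gene, a shared dispersion is estimated by
method of moments on normalized counts (pooled within-group variance, floored
at $10^{-8}$), the fold change is the log-ratio of group means (an all-zero
group receives a 0.5-count offset), and the Wald statistic divides the
natural-log fold change by a delta-method standard error:

$$\mathrm{SE}^2 = \left[\frac{1/\bar m_1 + \hat\phi}{n_1} +
  \frac{1/\bar m_2 + \hat\phi}{n_2}\right]\left(1 + \frac{2}{n_1+n_2-2}\right).$$

The trailing factor is the first-order correction for plugging in a noisy
dispersion estimate — the Wald analogue of referring $t^2$ rather than $z^2$.
Without it, simulation at $n = 10$ per group shows ~6.7% of null genes below
$p = 0.05$; with it, 4.9–5.3%, and an oracle given the true dispersion gives
4.9%. P-values are two-sided normal with BH adjustment; DEGs are called at
adjusted $p < 0.01$ and split by sign.

Not reproduced, on purpose: dispersion shrinkage across genes, Cook's
distance outlier handling, independent filtering, and the parametric
variance-stabilizing spline (`vst_surrogate()` is $\log_2(\text{normalized}
+ 1)$). DEG counts on real data will differ from a full DESeq2 run; none of
the package's validated claims depend on them.

One behaviour worth knowing: median-of-ratios assumes most genes unchanged.
If planted (or real) DEGs are heavily one-sided, the reference shifts and
fold changes acquire a compositional bias — the simulator plants balanced
up/down sets, and the unbiasedness test uses that balance.

## Reversal accounting

`reversal_report()` intersects signed DEG sets: *suppressed* =
intervention-up ∩ treatment-down, *restored* = intervention-down ∩
treatment-up. Percentages are always `100 k/n` of the two printed integers
(`format_pct()`, 1 decimal by default, integer mode available), reported as
not-applicable — never 0 — when the intervention set is empty. Overlap
significance is the upper-tail hypergeometric probability with category = the
intervention set, draw = the opposite-signed treatment set, and population
`background_n` defaulting to the genes tested in the tissue (the full
protein-coding universe can be supplied instead; both conventions appear in
published work). The Jaccard index of the same two sets accompanies each
overlap. `cross_tissue_concordance()` compares the fold changes of DEGs
shared by two tissues: fraction of same-sign pairs and the Spearman
correlation (t-approximation; undefined below 3 shared genes).

## Co-expression networks and modules

Per tissue, genes with mean TPM below 1 are removed (`filter_low_expression()`;
the boundary value is kept). `build_network()` computes all-pairs Spearman
correlations, BH-adjusts the t-approximate p-values across all tested pairs,
keeps positively correlated pairs passing FDR < 0.05, and then retains the
top decile of those candidate edges by correlation — the "top 10% positively
correlated" rule read as a cut on candidate *edges*, since correlation is a
pairwise quantity (a node-strength reading would discard 90% of genes
outright; the retained-edge graph achieves the same hub-selection effect
while keeping ties explicit). The FDR filter is applied before the decile
cut, and both parameters are recorded on the result. Pairs involving
constant genes are excluded and counted. Spearman makes the network
invariant to monotone transforms, so TPM versus log-TPM input is immaterial.

`detect_modules()` runs Leiden community detection with the modularity
objective on the correlation-weighted graph (seeded, 10 iterations);
communities under 30 genes — and genes without retained edges — go to the
unassigned set. Modules are labelled by decreasing size (`Liver.M0` the
largest). The module eigengene is the first right singular vector of the
gene-standardized module submatrix: a unit-norm per-sample summary whose sign
is fixed to correlate positively with mean standardized module expression, so
repeated runs and negated inputs agree up to convention.
`module_deg_enrichment()` tests each module against each signed DEG set
(hypergeometric, BH across the table) and `module_patterns()` names the joint
patterns, e.g. a module elevated by the intervention and suppressed by
treatment. `cross_tissue_module_correlation()` aligns eigengenes of two
tissues by animal ID, computes Spearman correlations for every inter-tissue
module pair and BH-adjusts across all pairs tested.

Numerical and design notes, from the recovery experiments:

* **Desk-scale decile sparsity.** On a 150-gene planted panel (3 × 50 genes,
  loading 0.9, 40 samples) the decile cut keeps ~370 of ~3700 candidate
  edges. All retained edges are intra-module — edge purity is how the cut is
  validated — but the surviving subgraphs are sparse enough that modularity
  optimally splits them below the 30-gene floor. Module-recovery tests
  therefore score the detection stage on the FDR-complete positive network
  (`top_frac = 1`), where the adjusted Rand index against the planted
  partition is 1.0 across 20 seeds. At study scale (thousands of retained
  genes, modules of hundreds) the decile cut and the 30-gene floor are
  compatible; at panel scale, lower `min_size` or raise `top_frac`.
* **TPM is compositional.** When planted modules occupy a large share of a
  small panel, a module factor's excursions move the library total, inducing
  anti-correlation in all other genes — background genes can then form their
  own module, and module factors mix. With modules at ~15% of a 1000-gene
  panel the effect is negligible (eigengene–factor correlation 0.994), and
  the cross-tissue coupling fixture is built that way: a planted eigengene
  coupling of 0.7 over 40 animals is recovered within the Fisher confidence
  interval of the observed Spearman R, whose expectation for a bivariate
  normal coupling $\rho$ is $\tfrac{6}{\pi}\arcsin(\rho/2) \approx 0.68$.
* Planted-module fixtures draw baselines as *expressed* genes (log-normal,
  sdlog 0.5) since module detection operates after the TPM filter.

## Gene-set enrichment

`enrich()` is one-sided hypergeometric over-representation of a query list
against a GMT collection (`read_gmt()`/`write_gmt()`), with set members
intersected to the universe and BH adjustment across the collection's sets.
The universe defaults to the genes tested in the relevant tissue — standard
over-representation practice. The kernel is literally `hypergeom_overlap()`,
the same function the reversal statistics use, so the two surfaces cannot
drift apart. Browser-era enrichment backends apply slightly different Fisher
variants; exact parity with them is not claimed.

## Metabolic reaction activity

`compass_scores()` implements a flux-balance-based potential-activity score
on small stoichiometric models (`metabolic_model()`, BiGG-style JSON I/O).
Gene rules are resolved per sample by `reaction_expression()` with AND = min
(limiting subunit) and OR = sum (isoenzymes add capacity); genes missing from
the expression matrix count as zero with a warning. Each gene-associated
reaction carries the penalty $1/(1 + \text{expression})$; reactions without
rules carry zero penalty by default (they contribute no expression evidence;
a mean-penalty mode exists). Scoring a reaction solves two LPs on the
forward/backward-split system: maximize the reaction's flux subject to
$Sv = 0$ and bounds; if the maximum exceeds a blocked-reaction tolerance
($10^{-6}$), minimize total penalty-weighted absolute flux subject to the
reaction carrying at least $w = 0.95$ of its maximum. The score is
$-\log(\text{optimal penalty} + \varepsilon)$, $\varepsilon = 10^{-10}$; all
parameters are recorded on the result. The solver is a dense two-phase
simplex, which is exact and entirely adequate for the desk-scale models in
scope (tens of reactions); genome-scale reconstructions (10⁴ reactions),
meta-reaction clustering and downstream information-theoretic machinery are
out of scope, and ortholog mapping between species reduces to a user-supplied
gene-ID mapping. The three-reaction linear pathway
(`linear_pathway_model()`) makes the optimum hand-checkable: with the
conversion gene at expression 9, the optimal penalty is
$0.95 \times 10 \times \tfrac{1}{1+9} = 0.95$.

`differential_activity()` compares scores between groups per reaction with a
two-sided Wilcoxon rank-sum test — exact when the smaller group has ≤ 10
samples and no ties, else the tie-corrected normal approximation with
continuity correction — plus BH adjustment and Cohen's d (numerator minus
denominator over pooled SD). `reversal_of_activity()` reports the fraction
of intervention-altered reactions that are significantly altered with
opposite sign under treatment, and `subsystem_summary()` partitions
significant reactions by subsystem and direction.

## The pipeline

`run_pipeline()` chains the stages — simulate (or load TSV datasets), DE for
the three intervention contrasts, reversal accounting and cross-tissue DEG
concordance, per-tissue networks/modules with inter-tissue module
correlation, gene-set enrichment (against a supplied GMT, or gene sets
derived from the planted truth when simulating), and metabolic scoring on a
bundled ten-reaction toy model wired to the most-expressed genes — writing
every intermediate as TSV/JSON under the output directory. Reports carry a
config hash, the seed, and per-stage computed/cached status; a rerun with the
same config and seed reproduces the report bit-for-bit. With
`resume = TRUE`, stages whose artifacts exist are reloaded, and deleting one
intermediate recomputes that stage and everything downstream. Thresholds
default to the package-wide conventions: DEG adjusted $p < 0.01$, edge FDR
0.05, edge decile 0.10, module floor 30 genes, module/metabolic significance
0.05.

Problem sizes in the shipped tests and acceptance script are desk-scale by
design — 150–3000 genes, 8–40 animals, ten-reaction models — chosen so each
recovery experiment isolates one statistical property of the method with
tight planted truth; the algorithms themselves are size-agnostic.

## Known limitations

* The NB Wald stand-in has no dispersion shrinkage: at very low counts or
  $n < 5$ per group it loses power relative to DESeq2, and its null
  calibration is verified at $n = 10$.
* Hypergeometric overlap statistics treat gene calls as exchangeable draws;
  correlated genes (co-expression!) make the p-values optimistic. The
  package reports them as published work does, but the recovery tests judge
  point estimates, not these p-values.
* Eigengene correlations are attenuated by module noise and TPM
  compositionality; on small panels with dominant modules the attenuation is
  visible (quantified above).
* The reaction-activity score is one number per reaction per sample; no
  meta-reactions, no exchange-bound calibration, no parity claim with any
  particular genome-scale implementation's defaults.
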