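---
title: "Methods: mining significant random signatures and diffusing their genes over a network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining significant random signatures and diffusing their genes over a network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randsig)
```

## The problem

Many published breast-cancer outcome signatures are no more associated with
survival than random gene sets of the same size: on a typical cohort a large
share of *random* signatures stratify patients with a significant
Cox/log-rank p-value, because any signature that brushes against an
outcome-relevant expression module (proliferation being the classic example)
inherits its signal.  `randsig` turns this nuisance into an inference
device.  Instead of discarding significant random signatures, it mines tens
of thousands of them, keeps the ones that are significant by *both* a
nominal and a permutation-based empirical criterion, counts how often each
gene occurs in the survivors, smooths those counts over a weighted
protein–protein interaction network, and calls the genes whose smoothed
scores are larger than chance.  The output is a ranked list of genes that
the random signatures keep "finding" — candidate outcome-relevant genes.

## Signature-level inference

For a signature $G$ and a cohort with expression $e_{g,p}$ and survival
$(t_p, \delta_p)$:

1. **Stratification.** Samples are split at the median of the first
   principal component of the signature submatrix (gene-wise mean-centered,
   unscaled, PC1 by SVD).  PC1 is defined only up to sign, so the package
   canonicalizes the sign deterministically (the sample deviating most from
   the median score gets a positive deviation); the resulting *partition*
   is invariant to negating the data, to the SVD implementation's sign
   convention, and — by the median rule — to affine rescaling.  Samples
   exactly at the median go to the low group; a split that empties either
   group is an error.
2. **Nominal p-value.** The two-group survival difference is tested with
   the Cox score test, which for one binary covariate is the log-rank
   test.  This flavor was chosen because it is closed-form and cannot fail
   to converge on the hundreds of thousands of permuted fits the pipeline
   performs; it is validated against `survival::survdiff` in the test
   suite.
3. **Empirical p-value.** The outcome labels are permuted `n_perm` times
   (default 1000) and the nominal p recomputed each time.  The observed p
   joins the permutation family (size $m = n_\mathrm{perm} + 1$), the whole
   family is Benjamini–Hochberg adjusted together, and the empirical p is
   the fraction of permutation adjusted p-values at or below the observed
   adjusted p-value.  The BH step-up is implemented from its recursion
   $p^{BH}_{(i)} = \min(p_{(i)} m / i,\; p^{BH}_{(i+1)})$ and checked
   against `stats::p.adjust` to $10^{-12}$.

A caveat that matters for interpretation: BH adjustment is monotone but not
*strictly* monotone — it produces plateaus of tied adjusted values.  With
the tie-inclusive "equal or less" count, a null observed value that lands in
a plateau counts every tied permutation, so under the null the empirical p
is far from uniform (mass piles up near 1) and the 0.05 tail holds only
about 2% instead of 5%.  The empirical p is therefore a *conservative*
screen, which is exactly the role it plays in the selection step; the test
suite asserts this actual behavior rather than an idealized uniformity.

## Mining random signatures

For each template signature (a published signature, or a synthetic
stand-in), `n_random_per_template` random signatures of identical size are
drawn uniformly without replacement from the cohort's gene universe and
evaluated as above.  A random signature is **selected** when

$$\text{empirical } p \le 0,\qquad \log_{10}(\text{nominal } p) \le -10,$$

both thresholds non-strict and configurable.  The log threshold is read as
base-10; at the defaults a signature must beat every permutation after
adjustment *and* have nominal $p \le 10^{-10}$.  Selection is idempotent,
order-independent, and monotone in both thresholds.

## Network diffusion and gene calling

Each gene's **occurrence score** $S_i$ counts the selected signatures
containing it.  Scores are smoothed with the heat (diffusion) kernel of the
weighted graph Laplacian $H = D - W$:

$$K_\beta = e^{-\beta H}, \qquad S_\beta = K_\beta S,$$

with $\beta = 0.3$ by default.  Two numerical notes:

* **Kernel sign.** The exponential of $+H$ amplifies high-degree structure
  and diverges with graph size; the Kondor–Lafferty diffusion kernel is the
  exponential of the *negative* Laplacian, which is what the package
  implements.  $K_\beta$ is symmetric, entrywise non-negative and doubly
  stochastic, so diffusion conserves total score mass (checked to
  $10^{-8}$), and $\beta \to 0$ recovers the raw scores.
* **Realization.** $K_\beta$ is built by eigendecomposition of the
  symmetric Laplacian, which is exact to machine precision (it agrees with
  an independent dense Padé matrix exponential to $10^{-14}$ on
  200-node graphs) and comfortably handles the few-thousand-node networks
  this package targets.  Genes absent from the network are isolated nodes:
  their kernel row is the identity, they keep their raw score, and they
  remain eligible for calling.

Significance of $S_\beta(j)$ is assessed by permutation: the score vector
is permuted across genes, re-diffused, and the **permutation score** of
gene $j$ is the fraction of the `n_perm` permuted diffusion scores at
position $j$ that are $\ge S_\beta(j)$ (non-strict).  By default the
*diffused* vector is permuted and diffused again, following the printed
formulation of the source method; `null_mode = "raw-scores"` permutes the
raw occurrence vector instead — the more conventional null — and is exposed
because the original formulation is ambiguous on this point.  Genes with
permutation score strictly below $\alpha = 0.05$ are called significant and
ranked by permutation score, then diffusion score (descending), then gene
id.  An exhaustive-enumeration mode (all $n!$ permutations, $n \le 8$)
backs the Monte-Carlo scores in the test suite.

## Pathway scores

For a pathway $P$ and the called set $SG$, with $P_{SG} = P \cap SG$ and
phenotype groups $N$ (good prognosis) and $\sim N$ (poor), each patient
$p_k \in \sim N$ receives

$$\mathrm{score}_N^{p_k}(P) = \sum_{g \in P_{SG}} e_{g,p_k}\,
  (e_{g,p_k} - \mu_N(g))^2, \qquad
  \mathrm{score}_{\sim N}^{p_k}(P) = \sum_{g \in P_{SG}} e_{g,p_k}\,
  (e_{g,p_k} - \mu_{\sim N}(g))^2,$$

expression-weighted squared deviations from the phenotype means.  The
weights are the expression values themselves, so the module requires a
non-negative expression scale; if negatives are present the matrix is
shifted by its global minimum (logged).  The two score arrays live on the
same patients, so the separation test defaults to a paired two-sided
t-test on the per-patient differences; an unpaired Welch option is exposed
because the source description does not state the pairing.

**Limitation (inherited from the score definition).**  The scored patients
belong to $\sim N$, so their own expression enters $\mu_{\sim N}$ but not
$\mu_N$; even with no phenotype effect,
$E[(e - \mu_N)^2] \approx \sigma^2(1 + 1/|N|)$ while
$E[(e - \mu_{\sim N})^2] \approx \sigma^2(1 - 1/|\sim N|)$.  The paired
difference therefore has a positive mean under the null and the test is
anti-conservative: its p-values should be read as a relative ranking of
pathways, not as calibrated error rates.  The test suite asserts this
offset's existence explicitly.

## Rank-sum inference

The exact Wilcoxon rank-sum machinery is self-contained: the null
distribution of the Mann–Whitney count statistic $W \in [0, nm]$ is built
by the standard partition-count recurrence and validated against both
exhaustive enumeration and `stats::dwilcox`.  One-sided tests read the tail
matching the stated alternative; ties trigger a midrank normal
approximation with tie and continuity corrections.  A bootstrap variant
resamples both groups with replacement and reports all replicate p-values
and their median.  For reference, the exact upper tail at $W = 75$ with
$n = m = 10$ is $0.0315064$; a published analysis of that configuration
printed $0.03191$, which is what a tie-corrected normal approximation
yields on tied data, so the two agree only to about two significant
figures.

## The synthetic generator

`synthetic_spec()` defines the study conditions every stage is exercised
under, chosen once to mirror an NKI-scale breast-cancer study compressed to
desk scale:

| parameter | default | why |
|---|---|---|
| `n_genes` × `n_samples` | 500 × 200 | desk-scale stand-in for ~13k genes × 295 patients |
| `n_driver_genes` | 25 (5%) | an outcome-relevant module is a small fraction of the genome |
| `driver_correlation` | 0.8 | tight co-expression module (shared latent factor) |
| `hazard_effect` | 1.0 | log-hazard per unit of the module factor; strong but not saturating |
| `censoring_rate` | 0.3 | typical overall-survival censoring |
| `mean_degree`, `weight_range` | 4, [0.4, 0.9] | sparse scale-free interactome with mid-to-high confidences |
| `template_sizes` | 10, 20, 35, 50 | the size range of published outcome signatures |

Survival is linked to the *latent module factor*, not to individual genes,
so a random signature gains signal exactly in proportion to how strongly
its PC1 picks up the planted module — the premise of the whole method.
Under these conditions only signatures with unusually high driver overlap
reach nominal $p \le 10^{-10}$, reproducing the selective regime in which
the source study operated (a few percent of random signatures selected);
early exploratory settings with a pervasive module (10% drivers, hazard
1.5) let most random signatures pass, which flattens the occurrence scores
and defeats the method — realism here *is* selectivity.  The generator
does not emulate microarray platform noise, batch effects, probe-level
preprocessing, or biologically structured networks beyond preferential
attachment, so passing tests demonstrate the machinery and its statistical
mechanism, not performance on real cohorts.

Everything is seed-deterministic: one master seed is fanned out by a Lehmer
step (`derive_seed`) to each stage and each signature, so reruns are
byte-identical and parallel evaluation stays reproducible.

## Problem sizes used in the checks

The packaged checks run the kernel oracle at 20–200 nodes, exhaustive
permutation enumeration at ≤ 7 genes against 20,000 Monte-Carlo draws,
null-cohort calibration with 200 signatures × 200 permutations on a
150 × 100 cohort, and five replicate end-to-end studies at the full
500 × 200 study conditions with 250 random signatures per template and 100
permutations per stage — sizes at which the end-to-end planted-driver
recovery is stable (median AUROC well above 0.9) while a full check pass
stays under a minute of compute.

## Known limitations

* The empirical p-value is conservative and non-uniform under the null
  (BH plateau ties); its 0.05 tail holds ~2%.
* The pathway separation test is anti-conservative under the null (own-group
  shrinkage); use its p-values comparatively.
* The kernel is realized densely via eigendecomposition; networks beyond a
  few thousand nodes would need an action-based exponential, which this
  package does not implement.
* The dual selection thresholds (0, −10) are tuned to cohorts of a few
  hundred samples; much smaller cohorts cannot reach nominal
  $p \le 10^{-10}$ and need a relaxed `log10_nominal_threshold`.
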