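---
title: "Methods: sequential CpG panel selection and neural-network classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential CpG panel selection and neural-network classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

## The problem and the model

Tumor tissue carries aberrant DNA methylation, measurable on the Illumina
450k array as per-CpG beta values $\beta = M/(M+U) \in [0,1]$. Human
methylation is strongly bimodal — most CpGs sit near 0 or near 1 — which
justifies hard-calling a site *methylated* when $\beta \ge 0.3$ and
*unmethylated* below. `methpanel` exploits that binarization twice: once to
make decision-tree splits trivial (every site is a ready-made binary test),
and once to make the classifier's inputs robust to measurement noise.

The pipeline is deliberately sequential, with each stage consuming the
previous stage's output:

1. **Cleaning.** Probes with the unmapped-position sentinel `*` are removed
   first (these account for the bulk of missing beta values in 450k
   exports). Then CpG *sites* with more than 15% missing values are
   discarded, and only then *patients* with more than 15% missing values
   over the remaining sites. Sites go first because a cohort has thousands
   of times more sites than patients, so a site costs less information. The
   order is observable: removing a bad site lowers the missingness fraction
   of the patients that carried it. Both comparisons are strict (an entity
   at exactly 15% survives); the tests pin this boundary and the ordering on
   a seven-patient toy where the two orders provably disagree.
2. **Imputation.** Remaining NAs become the arithmetic mean of their site's
   observed values, pooled over the whole cohort (both classes of the
   tissue). Note the mean is computed *before* the data split — faithful to
   the reference procedure, but a mild train/test leak; users wanting strict
   hygiene can split first and impute per partition with the exported
   building blocks.
3. **Split.** A seeded uniform permutation assigns round(0.70 n) samples to
   training, round(0.20 n) to validation, and the remainder (~10%) to test.
   Round-to-nearest for the first two with the remainder to test is the
   unique simple rule reproducing the reference partition sizes for
   n = 439/484/542 (307/88/44, 339/97/48, 379/108/55). The split is
   unstratified by default (a `stratify` flag exists). The test partition is
   tagged and quarantined: `train_network()` refuses it, and only
   `evaluate_test()` reads it.
4. **Panel selection.** On the binarized training data, a depth-2 decision
   tree is grown: the root split maximizes information gain under the
   base-2 node entropy $H = -p_N\log_2 p_N - p_C\log_2 p_C$ (0 for a pure
   node, 1 for an even mix; $0\log 0 = 0$), and each impure child is split
   once more, so one tree supplies a primary separating CpG and up to two
   mistake-correcting secondary CpGs. Trees are fitted repeatedly with a
   growing exclusion mask over already-selected sites; the loop stops at the
   end of the first run reaching 10 sites (hence 10–12 in practice), or
   early when no split with positive gain remains.
5. **Panel refinement.** For each selected site the cancer/normal medians
   and sample SDs are computed on *continuous* values of the pooled
   training + validation samples, and the separation score
   $-\frac{(\tilde\beta_C - c)}{s_C}\cdot\frac{(\tilde\beta_N - c)}{s_N}$
   (cutoff $c = 0.3$) is attached. The score is positive exactly when the
   medians straddle the cutoff; sites with non-positive or undefined
   (zero-SD) scores are excluded but recorded.
6. **Classification.** A feed-forward network with sigmoid activations
   throughout ($S(x) = 1/(1+e^{-x})$) and a single output unit scoring the
   Cancer class is trained by full-batch gradient descent on the binarized
   panel features of the training partition. Validation performance is
   reported by the fit; the test partition is scored once at the end.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cutoff` | 0.3 | beta | standard methylated/unmethylated threshold for bimodal human methylomes |
| `site_na_thresh`, `patient_na_thresh` | 0.15 | fraction | strict ">" filters, sites before patients |
| `fractions` | 0.70/0.20/0.10 | fraction | train/validation/test; reproduces the reference sizes |
| `min_panel` | 10 | sites | cost/accuracy trade-off for a clinically measurable panel; no hard cap, so runs end with 10–12 |
| `max_runs` | 50 | runs | safety stop for degenerate inputs |
| `arch` | "A" = (7,4) | neurons | presets B = (10,10), C = (5,4,3) |
| `lr0`, `decay` | 1, 0.001 | — | learning rate $lr_0/(1+k\,\mathrm{epoch})$, "slowly decreasing"; see below |
| `epochs` | 3000 | epochs | enough for all three presets to leave the plateau and converge on a ~10-feature binary panel |
| `tol` | 1e-9 | loss | early stop when the loss improvement falls below it |

The learning-rate defaults deserve a note. With the shallower presets almost
any slowly decaying schedule converges, but the three-hidden-layer preset
(5,4,3) is prone to the classic sigmoid plateau: with small initial weights
the output saturates at the class base rate and gradients vanish before the
schedule has done any work. A slower decay ($k = 0.001$) with $lr_0 = 1$
reliably moves all three presets to near-zero training MSE on panels of this
size; this was verified across several generator seeds before freezing the
defaults. Weight initialization is i.i.d. uniform(−0.5, 0.5), seeded. The
loss is mean squared error by default — pairing naturally with the "easy
gradient" motivation for the sigmoid — with cross-entropy behind
`loss = "cross_entropy"`.

## What the synthetic cohort emulates

`cohort_config()` defaults define the package's reference study conditions:
200 cancer and 120 normal samples (cancer outnumbering normal, as in public
tumor repositories), 2000 CpG sites of which 15 are planted informative
sites, 1% base missingness, and 10 "bad" sites plus 3 "bad" patients with
30% missingness each.

* **Bimodality.** Background sites draw from a two-component beta mixture
  (Beta(1.5, 8) and Beta(8, 1.5), weight 0.5). Each background site commits
  to one component — real uninformative CpGs are stably unmethylated or
  methylated across a cohort — so binarized background features are
  label-independent Bernoulli noise (about 17% minority calls), giving the
  selection trees realistic negative controls.
* **Planted signal.** Informative sites draw cancer and normal values from
  Beta(8, 2) versus Beta(2, 8) (medians ≈ 0.82 / 0.18, checked exactly via
  the beta quantile function to straddle 0.3). The direction follows the
  tissue tag: bladder/kidney cohorts plant hypomethylation in cancer,
  prostate hypermethylation, mirroring the tissue contrast the method was
  developed on. With ~20% of normal samples crossing the cutoff at any one
  informative site, a single site is a good-but-imperfect separator — which
  is exactly what makes the depth-2 correction structure and the masked
  iteration observable in tests.
* **Missingness.** Base-rate NAs are i.i.d. per cell; bad sites/patients
  receive an exact count $\lceil r\,m\rceil$ of missing cells so their NA
  fraction strictly exceeds the 15% threshold by construction (the
  configuration requires `na_rate_bad` > 0.15). Bad sites are drawn from the
  background only, so the filters have guaranteed work without destroying
  the planted signal.

What it does **not** emulate: covariate structure (age, smoking, cell-type
composition), batch or project effects, spatially correlated probes,
missing-not-at-random mechanisms, and class-dependent missingness. Passing
tests therefore demonstrate algorithmic correctness and end-to-end behavior
under clean, strongly separated conditions — not clinical performance on
real cohorts, where signal strength, confounding and cohort heterogeneity
are far less favorable.

## Numerical choices and degenerate inputs

* Entropy uses base-2 logarithms (forced by the stated 0–1 range; natural
  logs would peak at 0.693) and defines $0\log 0 = 0$.
* Information-gain ties at a tree node break to the lowest column index —
  deterministic and order-stable under the lexicographic site ordering.
* Leaf majority ties predict Cancer (the screening-safe side).
* A root with no positive-gain site raises a classed
  `methpanel_no_informative_split` condition; the selection loop converts it
  into an early stop with a warning.
* Separation-score SDs use the sample (n−1) convention; zero-SD sites are
  excluded with an `NA` score rather than scored against an epsilon. The
  retention rule is strictly positive: a zero score means a median sits
  exactly on the cutoff, which the median-side rule cannot classify.
* If refinement excludes every selected site (a signal-free cohort), the
  fit keeps the unrefined panel with a warning instead of failing, so null
  behavior (AUC ≈ 0.5) remains observable.
* The sigmoid is computed branch-wise to avoid overflow and clamped to the
  open interval (0, 1) so log-losses and ROC thresholds stay finite.
* ROC curves place one point per distinct score (ties grouped) and
  integrate trapezoidally; this equals the pairwise-concordance definition
  with half credit for ties, which the tests verify to 1e−9.
* PCA QC is mean-centered, unscaled, computed on continuous values of the
  train+validation samples only, with each component's sign fixed so its
  largest-magnitude loading is positive.

## Open design decisions

Where the procedure was genuinely under-specified, the package chooses once
and documents here: imputation happens before the split (faithful, slightly
leaky; building blocks allow split-first); selection trees see training data
only by default (`select_with_validation` exists because the original
description is ambiguous); separation statistics pool training + validation
(matching the reported figure/table provenance); the panel loop has no hard
cap at 10 because interdependent sites argue against truncation; networks
consume binarized panel values (binarization happened "prior to
processing"), with continuous inputs available by passing an unbinarized
matrix to the building-block functions.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
cohorts of 320 samples × 2000 sites for end-to-end checks (about 3 s for a
full fit), 100 samples × 300–600 sites for module tests, and toy matrices of
a handful of rows for the hand-verifiable oracles (worked gain example,
finite-difference gradients, concordance AUC). These sizes were chosen so
the full suite exercises every stage, including all three network presets,
in well under a minute of CPU each.

## Known limitations

Mean imputation before splitting leaks information between partitions;
depth-2 trees cannot express three-way interactions; the masked selection is
greedy and order-dependent, so the panel is *a* good panel, not a global
optimum; full-batch training assumes cohort sizes in the hundreds; and AUC 1
on the quarantined test partition of a strongly separated synthetic cohort
says nothing about external validity on real tissue, where independent
validation cohorts are indispensable.
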