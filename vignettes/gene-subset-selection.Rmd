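---
title: "Wrapper gene-subset selection with a binary quantum-behaved swarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper gene-subset selection with a binary quantum-behaved swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmselect)
```

## The problem

Two-class expression studies — a few dozen samples, thousands of genes —
need classifiers built on *small* gene subsets: small subsets generalize
better, are cheaper to assay, and keep their biological interpretability.
`swarmselect` treats subset selection as a combinatorial optimization over
0/1 strings (bit *j* = 1 means gene *j* is in the subset) and searches that
space with a binary quantum-behaved particle swarm optimizer (BQPSO),
scoring every candidate subset by the leave-one-out cross-validated (LOOCV)
accuracy of an RBF-kernel SVM trained on it. Sigmoid binary PSO and a
canonical genetic algorithm are included as baselines so the three search
strategies can be compared under identical conditions.

## The model and its pieces

### Prefilter

Wrapper search over all genes is hopeless and unnecessary: the search space
is first reduced by a classifier-independent filter. Each gene row is
z-scored (mean 0, sd 1 across samples; constant rows map to zeros), a
pooled-variance two-sample *t*-test compares the classes per gene, and the
50 genes with the smallest p-values become the search space, fixing the
particle length at 50. "Traditional t-test" is realized as the Student
(pooled) test; Welch is available via `t_test_rank(var_equal = FALSE)`. Ties
in p-value are broken by original gene index so rankings are deterministic.

Two protocol choices deserve flagging. First, normalization and filtering
use **all** samples, including every future LOOCV test sample; this leaks
label information into the gene ranking, and LOOCV accuracies downstream
are therefore optimistic estimates of generalization. This is the
classical single-pass protocol of wrapper gene-selection studies, and the
package keeps it because every reported accuracy is defined relative to
it; moving the filter inside folds would change every number. Second, no
multiple-testing correction is applied — the test is used only to rank.

### The BQPSO search

Positions are bitstrings; the distance is the Hamming distance $d_H$. Per
iteration:

1. **Mean best** — `mbest` is the per-bit strict majority over all
   particles' personal bests; exact ties are drawn uniformly (p = 0.5),
   freshly each call.
2. **Local attractor** — for particle *i*, a one-point crossover of
   `pbest_i` and `gbest` (cut uniform among the $l-1$ interior positions,
   one of the two offspring kept uniformly at random). Every bit of the
   attractor comes from one parent, so it always lies *between* the
   parents: $d_H(P, pbest) + d_H(P, gbest) = d_H(pbest, gbest)$.
3. **Jump length** — $b = \lceil c_e \cdot d_H(X_i, mbest) \cdot
   \ln(1/\mu) \rceil$ with $\mu \sim U(0,1)$ drawn on the open interval
   (avoiding $\ln(1/0)$) and the ceiling applied to the full product so
   $b$ is an integer; $b = 0$ exactly when the particle sits on `mbest`.
4. **Mutation** — the new position is the attractor with every bit flipped
   independently with probability $\Pr = \min(b/l, 1)$. Independent
   per-bit *flips* (not resampling to a random value) give expected
   displacement $l \cdot \Pr \approx b$, which is what makes the jump
   length mean what it says; resampling would halve the displacement.

Far from `mbest` the mutation probability is large (exploration); as the
personal bests agree, $d_H$ to `mbest` shrinks and so does the perturbation
(exploitation). When all personal bests and the global best coincide at
*s*, the swarm is at a fixed point: `mbest = s`, the attractor is *s*,
*b* = 0, and mutation is the identity.

### Baselines

*BPSO*: real-valued per-bit velocities with inertia 0.5, cognitive and
social coefficients 2 and 2, clamped to ±6; each bit is set to 1 with the
logistic sigmoid of its velocity as probability. *GA*: generational,
fitness-proportional (roulette) selection with one-point crossover
(p = 0.9), per-bit mutation (p = 0.04), elitism 1. Roulette weights are the
scores shifted by the population minimum; an all-equal population falls
back to uniform selection. The GA selection scheme is not forced by any
external contract, so roulette was chosen as the plainest "original
version", with tournament selection available by configuration; elitism 1
guarantees the monotone best-so-far trajectory the other two optimizers get
from their pbest/gbest bookkeeping.

### The objective

$$\mathrm{fitness}(X) = 0.6 \cdot \mathrm{accuracy}(X) +
  0.4 \cdot \frac{50}{|X|}$$

where accuracy is the LOOCV percent accuracy of an RBF-SVM on the selected
genes and $|X|$ the subset size. Accuracy enters on the **percent** scale
(0–100): with fractional accuracy the size term (range 0.4–20) would swamp
the accuracy term, inverting the intent that accuracy takes precedence.
One LOOCV error on 40 samples costs 1.5 fitness points, while shrinking a
7-gene subset to 5 gains only ~1.1, so the search never trades accuracy for
size until accuracy is maxed. The all-zero position is assigned the
sentinel score $-\infty$ so it can never become a personal or global best
while any non-empty subset exists.

The SVM is `e1071::svm` — R's binding of libsvm — with cost 1,
$\gamma = 1/(\text{selected features})$, `scale = FALSE` (libsvm's own
defaults; the pipeline has already normalized genes, and disabling the
binding's extra rescaling keeps the classifier identical to raw libsvm).
A training fold degenerating to a single class predicts that sole class.
Fitness values are memoized by position within each run: the SVM fit is
deterministic, so caching changes nothing but runtime, and the evaluation
counter still counts logical fitness calls (`swarm × iterations` plus the
initial swarm).

## The synthetic study condition

Real microarray collections are not bundled; all tests and benchmarks run
on `simulate_expression()`, which emulates the statistical shape the
wrapper assumes: a genes × samples matrix of i.i.d. Gaussian noise
(sd `noise_sd`) with `n_informative` genes shifted by
±`effect_size`·`noise_sd`/2 per class (class-mean difference =
`effect_size` sd). The default condition is 20 + 20 samples, 500 genes, 5
planted genes at effect 2 — chosen as a desk-scale analogue of a
60-sample/2,000-gene colon-cancer-shaped dataset: the 2-sd effect makes
each planted gene individually strong (per-gene t ≈ 6 at n = 40) yet keeps
single genes imperfect classifiers, and 500 genes give the t-filter a
realistic multiple-testing burden. Class imbalance (e.g. `c(22, 40)`) is
supported to exercise unequal LOOCV folds.

What the generator does *not* emulate: gene–gene correlation, heavy tails,
batch effects, or probe-level artifacts. Passing tests therefore show the
machinery is correct and the method behaves as designed under its own
assumptions — not that it will rank genes correctly on any particular real
platform.

An honest property of this condition worth knowing: because the prefilter
sees all samples, the top-50 space contains noise genes whose *in-sample*
discrimination is inflated by selection. Minimal subsets reaching 100%
LOOCV therefore usually mix two or three planted genes with such noise
genes — and since the objective strictly rewards smaller subsets at equal
accuracy, those mixed subsets *beat* the all-planted subset's score. Full
recovery of every planted gene in the single best subset is not an
equilibrium of this objective and should not be expected of it.

## Numerical and protocol choices

- **Repeated-run protocol**: each algorithm is run `repeats` times
  (default 25) with seeds `base_seed … base_seed + repeats − 1`; the report
  gives best, mean, and standard deviation of the per-run best LOOCV
  accuracies, the mean subset size over **all** runs, and per-gene
  selection counts over the runs attaining the maximum accuracy.
- **Standard deviation**: population form (denominator *n*) over the
  per-run accuracies; the sample form would differ slightly and the choice
  is asserted by a recomputation test.
- **Ties**: incumbent personal/global bests are retained on exactly equal
  scores (reproducibility); ranking ties break by gene index; frequency
  ties break by gene identifier.
- **RNG**: one seeded stream per run drives every stochastic draw, in a
  fixed order (initialization, then per iteration: mbest ties, crossover
  cut, offspring choice, μ, mutation mask — per particle). Runs restore
  the caller's RNG state.
- **Stopping**: fixed iteration budget only; the contraction–expansion
  coefficient stays constant (its single benchmark value is 1) over all
  iterations.
- **Problem sizes in the test-suite**: operator checks use 10,000-draw
  Monte Carlo; optimizer-vs-enumeration checks use 10-bit problems (1,024
  states, 20 seeds); the pipeline recovery check runs the full 20 × 100
  search on the standard 40 × 500 condition with 5 repeats, and the
  report-shape check uses a reduced 10 × 10 search budget. These sizes
  keep each property statistically meaningful at desk scale.

## Known limitations

- LOOCV accuracy after an all-sample prefilter is an optimistic,
  selection-biased estimate; treat reported accuracies as internal search
  criteria, not generalization estimates.
- On landscapes with no exploitable structure (e.g. random fitness
  tables), all three metaheuristics reduce to stochastic samplers, and
  finding the exact global optimum within 2,020 evaluations of 1,024
  states is a coverage lottery (≈ 86% even for an idealized duplicate-free
  sampler) — the swarm's value shows on structured objectives, not there.
- Multi-variable particle layouts are supported structurally (operators
  apply per substring) but the application uses a single 50-bit variable.
- No SVM hyperparameter tuning, and no k-fold alternative to LOOCV.
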