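---
title: "Methods: simulating cytokine-mediated suppression of osteogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating cytokine-mediated suppression of osteogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnsim)
```

`grnsim` generates labelled synthetic expression data for a curated
cytokine–NF-κB–osteogenesis network and benchmarks two learners on it: a
graph-convolutional autoencoder and a feed-forward inflammatory-state
classifier. This vignette records the model, the parameter choices and the
design decisions in enough detail that a maintainer can tell which behaviour
is principled and which is a convention that could be revisited.

## The regulatory model

Every gene follows a first-order ODE with basal transcription, saturating
activation, multiplicative repression and linear decay:

$$\frac{dx_i}{dt} = \Big[\, b_i\,(1+u_i(t)) \;+\;
\sum_{j \in \mathrm{Act}(i)} w_{ji}\,
  \frac{x_j^{n}}{K_{ji}^{n} + x_j^{n}} \Big]
\prod_{k \in \mathrm{Inh}(i)} \frac{K_{ki}^{n}}{K_{ki}^{n} + x_k^{n}}
\;-\; d_i\,x_i .$$

Assumptions worth making explicit:

* **Activation is additive and saturating; repression is multiplicative.**
  Additive Hill activation is the standard GRN-simulator convention; the
  multiplicative repression bracket is required so that strong NF-κB
  activity can drive osteogenic production arbitrarily close to zero (the
  severe regime), which no additive formulation can do.
* **Repression strength is carried by the Hill constants, not the weight.**
  A consequence of the multiplicative form is that the `weight` of an
  inhibitory edge does not enter the dynamics; it remains meaningful as the
  signed adjacency entry consumed by the autoencoder. The robustness claim —
  perturbing coefficients by ±25–50 % never flips the suppression outcome —
  is therefore non-trivial only through the activation weights, and is
  tested that way.
* **No sustained oscillation.** The cytokine forcing surges during the first
  6 h and then tapers monotonically; the transient spike-then-decline this
  produces matches the intended kinetics, and no oscillation period or
  amplitude is available to calibrate anything richer.
* **Expression units are arbitrary.** Only relative statements (fold
  changes, plateaus) are calibrated.

### Conditions and the forcing profile

The three conditions differ only in the forcing $u(t)$ applied to the basal
rate of cytokine-role genes: control has $u \equiv 0$; inflammatory holds
$u = A$ (default $A = 14$, a 15-fold induction over the healthy baseline)
until 6 h and then decays with a 120 h half-life — a *partial* taper that
stays above $A/4$ throughout the experiment; resolution switches to a
four-fold faster decay at 24 h.

**Pre-activated initial state.** Under forced conditions the cytokine
initial levels are raised to 90 % of their forced steady state
(`preactivation = 0.9`). This models cells placed into an already-inflamed
milieu: an inflamed sample is cytokine-high from the first measurement, and
the residual 10 % gap still produces the acute rise to a peak inside the
0–12 h window. Without pre-activation the two conditions would be
numerically identical at $t = 0$ (the initial condition knows nothing about
the condition), which contradicts both the biology of chronic periodontitis
and the severe-regime summary table this generator reproduces, and would cap
any classifier at ~90 % accuracy purely through the shared $t=0$ samples.

### Parameter presets

Defaults are $K = 1$, $n = 2$ on every edge except where noted. The
committed constants were calibrated once, by coarse search on the
*unperturbed* deterministic system, against the reference outcomes each preset is meant to reproduce, and are
not tuned per seed:

* **Cytokines** (IL1B, TNFA, IL6; decay 0.5 h⁻¹): healthy level ~0.12,
  forced plateau ~1.8, giving five-time-point inflammatory means near 1.7.
  IFNG and IL17 get the same forcing with lower basal rates (plateaus ~1.55
  and ~0.7) and carry weaker edges into NFKB1.
* **NFKB1** (moderate: basal 0.20, decay 0.6 h⁻¹, cytokine weights
  0.12/0.12/0.12/0.03/0.06): control level ~0.34, inflamed ~0.86, i.e. a
  2–3-fold induction.
* **Osteogenic markers** (RUNX2 0.8, SP7 0.07, ALPL 0.5, BMP2 0.4; decays
  0.12–0.18 h⁻¹): control plateaus of 3–5 units, with the RUNX2→SP7/ALPL
  cascade edges at $K = 3$ to match that scale. The moderate NF-κB
  repression then yields inflamed/control fold-factors of 0.6–0.7 at
  24–48 h. Running the osteogenic arm at a higher expression scale than the
  cytokines is deliberate: under the noise law below, the relative error of
  a condition mean is $\sqrt{c/x}/\sqrt{20}$, so the reference 0.6–0.7 band
  is a *stable* statistic of a 20-trajectory dataset only when osteogenic
  expression is well above one unit. Strongly induced differentiation
  markers exceeding the cytokine plateau is also the biologically natural
  ordering.
* **Severe preset**: NFKB1 becomes fast and strong (basal 0.8, decay
  1.2 h⁻¹, cytokine weights 5/5/5/1.2/2.5) and the repression edges steepen
  to $K = 0.3$, $n = 4$, so the inhibition bracket collapses within minutes
  and the osteogenic summary means stay below 0.01 — including the brief
  production transient before NF-κB saturates, which is what the default
  $K = 1, n = 2$ repression cannot achieve at any sane NFKB1 level.

### Numerics

`deSolve::ode` (lsoda) with `rtol = 1e-8`, `atol = 1e-10`; sampled values
are clamped at zero (the dynamics are nonnegative, the clamp only removes
round-off excursions). The tolerances are tighter than the integration
accuracy actually needed because the test suite holds the solver to the
linear birth–death closed form at ≤ 1e-6 *relative* error globally, and a
1e-6 local tolerance does not guarantee that. Cost is irrelevant at 10
genes. Solutions are deterministic; all stochasticity enters through edge
perturbation (upstream) and noise/dropout (downstream).

## Noise and dropout

Measurement noise is $y = \max(0, x + \varepsilon)$,
$\varepsilon \sim N(0, c\,x)$ with $c = 0.05$: variance proportional to
expression, zeros exactly preserved. The clamp biases means upward at low
expression (for $x$ near zero, $E[y] \approx \sigma\phi(0) > x$); this is
accepted and is why near-zero severe-regime means are reported as "below
0.01" rather than exactly zero.

Dropout zeroes each entry of gene $g$ independently with probability
$p_g = \min(0.9,\; s/(1+\mu_g))$ — the simplest bounded form that is
strictly decreasing in the gene's mean expression. The scale $s$ is
calibrated by bisection (the expected zero fraction is monotone in $s$) to a
target of 0.175, the midpoint of the realistic 15–20 % sparsity band. The
zero-inflated-negative-binomial idea is honoured as zero inflation on top of
a continuous signal; the ODE output is not count data, so no negative
binomial is fitted. Noise is applied first, dropout second: dropout emulates
a detection failure of the measured (noisy) signal. Both orders are
defensible; this one was fixed once.

## Datasets, splits and reports

`build_dataset()` draws 20 independently perturbed networks per condition
(weights multiplied by $1+U(-0.25, 0.25)$), integrates each, samples
0/6/12/24/48 h, then applies noise and calibrated dropout — 100 samples per
condition, 20 per condition–time. Whether the original protocol re-used one
trajectory per condition–time with 20 noise draws or drew 20 independent
trajectories is ambiguous; independent trajectories are the more honest
noise model and are used here.

* **Fold changes** use pre-dropout values when available, otherwise means
  over non-masked entries. Dropout is missing-completely-at-random within a
  gene column (the probability depends only on the column mean), so
  mask-exclusion is an unbiased estimate of the pre-dropout mean, while
  including technical zeros would bias every condition mean downward by its
  dropout rate. `fc_on_masked = TRUE` restores the naive behaviour. The
  ratio is ε-stabilised (ε = 1e-6) so log2 stays finite in the severe
  regime.
* **Summary tables** (`condition_summary`) follow the same exclusion policy,
  for the same reason: statistics of the expression *regime*, with dropout
  treated as a technical artifact. The `count = 5` convention is read as statistics over the five
  per-time-point condition means — the only interpretation consistent with
  the tight cytokine spreads of the severe reference regime.
* **DEG calls** use |log2FC| ≥ 0.5 (not the conventional 1.0) so that the
  0.6–0.7 suppression factors themselves qualify; no significance test is
  attached because none is defined for this generator.
* **Splits** (`trajectory_split`) partition trajectory ids stratified by
  condition: all five time points of a trajectory land on one side, so no
  temporal leakage is possible.

## The graph autoencoder

Node features are the per-(condition, time) mean expression of each gene
(d = 10 columns for the default two-condition design), standardised per
feature. The encoder is $Z = \hat A\,\mathrm{relu}(\hat A X W_1) W_2$ with
$\hat A = D^{-1/2}(max(|A|,|A|^T)+I)D^{-1/2}$; the decoders are a linear
feature readout $\hat X = Z W_\mathrm{dec}$ and an inner-product edge
decoder $P = \sigma(Z Z^T)$. The loss is
$\mathrm{MSE}(\hat X, X) + \lambda\,\mathrm{BCE}(P, \mathbf 1[A_\mathrm{gae}
> 0])$ with $\lambda = 1$; training is 100 full-batch Adam steps at learning
rate 0.005 from fan-in-scaled uniform initialisation, deterministic given
the seed. The variational variant is out of scope — no KL term is described
for this setting — and BCE against the binarised known adjacency is the
chosen reading of "a graph regularisation term that preserved known
connections" (the alternative, Laplacian smoothing, regularises embeddings
rather than preserving connections). The 16-dimensional latent space is
overcomplete for 10 genes; it is retained deliberately, with the graph term
preventing a trivial identity map.

**A known limitation, quantified.** Under this training budget the feature
reconstruction error plateaus far above the reference value of ~0.01: around 0.23
after 100 epochs, and around 0.05 even with fifty times the budget. The
target is *representable* — a rank-4 linear readout of the standardised
features reaches MSE below 0.01 — but 100 full-batch Adam steps at lr 0.005
bound each weight's total movement by roughly 0.5, and the factored layers
start in a small-scale regime where early gradients are products of small
terms. Data-dependent initialisations (least-squares, ridge, truncated-SVD
and spectral variants) and lazy-regime widths were all evaluated and either
bias the fit or destabilise joint training along the weak eigendirections of
$\hat A$. The package reports the error actually achieved rather than
adopting an initialisation that would make the number true by construction.
Relatedly, the reconstructed-degree hub ranking is dominated by NFKB1 (the
mediator connected to every other gene) and by the osteogenic module, whose
minority position under per-column standardisation inflates its embedding
norms; the inflammatory cytokines cluster tightly (silhouette well above
zero against the osteogenic genes) but do not reach the top of that
particular centrality score.

Sample embeddings project each standardised sample onto the gene embeddings,
$s = Z^T x / n_\mathrm{genes}$; two-means clustering of these recovers the
condition labels well above chance (the suite asserts > 0.75 agreement), with
the residual confusion concentrated where biology puts it, at early time
points. Latent-dimension enrichment ranks genes by absolute loading per
dimension and scores gene-set overlap among the top 3 with a hypergeometric
upper tail — a generic substitute for annotation-database enrichment, which
is out of scope.

## The classifier

Input is the per-sample 10-gene expression vector — time is deliberately not
a feature, so the same decision surface must work across all five time
points. Architecture: two rectified hidden layers (32, 16), logistic output,
binary cross-entropy, Adam at 0.001 for 100 epochs. Three choices matter:

* **Minibatched epochs** (batch 32, seeded reshuffle): one full-batch step
  per epoch would leave the scores unsaturated after 100 epochs, and
  individual borderline samples would then flip between training seeds.
* **Input-dropout augmentation** (rate 0.1): during training, entries are
  randomly reset to the standardised value of a raw zero, mirroring the
  generator's dropout mechanism. Converged networks otherwise disagree
  across seeds on rare many-zeros samples — the region is simply
  underdetermined by the training data — and with a 40-sample test split a
  single flip is 2.5 percentage points, more than the under-2-point
  seed-to-seed variability this benchmark targets. Augmentation makes the decision on such samples
  a property of the data rather than of the seed.
* **Fixed validation carve-out** (`val_seed`, trajectory-exclusive, 20 % of
  training trajectories): retraining with a new seed varies only the
  stochastic optimisation, never which rows were fitted.

Evaluation is pooled over all test time points (the stricter reading,
since a per-time evaluation would let the classifier specialise), at a fixed 0.5 threshold, with the rank-based (Mann–Whitney)
AUROC. With this generator's condition separation the classifier is at or
near ceiling: accuracy ≥ 95 % with at most one borderline error on a
40-sample split, which also means the F1 score typically exceeds the
reference ~0.95 rather than matching it.

## What the generator does and does not emulate

It emulates: condition- and time-structured mean expression driven by a
known signed network, cell-to-cell regulatory variability,
expression-proportional measurement noise, and expression-dependent technical
zeros at a realistic overall rate. It does **not** emulate: count data or
library-size effects, batch effects, gene-length bias, single-cell bursting,
delays or spatial structure, more than one mediator layer, or real biological
variability between donors. Tests passing on this generator therefore show
that a method can recover strong, cleanly separated network-driven signal
under noise and missingness — not that it will perform equally on real
transcriptomes, where the inflammatory–osteogenic separation is weaker and
confounded. External-cohort validation is intentionally out of scope; `predict_labels()` is the entry point for scoring any user-supplied
matrix over the same gene panel.

## Problem sizes used by the test suite

Unit tests run the generator at 2–4 trajectories per condition–time; the
acceptance checks use the full study design (20 per condition–time, 100
samples per condition; severe preset inflammatory-only) with the
autoencoder and classifier trained at their default budgets. The complete
pipeline runs in seconds on one CPU.
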