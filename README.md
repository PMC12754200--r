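# grnsim

Synthetic transcriptomics of cytokine-mediated suppression of stem-cell
osteogenesis.

Chronic inflammation in periodontitis impairs the osteogenic differentiation
of periodontal ligament stem cells (PDLSCs): IL-1β and TNF-α activate NF-κB,
which represses bone-forming genes such as *RUNX2* and *ALPL*, while IL-6
plays a context-dependent double role. `grnsim` is a desk-scale benchmark
generator and analysis toolkit for this system, aimed at people who want
labelled, biologically structured expression data to develop or stress-test
network-aware machine-learning methods:

* a curated 10-gene regulatory network (five cytokines, the NFKB1 mediator,
  four osteogenic markers) with signed, weighted Hill-kinetics edges;
* an ODE simulator of the 0–48 h osteogenic induction time course under
  control, inflammatory and resolution conditions;
* a noise model (expression-proportional Gaussian noise plus zero-inflated
  dropout calibrated to 15–20 % sparsity) that turns clean trajectories into
  realistic expression matrices;
* a two-layer graph-convolutional autoencoder (16-dimensional latent space)
  over the known network, with silhouette separation, reconstructed-graph hub
  scores and hypergeometric latent-dimension enrichment;
* a feed-forward classifier separating inflammatory from control samples,
  evaluated on trajectory-exclusive splits with a rank-based AUROC.

## The model

Each gene *i* follows a first-order regulatory ODE

```
dx_i/dt = [ b_i (1 + u_i(t)) + Σ_j w_ji x_j^n / (K_ji^n + x_j^n) ]
          · Π_k K_ki^n / (K_ki^n + x_k^n)  −  d_i x_i
```

with basal transcription `b_i`, first-order decay `d_i`, additive saturating
(Hill) activation over incoming activating edges *j*, multiplicative Hill
repression over incoming inhibitory edges *k*, and an external forcing
`u_i(t)` applied to cytokine-role genes only: an acute surge during the
first 6 h followed by a partial exponential taper (a faster decay after 24 h
in the resolution condition). Per-sample variability enters by multiplying
every edge weight by `1 + U(−f, f)` (default f = 0.25); measurement noise is
`N(0, c·x)` (default c = 0.05) clamped at zero; dropout zeroes each entry of
gene *g* with probability `min(0.9, s/(1+μ_g))`, with `s` calibrated by
bisection so the expected zero fraction hits a target (default 0.175).

Two presets are calibrated to two reference regimes: `"moderate"` (RUNX2 and
ALPL suppressed to 0.6–0.7 of control at 24–48 h, NFKB1 induced 2–3-fold)
and `"severe"` (cytokines plateau near 1.7 expression units while the
osteogenic program is shut down almost completely).

## Worked example

```r
library(grnsim)

ds <- build_dataset(seed = 42)      # moderate preset, control + inflammatory
ds
#> Synthetic expression dataset: 200 samples x 10 genes
#>               time_h
#> condition       0  6 12 24 48
#>   control      20 20 20 20 20
#>   inflammatory 20 20 20 20 20
#> dropout: 16.6% of entries zeroed (scale 0.3575)

fc <- fold_change(ds, 48)           # inflamed vs control at 48 h
fc[fc$gene %in% c("IL1B", "NFKB1", "RUNX2", "ALPL"), ]
#>   gene time_h mean_control mean_inflamed  ratio log2_ratio
#>   IL1B     48        0.126         1.519 12.011      3.586
#>  NFKB1     48        0.352         0.748  2.124      1.087
#>  RUNX2     48        3.948         2.591  0.656     -0.607
#>   ALPL     48        4.747         3.192  0.672     -0.573
```

The cytokines are strongly induced, NFKB1 roughly doubles, and the
osteogenic markers fall to ~0.65 of control — a 30–40 % suppression.
`identify_degs(fc)` calls all five inflammatory genes plus NFKB1 up and all
four osteogenic markers down at |log2FC| ≥ 0.5.

```r
sp  <- trajectory_split(ds, 0.2, seed = 7)   # whole trajectories held out
clf <- train_classifier(sp$train, seed = 1)
evaluate(clf, sp$test)
#> accuracy 1.000 | precision 1.000 | recall 1.000 | F1 1.000 | AUROC 1.000 (n = 40)
#> confusion: TP=20 FP=0 TN=20 FN=0

g <- train_gae(ds, default_network(), seed = 1)
g
#> Graph autoencoder: 10 genes -> 16 latent dimensions
#>   final loss 0.8533 (feature MSE 0.2358, adjacency BCE 0.6175) after 100 epochs
latent_separation(g$Z, c("IL1B", "TNFA", "IL6"), c("RUNX2", "ALPL"))
#> [1] 0.7
```

The latent space separates the inflammatory and osteogenic modules cleanly
(silhouette 0.7). See the methods vignette
(`vignettes/grn-simulation-methods.Rmd`) for the model's assumptions,
parameter choices and known limitations — including why the feature
reconstruction error plateaus well above zero under this training budget.

A thin command-line front end over the same functions ships in
`inst/cli/grnsim.R`:

```sh
Rscript inst/cli/grnsim.R dataset --preset moderate --seed 42 --out data/
Rscript inst/cli/grnsim.R report --in data/ --out report/
```

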