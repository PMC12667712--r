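---
title: "Joint imputation and deconvolution of paired SRT slices: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint imputation and deconvolution of paired SRT slices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siid)
```

## The problem

Spatially resolved transcriptomics (SRT) platforms trade off spatial
resolution against gene coverage. A targeted in-situ platform (we use
"Xenium" as shorthand throughout) measures a few hundred genes at
single-cell or subcellular resolution; a spot-array platform ("Visium")
measures the whole transcriptome, but each ~55 µm spot mixes several cells.
When both assays are run on adjacent sections of the same tissue and the
sections are registered into a common coordinate frame, each high-resolution
spot can be matched to the low-resolution spot it falls into. This package
exploits that pairing to do two things at once:

* **imputation** — predict, at every high-resolution spot, the expression of
  genes that are absent from the targeted panel but measured by the
  whole-transcriptome slice; and
* **deconvolution** — estimate, for every low-resolution spot, the mixture
  proportions of latent expression programs (intended to correspond to cell
  types), without any single-cell reference.

## Data model

A slice is a pair $(A, S)$: a spots × genes count matrix
$A \in \mathbb{N}^{|S| \times |G|}$ and 2-D coordinates
$S \in \mathbb{R}^{|S| \times 2}$ in micrometers. We are given
$(A_X, S_X)$ with panel $G_X$ and $(A_V, S_V)$ with panel $G_V$, where
$G_X \subset G_V$, plus a binary mapping
$\Gamma \in \{0,1\}^{|S_X| \times |S_V|}$ with $\Gamma[i,j] = 1$ when
high-resolution spot $i$ contributes to low-resolution spot $j$. Each row of
$\Gamma$ has at most one nonzero; `build_mapping()` constructs it by
matching each high-resolution spot to its nearest low-resolution spot within
100 µm (Euclidean distance, ties broken toward the lowest spot index so
results are order-stable). Registration itself is out of scope: coordinates
must already share a frame.

Both observed slices are treated as Poisson samples of one latent
high-resolution, whole-transcriptome expression matrix with a rank-$h$
nonnegative factorization. In count-scaled form the means are

$$\bar A_X = \mathrm{diag}(N)\, P\, Q_X, \qquad
  \bar A_V = M^{\mathsf T} P\, Q\,\mathrm{diag}(\phi),$$

where

* $P \in \mathbb{R}_{\ge 0}^{|S_X| \times h}$, rows summing to 1: each
  high-resolution spot's composition over latent factors;
* $Q \in \mathbb{R}_{\ge 0}^{h \times |G|}$, rows summing to 1: each
  factor's normalized expression profile over the modeled gene universe;
* $N \in \mathbb{R}_{> 0}^{|S_X|}$: the latent total counts of each
  high-resolution spot over the whole universe;
* $M \ge 0$ with $M \circ (1 - \Gamma) = 0$: the count mass each
  high-resolution spot contributes to its mapped low-resolution spot
  ($M = \mathrm{diag}(N) K$ for mixing weights $K$);
* $\phi \in \mathbb{R}_{>0}^{|G|}$ (optional, `platform_scaling = TRUE`): a
  gene-wise factor absorbing platform-specific capture efficiency on the
  low-resolution slice, fixed at $\phi_j = 1$ for genes outside the training
  panel to avoid non-identifiability.

`raw_to_scaled()` / `scaled_to_raw()` convert between this form and a plain
NMF $WH$ (the two parameterizations represent exactly the same mean
matrices; the count-scaled one is what the optimizer uses, because $N$, $P$,
$Q$ are individually interpretable).

The training objective is

$$\mathcal{L} = \mathrm{PoiLoss}(A_X;\ \mathrm{diag}(N) P Q_X)
 + \mathrm{PoiLoss}(A_V;\ M^{\mathsf T} P Q\,\mathrm{diag}(\phi))
 + \omega_k \left(-\textstyle\sum_{ij} P_{ij}\log P_{ij}\right)
 + \mu \textstyle\sum \theta^2,$$

with $\mathrm{PoiLoss}(Y;Z) = \sum (Z - Y \log Z)$ the Poisson negative
log-likelihood up to a data constant, $\omega_k = \exp(k/\lambda)$ an
entropy weight growing with the epoch index $k$, and $\mu$ an $\ell_2$
penalty on the *raw* parameters $\theta$ (see below). $Q_X$ is the column
submatrix of $Q$ over the genes actually used for high-resolution training.

## Parameterization and optimization

All constraints hold by construction rather than by projection or penalty:
$P$ and $Q$ are row-softmaxes of unconstrained logit matrices; $N$, $M$ and
$\phi$ are exponentials of unconstrained log-parameters; and $M$'s
log-parameters exist only on the support of $\Gamma$, so
$M \circ (1-\Gamma) = 0$ exactly. The $\ell_2$ penalty
(default $\mu = 10^{-5}$) applies to those raw parameters, including
$\phi$'s log-parameters when platform scaling is on.

Optimization is Adam (standard moment decays 0.9/0.999, $\epsilon=10^{-8}$)
with learning rate 0.05 for 5000 epochs by default and no early stopping;
gradients are the analytic derivatives of the objective above. Because NMF
losses are non-convex and sensitive to initialization, the fit is restarted
three times by default (restart $r$ seeded with `seed + r - 1`, logits and
log-parameters initialized i.i.d. Normal(0, 0.1)) and the restart with the
lowest final loss is returned; `restart_losses` records all of them.
Identical seeds give bitwise-identical fits.

Numerical choices:

* the Poisson log term uses `log(pmax(Z, mean_floor))` with
  `mean_floor = 1e-8`; the floor applies only inside the log, and the
  gradient uses the matching epsilon-smoothed form `1 - Y / pmax(Z, floor)`,
  which keeps a restoring force if a reconstructed mean underflows;
* the entropy term uses the natural log and its weight
  $\omega_k = \exp(k/\lambda)$ is left uncapped — with the default epoch
  budgets this reaches at most $e^{10}$ and did not need clipping;
* softmaxes subtract the row maximum before exponentiating;
* a non-finite loss aborts the fit with the offending epoch in the message.

## Entropy schedule

The entropy penalty $-\sum P \log P$ pushes each high-resolution spot toward
a single dominant factor. Its weight starts at 1 (epoch 0) and grows
exponentially, so early training is dominated by the likelihood and the
one-hot pressure only takes over near the end. Smaller $\lambda$ means
stronger end-of-training pressure. Suggested settings, exposed in
`siid_config()`: $\lambda = 1000$ when the goal is imputation (the Poisson
terms stay dominant) and $\lambda = 500$ for deconvolution and simulation
studies; `lambda_entropy = NULL` disables the term entirely.

## Imputation, deconvolution, assignment

For a fitted model, `impute(model, genes)` returns
$\mathrm{diag}(N) P Q_g$ — the latent mean, with no $\phi$ applied, since
imputed values live on the high-resolution platform's scale. Holdout genes
are removed from $Q_X$ during training but keep their $Q$ columns, which the
low-resolution loss informs; that is exactly what makes holdout imputation
possible, and their $\phi$ stays fixed at 1 because they are outside the
trained panel. `deconvolve_visium()` returns row-normalized
$M^{\mathsf T} P$; spots with no mapped cells have no support and are
returned as zero rows with an `empty_spots` flag rather than an error.
`assign_cell_types()` is the per-row argmax of $P$ with low-index
tie-breaking.

## Synthetic paired data

`simulate_pair()` emulates the ingredients of a paired experiment at a
configurable scale:

* low-resolution spots on a square lattice with 100 µm pitch (the pitch of
  common spot arrays), high-resolution spots uniform over the same domain,
  and $\Gamma$ built with the 100 µm nearest-spot rule — so nearly every
  cell maps, with occasional unmapped cells near partial lattice rows;
* a checkerboard cell-type layout: the bounding box is cut into
  `grid_side`² cells and grid cell $(r, c)$ gets type
  $(r + c) \bmod h$, which guarantees edge-adjacent grid cells always differ
  for any $h \ge 2$;
* type profiles drawn from a symmetric Dirichlet (default concentration
  0.3, giving sparse, well-separated programs; pairs with cosine similarity
  ≥ 0.95 are resampled so types stay distinguishable);
* per-cell UMI totals drawn log-normal around `base_umi` (default 150,
  a realistic per-cell transcript count for a targeted panel), multiplied by
  the coverage fraction `coverage` ($\rho$) to emulate shallower or deeper
  assays;
* high-resolution counts Poisson-sampled from
  $\rho \cdot \mathrm{umi}_i \cdot \mathrm{profile}_{t(i)}$ over the whole
  transcriptome, with the observed slice restricted to a random targeted
  panel; low-resolution counts formed by *exact summation* of mapped cells'
  latent counts (no re-sampling), so count conservation is an integer
  identity;
* ground-truth mixtures weight each mapped cell by its expected total
  $\rho \cdot \mathrm{umi}_i$, matching the count-mass meaning of $M$.

A real paired experiment differs in ways the generator deliberately does not
model: profiles come from real cell types rather than a Dirichlet; cells are
not spatially uniform nor type-pure in a checkerboard; the two sections are
different slices of tissue rather than one latent matrix observed twice;
platform effects (which $\phi$ exists to absorb) and registration error are
absent; and low-resolution counts are a fresh measurement, not an exact sum.
Passing the simulation checks therefore demonstrates correct inference under
the model's own generative assumptions — identifiability, optimizer
adequacy, and the end-to-end plumbing — not performance on real tissue data,
where reported holdout accuracies are far lower.

Simulated pairs model the full simulated transcriptome
(`gene_universe` = all genes), so out-of-panel genes are imputation targets.
For real data `align_panels()` defaults the universe to the targeted panel —
out-of-panel low-resolution genes carry platform effects the model only
absorbs via $\phi$, so they are discarded unless explicitly requested.

## Holdout evaluation and baselines

`make_folds()` shuffles the sorted panel with a seed and deals it
round-robin into folds of near-equal size; `holdout_evaluate()` refits with
each fold removed from the training panel, imputes the fold, and scores each
gene by the squared Pearson correlation
$\mathrm{cov}^2(x,y)/(\sigma_x^2 \sigma_y^2)$ against the held-out observed
counts, averaging over all panel genes. A constant vector (e.g. an all-zero
holdout gene) scores 0 with a `constant_input` flag instead of erroring, so
aggregation never aborts.

Four mapping-only baselines calibrate these scores. Baseline A copies each
cell's mapped low-resolution value, split equally among the cells mapped to
that spot (the equal split conserves count mass; a straight copy would
inflate it). Baseline B splits proportionally to each cell's observed panel
total, computed over the panel genes *not* being imputed so the holdout
protocol stays honest, with an equal-split fallback for spots whose totals
are all zero. Baselines C and D smooth A and B by averaging over the
`k_neighbors` (default 10) spatially nearest cells, self included.
Deconvolution quality is scored by the Jensen–Shannon divergence (natural
log, bounded by $\ln 2$) between predicted and true mixtures after matching
factors to types greedily on the cosine-similarity matrix of the two
labelings; clustering agreement uses the pair-counting adjusted Rand index.

## Problem sizes used by the package's own checks

The test suite and `scripts/acceptance.R` exercise the model on simulated
pairs with 3 cell types, 60 high-resolution spots, 12 low-resolution spots,
30 genes (panel 20), coverage 0.25–2, 2000 epochs, and 1–3 restarts (3 for
single fits, 2 per fold inside the 4-fold holdout loops, 1 per arm of the
entropy comparison), across 3 seeds. These sizes make every check a
from-scratch refit while each complete run stays in the minutes range. At
this scale the fits recover the true Poisson mean with $R^2 > 0.9$ and
deconvolved mixtures with mean JS divergence well under 0.05, and holdout
imputation clearly separates the model from the mapping baselines with the
expected monotone improvement in coverage.

## Limitations

The likelihood is Poisson; overdispersed or zero-inflated counts are not
modeled. $\Gamma$ is taken as given and binary — mapping noise propagates
directly into $M$. The number of factors $h$ is a configuration knob, not
inferred. Platform differences are modeled only as gene-wise multiplicative
scaling on the low-resolution slice. The optimizer runs a fixed epoch
budget; no convergence diagnostics beyond the recorded loss history are
applied.
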