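---
title: "Predicting drug-combination response surfaces with structured-output kernel regression"
author: "surfaceKR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-combination response surfaces with structured-output kernel regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfaceKR)
```

# The problem

Combination screens measure the response of a cell line to two drugs
dosed together on a small rectangular concentration grid — typically 3x3
to 7x2 wells per (cell line, drug pair) triplet. Because the number of
triplets grows combinatorially with the drug panel, most screens measure
only a fraction of the possible surfaces, and predictive models are needed
to prioritise untested combinations. Single-value predictors (of a synergy
score, or of the response at one concentration pair) discard the
surface structure; `surfaceKR` instead predicts the *entire continuous
dose-response surface* of a query triplet, from which responses at any
dose pair and any synergy score can then be read off.

# The surface model

Monotherapy behaviour of one (cell line, drug) pair is summarised by the
four-parameter Hill curve

$$E(d) = e_0 + (e_\max - e_0)\,\frac{d^{n}}{\mathrm{EC}_{50}^{\,n} + d^{n}},$$

with baseline $e_0$, asymptote $e_\max$, half-effect concentration
$\mathrm{EC}_{50}$ (same units as the doses, typically µM) and slope
$n > 0$. Responses are percent growth or viability; internally everything
is computed on the unit scale and `[0, 100]` data are rescaled at ingest.

A two-drug surface is modelled with the BRAID family (Bivariate Response
to Additive Interacting Doses): the two Hill curves plus an interaction
pair $(\kappa, \delta)$. Writing $x_i = (d_i/\mathrm{EC}_{50,i})^{n_i}$,
$F_i = (E_{f,i}-E_0)/(E_f-E_0)$ and
$\tilde D_i = F_i x_i / (1 + (1-F_i) x_i)$ for each drug, with
$h = \delta \sqrt{n_A n_B}$,

$$\mathbb{D} = \tilde D_A^{1/h} + \tilde D_B^{1/h}
  + \kappa \sqrt{\tilde D_A^{1/h} \tilde D_B^{1/h}}, \qquad
E(d_1, d_2) = E_0 + (E_f - E_0)\,\frac{\mathbb{D}^{h}}{1 + \mathbb{D}^{h}}.$$

$\kappa = 0,\ \delta = 1$ gives the additive surface: a drug combined
with itself then satisfies the Loewe sham identity exactly, and each axis
reduces exactly to its monotherapy curve. $\kappa > 0$ behaves
synergy-like, $-2 < \kappa < 0$ antagonism-like. We take the shared
baseline $E_0$ as the mean of the two monotherapy baselines and the
overall asymptote $E_f$ as the monotherapy asymptote furthest from
$E_0$; a drug whose effect points away from $E_f$ is treated as inert on
that surface.

```{r}
hA <- HillCurve(e0 = 1, emax = 0.2, ec50 = 0.5, n = 1.5)
hB <- HillCurve(e0 = 1, emax = 0.35, ec50 = 1.2, n = 2)
bs <- BraidSurface(hA, hB, kappa = 2, delta = 1)
braidResponse(bs, d1 = c(0, 0.5), d2 = c(0, 1.2))
```

## Fitting, and why the interaction fit is regularised

`fitHill()` is a bounded Levenberg-Marquardt least-squares fit with a
deterministic multi-start over slopes $n_0 \in \{0.5, 1, 2, 4\}$ and the
EC50 initialised at the median positive dose; response bounds come from
the declared scale, and the EC50 is constrained to within a factor 100 of
the observed dose range. Flat data return a constant curve with a
`degenerate` flag.

`fitBraid()` holds the monotherapy curves fixed (the additive baseline
must share them) and fits only $(\kappa, \delta)$, as
$u = \log(\kappa + 2)$, $v = \log\delta$ with bounds matching the modelled
interaction range ($\kappa \in (-1.95, 10]$, $\delta \in [0.2, 5]$) and a
multi-start over a fixed $\kappa$ grid. Two safeguards address a real
identifiability problem: on a 4x4 grid with assay noise, $\kappa$ and
$\delta$ are nearly collinear, and an unconstrained fit happily trades an
extreme $\kappa$ against a compensating $\delta$.

* the $\kappa$-only ($\delta = 1$) and $(\kappa, \delta)$ fits are
  compared by BIC, so $\delta$ is freed only when the data support it
  (the same nested-model philosophy as the BRAID reference
  implementation);
* a noise-calibrated ridge pulls $(u - \log 2, v)$ toward neutrality,
  with weight $4\hat\sigma$ where $\hat\sigma$ is the residual standard
  deviation of the unpenalised fit. Exact (noise-free) surfaces are
  therefore fitted without bias — parameter recovery on noiseless 4x4
  grids is exact to machine precision — while weakly identified noisy
  surfaces shrink toward additivity instead of exploding.

# Surfaces as vectors: normalization and the output kernel

Kernel regression needs surfaces to live in one common space although
every drug pair has its own dose ranges. `normalizeSurface()` samples a
surface on a canonical 8x8 grid placed at fixed multiples
$\{1/64, 1/16, 1/4, 1/2, 1, 2, 4, 16\} \times \mathrm{EC}_{50}$ of each
drug's own potency, rescales responses to $[0, 1]$ and flattens row-major
into a length-64 vector. Potency-relative placement makes surfaces of
drugs with very different dose ranges comparable; it is this package's
concrete choice of normalization scheme.

Two regression targets are supported (`mode`):

* **direct** — the normalized surface itself;
* **difference** — the normalized surface minus the normalized additive
  surface of the same monotherapies ($\Delta$). Most combinations are
  close to additive, so the additive part carries no information the
  monotherapies do not already contain; regressing only $\Delta$ spends
  the model capacity on the interaction pattern, and the neutral surface
  is added back at prediction time. This is the default and the better
  choice in our experiments (see the ablation below).

The output kernel is a normalized RBF kernel on these vectors with
bandwidth $\sigma$ set to the mean pairwise distance (the standard
heuristic, `sigmaHeuristic()`).

## The Nyström output map

The RBF feature space is infinite-dimensional, so the output feature map
is approximated with landmarks: `generateLandmarks()` builds a
deterministic grid of BRAID surfaces — four Hill archetype pairs
(strong/weak efficacy, steep/shallow slope) crossed with
$\kappa \in \{-1.5, -0.5, 0, 0.5, 1.5, 3\}$ and
$\delta \in \{0.5, 1, 2\}$, 72 raw landmarks — and `buildNystromMap()`
eigendecomposes their Gram matrix, retaining eigenvalues $\ge 0.1$. The
induced map is
$\tilde\psi(y) = \Lambda_r^{-1/2} V_r^\top k(y, L)$; the retained rank is
the effective output dimension, and with the full spectrum retained the
embedding inner products reproduce the kernel exactly, which is how the
scaled-up model coincides with the exact kernel-trick formulation on
small data (this identity is tested). Landmark EC50s are irrelevant on
the potency-relative grid, so archetypes only span $(e_\max, n)$ shapes.
The retained landmark count depends on the landmark set and threshold; it
is a regularizer, not a contract.

# Input kernels and the sampled Kronecker solver

Inputs are triplets (cell, drug A, drug B). Drugs are described by
166-key MACCS substructure fingerprints (computed from SMILES via
OpenBabel) under the Tanimoto kernel; cell lines by continuous profiles
(expression, copy number) under an RBF kernel with the mean-distance
bandwidth, or by the delta kernel on identities when only ids are
available. The triplet kernel is the product
$k_c \cdot k_{d_1} \cdot k_{d_2}$, i.e. the training kernel matrix is a
*row-sampled* three-factor Kronecker product
$R\,(K_c \otimes K_d \otimes K_d)\,R^\top$ — sampled because screens
measure only some triplets.

`buildInputOperator()` pre-expands the smaller pairing explicitly
(cell-drug if there are no more cells than drugs, else drug-drug) and
represents the result implicitly; `kronMatvec()` applies it by the
generalized vec trick (scatter into a $b \times a$ matrix, two dense
products, gather), never materialising the full product. `solveKRR()`
runs plain conjugate gradients on
$(\mathrm{Op} + \lambda I)\,C = \tilde\Psi$ from a zero start.

Training is symmetrized: every surface enters under both drug orderings
(with the transposed normalized vector), and prediction solves one
pre-image problem whose objective sums both orderings' embeddings, which
makes `predict(c, d1, d2)` exactly the transpose of `predict(c, d2, d1)`.

## Regularization: iterations and the ridge constant

With zero initialisation the CG iteration count acts as a spectral
filter, and `crossValidate()` selects it over $\{3, 5, 10\}$ by held-out
Pearson correlation on surface-grouped folds. Early stopping is, however,
only an *effective* regularizer while the iteration budget is small
relative to the spectrum: at a few hundred training samples CG essentially
converges within 10 iterations, and with a vanishing ridge the model
interpolates its (noisy) fitted targets. The default ridge is therefore a
real one, $\lambda = 0.1$ — the midpoint of the standard
$[10^{-2}, 5\cdot 10^{-1}]$ grid used for kernel ridge regression with
normalized kernels — rather than a conditioning-only constant. At the
data sizes where the sampled-Kronecker solver is actually needed, smaller
values are appropriate and both knobs are exposed in
`surfaceKRConfig()`.

# The pre-image problem

Prediction yields an embedding $\tilde g(x)$; a surface must be recovered
from it — an ill-posed pre-image problem solved in one of two ways
(`solver`):

* **candidate** (`candidatePreimage()`): evaluate
  $\langle \tilde g(x), \tilde\psi(y_{\kappa,\delta})\rangle$ for BRAID
  candidates built from the query triplet's own monotherapy curves over a
  25-point log-symmetric $\kappa$ grid on $[-1.9, 8]$, and return the
  argmax. Ties prefer neutrality (smallest $|\kappa|$, then smallest
  index). The default candidate grid fixes $\delta = 1$: searching
  $\delta$ lets extreme $(\kappa, \delta)$ pairs mimic mild surfaces and
  turns the argmax into a variance amplifier; $\delta$ is still estimated
  by the surface fit wherever the data support it. The $\delta$ grid
  remains a config option.
* **pgd** (`pgdPreimage()`): maximise the same objective over the free
  64-vector of canonical-grid samples with Nesterov-accelerated Adam
  (Nadam; 200 steps, learning rate 0.05 annealed linearly, analytic RBF
  gradient), starting from the neutral surface (direct mode) or the zero
  function (difference mode), then *project* the end-result back to a
  valid surface by fitting the BRAID interaction parameters to it. If the
  projection errors or loses the ascent the descent achieved (scores
  below its own start), the candidate solution is returned instead. The
  Nadam hyperparameters are exposed in the config.

The four (mode, solver) pairs form the ablation grid, with the shorthand
constructor `ablationConfig("GD-Diff")` etc. In our synthetic
experiments, difference-mode targets beat direct targets for both
solvers, and gradient descent helps with difference targets while hurting
with direct ones — the direct-target objective landscape is dominated by
the monotherapy shape, and free-form ascent wanders before projection.

# Synergy scores

From any surface (measured or predicted), `surfaceSynergy()` computes a
per-surface score as the mean excess of a null model's expected response
over the observed response across the combination cells, positive =
synergy, in the surface's response units:

* **Bliss**: inhibition fractions combine independently,
  $f_{AB} = f_A + f_B - f_A f_B$, fractions clipped to $[0, 1]$;
* **Loewe**: the expected response solves the dose-equivalence equation
  $d_1 / D_A(y) + d_2 / D_B(y) = 1$ by bisection on the bracketed
  response range (tolerance $10^{-10}$, 200 iterations), with the inverse
  Hill curves $D_\cdot(y)$; a partial agonist that cannot reach $y$
  contributes no dose equivalent, and a flat curve none at all.

The additive BRAID surface is exactly Loewe-additive when the two Hill
curves share slope and maximal effect (then the equation is solvable in
closed form, which the tests compare against); for mismatched shapes it
is only approximately so — a known property of the surface family, not a
numerical artefact.

# Predictive scenarios and splits

`makeSplits()` builds surface-grouped folds for three scenarios of
increasing difficulty: **new combo** (random surfaces held out; all
entities seen), **new drug** (whole (cell, drug) pairs held out so every
test surface contains exactly one pair unseen with that cell line) and
**new cell line** (whole cell lines held out). `auditSplits()` verifies
the constraint on every fold and is exercised across seeds in the tests.
Monotherapy data are shared across folds: the baseline and the candidate
surfaces both require the query triplet's own Hill curves, which in
practice are cheap to measure; what is predicted is the interaction.
Unseen entities require features (not history) — predictions error
otherwise, naming the scenario.

# The synthetic data generator

`simulateComboData()` emulates the structure of the public combination
screens without downloads: per-(cell, drug) Hill curves with
log-uniform EC50 in $[0.01, 10]$ µM, slopes in $[0.5, 3]$, baseline 1 and
asymptotes in $[0, 0.6]$ on the unit scale; fixed per-drug dose ranges
around each drug's typical potency; binary fingerprints (density 0.3) and
continuous cell features; and a per-triplet $\kappa$ linked to the
features through a standardized bilinear form of the cell features and
the drugs' fingerprint difference, soft-thresholded so that roughly 70%
of triplets are near-additive ($|\kappa| < 0.3$) with heavier
synergy/antagonism tails — the empirical hallmark of real screens.
Responses are BRAID values plus Gaussian noise, clipped to scale. The
generator interaction uses $\delta = 1$; $\delta \ne 1$ shapes enter the
pipeline through landmarks and candidate/projection fits, not the truth.

The reference study conditions, used by the acceptance checks, are 5 cell
lines x 8 drugs on 4x4 grids with noise 0.05 and feature-linked
interactions; with three new-combo folds this gives 140 surfaces and
roughly 90 training surfaces per fold — deliberately desk-sized so the
whole pipeline runs in minutes on one CPU.

What the generator does *not* emulate: plate and edge effects, dose
misregistration, replicate heteroscedasticity, biologically structured
features, or interaction mechanisms beyond a smooth feature link. Passing
tests on it demonstrate internal consistency and learnability-by-
construction, not clinical performance.

# Numerical choices and degenerate inputs

* BRAID evaluation uses the logistic form
  $E = E_0 + (E_f - E_0)\,\mathrm{plogis}(h \log \mathbb{D})$, stable for
  $\mathbb{D} \in \{0, \infty\}$; infinite $x_i$ (huge doses) reduce to
  the correct asymptotes.
* Flat monotherapy pairs short-circuit to a constant surface; degenerate
  fits are flagged, and a both-flat interaction fit returns neutral
  parameters with a flag.
* The Nyström inverse square root is always the truncated one; the
  threshold 0.1 is the default regularizer and tiny thresholds recover
  the exact-kernel limit.
* Raw responses outside the declared scale are kept for fitting and
  evaluation; predictions are clipped to the scale bounds.
* CG stops early only at machine-level residuals; everything is
  deterministic, including the multi-starts, the landmark order, the
  Nadam trajectory and the tie-breaks (neutrality first).

# Known limitations

* The BRAID family cannot represent every empirical surface (e.g.
  non-monotone dose responses); projection onto it is part of the model.
* Pre-image decoding by argmax does not shrink: when the predicted
  embedding carries little signal, the decoded $\kappa$ is noise around
  neutrality rather than exactly neutral. The ridge default and the
  regularised interaction fit mitigate, but cannot eliminate, this.
* The additive baseline is extremely competitive on screens dominated by
  additive combinations; improvements concentrate in the synergy and
  antagonism tails, and pooled correlation margins over the baseline are
  accordingly modest.
* Cell-by-cell scope trains an independent model per cell line and
  cannot address the new-cell-line scenario.
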