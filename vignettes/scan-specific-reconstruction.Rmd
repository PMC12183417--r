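---
title: "Scan-specific parallel MRI reconstruction: models, training and metrics"
author: "pirecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-specific parallel MRI reconstruction: models, training and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirecon)
```

## The reconstruction task

In Cartesian parallel imaging (PI) a multi-coil 2-D acquisition samples a
complex k-space tensor $S(i, j, c)$ over $N_x$ readout points, $N_y$
phase-encoding lines and $N_c$ coils. Uniform undersampling acquires one ky
line out of every $R$, cutting scan time by (up to) a factor $R$; the missing
lines must be recovered from the redundancy between coils. Writing $T_R(m) =
\{m, m+R, m+2R, \dots\}$ for the line set of phase $m$, the acquired data is
the view $S_u(1)$ on $T_R(1)$ and the task decomposes into $R-1$ independent
subtasks, one per missing-line offset $m \in \{1, \dots, R-1\}$: predict the
line at distance $m$ above each acquired line. `pirecon` trains one model per
offset, **on the scan's own auto-calibration signals (ACS)** — a small fully
sampled central k-space block — so nothing is learned from external data.

The ACS can be *integrated* (taken from the accelerated scan itself, same
contrast; the measured ACS lines are kept in the output for data consistency)
or *separated* (a fast low-flip pre-scan; different echo time, hence
different magnitude and phase contrast). The separated mode is cheaper —
`reff_separated()` and `reff_integrated()` quantify the effective
acceleration after ACS overhead — but it stresses model generalization,
which is the central question the package's model comparison addresses.

## Model families

All three families are **bias-free convolutional interpolators in k-space**
whose ky taps address the decimated grid of acquired lines (taps are spaced
$R$ full-grid lines apart):

* **GRAPPA** — a single complex-valued convolution with kernel
  $(n_x, n_y)$ over all $N_c$ coils; a linear model. Weights come either
  from gradient training (`train_model()`, "GRAPPA(TVP)") or from the
  closed-form Tikhonov-regularized least-squares calibration
  (`fit_grappa_tikhonov()`, "GRAPPA(TR)").
* **rRAKI** — a three-layer real-valued CNN (the RAKI section) summed with a
  linear *GRAPPA short connection*. The complex input is split into $2N_c$
  real channels (real parts, then imaginary parts). Default layers:
  $[5,2,2N_c,32] \to [1,1,32,8] \to [3,2,8,2N_c]$, residual $[5,2]$.
* **crRAKI** — the complex-valued counterpart: every convolution is an exact
  complex multiply-accumulate implemented with two real kernels, default
  layers $[5,2,N_c,16] \to [1,1,16,32] \to [3,2,32,N_c]$, residual $[1,1]$.

The LeakyReLU negative slope $c \in [0,1]$ dials the nonlinearity:
$c = 0$ is a pure ReLU, $c = 1$ makes the whole model an exactly linear
operator. For complex activations we use the **split** form (LeakyReLU
applied to real and imaginary parts separately): it is the unique simple
choice that is exactly the identity at $c = 1$, which the linear limit
requires. Activations follow layers 1 and 2 only, the three-layer RAKI
convention; the final layer and the short connection stay linear.

### Geometric conventions

Convolutions are **valid-mode** (no padding) during calibration and
training: no k-space border data is fabricated when fitting. The target
sample sits at the kernel center along kx (all kx extents are odd) and at
$\lfloor (r_y - 1)/2 \rfloor$ acquired lines from the window start along ky,
where $r_y$ is the path's total ky receptive extent — for even extents the
target line falls between the two central taps. The same anchor constants
are applied in fitting and forward evaluation. When the two paths of a
residual model have different receptive fields, their outputs are cropped to
the common anchor support before summation.

At **prediction** time every missing line must be produced, including those
whose window would overrun the matrix. Because the image-domain product of
sensitivity and object corresponds to *circular* convolution of their
discrete spectra, the DFT grid is periodic, and the acquired-line stack is
extended circularly along kx (always) and along ky when $R \mid N_y$; the
border lines are then predicted exactly like interior ones. When
$R \nmid N_y$ the ky pad falls back to edge replication, an approximation
confined to the outermost lines. This choice is what lets the bandlimited
coil oracle (below) hold to $10^{-6}$ over the whole grid.

## Training on the ACS partition (TVP)

`build_tvp_pairs()` artificially undersamples the ACS into its $R$
phase-shifted views. For offset $m$, phase $p$ supplies input lines
$T_R(p)$ (ACS-local) and targets at distance $m$; $R-1$ pair-sets train and
the reserved one (the last, by default) validates. `train_model()` then
minimizes the weighted two-term loss

$$\mathcal{L} = \mathrm{MSE}(f(x), y) + \lambda\,\mathrm{MSE}(f_{\rm short}(x), y)$$

with full-batch Adam (learning rate $10^{-3}$ by default, at most 1000
epochs) after normalizing the ACS by its global 2-norm. The *linear*
variants use $\lambda = 0, c = 1$; the *nonlinear* ones $\lambda = 1, c = 0$.
Gradients are exact: the convolution stacks are expressed through an
im2col patch-matrix formulation, and the real and imaginary kernel parts are
treated as independent real parameters (for output $Z = PW$ and loss
gradient $G$ at the output, the kernel gradient is $P^H G$ and the input
gradient $G W^H$, with the split-activation mask applied between layers).
One batch is all sliding positions of all training pair-sets: at ACS scale
mini-batching buys nothing, and full-batch training is deterministic given
the initialization seed.

**Early stopping.** "Validation MSE increased for more than 20 consecutive
epochs" is read against the *running best* value: a counter of epochs
without a new best, reset on improvement, stopping when it exceeds the
patience. This matches the retained-best-epoch semantics (the weights
returned are always those of the epoch with the lowest validation MSE); the
alternative previous-epoch reading is available as
`train_config(stop_rule = "previous")`.

**Initialization.** Layer weights are zero-mean normal draws with standard
deviation $\sqrt{2 / n_{\rm in}}$ — He initialization with fan-in
$n_x n_y d_{\rm in}$, the standard deep-learning-framework default for
ReLU-family networks; complex kernels draw their two real kernels
independently.

**Inference scaling.** Models are trained in ACS-normalized units; at
reconstruction the undersampled data is divided by the *ACS* scale and the
prediction multiplied back (both live in the same acquisition units). This
is exact for linear models and is the convention for nonlinear ones.

## Hyperparameter selection

`enumerate_grid()` reproduces the candidate sets: 8 GRAPPA kernels, and for
the RAKI families the Cartesian product first layer $\{[5,2],[5,4]\}$ ×
hidden depths $\{32,16,8\}$ real ($\{16,8,4\}$ complex) for each of the two
hidden layers × third layer $\{[3,2],[3,4]\}$ × residual $\{[5,2],[1,1]\}$
— 72 configurations. `kfold_cv()` scores one configuration with $K = R$
folds: each TVP phase validates once, all offsets $m$ are trained, and the
validation k-space MSEs are averaged per (slice, fold) — the pooling level
across offsets is our choice of pooling level. Per-fold seeds
derive from the configuration id, so grid results are independent of
execution order.

`select_architectures()` takes the configuration with the lowest mean MSE
as best (ties broken toward fewer parameters) and screens the rest with a
one-tailed Welch t-test of "best < config": configurations *not*
significantly worse ($p \ge \alpha$) join the optimal set. (Defining the
optimal set as the configurations the best *does* beat would be the other
conceivable reading; it is statistically incoherent — it would keep the
provably worse ones — but the full p-value table is exposed so either
screening rule can be applied downstream.)
`linearity_ablation()` runs the $9 \times 2$ grid of
$c \in \{0, 0.01, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9, 1\}$ and
$\lambda \in \{0, 1\}$.

## Image metrics and COBRAI

Reconstructions are scored against the fully sampled ground truth after
coil combination (sum-of-squares, or sensitivity-weighted with low-pass
estimated sensitivities — a centered Hamming-tapered k-space window of
fractional width 0.25 per dimension, RSS-normalized with a $10^{-8}$
relative floor; the filter is our specification, none being stated).
NRMSE, NMAE, PSNR, SSIM (Gaussian-weighted 11×11, $\sigma = 1.5$,
population moments, data range = ground-truth maximum) and a no-reference
re-blur metric are standard. `brain_mask()` builds the evaluation mask by
Otsu thresholding, morphological closing, hole filling and largest
connected component.

**COBRAI** targets what those metrics miss: *structured* residual
artifacts. Both magnitude images are normalized by the ground-truth
maximum; the residual map is $RM = \hat{I} - I$. At every pixel the Pearson
correlation between the sliding $11 \times 11$ patch of $RM$ and the
co-located patch of $I$ is computed (dense, stride 1, like SSIM; the stride
is configurable since block-wise patches are also defensible); the COBRA
map holds $|r|$ and COBRAI is its mean over patch centers inside the mask,
guaranteed in $[0, 1]$. Conventions: patches with zero variance in either
operand score 0 (a flat residual carries no structured artifact); border
patches use the available pixels. For residuals independent of the ground
truth the per-patch $|r|$ is approximately half-normal with
$\mathbb{E}|r| \approx \sqrt{2 / (\pi \cdot 121)} \approx 0.073$, the
metric's noise floor — the test suite verifies this null level to ±20% and
that a shifted-copy ghost at matched RMSE always scores higher than iid
noise. `compare_methods()` applies the evaluation protocol: Shapiro–Wilk on
the paired differences, then a paired one-tailed t-test; when normality is
rejected the result is flagged and a one-sided Wilcoxon signed-rank p-value
is reported instead (the fallback convention is ours).

## The synthetic acquisition generator

`make_phantom()` builds piecewise-constant ellipse phantoms with per-tissue
relaxation rates, smooth polynomial phase and off-resonance maps;
`make_coil_maps()` produces either smooth Gaussian-lobe sensitivities at
equally spaced angles or **bandlimited** maps synthesized from random
spectra confined to a declared central k-space box;
`simulate_acquisition()` applies the forward model per echo time
($\mathrm{sens} \times M e^{-TE \cdot R_2^*} e^{i(\phi + TE\,\Delta\omega)}$),
a centered orthonormal 2-D DFT (chosen so Parseval holds exactly; no
convention being stated) and circularly symmetric complex Gaussian k-space
noise. Separated-mode contrast difference is emulated by simulating the
ACS source at a shorter echo time.

The bandlimited mode exists because of a useful theorem-like fact: with
noiseless data and coil spectra confined to a box no larger than the kernel
reach — and covering every ky residue class mod $R$, i.e. ky support
$\ge R$ — an exact linear interpolation kernel exists, so linear models
must reconstruct to numerical precision. This is the package's strongest
correctness oracle and is enforced in the test suite at $R = 2$ (and
checked for the closed form at $R = 4$ with ky support 4).

What the generator does *not* emulate: anatomy, Biot–Savart coil physics,
gradient-timing effects, motion, partial Fourier. Passing tests therefore
demonstrate algorithmic correctness and the contrast-generalization
mechanism, not clinical image quality.

## Desk-scale study sizes

The shipped tests run, deliberately, at desk scale: $64 \times 64$
matrices, 4–6 coils, 24–32 ACS lines, $R \in \{2, 4\}$, 10 synthetic slices
for the separated-mode model comparison, and up to a few thousand Adam
epochs for the exactness oracles (the convex GRAPPA problem benefits from a
larger learning rate, $10^{-2}$–$3\times10^{-2}$, than the default; the
oracle tests use it, with the short-connection loss anchoring the linear
path of crRAKI). These sizes are the package's own choices for fast,
deterministic verification; the algorithms are size-agnostic.

On those conditions the package reproduces the headline qualitative
finding: with separated-mode ACS (contrast mismatch between calibration
and scan), the *linear complex* crRAKI reconstructs with lower NRMSE and
markedly lower COBRAI than the *nonlinear real* rRAKI, and the paired
one-tailed protocol flags the difference — nonlinear scan-specific models
learn ACS-contrast features that do not transfer, while linear
coil-geometry kernels do.

## Known limitations

* Training is plain full-batch Adam in R; it is fast at ACS scale but not
  meant for 3-D or very large coil arrays.
* Deterministic full-batch Adam exhibits a small limit-cycle floor
  proportional to the learning rate; the exactness oracles choose the rate
  and epoch budget accordingly.
* Circular ky padding at prediction assumes $R \mid N_y$; otherwise the two
  outermost missing lines use replicated context.
* HDF5 interchange shells out to the environment's Python h5py (no R HDF5
  binding is available here); all numerical work is native R.
* Only uniform Cartesian undersampling is supported (no CAIPIRINHA,
  partial Fourier or non-uniform patterns).
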